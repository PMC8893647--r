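#' @keywords internal
"_PACKAGE"

# Canonical ordering of the seven molecular species. All counts are in units
# of 10^6 molecules; volumes in um^3; time in hours. Table-of-parameters
# coefficients apply verbatim under this convention.
STATE_NAMES <- c("A_C", "P_C", "RP_C", "R_C", "P_N", "RP_N", "R_N")

#' Molecular state of a single cell
#'
#' Bundles the seven molecular counts the growth model tracks: the free
#' cytoplasmic amino-acid pool, non-ribosomal proteins, free ribosomal
#' proteins and assembled mature ribosomes, the last three resolved into
#' cytoplasmic (`_C`) and nuclear (`_N`) pools. Counts are stored in units of
#' 10^6 molecules so that the shipped rate coefficients apply without unit
#' conversion.
#'
#' @param A_C Cytoplasmic free amino acids (10^6 molecules).
#' @param P_C,P_N Cytoplasmic / nuclear non-ribosomal proteins (10^6).
#' @param RP_C,RP_N Cytoplasmic / nuclear free ribosomal proteins (10^6).
#' @param R_C,R_N Cytoplasmic / nuclear mature ribosomes (10^6).
#'
#' @return A named numeric vector of class `"cell_state"` in canonical order
#'   `A_C, P_C, RP_C, R_C, P_N, RP_N, R_N`.
#' @examples
#' cell_state(A_C = 3200, P_C = 15, RP_C = 1.35, R_C = 0.135,
#'            P_N = 1.65, RP_N = 0.15, R_N = 0.015)
#' @export
cell_state <- function(A_C, P_C, RP_C, R_C, P_N, RP_N, R_N) {
  x <- c(A_C = A_C, P_C = P_C, RP_C = RP_C, R_C = R_C,
         P_N = P_N, RP_N = RP_N, R_N = R_N)
  validate_cell_state(x)
  structure(x, class = "cell_state")
}

#' @rdname cell_state
#' @param x A named numeric vector carrying all seven component names.
#' @export
as_cell_state <- function(x) {
  if (!all(STATE_NAMES %in% names(x)))
    stop("state must carry all of: ", paste(STATE_NAMES, collapse = ", "))
  y <- as.numeric(x[STATE_NAMES])
  names(y) <- STATE_NAMES
  validate_cell_state(y)
  structure(y, class = "cell_state")
}

validate_cell_state <- function(x) {
  if (any(!is.finite(x))) stop("cell state contains non-finite counts")
  if (any(x < 0)) stop("cell state counts must be non-negative")
  invisible(x)
}

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state>  counts in 10^6 molecules\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Compartment volumes from macromolecule counts
#'
#' The cytoplasmic and nuclear volumes are taken to be proportional to the
#' number of osmotically active macromolecules (proteins, free ribosomal
#' proteins, and ribosome particles) in each compartment, a consequence of
#' cellular ion/water homeostasis: `V_C = (P_C + R_C + RP_C) / r1` and
#' `V_N = (P_N + R_N + RP_N) / r2`. The free amino-acid pool equilibrates
#' with the ionic osmotic system and does not enter the volume law.
#'
#' @param state A [cell_state()].
#' @param params A [kinetic_params()] (only `r1`, `r2` are used).
#' @param require_positive If `TRUE`, signal an error when either volume is
#'   zero (degenerate state used as a divisor downstream).
#' @return Named numeric vector `c(V_C, V_N)` in um^3.
#' @examples
#' st <- yeast_state()
#' compartment_volumes(st, yeast_params())
#' @export
compartment_volumes <- function(state, params, require_positive = FALSE) {
  V_C <- (state[["P_C"]] + state[["R_C"]] + state[["RP_C"]]) / params$r1
  V_N <- (state[["P_N"]] + state[["R_N"]] + state[["RP_N"]]) / params$r2
  if (require_positive && (V_C <= 0 || V_N <= 0))
    stop("degenerate state: compartment volume is zero")
  c(V_C = V_C, V_N = V_N)
}
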