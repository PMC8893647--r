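PARAM_NAMES <- c("s1", "s2", "s3", "n1", "n2", "n3",
                 "t1", "t2", "t3", "t4", "t5",
                 "d1C", "d1N", "d2C", "d2N", "d3C", "d3N",
                 "r1", "r2")

#' Kinetic and stoichiometric parameters of the growth model
#'
#' All rate coefficients of the model, in units chosen so that counts in 10^6
#' molecules, volumes in um^3 and time in hours combine without conversion
#' factors.
#'
#' @param s1,s2 Non-ribosomal / ribosomal protein synthesis coefficients
#'   (um^3/10^6 h).
#' @param s3 Ribosome assembly coefficient (1/h).
#' @param n1,n2 Amino acids per non-ribosomal / ribosomal protein.
#' @param n3 Ribosomal proteins per mature ribosome.
#' @param t1 Amino-acid import coefficient in the rich regime (1/h); the
#'   effective uptake is `t1 * P_C`.
#' @param t2 Ribosomal-protein nuclear import coefficient (um^3/10^6 h).
#' @param t3 Ribosome nuclear export coefficient (um^3/10^6 h).
#' @param t4,t5 Non-ribosomal protein nuclear import / export coefficients
#'   (um^3/10^6 h).
#' @param d1C,d1N Non-ribosomal protein degradation coefficients (um^3/10^6 h).
#' @param d2C,d2N Ribosomal protein degradation coefficients (um^3/10^6 h).
#' @param d3C,d3N Ribosome disassembly coefficients (um^3/10^6 h).
#' @param r1,r2 Macromolecule-count-to-volume conversion factors (10^6/um^3)
#'   for cytoplasm and nucleus.
#' @return A list of class `"kinetic_params"`.
#' @seealso [yeast_params()], [mammalian_params()], [organism_params()]
#' @export
kinetic_params <- function(s1, s2, s3, n1, n2, n3,
                           t1, t2, t3, t4, t5,
                           d1C, d1N, d2C, d2N, d3C, d3N,
                           r1, r2) {
  p <- list(s1 = s1, s2 = s2, s3 = s3, n1 = n1, n2 = n2, n3 = n3,
            t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
            d1C = d1C, d1N = d1N, d2C = d2C, d2N = d2N, d3C = d3C, d3N = d3N,
            r1 = r1, r2 = r2)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1 ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad))
    stop("kinetic parameters must be positive finite scalars; bad: ",
         paste(names(p)[bad], collapse = ", "))
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Growth regime specification
#'
#' The model distinguishes three nutrient regimes. In the *rich* regime the
#' amino-acid uptake scales with the transporter proteome, `t1 * P_C`,
#' producing exponential growth. In the *poor* regime uptake saturates at a
#' constant `t1_bar`, producing asymptotically linear growth. The *quiescent*
#' regime additionally replaces every bimolecular degradation/disassembly
#' term with first-order decay at rate `d` and lowers the ribosome assembly
#' coefficient to `s3`, yielding a constant-volume fixed point.
#'
#' @param regime One of `"rich"`, `"poor"`, `"quiescent"`.
#' @param t1_bar Constant amino-acid uptake (10^6/h); required for poor and
#'   quiescent regimes, ignored in rich.
#' @param d First-order degradation/disassembly rate (1/h); quiescent only.
#' @param s3 Ribosome assembly coefficient override (1/h); quiescent only.
#' @return A list of class `"growth_mode"`.
#' @examples
#' growth_mode("rich")
#' growth_mode("quiescent", t1_bar = 2850, d = 0.8, s3 = 5)
#' @export
growth_mode <- function(regime = c("rich", "poor", "quiescent"),
                        t1_bar = NULL, d = NULL, s3 = NULL) {
  regime <- match.arg(regime)
  if (regime != "rich") {
    if (is.null(t1_bar) || t1_bar <= 0)
      stop(regime, " regime requires a positive constant uptake t1_bar")
  }
  if (regime == "quiescent") {
    if (is.null(d) || d <= 0) stop("quiescent regime requires d > 0")
    if (is.null(s3) || s3 <= 0) stop("quiescent regime requires s3 > 0")
  }
  structure(list(regime = regime, t1_bar = t1_bar, d = d, s3 = s3),
            class = "growth_mode")
}

#' @export
print.growth_mode <- function(x, ...) {
  cat("<growth_mode> ", x$regime, "\n", sep = "")
  ov <- unlist(x[c("t1_bar", "d", "s3")])
  if (length(ov)) print(ov)
  invisible(x)
}

#' Load an organism's parameter fixture
#'
#' Reads the shipped key/value (YAML) fixture for an organism and returns the
#' newborn state, the kinetic parameters, and the regime definitions
#' (constant uptake, quiescent decay rate and assembly override). Fixture
#' keys mirror the model symbol names (`s1`, `t4`, `d1C`, ...). A path to a
#' user fixture in the same format is also accepted.
#'
#' @param organism `"yeast"`, `"mammalian"`, or a path to a fixture file.
#' @return A list with elements `organism`, `state` ([cell_state()]),
#'   `params` ([kinetic_params()]) and `modes` (named list of
#'   [growth_mode()]s for `rich`, `poor`, `quiescent`).
#' @examples
#' org <- organism_params("yeast")
#' org$params$s3
#' @export
organism_params <- function(organism = "yeast") {
  path <- if (file.exists(organism)) organism else
    system.file("extdata", paste0(organism, ".yaml"), package = "cngrowth")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown organism or missing fixture: ", organism)
  raw <- yaml::read_yaml(path)
  state <- as_cell_state(unlist(raw[STATE_NAMES]))
  params <- do.call(kinetic_params, raw[PARAM_NAMES])
  modes <- list(rich = growth_mode("rich"))
  if (!is.null(raw$poor_t1_bar))
    modes$poor <- growth_mode("poor", t1_bar = raw$poor_t1_bar)
  if (!is.null(raw$quiescent_t1_bar))
    modes$quiescent <- growth_mode("quiescent", t1_bar = raw$quiescent_t1_bar,
                                   d = raw$quiescent_d, s3 = raw$quiescent_s3)
  list(organism = raw$organism %||% organism, state = state,
       params = params, modes = modes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default yeast parameters and newborn state
#'
#' Convenience accessors for the budding-yeast fixture.
#' @return `yeast_params()`: a [kinetic_params()]; `yeast_state()`: a
#'   [cell_state()] for a newborn cell.
#' @export
yeast_params <- function() organism_params("yeast")$params

#' @rdname yeast_params
#' @export
yeast_state <- function() organism_params("yeast")$state

#' Default mammalian parameters and newborn state
#'
#' Convenience accessors for the prototypical mammalian (HeLa-like) fixture.
#' Compartment volumes are always derived from the tabulated counts via
#' `r1`, `r2` (giving V_C = 1210, V_N = 302.5 um^3 at the newborn counts).
#' @return `mammalian_params()`: a [kinetic_params()]; `mammalian_state()`:
#'   a newborn [cell_state()].
#' @export
mammalian_params <- function() organism_params("mammalian")$params

#' @rdname mammalian_params
#' @export
mammalian_state <- function() organism_params("mammalian")$state

#' Write a parameter fixture
#'
#' Serializes a state + parameter set (and optional regime overrides) in the
#' same flat key/value format the shipped fixtures use, so calibration output
#' round-trips through [organism_params()].
#'
#' @param path Output file.
#' @param state A [cell_state()].
#' @param params A [kinetic_params()].
#' @param organism Organism tag written into the file.
#' @param modes Optional named list with `poor_t1_bar`, `quiescent_t1_bar`,
#'   `quiescent_d`, `quiescent_s3`.
#' @param header Optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_params <- function(path, state, params, organism = "custom",
                         modes = NULL, header = NULL) {
  x <- c(list(organism = organism),
         as.list(unclass(state)),
         unclass(params)[PARAM_NAMES],
         modes)
  txt <- yaml::as.yaml(x, precision = 12)
  if (!is.null(header))
    txt <- paste0(paste0("# ", header, collapse = "\n"), "\n", txt)
  writeLines(txt, path)
  invisible(path)
}
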