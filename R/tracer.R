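#' Describe a tracer experiment
#'
#' Records which substrate was fed, which of its carbons are 13C
#' labeled, and (for tracer cocktails) the mixture proportions. The
#' descriptor drives both the interpretation of measured MIDs and the
#' simulator's label input.
#'
#' @param substrate substrate name, one of `"glucose"`, `"glutamine"`,
#'   `"pyruvate"`, `"acetate"`, `"leucine"`, `"lysine"`,
#'   `"phenylalanine"`, or `"none"` (unlabeled control).
#' @param positions either `"U"` (uniformly labeled), an integer vector
#'   of labeled carbon positions (e.g. `1` for 1-13C1 glucose), or
#'   `"none"`.
#' @param mixture optional list of `tracer_experiment` objects mixed in
#'   the medium (e.g. the 1:1 U-13C6 / 1-13C1 glucose cocktail); all
#'   must share the same substrate.
#' @param proportions mixture proportions, summing to 1.
#' @param duration_hr labeling duration in hours.
#' @return An object of class `tracer_experiment`.
#' @export
#' @examples
#' glucose_mix_1to1()        # the 1:1 U-13C6 / 1-13C1 glucose cocktail
#' tracer_experiment("glutamine", "U")
tracer_experiment <- function(substrate,
                              positions = "U",
                              mixture = NULL,
                              proportions = NULL,
                              duration_hr = 24) {
  n_c <- substrate_carbons(substrate)
  if (!is.null(mixture)) {
    if (is.null(proportions) || length(proportions) != length(mixture))
      stop("mixture needs one proportion per component", call. = FALSE)
    if (abs(sum(proportions) - 1) > 1e-9)
      stop("mixture proportions must sum to 1", call. = FALSE)
    subs <- vapply(mixture, function(t) t$substrate, character(1))
    if (any(subs != substrate))
      stop("all mixture components must share the substrate", call. = FALSE)
  }
  if (identical(positions, "U")) positions <- seq_len(n_c)
  else if (identical(positions, "none")) positions <- integer(0)
  else {
    positions <- as.integer(positions)
    if (any(positions < 1L | positions > n_c))
      stop("labeled positions outside the substrate backbone", call. = FALSE)
  }
  structure(
    list(substrate = substrate, n_carbons = n_c,
         positions = positions,
         mixture = mixture, proportions = proportions,
         duration_hr = duration_hr),
    class = "tracer_experiment"
  )
}

substrate_carbons <- function(substrate) {
  tbl <- c(glucose = 6L, glutamine = 5L, pyruvate = 3L, acetate = 2L,
           leucine = 6L, lysine = 6L, phenylalanine = 9L, none = 1L)
  if (!substrate %in% names(tbl))
    stop("unsupported substrate: ", substrate, call. = FALSE)
  tbl[[substrate]]
}

#' @export
print.tracer_experiment <- function(x, ...) {
  if (!is.null(x$mixture)) {
    cat(sprintf("<tracer_experiment> %s mixture (%s), %g hr\n", x$substrate,
                paste(sprintf("%.0f%%", 100 * x$proportions), collapse = ":"),
                x$duration_hr))
  } else {
    lab <- if (length(x$positions) == x$n_carbons) "U-13C"
           else if (!length(x$positions)) "unlabeled"
           else paste0(paste(x$positions, collapse = ","), "-13C")
    cat(sprintf("<tracer_experiment> %s %s (%d C), %g hr\n",
                x$substrate, lab, x$n_carbons, x$duration_hr))
  }
  invisible(x)
}

#' The 1:1 uniformly/positionally labeled glucose cocktail
#'
#' Convenience constructor for the 50:50 mixture of U-13C6 glucose and
#' 1-13C1 glucose used to read out glycolysis (M3 pyruvate/lactate from
#' the uniform tracer; M1 pyruvate from C1-labeled glucose surviving
#' phosphoglucoisomerase rather than being lost in the oxidative
#' pentose-phosphate shunt).
#'
#' @param duration_hr labeling duration in hours.
#' @return A `tracer_experiment`.
#' @export
glucose_mix_1to1 <- function(duration_hr = 24) {
  tracer_experiment(
    "glucose",
    mixture = list(tracer_experiment("glucose", "U", duration_hr = duration_hr),
                   tracer_experiment("glucose", 1L, duration_hr = duration_hr)),
    proportions = c(0.5, 0.5),
    duration_hr = duration_hr
  )
}

#' Maximum achievable enrichment of a tracer
#'
#' The fraction of substrate carbons that are 13C in the feed: 1 for a
#' uniform tracer, and the proportion-weighted mean for cocktails
#' (7/12 for the 1:1 U-13C6 / 1-13C1 glucose mix). Used to normalize
#' downstream mean enrichment into a percentage substrate contribution.
#'
#' @param tracer a [tracer_experiment()].
#' @return Fraction in `[0, 1]`.
#' @export
tracer_enrichment <- function(tracer) {
  stopifnot(inherits(tracer, "tracer_experiment"))
  if (!is.null(tracer$mixture)) {
    comps <- vapply(tracer$mixture, tracer_enrichment, numeric(1))
    return(sum(comps * tracer$proportions))
  }
  length(tracer$positions) / tracer$n_carbons
}

is_uniform_tracer <- function(tracer) {
  is.null(tracer$mixture) && length(tracer$positions) == tracer$n_carbons
}
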