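#' Oxidative vs reductive glutamine entry into citrate
#'
#' Under U-13C5 glutamine, oxidative TCA cycling produces M4 citrate
#' (labeled oxaloacetate condensed with unlabeled acetyl-CoA) while
#' reductive carboxylation of alpha-ketoglutarate produces M5 citrate.
#' The oxidative and reductive contributions are therefore read off as
#' the M4 and M5 citrate fractions; a lower M4/M5 ratio indicates more
#' reductive carboxylation.
#'
#' @param citrate a corrected 6-carbon citrate `mid` measured under
#'   U-13C5 glutamine.
#' @return A list of class `ox_red_split`: `oxidative_fraction` (M4),
#'   `reductive_fraction` (M5), and `ox_over_red` (`Inf` when the
#'   reductive fraction is zero).
#' @export
#' @examples
#' citrate_ox_red(mid(c(0.4, 0, 0, 0, 0.2, 0.4, 0), corrected = TRUE))
citrate_ox_red <- function(citrate) {
  stopifnot(is_mid(citrate))
  if (citrate$n_carbons != 6L)
    stop("citrate MID must have 6 backbone carbons", call. = FALSE)
  ox <- citrate$fractions[5L]   # M+4
  red <- citrate$fractions[6L]  # M+5
  structure(
    list(oxidative_fraction = ox,
         reductive_fraction = red,
         ox_over_red = if (red > 0) ox / red else Inf),
    class = "ox_red_split"
  )
}

#' @export
print.ox_red_split <- function(x, ...) {
  cat(sprintf("<ox_red_split> M4 (oxidative) = %.4f, M5 (reductive) = %.4f, M4/M5 = %s\n",
              x$oxidative_fraction, x$reductive_fraction,
              if (is.finite(x$ox_over_red))
                sprintf("%.3f", x$ox_over_red) else "Inf"))
  invisible(x)
}

#' Ratio of two metabolite pool abundances
#'
#' Ratio of total ion currents (normalized to the same internal
#' standard and protein content), e.g. the alpha-ketoglutarate / citrate
#' pool ratio whose increase accompanies glutamine-driven reductive
#' carboxylation.
#'
#' @param a_abundance,b_abundance positive normalized ion currents.
#' @return `a_abundance / b_abundance`.
#' @export
pool_ratio <- function(a_abundance, b_abundance) {
  if (!is.finite(a_abundance) || !is.finite(b_abundance) ||
      a_abundance < 0 || b_abundance < 0)
    stop("pool abundances must be non-negative and finite", call. = FALSE)
  if (b_abundance == 0)
    stop("denominator pool abundance is zero", call. = FALSE)
  a_abundance / b_abundance
}

#' Percentage substrate contribution to a downstream metabolite
#'
#' Operationalized as the mean enrichment of the downstream metabolite
#' divided by the maximum enrichment achievable from the tracer feed
#' (1 for a uniform tracer; 7/12 for the 1:1 U-13C6 / 1-13C1 glucose
#' cocktail), capped at 1. The raw mean enrichment is attached as
#' attribute `"mean_enrichment"` so either convention can be audited.
#'
#' @param downstream corrected `mid` of the downstream metabolite.
#' @param tracer_enrichment achievable feed enrichment in `(0, 1]`;
#'   compute it from the experiment with [tracer_enrichment()].
#' @return Fraction in `[0, 1]` with attribute `mean_enrichment`.
#' @export
substrate_contribution <- function(downstream, tracer_enrichment) {
  stopifnot(is_mid(downstream))
  if (!is.numeric(tracer_enrichment) || tracer_enrichment <= 0 ||
      tracer_enrichment > 1)
    stop("tracer_enrichment must lie in (0, 1]", call. = FALSE)
  me <- mean_enrichment(downstream)
  structure(min(me / tracer_enrichment, 1), mean_enrichment = me)
}

#' M1 glycolysis index under the 1:1 glucose cocktail
#'
#' With a 1:1 mixture of U-13C6 glucose and 1-13C1 glucose, M1
#' pyruvate (or lactate) can only arise from glucose-6-phosphate that
#' passed through phosphoglucoisomerase with its C1 label intact;
#' routing through the oxidative pentose-phosphate shunt decarboxylates
#' C1 and erases the signal. The index is simply the M1 fraction of the
#' corrected 3-carbon MID; its interpretation as glycolytic routing is
#' qualitative.
#'
#' @param pyruvate_or_lactate corrected 3-carbon `mid`.
#' @param tracer the [tracer_experiment()] used; must be a glucose
#'   mixture containing a 1-13C1 component.
#' @return The M1 fraction.
#' @export
m1_glycolysis_index <- function(pyruvate_or_lactate,
                                tracer = glucose_mix_1to1()) {
  stopifnot(is_mid(pyruvate_or_lactate))
  if (pyruvate_or_lactate$n_carbons != 3L)
    stop("pyruvate/lactate MID must have 3 backbone carbons", call. = FALSE)
  if (!valid_m1_tracer(tracer))
    stop("index undefined for tracer: requires a glucose mixture with a 1-13C1 component",
         call. = FALSE)
  pyruvate_or_lactate$fractions[2L]
}

valid_m1_tracer <- function(tracer) {
  if (!inherits(tracer, "tracer_experiment")) return(FALSE)
  if (tracer$substrate != "glucose" || is.null(tracer$mixture)) return(FALSE)
  any(vapply(tracer$mixture,
             function(t) identical(t$positions, 1L), logical(1)))
}
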