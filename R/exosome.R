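#' Exosome metabolite cargo contribution
#'
#' When producer fibroblasts are labeled to completion short of one
#' replication, their exosomes carry partially labeled metabolite
#' cargo. The fraction of a recipient-cell metabolite pool supplied by
#' exosomes is estimated by normalizing the mean enrichment measured in
#' the recipient cells by the enrichment of the same metabolite inside
#' the labeled exosomes; the unknown labeling fraction of the producer
#' pool cancels in the ratio.
#'
#' For essential amino acids the recipient cannot synthesize the
#' metabolite, so at steady state the cell enrichment cannot exceed the
#' source enrichment and a contribution above 1 is clipped (with a
#' warning). Non-essential metabolites can legitimately exceed 1 via
#' endogenous pathways and are flagged, never clipped. When the cell
#' catabolizes the metabolite, the measured contribution is a lower
#' bound on cumulative supply.
#'
#' @param me_cell mean enrichment of the metabolite in recipient cells.
#' @param me_exosome mean enrichment of the metabolite inside labeled
#'   exosomes; must be positive.
#' @param metabolite metabolite name (used for the essential amino acid
#'   classification).
#' @return An object of class `cargo_contribution` with fields
#'   `metabolite`, `me_cell`, `me_exosome`, `contribution`,
#'   `essential_amino_acid`, `exceeds_source`.
#' @export
#' @examples
#' cargo_contribution(0.06, 0.40, "phenylalanine")
cargo_contribution <- function(me_cell, me_exosome, metabolite) {
  if (!is.finite(me_exosome) || me_exosome <= 0)
    stop("source unlabeled: exosome mean enrichment must be > 0",
         call. = FALSE)
  if (!is.finite(me_cell) || me_cell < 0)
    stop("cell mean enrichment must be non-negative", call. = FALSE)
  essential <- is_essential_amino_acid(metabolite)
  contribution <- me_cell / me_exosome
  exceeds <- contribution > 1
  if (essential && exceeds) {
    warning(sprintf(
      "%s: cell enrichment exceeds source enrichment for an essential amino acid; clipping contribution to 1",
      metabolite), call. = FALSE)
    contribution <- 1
  }
  structure(
    list(metabolite = metabolite,
         me_cell = me_cell, me_exosome = me_exosome,
         contribution = contribution,
         essential_amino_acid = essential,
         exceeds_source = exceeds),
    class = "cargo_contribution"
  )
}

#' @export
print.cargo_contribution <- function(x, ...) {
  cat(sprintf("<cargo_contribution> %s: %.1f%%%s%s\n",
              x$metabolite, 100 * x$contribution,
              if (x$essential_amino_acid) " (essential AA)" else "",
              if (x$exceeds_source) " [exceeds source]" else ""))
  invisible(x)
}

#' Essential amino acid classification
#'
#' Human cells cannot synthesize the canonical essential amino acids;
#' glutamine, although conditionally essential in proliferating cells,
#' is treated as non-essential because glutamine synthetase provides an
#' endogenous route.
#'
#' @param metabolite metabolite name (case-insensitive).
#' @return Logical.
#' @export
is_essential_amino_acid <- function(metabolite) {
  essential <- c("histidine", "isoleucine", "leucine", "lysine",
                 "methionine", "phenylalanine", "threonine",
                 "tryptophan", "valine")
  tolower(metabolite) %in% essential
}

#' Exosome particle count from protein mass
#'
#' Converts an exosome dose measured as protein mass (BCA) into a
#' particle count via the calibration constant mass-per-1e9-particles
#' (4.9 micrograms per 1e9 particles by nanoparticle tracking).
#'
#' @param protein_mass_ug exosome protein mass in micrograms.
#' @param mass_per_1e9_particles_ug calibration constant, micrograms
#'   per 1e9 particles.
#' @return Particle count.
#' @export
#' @examples
#' particles_from_mass(270, 4.9)  # ~5.51e10 particles
particles_from_mass <- function(protein_mass_ug,
                                mass_per_1e9_particles_ug = 4.9) {
  if (!is.finite(protein_mass_ug) || protein_mass_ug <= 0)
    stop("protein mass must be positive", call. = FALSE)
  if (!is.finite(mass_per_1e9_particles_ug) ||
      mass_per_1e9_particles_ug <= 0)
    stop("calibration constant must be positive", call. = FALSE)
  protein_mass_ug / mass_per_1e9_particles_ug * 1e9
}

#' Exosome protein mass from particle count
#'
#' Inverse of [particles_from_mass()].
#'
#' @param particle_count number of particles.
#' @param mass_per_1e9_particles_ug calibration constant, micrograms
#'   per 1e9 particles.
#' @return Protein mass in micrograms.
#' @export
mass_from_particles <- function(particle_count,
                                mass_per_1e9_particles_ug = 4.9) {
  if (!is.finite(particle_count) || particle_count <= 0)
    stop("particle count must be positive", call. = FALSE)
  particle_count / 1e9 * mass_per_1e9_particles_ug
}

#' Producer-cell equivalents of an exosome dose
#'
#' Expresses an exosome dose as the ratio of producer fibroblasts to
#' recipient cancer cells whose 48-hour secretion it represents:
#' `dose_particles / per_producer_yield / cancer_cells`.
#'
#' @param dose_particles particles applied per ml of culture.
#' @param cancer_cells_per_ml recipient cell density per ml.
#' @param per_producer_yield particles secreted per producer fibroblast
#'   per 48 hr (28000 for the calibrated prostate CAF cultures).
#' @return Producer:cancer cell ratio.
#' @export
caf_equivalents <- function(dose_particles, cancer_cells_per_ml,
                            per_producer_yield = 28000) {
  vals <- c(dose_particles, cancer_cells_per_ml, per_producer_yield)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dosimetry inputs must be positive", call. = FALSE)
  dose_particles / per_producer_yield / cancer_cells_per_ml
}
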