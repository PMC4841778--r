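# ---------------------------------------------------------------------
# Positional isotopomer engine
#
# A metabolite with n backbone carbons is represented as a probability
# vector over its 2^n positional isotopomers; state index s (0-based)
# has bit (k-1) set when carbon k is 13C. Reactions are carbon maps:
# integer vectors giving, for each product carbon, the source carbon it
# derives from. Unmapped source carbons are marginalized out (CO2 loss).
# ---------------------------------------------------------------------

# independent-position input distribution: listed positions are 13C
# with probability `purity`, all others 12C
iso_input <- function(n, positions, purity = 1) {
  d <- 1
  for (k in seq_len(n)) {
    p <- if (k %in% positions) purity else 0
    d <- c(d * (1 - p), d * p)
  }
  d
}

iso_unlabeled <- function(n) iso_input(n, integer(0))

popcounts <- function(n) {
  s <- 0:(2^n - 1L)
  counts <- integer(length(s))
  for (k in seq_len(n)) counts <- counts + bitwAnd(s, 2^(k - 1L)) %/% 2^(k - 1L)
  counts
}

# collapse an isotopomer distribution to its MID (length n + 1)
iso_to_mid <- function(d, n) {
  as.numeric(tapply(d, popcounts(n), sum))
}

# product carbon j derives from source carbon map[j]
apply_carbon_map <- function(d, n_src, map) {
  n_out <- length(map)
  s <- 0:(2^n_src - 1L)
  t <- integer(length(s))
  for (j in seq_len(n_out)) {
    bit <- bitwAnd(s, 2^(map[j] - 1L)) %/% 2^(map[j] - 1L)
    t <- t + bit * 2^(j - 1L)
  }
  out <- numeric(2^n_out)
  for (i in seq_along(s)) out[t[i] + 1L] <- out[t[i] + 1L] + d[i]
  out
}

# condensation: product carbons 1..nA from A, nA+1..nA+nB from B
iso_condense <- function(dA, nA, dB, nB) {
  as.vector(outer(dA, dB))
}

# symmetric-intermediate scrambling (succinate/fumarate): the molecule
# is read in either carbon order with equal probability
iso_scramble <- function(d, n) {
  0.5 * d + 0.5 * apply_carbon_map(d, n, rev(seq_len(n)))
}

# per-position marginal probability of label; used for carbon-balance checks
iso_position_marginals <- function(d, n) {
  s <- 0:(2^n - 1L)
  vapply(seq_len(n), function(k)
    sum(d[bitwAnd(s, 2^(k - 1L)) > 0]), numeric(1))
}

# ---------------------------------------------------------------------
# Simulation configuration and presets
# ---------------------------------------------------------------------

#' Configure a tracer simulation
#'
#' Bundles the tracer experiment, the branch fractions of the toy
#' atom-mapped network, the lipogenic acetyl-CoA source shares, exosome
#' cargo parameters, measurement noise, and the mandatory RNG seed.
#'
#' Network branch fractions: `f_red` is the fraction of citrate made by
#' reductive carboxylation of alpha-ketoglutarate (the rest by citrate
#' synthase); `f_ppp` the fraction of glucose routed through the
#' oxidative pentose-phosphate shunt (losing C1 as CO2);
#' `akg_gln_share` the fraction of the alpha-ketoglutarate pool fed by
#' glutaminolysis; `glu_gln_share` the glutamate pool's direct
#' glutamine share; `pyr_media_share` the pyruvate pool's share taken
#' up from the medium; `acetyl_acetate_share` the mitochondrial
#' acetyl-CoA share from acetate activation.
#'
#' Lipogenic acetyl shares `glucose_share_of_acetyl`, `glutamine_share`,
#' `acetate_share`, `pyruvate_share` must sum to at most 1; the
#' remainder is pre-existing unlabeled acetyl-CoA. `g_true` is the
#' fraction of the palmitate pool newly synthesized.
#'
#' @param tracer a [tracer_experiment()].
#' @param f_red,f_ppp,akg_gln_share,glu_gln_share,pyr_media_share,acetyl_acetate_share
#'   network branch fractions in `[0, 1]`.
#' @param glucose_share_of_acetyl,glutamine_share,acetate_share,pyruvate_share
#'   lipogenic acetyl-CoA source shares.
#' @param g_true de novo palmitate fraction.
#' @param exosome_label_fraction fraction of producer-cell pools labeled
#'   after 72 hr (must be < 1: sub-replication labeling).
#' @param cargo_supply_fraction named vector, fraction of each
#'   recipient-cell pool supplied by exosomes.
#' @param cargo_turnover fraction of delivered label catabolized before
#'   measurement (makes measured contribution a lower bound).
#' @param tracer_purity 13C purity per labeled tracer position.
#' @param noise_sd per-isotopologue Gaussian measurement noise (fraction
#'   scale).
#' @param n_replicates replicate measurements per condition.
#' @param pool_akg,pool_citrate relative pool abundances (normalized ion
#'   currents) for the pool-ratio readout.
#' @param ocr_basal,ocr_maximal,ocr_nonmito,ecar_basal,protein_ug
#'   extracellular-flux plateau levels for the simulated stress test.
#' @param seed RNG seed; mandatory for any stochastic output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(tracer = glucose_mix_1to1(),
                              f_red = 0.2, f_ppp = 0.25,
                              akg_gln_share = 0.5, glu_gln_share = 0.4,
                              pyr_media_share = 0.3,
                              acetyl_acetate_share = 0.1,
                              glucose_share_of_acetyl = 0.55,
                              glutamine_share = 0.12,
                              acetate_share = 0.05,
                              pyruvate_share = 0.08,
                              g_true = 0.5,
                              exosome_label_fraction = 0.5,
                              cargo_supply_fraction = c(
                                leucine = 0.05, lysine = 0.12,
                                glutamine = 0.14, phenylalanine = 0.16),
                              cargo_turnover = 0,
                              tracer_purity = 0.99,
                              noise_sd = 0.005,
                              n_replicates = 4L,
                              pool_akg = 1.0, pool_citrate = 2.0,
                              ocr_basal = 100, ocr_maximal = 250,
                              ocr_nonmito = 10, ecar_basal = 30,
                              protein_ug = 1,
                              seed) {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory for any stochastic simulation", call. = FALSE)
  fracs <- c(f_red = f_red, f_ppp = f_ppp, akg_gln_share = akg_gln_share,
             glu_gln_share = glu_gln_share,
             pyr_media_share = pyr_media_share,
             acetyl_acetate_share = acetyl_acetate_share,
             g_true = g_true,
             exosome_label_fraction = exosome_label_fraction,
             cargo_turnover = cargo_turnover)
  if (any(fracs < 0 | fracs > 1))
    stop("branch fractions must lie in [0, 1]", call. = FALSE)
  if (exosome_label_fraction >= 1)
    stop("exosome_label_fraction must be < 1 (72 hr is sub-replication)",
         call. = FALSE)
  shares <- c(glucose_share_of_acetyl, glutamine_share, acetate_share,
              pyruvate_share)
  if (any(shares < 0) || sum(shares) > 1 + 1e-9)
    stop("lipogenic acetyl shares must be non-negative and sum to <= 1",
         call. = FALSE)
  if (any(cargo_supply_fraction < 0 | cargo_supply_fraction > 1))
    stop("cargo supply fractions must lie in [0, 1]", call. = FALSE)
  if (ocr_maximal < ocr_basal || ocr_basal < ocr_nonmito || ocr_nonmito < 0)
    stop("OCR plateaus must satisfy maximal >= basal >= nonmito >= 0",
         call. = FALSE)
  structure(
    list(tracer = tracer, f_red = f_red, f_ppp = f_ppp,
         akg_gln_share = akg_gln_share, glu_gln_share = glu_gln_share,
         pyr_media_share = pyr_media_share,
         acetyl_acetate_share = acetyl_acetate_share,
         glucose_share_of_acetyl = glucose_share_of_acetyl,
         glutamine_share = glutamine_share,
         acetate_share = acetate_share, pyruvate_share = pyruvate_share,
         g_true = g_true,
         exosome_label_fraction = exosome_label_fraction,
         cargo_supply_fraction = cargo_supply_fraction,
         cargo_turnover = cargo_turnover,
         tracer_purity = tracer_purity,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         pool_akg = pool_akg, pool_citrate = pool_citrate,
         ocr_basal = ocr_basal, ocr_maximal = ocr_maximal,
         ocr_nonmito = ocr_nonmito, ecar_basal = ecar_basal,
         protein_ug = protein_ug, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Preset study conditions for the simulator
#'
#' Two presets describe a control culture and an exosome-treated
#' (`"cde"`) culture. The treated preset moves every branch fraction in
#' the direction the biology dictates for fibroblast-exosome exposure —
#' more reductive carboxylation, lower glucose and higher
#' glutamine/acetate contribution to lipogenic acetyl-CoA, higher
#' alpha-ketoglutarate/citrate pool ratio, lower OCR, higher ECAR —
#' without targeting any particular measured magnitude: the presets
#' define directions, not calibrated fluxes.
#'
#' @param name `"control"` or `"cde"`.
#' @param tracer tracer experiment to simulate under.
#' @param seed RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
simulation_preset <- function(name = c("control", "cde"),
                              tracer = glucose_mix_1to1(), seed, ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(f_red = 0.2, f_ppp = 0.25,
                   akg_gln_share = 0.5, pyr_media_share = 0.30,
                   acetyl_acetate_share = 0.10,
                   glucose_share_of_acetyl = 0.55, glutamine_share = 0.12,
                   acetate_share = 0.05, pyruvate_share = 0.08,
                   pool_akg = 1.0, pool_citrate = 2.0,
                   ocr_basal = 100, ocr_maximal = 250, ocr_nonmito = 10,
                   ecar_basal = 30),
    cde = list(f_red = 0.5, f_ppp = 0.15,
               akg_gln_share = 0.65, pyr_media_share = 0.15,
               acetyl_acetate_share = 0.20,
               glucose_share_of_acetyl = 0.30, glutamine_share = 0.25,
               acetate_share = 0.10, pyruvate_share = 0.04,
               pool_akg = 1.5, pool_citrate = 1.5,
               ocr_basal = 55, ocr_maximal = 140, ocr_nonmito = 10,
               ecar_basal = 50)
  )
  args <- utils::modifyList(c(base, list(tracer = tracer, seed = seed)),
                            list(...))
  do.call(simulation_config, args)
}

# representative derivatized GC-MS fragments (synthetic stand-ins for
# the instrument-specific fragment list; backbone carbon counts are the
# biochemical ones, derivatization atoms are plausible TBDMS/methyl
# ester adducts)
metabolite_fragments <- function() {
  data.frame(
    metabolite = c("pyruvate", "lactate", "citrate", "akg", "fumarate",
                   "malate", "glutamate", "glutamine", "palmitate",
                   "leucine", "lysine", "phenylalanine"),
    backbone_carbons = c(3L, 3L, 6L, 5L, 4L, 4L, 5L, 5L, 16L, 6L, 6L, 9L),
    fragment_formula = c("C6H12NO2Si", "C11H25O3Si2", "C20H39O7Si3",
                         "C14H28NO5Si2", "C12H23O4Si2", "C18H37O5Si3",
                         "C19H42NO4Si3", "C19H41N2O3Si3", "C17H34O2",
                         "C13H30NO2Si2", "C18H41N2O2Si3", "C15H26NO2Si"),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------
# Steady-state label propagation
# ---------------------------------------------------------------------

# tracer feed -> glucose/glutamine/pyruvate/acetate input distributions
tracer_inputs <- function(tracer, purity) {
  inputs <- list(glucose = iso_unlabeled(6L), glutamine = iso_unlabeled(5L),
                 pyruvate = iso_unlabeled(3L), acetate = iso_unlabeled(2L))
  set_one <- function(tr) {
    if (tr$substrate %in% names(inputs) && length(tr$positions))
      inputs[[tr$substrate]] <<-
        iso_input(tr$n_carbons, tr$positions, purity)
  }
  if (!is.null(tracer$mixture)) {
    d <- Reduce(`+`, Map(function(tr, w)
      w * iso_input(tr$n_carbons, tr$positions, purity),
      tracer$mixture, tracer$proportions))
    inputs[[tracer$substrate]] <- d
  } else {
    set_one(tracer)
  }
  inputs
}

#' Propagate tracer label to network steady state
#'
#' Runs the fixed-point iteration over the atom-mapped toy network
#' (glycolysis with an oxidative pentose-phosphate shunt, PDH, an
#' oxidative TCA turn with symmetric succinate/fumarate scrambling, a
#' reductive carboxylation branch, glutaminolysis, citrate cleavage and
#' acetate activation feeding a lipogenic acetyl-CoA pool, palmitate as
#' eight acetyl units) and returns the steady-state positional
#' isotopomer distributions and collapsed MIDs of every node.
#'
#' @param config a [simulation_config()].
#' @param tol fixed-point convergence tolerance (max absolute change).
#' @param max_iter iteration cap; exceeding it is an error with
#'   diagnostics.
#' @return List with `iso` (named isotopomer distributions), `mids`
#'   (named MID vectors), `lipogenic_acetyl` (3-entry MID of the mixed
#'   pool), `palmitate` (17-entry MID), and `iterations`.
#' @export
propagate_labels <- function(config, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(config, "simulation_config"))
  inp <- tracer_inputs(config$tracer, config$tracer_purity)

  # glycolysis arms: glucose C1,C2,C3 -> pyruvate C3,C2,C1 (DHAP arm);
  # glucose C4,C5,C6 -> pyruvate C1,C2,C3 (GAP arm). The oxidative PPP
  # shunt loses glucose C1 as CO2 and yields pyruvate via the GAP arm
  # only, so per glucose it makes 1 pyruvate instead of 2.
  armA <- apply_carbon_map(inp$glucose, 6L, c(3L, 2L, 1L))
  armB <- apply_carbon_map(inp$glucose, 6L, c(4L, 5L, 6L))
  w_glyc <- 2 * (1 - config$f_ppp); w_ppp <- config$f_ppp
  pyr_glc <- ((1 - config$f_ppp) * (armA + armB) + config$f_ppp * armB) /
    (w_glyc + w_ppp)
  pyr <- (1 - config$pyr_media_share) * pyr_glc +
    config$pyr_media_share * inp$pyruvate
  lac <- pyr
  # PDH loses pyruvate C1; acetyl C1,C2 = pyruvate C2,C3
  ac_pdh <- apply_carbon_map(pyr, 3L, c(2L, 3L))
  ac_mito <- (1 - config$acetyl_acetate_share) * ac_pdh +
    config$acetyl_acetate_share * inp$acetate

  co2 <- iso_unlabeled(1L)
  gln <- inp$glutamine

  # carbon numbering: citrate c1..c4 from oxaloacetate o1..o4, c5..c6
  # from acetyl a1..a2; alpha-ketoglutarate k1..k5 = citrate c2..c6
  cit <- iso_unlabeled(6L); akg <- iso_unlabeled(5L)
  fum <- iso_unlabeled(4L); oaa <- iso_unlabeled(4L)

  delta <- Inf; it <- 0L
  while (delta > tol) {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf(
        "label propagation did not converge: max change %.3g after %d iterations (tol %.1g)",
        delta, max_iter, tol), call. = FALSE)
    cit_new <- (1 - config$f_red) * iso_condense(oaa, 4L, ac_mito, 2L) +
      config$f_red * iso_condense(co2, 1L, akg, 5L)
    akg_new <- config$akg_gln_share * gln +
      (1 - config$akg_gln_share) * apply_carbon_map(cit_new, 6L, 2:6)
    # oxidative: alpha-ketoglutarate loses C1; succinate scrambles.
    # reductive: citrate-cleavage oxaloacetate re-enters via malate.
    suc <- iso_scramble(apply_carbon_map(akg_new, 5L, 2:5), 4L)
    oaa_acl <- iso_scramble(apply_carbon_map(cit_new, 6L, 1:4), 4L)
    fum_new <- (1 - config$f_red) * suc + config$f_red * oaa_acl
    oaa_new <- fum_new
    delta <- max(abs(cit_new - cit), abs(akg_new - akg),
                 abs(fum_new - fum), abs(oaa_new - oaa))
    cit <- cit_new; akg <- akg_new; fum <- fum_new; oaa <- oaa_new
  }
  mal <- fum
  glu <- config$glu_gln_share * gln + (1 - config$glu_gln_share) * akg

  # lipogenic acetyl-CoA sources (per-source routes, so the configured
  # shares are exact ground truth for ISA's D)
  ac_glc <- iso_to_mid(apply_carbon_map(pyr_glc, 3L, c(2L, 3L)), 2L)
  ac_gln <- iso_to_mid(apply_carbon_map(gln, 5L, c(4L, 5L)), 2L)
  ac_ace <- iso_to_mid(inp$acetate, 2L)
  ac_pyr <- iso_to_mid(apply_carbon_map(inp$pyruvate, 3L, c(2L, 3L)), 2L)
  unl <- c(1, 0, 0)
  rest <- max(0, 1 - config$glucose_share_of_acetyl - config$glutamine_share -
    config$acetate_share - config$pyruvate_share)
  lipo <- config$glucose_share_of_acetyl * ac_glc +
    config$glutamine_share * ac_gln +
    config$acetate_share * ac_ace +
    config$pyruvate_share * ac_pyr + rest * unl
  palm <- config$g_true * self_convolve(lipo, 8L) +
    (1 - config$g_true) * self_convolve(unl, 8L)

  iso <- list(glucose = inp$glucose, glutamine = gln, pyruvate = pyr,
              lactate = lac, acetyl_mito = ac_mito, citrate = cit,
              akg = akg, fumarate = fum, malate = mal, oaa = oaa,
              glutamate = glu)
  ncarb <- c(glucose = 6L, glutamine = 5L, pyruvate = 3L, lactate = 3L,
             acetyl_mito = 2L, citrate = 6L, akg = 5L, fumarate = 4L,
             malate = 4L, oaa = 4L, glutamate = 5L)
  mids <- Map(iso_to_mid, iso, as.list(ncarb))
  list(iso = iso, mids = mids, lipogenic_acetyl = lipo,
       palmitate = palm, iterations = it)
}

# ---------------------------------------------------------------------
# Measurement model: natural-abundance convolution + noise + intensities
# ---------------------------------------------------------------------

# forward-convolve a clean MID with the fragment correction matrix,
# producing the raw relative abundances an instrument would report
convolve_natural <- function(fractions, metabolite, frag_table,
                             isotope_abundances = iupac_isotopes(),
                             tracer_purity = 1) {
  row <- frag_table[frag_table$metabolite == metabolite, ]
  frag <- fragment_formula(row$fragment_formula, row$backbone_carbons)
  M <- build_correction_matrix(frag, isotope_abundances,
                               tracer_purity = tracer_purity)
  as.numeric(M %*% fractions)
}

# one replicate's raw intensity vector: noisy fractions scaled by a
# lognormal total ion current around the pool size
noisy_intensities <- function(fractions, noise_sd, pool_size = 1) {
  f <- fractions + stats::rnorm(length(fractions), sd = noise_sd)
  f[f < 0] <- 0
  if (sum(f) <= 0) f <- fractions
  tic <- pool_size * 1e6 * stats::rlnorm(1, sdlog = 0.05)
  f / sum(f) * tic
}

#' Simulate a GC-MS MID table for one condition
#'
#' Propagates the configured tracer to steady state, converts the clean
#' MIDs of the measurable metabolites (lactate, pyruvate, citrate,
#' alpha-ketoglutarate, malate, fumarate, glutamate, palmitate) into
#' raw intensities by forward-convolving natural isotope abundance over
#' each metabolite's fragment formula, adds per-isotopologue Gaussian
#' noise, and writes replicate rows in the MID table dialect. Pool
#' sizes scale the total ion current of alpha-ketoglutarate and citrate
#' so the pool-ratio readout carries signal.
#'
#' @param config a [simulation_config()].
#' @param condition condition label stamped on the rows.
#' @return List with `table` (MID table data.frame), `truth` (the
#'   config plus clean MIDs), and `propagation` (see
#'   [propagate_labels()]).
#' @export
simulate_mids <- function(config, condition = "control") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  prop <- propagate_labels(config)
  frag <- metabolite_fragments()
  mets <- c("lactate", "pyruvate", "citrate", "akg", "malate",
            "fumarate", "glutamate", "palmitate")
  pool_sizes <- c(lactate = 5, pyruvate = 2, citrate = config$pool_citrate,
                  akg = config$pool_akg, malate = 1.5, fumarate = 1,
                  glutamate = 3, palmitate = 2)
  width <- max(frag$backbone_carbons)
  rows <- list()
  for (met in mets) {
    clean <- if (met == "palmitate") prop$palmitate else prop$mids[[met]]
    raw <- convolve_natural(clean, met, frag,
                            tracer_purity = config$tracer_purity)
    n <- frag$backbone_carbons[frag$metabolite == met]
    for (r in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1L]] <- mid_table_row(
        sample_id = sprintf("%s_rep%d", condition, r),
        condition = condition, metabolite = met,
        formula = frag$fragment_formula[frag$metabolite == met],
        backbone_carbons = n,
        intensities = noisy_intensities(raw, config$noise_sd,
                                        pool_sizes[[met]]),
        width = width)
    }
  }
  table <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(table = table,
       truth = list(config = config,
                    clean_mids = c(prop$mids,
                                   list(palmitate = prop$palmitate)),
                    lipogenic_acetyl = prop$lipogenic_acetyl),
       propagation = prop)
}

#' Simulate paired exosome / recipient-cell MID tables
#'
#' Producer fibroblasts labeled for 72 hr (less than one replication)
#' yield exosome cargo that mixes the tracer pattern with pre-existing
#' unlabeled molecules at `exosome_label_fraction`. Recipient-cell
#' pools mix exosome-supplied and endogenous unlabeled molecules at
#' each metabolite's `cargo_supply_fraction`; optional `cargo_turnover`
#' catabolizes part of the delivered label first, which makes the
#' measured contribution a lower bound on cumulative supply. Both
#' tables carry natural-abundance-convolved noisy intensities.
#'
#' @param config a [simulation_config()]; cargo metabolites are the
#'   names of `config$cargo_supply_fraction`.
#' @return List with `exosome_table`, `cell_table`, and `truth`.
#' @export
simulate_exosome_transfer <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  frag <- metabolite_fragments()
  mets <- names(config$cargo_supply_fraction)
  if (!all(mets %in% frag$metabolite))
    stop("no fragment definition for cargo metabolite(s): ",
         paste(setdiff(mets, frag$metabolite), collapse = ", "),
         call. = FALSE)
  width <- max(frag$backbone_carbons)
  exo_rows <- list(); cell_rows <- list()
  truth_mids <- list()
  for (met in mets) {
    n <- frag$backbone_carbons[frag$metabolite == met]
    tracer_iso <- iso_to_mid(iso_input(n, seq_len(n),
                                       config$tracer_purity), n)
    m0 <- c(1, numeric(n))
    exo <- config$exosome_label_fraction * tracer_iso +
      (1 - config$exosome_label_fraction) * m0
    supply <- config$cargo_supply_fraction[[met]]
    cell <- supply * ((1 - config$cargo_turnover) * exo +
                        config$cargo_turnover * m0) +
      (1 - supply) * m0
    truth_mids[[met]] <- list(exosome = exo, cell = cell)
    raw_exo <- convolve_natural(exo, met, frag,
                                tracer_purity = config$tracer_purity)
    raw_cell <- convolve_natural(cell, met, frag,
                                 tracer_purity = config$tracer_purity)
    fml <- frag$fragment_formula[frag$metabolite == met]
    for (r in seq_len(config$n_replicates)) {
      exo_rows[[length(exo_rows) + 1L]] <- mid_table_row(
        sprintf("exo_rep%d", r), "exosome", met, fml, n,
        noisy_intensities(raw_exo, config$noise_sd), width)
      cell_rows[[length(cell_rows) + 1L]] <- mid_table_row(
        sprintf("cell_rep%d", r), "cell", met, fml, n,
        noisy_intensities(raw_cell, config$noise_sd), width)
    }
  }
  to_df <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(exosome_table = to_df(exo_rows), cell_table = to_df(cell_rows),
       truth = list(config = config, mids = truth_mids))
}

#' Estimate exosome cargo contributions from paired MID tables
#'
#' The full measurement-side chain: natural-abundance correct both
#' tables, compute per-replicate mean enrichment, divide each cell
#' replicate's enrichment by the mean exosome enrichment, and summarize
#' per metabolite as the median with a seeded bootstrap percentile CI
#' over replicates.
#'
#' @param cell_table,exosome_table MID tables (raw intensities) for the
#'   recipient cells and the labeled exosomes.
#' @param tracer_purity purity folded into the correction matrices.
#' @param n_boot bootstrap resamples; 0 disables the CI.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns `metabolite`, `contribution`
#'   (median), `ci_lo`, `ci_hi`, `me_cell`, `me_exosome`,
#'   `essential_amino_acid`.
#' @export
summarize_cargo_contributions <- function(cell_table, exosome_table,
                                          tracer_purity = 0.99,
                                          n_boot = 200L, seed = 1L) {
  cc <- correct_mid_table(cell_table, tracer_purity = tracer_purity)
  ce <- correct_mid_table(exosome_table, tracer_purity = tracer_purity)
  mets <- unique(cc$metabolite)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(mets, function(met) {
    me_cell <- vapply(mids_from_table(cc[cc$metabolite == met, ],
                                      normalized = TRUE, corrected = TRUE),
                      mean_enrichment, numeric(1))
    me_exo <- vapply(mids_from_table(ce[ce$metabolite == met, ],
                                     normalized = TRUE, corrected = TRUE),
                     mean_enrichment, numeric(1))
    contrib <- me_cell / mean(me_exo)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0L && length(contrib) > 1L) {
      boots <- vapply(seq_len(n_boot), function(b) {
        stats::median(me_cell[sample.int(length(me_cell), replace = TRUE)]) /
          mean(me_exo[sample.int(length(me_exo), replace = TRUE)])
      }, numeric(1))
      ci <- stats::quantile(boots, c(0.025, 0.975))
    }
    data.frame(metabolite = met,
               contribution = stats::median(contrib),
               ci_lo = ci[[1]], ci_hi = ci[[2]],
               me_cell = mean(me_cell), me_exosome = mean(me_exo),
               essential_amino_acid = is_essential_amino_acid(met),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a mitochondrial stress-test time series
#'
#' Piecewise-constant OCR at the configured plateau levels (baseline,
#' post-oligomycin, post-FCCP, post-ETC-block), with a short mixing
#' transient on the first two measurements after each injection and
#' optional Gaussian noise. With zero noise the trailing measurements
#' of every segment sit exactly on the plateau, so
#' [derive_bioenergetics()] recovers the configured levels exactly.
#'
#' @param basal,maximal,nonmito raw OCR plateau levels
#'   (`maximal >= basal >= nonmito >= 0`).
#' @param ecar basal ECAR level.
#' @param protein_ug protein per well.
#' @param noise_sd Gaussian noise sd on OCR/ECAR.
#' @param n_per_segment measurements per segment (>= 5 so the trailing
#'   window clears the transient).
#' @param dt_min measurement spacing in minutes.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param well,condition labels for the series.
#' @return List with `series` ([flux_time_series()]) and `schedule`
#'   ([injection_schedule()]).
#' @export
simulate_flux_series <- function(basal, maximal, nonmito, ecar = 30,
                                 protein_ug = 1, noise_sd = 0,
                                 n_per_segment = 5L, dt_min = 6,
                                 seed = NULL, well = "A1",
                                 condition = NA_character_) {
  if (!(maximal >= basal && basal >= nonmito && nonmito >= 0))
    stop("require maximal >= basal >= nonmito >= 0", call. = FALSE)
  if (n_per_segment < 5L)
    stop("need at least 5 measurements per segment", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required for noisy simulation", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # oligomycin removes ATP-linked respiration: drop toward nonmito,
  # retaining a proton-leak remnant of the basal mitochondrial rate
  post_oligo <- nonmito + 0.2 * (basal - nonmito)
  plateaus <- c(basal, post_oligo, maximal, nonmito)
  times <- dt_min * (seq_len(4L * n_per_segment) - 1L)
  ocr <- numeric(length(times))
  prev <- plateaus[1]
  for (s in 1:4) {
    idx <- (s - 1L) * n_per_segment + seq_len(n_per_segment)
    seg <- rep(plateaus[s], n_per_segment)
    if (s > 1L) {
      seg[1] <- prev + 0.5 * (plateaus[s] - prev)
      seg[2] <- prev + 0.9 * (plateaus[s] - prev)
    }
    ocr[idx] <- seg
    prev <- plateaus[s]
  }
  ecar_series <- rep(ecar, length(times))
  if (noise_sd > 0) {
    ocr <- ocr + stats::rnorm(length(ocr), sd = noise_sd)
    ecar_series <- ecar_series + stats::rnorm(length(times), sd = noise_sd)
  }
  inj_times <- dt_min * n_per_segment * (1:3) - dt_min / 2
  list(
    series = flux_time_series(times, ocr, ecar_series,
                              protein_ug = protein_ug, well = well,
                              condition = condition),
    schedule = injection_schedule(inj_times,
                                  c("oligomycin", "fccp", "rotenone"))
  )
}
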