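#' Isotopologue spectral analysis (ISA)
#'
#' ISA estimates two parameters from the MID of a fatty acid measured
#' after 13C tracer feeding: D, the fraction of the lipogenic
#' acetyl-CoA pool derived from the tracer, and g, the fraction of the
#' fatty-acid pool newly synthesized over the labeling period. The
#' lipogenic acetyl-CoA pool is modeled as the convex mixture
#' `X = D * T + (1 - D) * Nnat` of a tracer-derived acetyl MID T and a
#' naturally labeled acetyl MID Nnat (both length-3: M+0, M+1, M+2).
#' Palmitate (8 acetyl units) synthesized de novo from pool X has MID
#' `f(X)`, the 8-fold self-convolution of X; the observed pool is
#' `P = g * f(X) + (1 - g) * f(Nnat)`.
#'
#' @name isa
NULL

#' Acetyl-CoA precursor pool description for ISA
#'
#' @param T_mid length-3 MID (M+0, M+1, M+2) of tracer-derived
#'   acetyl-CoA; see [tracer_acetyl_template()].
#' @param Nnat length-3 MID of naturally labeled acetyl-CoA; defaults to
#'   [natural_acetyl()].
#' @param D fraction of the lipogenic acetyl pool derived from tracer.
#' @return An object of class `acetyl_pool`.
#' @export
acetyl_pool <- function(T_mid, Nnat = natural_acetyl(), D) {
  T_mid <- as_acetyl(T_mid)
  Nnat <- as_acetyl(Nnat)
  if (D < 0 || D > 1) stop("D must lie in [0, 1]", call. = FALSE)
  structure(list(T = T_mid, Nnat = Nnat, D = D), class = "acetyl_pool")
}

as_acetyl <- function(x) {
  f <- as_fraction_vector(x)
  if (length(f) != 3L)
    stop("acetyl MIDs have exactly 3 entries (M+0, M+1, M+2)", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-9)
    stop("acetyl MID must sum to 1", call. = FALSE)
  f
}

#' Naturally labeled acetyl-CoA MID
#'
#' Each acetyl carbon is independently 13C at natural abundance,
#' giving approximately `[0.97871, 0.02118, 0.00011]`.
#'
#' @param p13 natural 13C abundance per carbon.
#' @return Length-3 numeric MID.
#' @export
natural_acetyl <- function(p13 = 0.0107) {
  c((1 - p13)^2, 2 * p13 * (1 - p13), p13^2)
}

#' Mix the tracer-derived and natural acetyl pools
#'
#' Computes `X = D * T + (1 - D) * Nnat`, the MID of the lipogenic
#' acetyl-CoA pool feeding fatty-acid synthase.
#'
#' @param pool an [acetyl_pool()].
#' @return A 2-carbon `mid`.
#' @export
mix_acetyl_pool <- function(pool) {
  stopifnot(inherits(pool, "acetyl_pool"))
  x <- pool$D * pool$T + (1 - pool$D) * pool$Nnat
  mid(x / sum(x), n_carbons = 2L, metabolite = "acetyl-CoA",
      corrected = TRUE)
}

#' Forward ISA model: fatty-acid MID from an acetyl pool
#'
#' A fatty acid of `2 * n_units` carbons is assembled from `n_units`
#' acetyl units drawn independently from pool X, so the de novo MID
#' `f(X)` is the `n_units`-fold self-convolution of X (equivalently the
#' multinomial over unit compositions). The measured pool mixes de novo
#' and pre-existing molecules: `P = g * f(X) + (1 - g) * f(Nnat)`.
#'
#' @param X length-3 acetyl MID of the mixed lipogenic pool.
#' @param Nnat length-3 natural acetyl MID.
#' @param g fraction of the fatty-acid pool newly synthesized.
#' @param n_units number of acetyl units (8 for palmitate, 9 for
#'   stearate).
#' @return A `mid` with `2 * n_units` carbons.
#' @export
#' @examples
#' fatty_acid_forward_mid(c(0, 0, 1), natural_acetyl(), g = 1, n_units = 8)
fatty_acid_forward_mid <- function(X, Nnat = natural_acetyl(), g,
                                   n_units = 8L) {
  X <- as_acetyl(X); Nnat <- as_acetyl(Nnat)
  if (g < 0 || g > 1) stop("g must lie in [0, 1]", call. = FALSE)
  if (n_units < 1L) stop("n_units must be >= 1", call. = FALSE)
  P <- g * self_convolve(X, n_units) +
    (1 - g) * self_convolve(Nnat, n_units)
  mid(P / sum(P), n_carbons = 2L * n_units, metabolite = "fatty_acid",
      corrected = TRUE)
}

#' Fit the ISA model to a measured fatty-acid MID
#'
#' Estimates `(D, g)` by bounded least squares on `[0, 1]^2`,
#' minimizing the sum of squared differences between the measured MID
#' and [fatty_acid_forward_mid()]. A grid of starting points (default
#' 5 x 5) guards against local minima. When replicate MIDs are
#' supplied, the fit uses their mean and a seeded bootstrap over
#' replicates provides percentile confidence intervals.
#'
#' If the measured MID is indistinguishable from the no-synthesis limit
#' `f(Nnat)`, g (and hence D) is unidentifiable; the fit is returned
#' with the `"g-at-boundary"` flag instead of failing.
#'
#' @param measured a corrected fatty-acid `mid`, or a numeric matrix of
#'   replicate MIDs (one row per replicate).
#' @param T_mid length-3 tracer-derived acetyl MID
#'   (see [tracer_acetyl_template()]).
#' @param Nnat length-3 natural acetyl MID.
#' @param n_units acetyl units per molecule; inferred from the MID
#'   length when NULL.
#' @param n_starts starting grid is `n_starts x n_starts`.
#' @param n_boot bootstrap resamples for CIs (used when `measured` has
#'   replicate rows).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `isa_fit`: `D_hat`, `g_hat`,
#'   `residual_norm`, `ci` (2x2 matrix or NULL), `flags`, `n_boot`.
#' @export
fit_isa <- function(measured, T_mid, Nnat = natural_acetyl(),
                    n_units = NULL, n_starts = 5L, n_boot = 200L,
                    seed = NULL) {
  reps <- NULL
  if (is.matrix(measured)) {
    reps <- measured / rowSums(measured)
    y <- colMeans(reps)
  } else {
    y <- as_fraction_vector(measured)
    if (is_mid(measured) && !measured$corrected)
      stop("measured MID must be natural-abundance corrected", call. = FALSE)
  }
  if (is.null(n_units)) {
    if ((length(y) - 1L) %% 2L != 0L)
      stop("fatty-acid MID length must be odd (even carbon number)",
           call. = FALSE)
    n_units <- (length(y) - 1L) %/% 2L
  }
  T_mid <- as_acetyl(T_mid); Nnat <- as_acetyl(Nnat)

  est <- isa_minimize(y, T_mid, Nnat, n_units, n_starts)

  flags <- character(0)
  fN <- self_convolve(Nnat, n_units)
  if (sum((y - fN)^2) < 1e-12 || est$par[2] < 1e-6)
    flags <- c(flags, "g-at-boundary")

  ci <- NULL
  if (!is.null(reps) && nrow(reps) > 1L && n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boots <- matrix(NA_real_, n_boot, 2L)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(reps), replace = TRUE)
      yb <- colMeans(reps[idx, , drop = FALSE])
      boots[b, ] <- isa_minimize(yb, T_mid, Nnat, n_units,
                                 n_starts = 3L)$par
    }
    ci <- t(apply(boots, 2L, stats::quantile, probs = c(0.025, 0.975)))
    dimnames(ci) <- list(c("D", "g"), c("2.5%", "97.5%"))
  }

  structure(
    list(D_hat = est$par[1], g_hat = est$par[2],
         residual_norm = sqrt(est$value), ci = ci,
         flags = flags, n_boot = if (is.null(ci)) 0L else n_boot),
    class = "isa_fit"
  )
}

# Bounded least squares on [0,1]^2 via the g-profile: for fixed D the
# model P = g f(X_D) + (1-g) f(Nnat) is linear in g, so the optimal g
# is the clipped 1-D projection and only D needs numerical search.
# Multistart over D subintervals guards against local minima of the
# profiled objective.
isa_minimize <- function(y, T_mid, Nnat, n_units, n_starts) {
  fN <- self_convolve(Nnat, n_units)
  g_star <- function(D) {
    fX <- self_convolve(D * T_mid + (1 - D) * Nnat, n_units)
    dd <- fX - fN
    denom <- sum(dd^2)
    g <- if (denom > 0) sum((y - fN) * dd) / denom else 0
    list(g = min(max(g, 0), 1), fX = fX)
  }
  profile_obj <- function(D) {
    gs <- g_star(D)
    sum((gs$g * gs$fX + (1 - gs$g) * fN - y)^2)
  }
  bounds <- seq(0, 1, length.out = n_starts + 1L)
  best <- NULL
  for (k in seq_len(n_starts)) {
    o <- stats::optimize(profile_obj, c(bounds[k], bounds[k + 1L]),
                         tol = 1e-10)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  # the interior optimum can sit exactly on a boundary of [0, 1]
  for (D_edge in c(0, 1)) {
    v <- profile_obj(D_edge)
    if (v < best$objective) best <- list(minimum = D_edge, objective = v)
  }
  D_hat <- best$minimum
  list(par = c(D_hat, g_star(D_hat)$g), value = best$objective)
}

#' @export
print.isa_fit <- function(x, ...) {
  cat(sprintf("<isa_fit> D = %.4f, g = %.4f, residual = %.3g\n",
              x$D_hat, x$g_hat, x$residual_norm))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI (n_boot = %d):\n", x$n_boot))
    print(round(x$ci, 4))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tracer-derived acetyl-CoA MID for a fed substrate
#'
#' For uniformly labeled glucose, glutamine, pyruvate, or acetate both
#' acetyl carbons derive from tracer carbons, so each carries 13C with
#' probability equal to the tracer purity: `T = [(1-p)^2, 2p(1-p), p^2]`.
#' An unlabeled substrate gives `[1, 0, 0]`.
#'
#' @param tracer a [tracer_experiment()] or a substrate name.
#' @param purity tracer 13C purity per labeled position.
#' @return Length-3 numeric MID.
#' @export
#' @examples
#' tracer_acetyl_template("glucose", purity = 0.99)
tracer_acetyl_template <- function(tracer, purity = 0.99) {
  if (inherits(tracer, "tracer_experiment")) {
    if (tracer$substrate == "none" || !length(tracer$positions))
      return(c(1, 0, 0))
    if (!is_uniform_tracer(tracer))
      stop("acetyl template requires a uniformly labeled tracer",
           call. = FALSE)
    tracer <- tracer$substrate
  }
  supported <- c("glucose", "glutamine", "pyruvate", "acetate")
  if (identical(tracer, "none")) return(c(1, 0, 0))
  if (!tracer %in% supported)
    stop("unsupported tracer for acetyl template: ", tracer, call. = FALSE)
  if (purity <= 0 || purity > 1)
    stop("purity must be in (0, 1]", call. = FALSE)
  c((1 - purity)^2, 2 * purity * (1 - purity), purity^2)
}
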