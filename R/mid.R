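#' Mass isotopologue distribution (MID) objects
#'
#' A `mid` holds the relative abundances of the mass isotopologues
#' M+0 .. M+n of one metabolite fragment, where n is the number of
#' backbone carbons that can carry tracer label. Fractions are kept
#' normalized to sum to one; the `corrected` flag records whether
#' natural-isotope abundance has been removed, so downstream metrics
#' can refuse uncorrected input.
#'
#' @param fractions numeric vector of length `n_carbons + 1`; entry i is
#'   the fraction of the M+(i-1) isotopologue. Must be non-negative and
#'   sum to 1 within `1e-9` (use [normalize_mid()] for raw intensities).
#' @param n_carbons number of labelable backbone carbons. Defaults to
#'   `length(fractions) - 1`.
#' @param metabolite optional metabolite identifier.
#' @param corrected logical; has natural abundance been removed?
#'
#' @return An object of class `mid`: a list with fields `metabolite_id`,
#'   `n_carbons`, `fractions`, `corrected`.
#' @seealso [normalize_mid()], [mean_enrichment()], [convolve_mids()]
#' @export
#' @examples
#' mid(c(0.5, 0.25, 0.25))
mid <- function(fractions, n_carbons = length(fractions) - 1L,
                metabolite = NA_character_, corrected = FALSE) {
  fractions <- as.numeric(fractions)
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 1L)
    stop("a MID needs at least one backbone carbon", call. = FALSE)
  if (length(fractions) != n_carbons + 1L)
    stop("fractions must have length n_carbons + 1 (M+0 .. M+n)",
         call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions < -1e-12))
    stop("fractions must be finite and non-negative", call. = FALSE)
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("fractions must sum to 1 (got %.12g); normalize first", s),
         call. = FALSE)
  structure(
    list(metabolite_id = as.character(metabolite),
         n_carbons = n_carbons,
         fractions = fractions,
         corrected = isTRUE(corrected)),
    class = "mid"
  )
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s, %d carbons, %s\n",
              ifelse(is.na(x$metabolite_id), "(unnamed)", x$metabolite_id),
              x$n_carbons,
              if (x$corrected) "corrected" else "uncorrected"))
  v <- x$fractions
  names(v) <- paste0("M", seq_along(v) - 1L)
  print(round(v, 5))
  invisible(x)
}

is_mid <- function(x) inherits(x, "mid")

as_fraction_vector <- function(x) {
  if (is_mid(x)) x$fractions else as.numeric(x)
}

#' Normalize raw isotopologue intensities to a MID
#'
#' Converts integrated GC-MS ion intensities for M+0 .. M+n into
#' relative abundances summing to one.
#'
#' @param raw_intensities non-negative numeric vector of intensities,
#'   ordered M+0 first.
#' @inheritParams mid
#' @return A `mid` with proportionally normalized fractions.
#' @export
#' @examples
#' normalize_mid(c(2, 1, 1))$fractions  # 0.5 0.25 0.25
normalize_mid <- function(raw_intensities,
                          n_carbons = length(raw_intensities) - 1L,
                          metabolite = NA_character_, corrected = FALSE) {
  raw_intensities <- as.numeric(raw_intensities)
  if (any(!is.finite(raw_intensities)) || any(raw_intensities < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  s <- sum(raw_intensities)
  if (s <= 0)
    stop("empty spectrum: all intensities are zero", call. = FALSE)
  mid(raw_intensities / s, n_carbons = n_carbons,
      metabolite = metabolite, corrected = corrected)
}

#' Mean enrichment of a MID
#'
#' The average fraction of a metabolite's backbone carbons that carry
#' tracer label: ME = sum(i * M_i) / N over the N backbone carbons.
#' It is 0 for an unlabeled pool and 1 for a uniformly labeled one.
#'
#' @param x a `mid` (or a normalized fraction vector, in which case the
#'   carbon count is taken as `length(x) - 1`).
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' mean_enrichment(mid(c(0.5, 0.25, 0.25)))  # 0.375
mean_enrichment <- function(x) {
  f <- as_fraction_vector(x)
  n <- if (is_mid(x)) x$n_carbons else length(f) - 1L
  sum((seq_along(f) - 1L) * f) / n
}

#' Convolve two MIDs
#'
#' The MID of a condensation product (e.g. oxaloacetate + acetyl-CoA ->
#' citrate) is the discrete convolution of the reactant MIDs, assuming
#' the two labeling states are independent. Carbon counts add.
#'
#' @param a,b `mid` objects (normalized).
#' @return A `mid` with `a$n_carbons + b$n_carbons` carbons.
#' @export
#' @examples
#' convolve_mids(mid(c(0.5, 0.5)), mid(c(0.5, 0.5)))$fractions
convolve_mids <- function(a, b) {
  if (!is_mid(a) || !is_mid(b))
    stop("convolve_mids expects two mid objects", call. = FALSE)
  f <- conv_vec(a$fractions, b$fractions)
  f <- f / sum(f)
  mid(f, n_carbons = a$n_carbons + b$n_carbons,
      metabolite = NA_character_,
      corrected = a$corrected && b$corrected)
}

# plain polynomial-product convolution of two probability vectors
conv_vec <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# n-fold self convolution (square-and-multiply not needed at these sizes)
self_convolve <- function(f, n) {
  out <- 1
  for (k in seq_len(n)) out <- conv_vec(out, f)
  out
}
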