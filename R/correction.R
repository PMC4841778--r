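#' Natural isotope abundance tables
#'
#' Per-element natural isotope distributions as vectors of probabilities
#' indexed by nominal mass shift (entry 1 = +0, entry 2 = +1, ...).
#' Values are current IUPAC representative abundances for the elements
#' found in TBDMS/methyl-ester derivatized GC-MS fragments.
#'
#' @return Named list mapping element symbol to a numeric shift
#'   distribution summing to 1.
#' @export
#' @examples
#' iupac_isotopes()$C  # 12C, 13C
iupac_isotopes <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Read an isotope abundance table from YAML
#'
#' The file maps element symbols to lists of `(shift, abundance)` pairs,
#' e.g. `C: [[0, 0.9893], [1, 0.0107]]`. Missing shifts are zero.
#'
#' @param path path to a YAML file.
#' @return Named list in the [iupac_isotopes()] format.
#' @export
read_isotope_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(entries) {
    shifts <- vapply(entries, function(e) as.numeric(e[[1]]), numeric(1))
    abund  <- vapply(entries, function(e) as.numeric(e[[2]]), numeric(1))
    v <- numeric(max(shifts) + 1L)
    v[shifts + 1L] <- abund
    v
  })
  for (el in names(out)) {
    if (abs(sum(out[[el]]) - 1) > 1e-6)
      stop(sprintf("abundances for element %s do not sum to 1", el),
           call. = FALSE)
  }
  out
}

#' Elemental formula of a measured GC-MS fragment
#'
#' Describes the fragment actually measured, including derivatization
#' atoms, plus how many of its carbons belong to the metabolite backbone
#' (and can therefore carry tracer label).
#'
#' @param formula either a named vector/list of element counts
#'   (`C`, `H`, `N`, `O`, `Si`, `S`) or a formula string like
#'   `"C14H28NO3Si2"`.
#' @param n_backbone_carbons number of backbone (tracer-labelable)
#'   carbons; must not exceed the total carbon count.
#' @return An object of class `fragment_formula`.
#' @export
#' @examples
#' fragment_formula("C9H15NO2Si", 3)  # a 3-carbon metabolite fragment
fragment_formula <- function(formula, n_backbone_carbons) {
  counts <- if (is.character(formula)) parse_formula(formula)
            else unlist(formula)
  known <- c("C", "H", "N", "O", "Si", "S")
  bad <- setdiff(names(counts), known)
  if (length(bad))
    stop("unsupported element: ", paste(bad, collapse = ", "),
         call. = FALSE)
  full <- stats::setNames(numeric(length(known)), known)
  full[names(counts)] <- as.numeric(counts)
  if (any(full < 0) || any(full != round(full)))
    stop("element counts must be non-negative integers", call. = FALSE)
  n_backbone_carbons <- as.integer(n_backbone_carbons)
  if (n_backbone_carbons < 1L || n_backbone_carbons > full[["C"]])
    stop("backbone carbons must be between 1 and the total carbon count",
         call. = FALSE)
  structure(list(counts = full, n_backbone_carbons = n_backbone_carbons),
            class = "fragment_formula")
}

# "C14H28NO3Si2" -> named count vector
parse_formula <- function(s) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (!length(pieces) || paste(pieces, collapse = "") != s)
    stop("cannot parse formula string: ", s, call. = FALSE)
  els <- sub("[0-9]*$", "", pieces)
  ns  <- sub("^[A-Z][a-z]?", "", pieces)
  ns  <- ifelse(ns == "", 1L, as.integer(ns))
  tapply(ns, els, sum)
}

#' Build a natural-abundance correction matrix
#'
#' Constructs the square matrix M of size `(n_backbone + 1)` whose entry
#' `(j, i)` (zero-based shifts) is the probability that a molecule with
#' i tracer-derived backbone carbons is observed at nominal mass shift j.
#' Column i is the convolution of (a) the binomial labeling distribution
#' of the i tracer positions at the stated tracer purity, (b) natural
#' 13C in the remaining unlabeled backbone carbons, and (c) natural
#' isotopes of every non-backbone atom (extra C, H, N, O, Si, S from
#' derivatization). Shifts beyond the measured M+0..M+n window are
#' truncated, so columns may sum to slightly less than 1.
#'
#' @param formula a [fragment_formula()].
#' @param isotope_abundances per-element shift distributions; defaults
#'   to [iupac_isotopes()].
#' @param tracer_purity isotopic purity of the tracer (probability that
#'   a nominally labeled position actually carries 13C). Default 1;
#'   pass e.g. 0.99 to fold tracer-impurity correction into the matrix.
#' @param backbone_natural apply natural 13C abundance to the unlabeled
#'   backbone positions (default TRUE). Set FALSE to treat the backbone
#'   as tracer-only, e.g. when the backbone correction is handled
#'   elsewhere.
#' @return A `(n+1) x (n+1)` matrix with non-negative entries and
#'   column sums <= 1.
#' @export
build_correction_matrix <- function(formula,
                                    isotope_abundances = iupac_isotopes(),
                                    tracer_purity = 1,
                                    backbone_natural = TRUE) {
  if (!inherits(formula, "fragment_formula"))
    stop("formula must be a fragment_formula", call. = FALSE)
  if (tracer_purity <= 0 || tracer_purity > 1)
    stop("tracer_purity must be in (0, 1]", call. = FALSE)
  ab <- isotope_abundances
  bad <- setdiff(names(formula$counts)[formula$counts > 0], names(ab))
  if (length(bad))
    stop("unsupported element: ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- formula$n_backbone_carbons
  counts <- formula$counts

  # shift distribution of all fixed non-tracer atoms
  fixed <- 1
  extra_c <- counts[["C"]] - n
  if (extra_c > 0) fixed <- conv_pow(fixed, ab$C, extra_c)
  for (el in c("H", "N", "O", "Si", "S")) {
    k <- counts[[el]]
    if (k > 0) fixed <- conv_pow(fixed, ab[[el]], k)
  }

  size <- n + 1L
  M <- matrix(0, size, size)
  for (i in 0:n) {
    col <- fixed
    # tracer positions: each nominally labeled carbon is 13C w.p. purity,
    # so the shift they contribute is Binomial(i, purity)
    if (i > 0)
      col <- conv_vec(col, stats::dbinom(0:i, i, tracer_purity))
    if (backbone_natural && (n - i) > 0)
      col <- conv_pow(col, ab$C, n - i)
    M[, i + 1L] <- replace_na0(col[seq_len(size)])
  }
  M
}

replace_na0 <- function(x) { x[is.na(x)] <- 0; x }

# convolve `base` with k copies of `d`
conv_pow <- function(base, d, k) {
  for (j in seq_len(k)) base <- conv_vec(base, d)
  base
}

#' Remove natural isotope abundance from a raw MID
#'
#' Solves the non-negative least-squares problem
#' `min || M x - raw ||^2, x >= 0` where M is the fragment's correction
#' matrix, then renormalizes x to sum to one. NNLS keeps the corrected
#' fractions non-negative, so downstream ratios stay well defined.
#'
#' @param raw an uncorrected `mid` (raw relative abundances).
#' @param matrix correction matrix from [build_correction_matrix()].
#' @return A corrected `mid`.
#' @export
correct_natural_abundance <- function(raw, matrix) {
  if (!is_mid(raw))
    stop("raw must be a mid", call. = FALSE)
  if (raw$corrected)
    stop("MID is already flagged as corrected", call. = FALSE)
  size <- raw$n_carbons + 1L
  if (!is.matrix(matrix) || nrow(matrix) != size || ncol(matrix) != size)
    stop("correction matrix dimensions do not match the MID", call. = FALSE)
  fit <- pracma::lsqnonneg(matrix, raw$fractions)
  x <- fit$x
  if (sum(x) <= 0)
    stop("correction produced an empty spectrum", call. = FALSE)
  mid(x / sum(x), n_carbons = raw$n_carbons,
      metabolite = raw$metabolite_id, corrected = TRUE)
}
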