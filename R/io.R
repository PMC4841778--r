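#' Read and write MID tables
#'
#' The on-disk dialect is a plain CSV with one measured fragment per
#' row: `sample_id`, `condition`, `metabolite`, `fragment_formula`,
#' `backbone_carbons`, then raw intensity columns `m0`, `m1`, ...
#' Rows for metabolites with fewer carbons than the widest row leave
#' their trailing isotopologue columns empty; the reader fills them
#' with 0.
#'
#' @param path CSV path.
#' @return `read_mid_table`: a data.frame in the dialect above.
#' @export
read_mid_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "metabolite", "fragment_formula",
            "backbone_carbons")
  if (!all(need %in% names(df)))
    stop("MID table must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  if (!length(mcols))
    stop("MID table has no m0..mN intensity columns", call. = FALSE)
  for (col in mcols) {
    v <- df[[col]]
    v[is.na(v)] <- 0
    df[[col]] <- as.numeric(v)
  }
  df[, c(need, mcols[order(as.integer(sub("^m", "", mcols)))])]
}

#' @param table a data.frame in the MID table dialect.
#' @rdname read_mid_table
#' @export
write_mid_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract MID objects from a MID table
#'
#' Each row becomes a `mid` of its own `backbone_carbons` length
#' (columns beyond `m<backbone_carbons>` are ignored; they are padding
#' for narrower metabolites). Raw intensities are proportionally
#' normalized unless the table is flagged as already normalized.
#'
#' @param table a data.frame from [read_mid_table()].
#' @param normalized if TRUE, rows are trusted to already sum to 1.
#' @param corrected correction state to stamp on the returned MIDs.
#' @return A list of `mid` objects, one per row, with the row's
#'   metadata attached as attributes `sample_id` and `condition`.
#' @export
mids_from_table <- function(table, normalized = FALSE, corrected = FALSE) {
  mcols <- grep("^m[0-9]+$", names(table), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  lapply(seq_len(nrow(table)), function(i) {
    n <- as.integer(table$backbone_carbons[i])
    v <- as.numeric(unlist(table[i, mcols[seq_len(n + 1L)]]))
    m <- if (normalized)
      mid(v, n_carbons = n, metabolite = table$metabolite[i],
          corrected = corrected)
    else
      normalize_mid(v, n_carbons = n, metabolite = table$metabolite[i],
                    corrected = corrected)
    attr(m, "sample_id") <- table$sample_id[i]
    attr(m, "condition") <- table$condition[i]
    m
  })
}

#' Natural-abundance correct every row of a MID table
#'
#' Builds a correction matrix per row from its fragment formula and
#' backbone carbon count, solves the non-negative least-squares
#' deconvolution, and returns a table of corrected fractions in the
#' same dialect (intensities replaced by corrected relative
#' abundances).
#'
#' @param table a data.frame in the MID table dialect.
#' @param tracer_purity tracer 13C purity folded into the correction
#'   (default 0.99).
#' @param isotope_abundances per-element isotope table.
#' @return A data.frame in the same dialect with corrected fractions.
#' @export
correct_mid_table <- function(table, tracer_purity = 0.99,
                              isotope_abundances = iupac_isotopes()) {
  mcols <- grep("^m[0-9]+$", names(table), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  out <- table
  for (i in seq_len(nrow(table))) {
    n <- as.integer(table$backbone_carbons[i])
    frag <- fragment_formula(table$fragment_formula[i], n)
    M <- build_correction_matrix(frag, isotope_abundances,
                                 tracer_purity = tracer_purity)
    raw <- normalize_mid(as.numeric(unlist(table[i, mcols[seq_len(n + 1L)]])),
                         n_carbons = n,
                         metabolite = table$metabolite[i])
    corr <- correct_natural_abundance(raw, M)
    out[i, mcols] <- NA_real_
    out[i, mcols[seq_len(n + 1L)]] <- corr$fractions
  }
  out
}

# assemble one MID-table row, padding to the table's widest MID
mid_table_row <- function(sample_id, condition, metabolite, formula,
                          backbone_carbons, intensities, width) {
  row <- as.list(c(rep(NA_real_, width + 1L)))
  names(row) <- paste0("m", 0:width)
  row[seq_along(intensities)] <- intensities
  c(list(sample_id = sample_id, condition = condition,
         metabolite = metabolite, fragment_formula = formula,
         backbone_carbons = backbone_carbons), row)
}
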