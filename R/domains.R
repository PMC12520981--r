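#' Boundary probability per cell type
#'
#' The boundary probability of a 25 kb bin in a cell type is the fraction of
#' that type's cells calling the bin a domain boundary. Per-cell boundary
#' calls (e.g. from a TAD caller on imputed single-cell matrices) are
#' consumed, not produced, here.
#'
#' @param boundaries logical/0-1 matrix, cells in rows (rownames =
#'   barcodes), 25 kb bins in columns.
#' @param cell_types character vector of labels, one per row.
#' @return tibble `cell_type`, `bin`, `n_cells`, `probability`.
#' @export
boundary_probability <- function(boundaries, cell_types) {
  stopifnot(nrow(boundaries) == length(cell_types))
  if (anyNA(cell_types)) stop("missing cell-type label: every cell must belong to a non-empty type")
  if (any(table(cell_types) == 0)) stop("empty cell type")
  out <- lapply(split(seq_len(nrow(boundaries)), cell_types), function(idx) {
    tibble::tibble(
      bin = seq_len(ncol(boundaries)),
      n_cells = length(idx),
      probability = colMeans(boundaries[idx, , drop = FALSE])
    )
  })
  dplyr::bind_rows(out, .id = "cell_type")
}

#' Chi-square test for cell-type-variable domain boundaries
#'
#' Per bin, an n x 2 contingency table (cell types x boundary
#' presence/absence) is tested with the chi-square statistic (no continuity
#' correction); Benjamini-Hochberg FDRs are computed across tested bins. A
#' boundary is "variable" when FDR < `fdr` AND the boundary-probability
#' spread (max - min across types) exceeds `min_diff`. Bins with no
#' positive cell in any type are skipped and flagged.
#'
#' @param boundaries logical/0-1 matrix, cells x bins.
#' @param cell_types labels, one per row (>= 2 types).
#' @param fdr FDR threshold (default 0.001).
#' @param min_diff boundary-probability difference threshold (default 0.05).
#' @return tibble `bin`, `statistic`, `p_value`, `fdr`, `prob_diff`,
#'   `tested`, `low_expected` (any expected count < 5), `variable`.
#' @export
variable_boundary_test <- function(boundaries, cell_types, fdr = 0.001,
                                   min_diff = 0.05) {
  types <- unique(cell_types)
  if (length(types) < 2) stop("need >= 2 cell types")
  idx <- split(seq_len(nrow(boundaries)), cell_types)
  n_by_type <- lengths(idx)
  pos <- vapply(idx, function(i) colSums(boundaries[i, , drop = FALSE]),
                numeric(ncol(boundaries)))
  pos <- matrix(pos, ncol = length(idx),
                dimnames = list(NULL, names(idx))) # bins x types
  out <- tibble::tibble(
    bin = seq_len(ncol(boundaries)),
    statistic = NA_real_, p_value = NA_real_,
    prob_diff = apply(sweep(pos, 2, n_by_type, "/"), 1, function(p)
      max(p) - min(p)),
    tested = rowSums(pos) > 0, low_expected = NA
  )
  for (b in which(out$tested)) {
    tab <- rbind(present = pos[b, ], absent = n_by_type - pos[b, ])
    suppressWarnings(ct <- stats::chisq.test(t(tab), correct = FALSE))
    out$statistic[b] <- unname(ct$statistic)
    out$p_value[b] <- ct$p.value
    out$low_expected[b] <- any(ct$expected < 5)
  }
  out$fdr <- NA_real_
  out$fdr[out$tested] <- stats::p.adjust(out$p_value[out$tested],
                                         method = "BH")
  out$variable <- !is.na(out$fdr) & out$fdr < fdr & out$prob_diff > min_diff
  out
}
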