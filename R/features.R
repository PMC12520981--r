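#' Hub index: Gini coefficient of per-chromosome trans contacts
#'
#' For a query 1 Mb bin, trans contacts are aggregated per partner chromosome
#' (every eligible chromosome contributes an entry, zeros included; the query
#' bin's own chromosome and excluded chromosomes such as chrY are left out)
#' and their evenness is summarised by the Gini coefficient
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x).}
#' A low hub index means trans contacts spread evenly across chromosomes
#' (ecDNA-like dispersion); a high index means concentration on few
#' chromosomes (HSR-like). Operates on raw counts and is scale-invariant.
#'
#' @param x numeric vector of trans contact counts, one entry per eligible
#'   chromosome (zeros included).
#' @return Gini in [0, 1], or `NA_real_` when all counts are zero.
#' @examples
#' hub_index(c(10, 10, 10, 10)) # 0
#' hub_index(c(40, 0, 0, 0))    # 0.75
#' @export
hub_index <- function(x) {
  if (length(x) == 0) stop("empty trans-count vector")
  if (any(x < 0)) stop("negative counts")
  tot <- sum(x)
  if (tot == 0) return(NA_real_)
  n <- length(x)
  # mean-difference form via the sorted-rank identity (O(n log n))
  xs <- sort(x)
  i <- seq_len(n)
  sum((2 * i - n - 1) * xs) / (n^2 * mean(x))
}

#' Per-chromosome trans contact counts for a query bin
#'
#' @param set an `sc_cellset` at the feature resolution.
#' @param barcode cell identifier.
#' @param bin global query bin.
#' @return named numeric vector over eligible chromosomes (query bin's own
#'   chromosome and the genome's excluded chromosomes omitted; zeros kept).
#' @export
trans_counts_by_chrom <- function(set, barcode, bin) {
  g <- set$genome
  chrom_of <- bin_chrom(g)
  own <- chrom_of[bin]
  eligible <- setdiff(g$chrom_names, c(own, g$excluded_chroms))
  ct <- set$contacts
  sel <- ct$barcode == barcode & (ct$bin1 == bin | ct$bin2 == bin)
  ct <- ct[sel, ]
  partner <- ifelse(ct$bin1 == bin, ct$bin2, ct$bin1)
  pchrom <- chrom_of[partner]
  keep <- pchrom %in% eligible
  agg <- tapply(ct$count[keep], factor(pchrom[keep], levels = eligible), sum)
  out <- as.numeric(agg)
  out[is.na(out)] <- 0
  names(out) <- eligible
  out
}

#' Trans-to-cis contacting-bin ratio for a query bin
#'
#' R = N_T / N_C where N_T is the number of distinct trans partner bins with
#' at least one contact to the query bin and N_C the number of distinct cis
#' partner bins (same chromosome, the query bin itself included when
#' intra-bin contacts exist). A copy-number-robust measure of trans contact
#' tendency. Undefined (NA) when N_C = 0.
#'
#' @param set an `sc_cellset`.
#' @param barcode cell identifier.
#' @param bin global query bin.
#' @return list with `ratio`, `n_trans_bins`, `n_cis_bins`, `n_trans_contacts`.
#' @export
trans_cis_bin_ratio <- function(set, barcode, bin) {
  chrom_of <- bin_chrom(set$genome)
  own <- chrom_of[bin]
  ct <- set$contacts
  sel <- ct$barcode == barcode & (ct$bin1 == bin | ct$bin2 == bin)
  ct <- ct[sel & ct$count > 0, ]
  partner <- ifelse(ct$bin1 == bin, ct$bin2, ct$bin1)
  is_cis <- chrom_of[partner] == own
  n_c <- length(unique(partner[is_cis]))
  n_t <- length(unique(partner[!is_cis]))
  list(
    ratio = if (n_c > 0) n_t / n_c else NA_real_,
    n_trans_bins = n_t, n_cis_bins = n_c,
    n_trans_contacts = sum(ct$count[!is_cis])
  )
}

#' Per-(cell, bin) ecDNA feature table
#'
#' Computes, for every requested (cell, bin), the triplet used by both ecDNA
#' callers: inferred copy number, hub index and trans-to-cis contacting-bin
#' ratio, plus the supporting counts.
#'
#' @param set an `sc_cellset` at the feature resolution (1 Mb typical).
#' @param cnv_per_cell tibble `barcode`, `bin`, `inferred_copy` (e.g. stacked
#'   [infer_cnv()] outputs per cell); may cover only the bins of interest.
#' @param bins global bins to evaluate; default all.
#' @param barcodes cells to evaluate; default all in `set`.
#' @return a tibble with one row per (barcode, bin): `barcode`, `bin`,
#'   `inferred_copy`, `hub_index`, `trans_cis_ratio`, `n_trans_contacts`,
#'   `n_cis_bins`, `n_trans_bins`.
#' @export
build_feature_table <- function(set, cnv_per_cell = NULL,
                                bins = seq_len(n_bins(set$genome)),
                                barcodes = set$barcodes) {
  g <- set$genome
  chrom_of <- bin_chrom(g)
  ct <- set$contacts |> dplyr::filter(.data$barcode %in% barcodes)
  if (length(bins) < n_bins(g)) {
    ct <- ct[ct$bin1 %in% bins | ct$bin2 %in% bins, ]
  }
  # long form: one row per (cell, anchor bin, partner bin)
  long <- dplyr::bind_rows(
    tibble::tibble(barcode = ct$barcode, qbin = ct$bin1, partner = ct$bin2,
                   count = ct$count),
    {
      off <- ct[ct$bin1 != ct$bin2, ]
      tibble::tibble(barcode = off$barcode, qbin = off$bin2,
                     partner = off$bin1, count = off$count)
    }
  ) |>
    dplyr::filter(.data$qbin %in% bins)
  long$own_chrom <- chrom_of[long$qbin]
  long$partner_chrom <- chrom_of[long$partner]
  long$is_cis <- long$partner_chrom == long$own_chrom
  long$eligible_trans <- !long$is_cis &
    !(long$partner_chrom %in% g$excluded_chroms)

  n_eligible <- vapply(bins, function(b) {
    length(setdiff(g$chrom_names, c(chrom_of[b], g$excluded_chroms)))
  }, numeric(1))
  names(n_eligible) <- as.character(bins)

  stats_tbl <- long |>
    dplyr::group_by(.data$barcode, .data$qbin) |>
    dplyr::summarise(
      n_cis_bins = dplyr::n_distinct(.data$partner[.data$is_cis]),
      n_trans_bins = dplyr::n_distinct(.data$partner[!.data$is_cis]),
      n_trans_contacts = sum(.data$count[!.data$is_cis]),
      .groups = "drop"
    )

  gini_tbl <- long |>
    dplyr::filter(.data$eligible_trans) |>
    dplyr::group_by(.data$barcode, .data$qbin, .data$partner_chrom) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop_last") |>
    dplyr::summarise(
      hub_index = gini_with_zeros(.data$n,
                                  n_eligible[as.character(.data$qbin[1])]),
      .groups = "drop"
    )

  grid <- tidyr::expand_grid(barcode = barcodes, bin = as.integer(bins))
  out <- grid |>
    dplyr::left_join(stats_tbl, by = c("barcode", bin = "qbin")) |>
    dplyr::left_join(gini_tbl, by = c("barcode", bin = "qbin")) |>
    dplyr::mutate(
      n_cis_bins = dplyr::coalesce(.data$n_cis_bins, 0L),
      n_trans_bins = dplyr::coalesce(.data$n_trans_bins, 0L),
      n_trans_contacts = dplyr::coalesce(.data$n_trans_contacts, 0),
      trans_cis_ratio = dplyr::if_else(.data$n_cis_bins > 0,
                                       .data$n_trans_bins / .data$n_cis_bins,
                                       NA_real_)
    )
  if (!is.null(cnv_per_cell)) {
    out <- dplyr::left_join(
      out, dplyr::select(cnv_per_cell, "barcode", "bin", "inferred_copy"),
      by = c("barcode", "bin")
    )
  } else {
    out$inferred_copy <- NA_real_
  }
  dplyr::select(out, "barcode", "bin", "inferred_copy", "hub_index",
                "trans_cis_ratio", "n_trans_contacts", "n_cis_bins",
                "n_trans_bins")
}

# Gini over observed per-chromosome totals padded with zeros up to n_chrom
gini_with_zeros <- function(counts, n_chrom) {
  x <- c(counts, rep(0, max(0, n_chrom - length(counts))))
  hub_index(x)
}

#' Per-cell inferred copy number at selected bins
#'
#' Convenience wrapper running [infer_cnv()] cell by cell and returning the
#' stacked per-(cell, bin) copies, suitable for [build_feature_table()].
#'
#' @param set an `sc_cellset`.
#' @param bins bins to report (default all).
#' @param smooth_window rolling-median window passed to [infer_cnv()].
#' @param mask optional logical mask of length B.
#' @return tibble `barcode`, `bin`, `inferred_copy`.
#' @export
cnv_per_cell <- function(set, bins = seq_len(n_bins(set$genome)),
                         smooth_window = 5, mask = NULL) {
  marg <- cell_marginals(set)
  out <- lapply(split(marg, marg$barcode), function(df) {
    prof <- infer_cnv(df, set$genome, mask = mask,
                      smooth_window = smooth_window)
    tibble::tibble(barcode = df$barcode[1], bin = as.integer(bins),
                   inferred_copy = prof$inferred_copy[bins])
  })
  dplyr::bind_rows(out)
}
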