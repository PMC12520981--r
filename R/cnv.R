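#' Infer copy number from contact coverage marginals
#'
#' A self-contained coverage-ratio estimator: per-bin marginal coverage is
#' smoothed with a rolling median (window `smooth_window` bins, applied within
#' each chromosome), divided by the genome-wide median over unmasked bins to
#' give a copy ratio, and doubled under the diploid assumption:
#' `inferred_copy = 2 * copy_ratio`. Masked bins (blacklist, zero
#' mappability) are reported as missing.
#'
#' @param marginals tibble with `bin` and `marginal` (one cell or pseudo-bulk;
#'   bins absent from the table count as zero coverage).
#' @param genome the `sc_genome` the bins refer to.
#' @param mask optional logical vector of length B, `TRUE` = exclude bin.
#' @param smooth_window rolling-median window in bins (odd; default 5).
#' @return a `cnv_profile` tibble: `bin`, `chrom`, `coverage`, `copy_ratio`,
#'   `inferred_copy`, `masked`.
#' @export
infer_cnv <- function(marginals, genome, mask = NULL, smooth_window = 5) {
  B <- n_bins(genome)
  cov <- numeric(B)
  cov[marginals$bin] <- marginals$marginal
  if (is.null(mask)) mask <- rep(FALSE, B)
  stopifnot(length(mask) == B)
  if (all(cov[!mask] == 0)) stop("all-zero coverage on unmasked bins")
  chrom <- bin_chrom(genome)
  sm <- unlist(lapply(split(cov, factor(chrom, levels = genome$chrom_names)),
                      rolling_median, k = smooth_window), use.names = FALSE)
  med <- stats::median(sm[!mask])
  # sparse high-resolution profiles can have a zero median; fall back to the
  # mean so the ratio stays defined (flagged for diploid calibration)
  if (med == 0) med <- mean(sm[!mask])
  ratio <- sm / med
  ratio[mask] <- NA_real_
  structure(
    tibble::tibble(
      bin = seq_len(B), chrom = chrom, coverage = cov,
      copy_ratio = ratio, inferred_copy = 2 * ratio, masked = mask
    ),
    class = c("cnv_profile", "tbl_df", "tbl", "data.frame"),
    genome = genome
  )
}

# centered rolling median with partial windows at the edges
rolling_median <- function(x, k) {
  if (k <= 1 || length(x) == 1) return(x)
  zoo::rollapply(x, width = k, FUN = stats::median, partial = TRUE,
                 align = "center")
}

# centered rolling mean with partial windows at the edges
rolling_mean <- function(x, k) {
  if (k <= 1 || length(x) == 1) return(x)
  zoo::rollapply(x, width = k, FUN = mean, partial = TRUE, align = "center")
}

#' Segment a copy-number profile into constant-copy runs
#'
#' Greedy changepoint scan per chromosome: a new segment opens where the
#' smoothed copy number changes by more than `fold` relative to the running
#' segment mean; segments shorter than `min_seg_bins` are absorbed into the
#' neighbouring segment with the closer mean.
#'
#' @param profile a `cnv_profile` from [infer_cnv()].
#' @param min_seg_bins minimum segment length in bins.
#' @param fold relative change opening a breakpoint (default 0.5 = 50%).
#' @return tibble `chrom`, `start_bin`, `end_bin`, `mean_copy` (global bins,
#'   inclusive), tiling every chromosome.
#' @export
segment_cnv <- function(profile, min_seg_bins = 3, fold = 0.5) {
  genome <- attr(profile, "genome")
  out <- lapply(split(profile, factor(profile$chrom,
                                      levels = genome$chrom_names)), function(df) {
    x <- df$inferred_copy
    x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    n <- length(x)
    # greedy scan
    starts <- 1L
    seg_mean <- x[1]
    seg_len <- 1L
    for (i in seq_len(n)[-1]) {
      ref <- max(seg_mean, 1e-9)
      if (abs(x[i] - seg_mean) / ref > fold) {
        starts <- c(starts, i)
        seg_mean <- x[i]; seg_len <- 1L
      } else {
        seg_mean <- (seg_mean * seg_len + x[i]) / (seg_len + 1)
        seg_len <- seg_len + 1L
      }
    }
    ends <- c(starts[-1] - 1L, n)
    # merge adjacent segments whose means no longer differ beyond the fold
    merge_similar <- function(starts, ends) {
      repeat {
        if (length(starts) <= 1) break
        means <- vapply(seq_along(starts),
                        function(j) mean(x[starts[j]:ends[j]]), numeric(1))
        rel <- abs(diff(means)) / pmax(pmin(means[-length(means)],
                                            means[-1]), 1e-9)
        k <- which(rel <= fold)[1]
        if (is.na(k)) break
        starts <- starts[-(k + 1)]
        ends <- ends[-k]
      }
      list(starts = starts, ends = ends)
    }
    # absorb short segments
    repeat {
      len <- ends - starts + 1L
      if (length(starts) <= 1 || all(len >= min_seg_bins)) break
      k <- which(len < min_seg_bins)[1]
      means <- vapply(seq_along(starts),
                      function(j) mean(x[starts[j]:ends[j]]), numeric(1))
      nb <- c(if (k > 1) k - 1L, if (k < length(starts)) k + 1L)
      tgt <- nb[which.min(abs(means[nb] - means[k]))]
      lo <- min(k, tgt); hi <- max(k, tgt)
      starts <- starts[-hi]
      ends <- ends[-lo]
    }
    ms <- merge_similar(starts, ends)
    starts <- ms$starts; ends <- ms$ends
    tibble::tibble(
      chrom = df$chrom[1],
      start_bin = df$bin[starts],
      end_bin = df$bin[ends],
      mean_copy = vapply(seq_along(starts),
                         function(j) mean(x[starts[j]:ends[j]]), numeric(1))
    )
  })
  dplyr::bind_rows(out)
}

#' Plot a copy-number profile along the genome
#' @param profile a `cnv_profile`.
#' @return a ggplot object.
#' @export
plot_cnv_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data$inferred_copy,
                               colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = "global bin", y = "inferred copy number") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
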