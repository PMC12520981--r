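#' Extract multi-way (>= 3-bin) contacts from walk-aware pairs
#'
#' Pairs sharing a read ID describe one sequencing read (a chromatin walk).
#' Per-contact filters apply first: only trans contacts and cis contacts
#' with genomic distance > `min_cis_bp` (10 kb) are retained, anchors
#' overlapping the blacklist are removed, and only autosomal anchors count.
#' A read qualifies as multi-way if its surviving anchors cover >= 3 unique
#' 10 kb bins; a cell's bin indicator is 1 iff the bin appears in at least
#' one qualifying read of that cell.
#'
#' @param pairs pairs tibble carrying a `read_id` column.
#' @param genome an `sc_genome` (any resolution; rebinned to `resolution`).
#' @param blacklist optional interval tibble (`chrom`, `start` 0-based, `end`).
#' @param resolution bin width for multiway analysis (default 10 kb).
#' @param min_cis_bp minimum cis distance (exclusive; default 10 kb).
#' @param autosomes chromosomes counted as autosomes; default all chromosomes
#'   except chrX/chrY and the genome's excluded set.
#' @return list with `indicators` (tibble `barcode`, `bin`, value 1) and
#'   `reads` (tibble `barcode`, `read_id`, `n_bins`).
#' @export
extract_multiway <- function(pairs, genome, blacklist = NULL,
                             resolution = 1e4, min_cis_bp = 1e4,
                             autosomes = NULL) {
  if (!"read_id" %in% names(pairs)) {
    stop("pairs table has no read_id column; multi-way extraction needs walks")
  }
  g <- with_resolution(genome, resolution)
  if (is.null(autosomes)) {
    autosomes <- setdiff(g$chrom_names, c("chrX", "chrY", g$excluded_chroms))
  }
  keep <- (pairs$chrom1 != pairs$chrom2 |
             abs(pairs$pos2 - pairs$pos1) > min_cis_bp) &
    pairs$chrom1 %in% autosomes & pairs$chrom2 %in% autosomes
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    keep <- keep &
      !anchor_in_intervals(pairs$chrom1, pairs$pos1, blacklist) &
      !anchor_in_intervals(pairs$chrom2, pairs$pos2, blacklist)
  }
  pr <- pairs[keep, , drop = FALSE]
  if (nrow(pr) == 0) {
    return(list(indicators = tibble::tibble(barcode = character(),
                                            bin = integer()),
                reads = tibble::tibble(barcode = character(),
                                       read_id = character(),
                                       n_bins = integer())))
  }
  anchors <- tibble::tibble(
    barcode = rep(pr$barcode, 2),
    read_id = rep(pr$read_id, 2),
    bin = c(bin_index(g, pr$chrom1, pr$pos1), bin_index(g, pr$chrom2, pr$pos2))
  ) |> dplyr::distinct()
  reads <- anchors |>
    dplyr::count(.data$barcode, .data$read_id, name = "n_bins")
  multi <- reads[reads$n_bins >= 3, c("barcode", "read_id")]
  indicators <- anchors |>
    dplyr::semi_join(multi, by = c("barcode", "read_id")) |>
    dplyr::distinct(.data$barcode, .data$bin)
  list(indicators = indicators, reads = reads)
}

#' Call multi-way chromatin hubs per cell type
#'
#' For each cell type, the per-bin frequency f is the fraction of that
#' type's cells whose multi-way indicator is 1. Bins in the top 1% of
#' frequency (nearest-rank percentile, strictly greater) or with mappability
#' < `min_mappability` are excluded from the mean/SD estimation (they are
#' flagged in the output but remain eligible: hub status is defined purely
#' by the Z-score). Frequencies are converted to Z-scores,
#' z = (f - mean) / SD, and a bin is a hub when z > `z_cutoff` (1.96).
#'
#' @param indicators tibble `barcode`, `bin` (presence records) as from
#'   [extract_multiway()].
#' @param cell_types tibble `barcode`, `cell_type` labelling every cell
#'   (cells without indicator records count as all-zero).
#' @param genome the 10 kb `sc_genome` (gives the bin universe).
#' @param mappability numeric vector of length B (default all 1).
#' @param z_cutoff hub threshold on the Z-score.
#' @param top_quantile frequency quantile excluded from estimation (0.99).
#' @param min_mappability mappability threshold (0.8).
#' @param bins restrict the tested universe (default all autosomal bins of
#'   `genome` excluding chrX/chrY).
#' @return a hub tibble: `cell_type`, `bin`, `frequency`, `z_score`,
#'   `excluded`, `hub`.
#' @export
call_hubs <- function(indicators, cell_types, genome, mappability = NULL,
                      z_cutoff = 1.96, top_quantile = 0.99,
                      min_mappability = 0.8, bins = NULL) {
  B <- n_bins(genome)
  if (is.null(mappability)) mappability <- rep(1, B)
  stopifnot(length(mappability) == B)
  if (is.null(bins)) {
    chrom_of <- bin_chrom(genome)
    bins <- which(!(chrom_of %in% c("chrX", "chrY", genome$excluded_chroms)))
  }
  out <- lapply(split(cell_types$barcode, cell_types$cell_type), function(bcs) {
    n_cells <- length(bcs)
    if (n_cells < 2) stop("each cell type needs >= 2 cells")
    pos <- indicators |>
      dplyr::filter(.data$barcode %in% bcs, .data$bin %in% bins) |>
      dplyr::count(.data$bin)
    f <- numeric(length(bins))
    f[match(pos$bin, bins)] <- pos$n / n_cells
    # nearest-rank 99th percentile; strictly greater is excluded
    q <- sort(f)[max(1, ceiling(top_quantile * length(f)))]
    excluded <- f > q | mappability[bins] < min_mappability
    use <- !excluded
    mu <- mean(f[use]); sdv <- stats::sd(f[use])
    if (is.na(sdv) || sdv == 0) {
      warning("zero frequency SD; no hubs called for this type")
      z <- rep(NA_real_, length(f))
    } else {
      z <- (f - mu) / sdv
    }
    tibble::tibble(bin = bins, frequency = f, z_score = z,
                   excluded = excluded,
                   hub = !is.na(z) & z > z_cutoff)
  })
  dplyr::bind_rows(out, .id = "cell_type")
}

#' Enrichment of annotation bins at multi-way hubs
#'
#' For each (hub cell type A, annotation cell type B) pair, builds the 2 x 2
#' table hub/non-hub x annotated/not over the tested bin universe and
#' reports Fisher's exact test p-value and the log2 sample odds ratio
#' (Haldane-Anscombe 0.5 correction when any cell is zero).
#'
#' @param hubs hub tibble from [call_hubs()].
#' @param annotations tibble `cell_type`, `bin` of annotation bins (e.g.
#'   cCRE or marker-gene-TSS 10 kb bins per type).
#' @return tibble `hub_type`, `annotation_type`, `matched`, `a`, `b`, `c`,
#'   `d` (table cells), `odds_ratio`, `log2_or`, `p_value`.
#' @export
hub_enrichment <- function(hubs, annotations) {
  universe <- sort(unique(hubs$bin))
  combos <- tidyr::expand_grid(hub_type = unique(hubs$cell_type),
                               annotation_type = unique(annotations$cell_type))
  out <- purrr::pmap(combos, function(hub_type, annotation_type) {
    hb <- hubs$bin[hubs$cell_type == hub_type & hubs$hub]
    ab <- intersect(annotations$bin[annotations$cell_type == annotation_type],
                    universe)
    a <- length(intersect(hb, ab))
    b <- length(setdiff(hb, ab))
    cc <- length(setdiff(ab, hb))
    d <- length(universe) - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- if (any(c(a, b, cc, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * d) / (b * cc)
    }
    tibble::tibble(hub_type = hub_type, annotation_type = annotation_type,
                   matched = hub_type == annotation_type,
                   a = a, b = b, c = cc, d = d,
                   odds_ratio = or, log2_or = log2(or), p_value = p)
  })
  dplyr::bind_rows(out)
}
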