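#' Bin contacts into per-cell sparse matrices
#'
#' Assigns each contact's anchors to global bins at `resolution` and
#' accumulates per-cell symmetric sparse matrices, stored as an upper-triangle
#' triplet tibble (`barcode`, `bin1 <= bin2`, `count`). Intra-bin (diagonal)
#' contacts are counted once and retained. Records with an anchor overlapping
#' a blacklist interval are removed and counted.
#'
#' @param pairs a pairs tibble (ideally QC-filtered).
#' @param genome an `sc_genome`; its resolution is overridden by `resolution`.
#' @param resolution bin width in bp.
#' @param blacklist optional tibble of intervals (`chrom`, `start` 0-based,
#'   `end`) as from [read_bed()]; anchors inside are dropped.
#' @return an `sc_cellset`: list with `contacts` (triplet tibble), `genome`
#'   (rebinned at `resolution`), `resolution`, `barcodes`, and
#'   `n_blacklisted`.
#' @export
bin_contacts <- function(pairs, genome, resolution = 1e6, blacklist = NULL) {
  if (resolution <= 0) stop("resolution must be > 0")
  g <- with_resolution(genome, resolution)
  keep <- rep(TRUE, nrow(pairs))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    keep <- !(anchor_in_intervals(pairs$chrom1, pairs$pos1, blacklist) |
                anchor_in_intervals(pairs$chrom2, pairs$pos2, blacklist))
  }
  n_blacklisted <- sum(!keep)
  pr <- pairs[keep, , drop = FALSE]
  b1 <- bin_index(g, pr$chrom1, pr$pos1)
  b2 <- bin_index(g, pr$chrom2, pr$pos2)
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  contacts <- tibble::tibble(barcode = pr$barcode, bin1 = lo, bin2 = hi) |>
    dplyr::count(.data$barcode, .data$bin1, .data$bin2, name = "count")
  structure(
    list(contacts = contacts, genome = g, resolution = resolution,
         barcodes = sort(unique(pr$barcode)), n_blacklisted = n_blacklisted),
    class = "sc_cellset"
  )
}

#' @export
print.sc_cellset <- function(x, ...) {
  cat(sprintf(
    "<sc_cellset> %d cells, %d bins (%s bp), %s nonzero entries\n",
    length(x$barcodes), n_bins(x$genome),
    format(x$resolution, big.mark = ","),
    format(nrow(x$contacts), big.mark = ",")
  ))
  invisible(x)
}

# TRUE where (chrom, pos) falls in a 0-based half-open interval set
anchor_in_intervals <- function(chrom, pos, intervals) {
  hit <- rep(FALSE, length(chrom))
  for (k in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[k] &
                    pos > intervals$start[k] & pos <= intervals$end[k])
  }
  hit
}

#' Per-cell per-bin marginal coverage
#'
#' Marginal of bin b in a cell = row sum of the symmetric contact matrix:
#' each off-diagonal entry contributes to both anchors, diagonal entries once.
#'
#' @param set an `sc_cellset`.
#' @return tibble with `barcode`, `bin`, `marginal` (nonzero bins only).
#' @export
cell_marginals <- function(set) {
  ct <- set$contacts
  dplyr::bind_rows(
    tibble::tibble(barcode = ct$barcode, bin = ct$bin1, marginal = ct$count),
    {
      off <- ct[ct$bin1 != ct$bin2, ]
      tibble::tibble(barcode = off$barcode, bin = off$bin2,
                     marginal = off$count)
    }
  ) |>
    dplyr::count(.data$barcode, .data$bin, wt = .data$marginal,
                 name = "marginal")
}

#' Sum selected cells into one pseudo-bulk sparse matrix
#'
#' @param set an `sc_cellset`.
#' @param barcodes cells to aggregate; default all.
#' @return a triplet tibble (`bin1`, `bin2`, `count`) with attributes
#'   `genome` and `resolution`.
#' @export
aggregate_pseudobulk <- function(set, barcodes = set$barcodes) {
  if (length(barcodes) == 0) stop("empty barcode selection")
  missing <- setdiff(barcodes, set$barcodes)
  if (length(missing) > 0) {
    stop("barcodes not in set: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  out <- set$contacts |>
    dplyr::filter(.data$barcode %in% barcodes) |>
    dplyr::count(.data$bin1, .data$bin2, wt = .data$count, name = "count")
  attr(out, "genome") <- set$genome
  attr(out, "resolution") <- set$resolution
  out
}

#' Dense symmetric matrix for one cell (or a pseudo-bulk triplet table)
#'
#' Mostly a convenience for tests and small genomes; B x B dense.
#' @param x an `sc_cellset` plus `barcode`, or a pseudo-bulk triplet tibble.
#' @param barcode cell to extract when `x` is an `sc_cellset`.
#' @return base matrix B x B.
#' @export
dense_matrix <- function(x, barcode = NULL) {
  if (inherits(x, "sc_cellset")) {
    g <- x$genome
    tr <- x$contacts[x$contacts$barcode == barcode, ]
  } else {
    g <- attr(x, "genome")
    tr <- x
  }
  B <- n_bins(g)
  m <- matrix(0, B, B)
  m[cbind(tr$bin1, tr$bin2)] <- m[cbind(tr$bin1, tr$bin2)] + tr$count
  lower <- tr$bin1 != tr$bin2
  m[cbind(tr$bin2[lower], tr$bin1[lower])] <-
    m[cbind(tr$bin2[lower], tr$bin1[lower])] + tr$count[lower]
  m
}

#' Marginals of a pseudo-bulk triplet table
#' @param bulk triplet tibble from [aggregate_pseudobulk()].
#' @return tibble `bin`, `marginal` covering all genome bins (zeros included).
#' @export
bulk_marginals <- function(bulk) {
  g <- attr(bulk, "genome")
  B <- n_bins(g)
  m <- numeric(B)
  add1 <- tapply(bulk$count, bulk$bin1, sum)
  m[as.integer(names(add1))] <- m[as.integer(names(add1))] + add1
  off <- bulk[bulk$bin1 != bulk$bin2, ]
  if (nrow(off) > 0) {
    add2 <- tapply(off$count, off$bin2, sum)
    m[as.integer(names(add2))] <- m[as.integer(names(add2))] + add2
  }
  tibble::tibble(bin = seq_len(B), marginal = m)
}
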