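#' Specification for the synthetic barcoded contact generator
#'
#' The generator emulates the features of barcoded single-cell Hi-C data the
#' toolkit's statistics react to: power-law cis distance decay on a diploid
#' background, amplicons whose per-bin emission scales with copy number,
#' ecDNA-mode amplicons whose trans partners spread over chromosomes with
#' only mild per-cell preference (low Gini), HSR-mode amplicons whose trans
#' partners concentrate on a small chromosome subset plus local cis
#' enrichment (high Gini), and elevated intra-amplicon contacts irrespective
#' of distance (the circular-ecDNA signature used for 10 kb boundary
#' refinement). Per-cell amplicon copies are drawn Poisson around
#' `amplicon_copies` so copy number varies across cells.
#'
#' The default toy genome is 4 chromosomes x 20 Mb (80 bins at 1 Mb) so the
#' CNN trains in minutes on one CPU; sizes are configurable up to realistic
#' scale.
#'
#' @param n_chroms,chrom_length,resolution toy genome shape.
#' @param n_cells named vector: cells per population; names from
#'   `none`/`ecdna`/`hsr`.
#' @param amplicon_chrom,amplicon_start,amplicon_end amplicon locus (1-based
#'   inclusive; default chr1:8,000,001-13,000,000, five 1 Mb bins).
#' @param amplicon_copies mean amplicon copy number; per-cell copies are
#'   negative-binomial around this mean (amplicon copy number is strongly
#'   heterogeneous across cells).
#' @param copy_dispersion negative-binomial size for per-cell copies
#'   (smaller = more heterogeneous; default 5, coefficient of variation
#'   about 0.5).
#' @param depth mean contacts per cell (Poisson unless `depth_exact`).
#' @param depth_exact draw exactly `depth` contacts per cell.
#' @param decay_exponent cis distance-decay power-law exponent.
#' @param min_cis_dist,max_cis_dist cis distance range in bp.
#' @param trans_rate background probability that a contact is trans.
#' @param ecdna_trans_rate trans probability for ecDNA-amplicon anchors.
#' @param ecdna_chrom_alpha Dirichlet concentration of each ecDNA cell's
#'   trans-chromosome preference (large = even; mildly uneven by default so
#'   observed hub indices sit above a uniform shuffle null).
#' @param ecdna_intra_rate fraction of ecDNA-amplicon cis contacts drawn
#'   uniformly within the amplicon (distance-free, circle-like).
#' @param hsr_trans_rate trans probability for HSR-amplicon anchors.
#' @param hsr_target_chroms number of chromosomes HSR trans contacts favour.
#' @param hsr_concentration probability mass on the favoured chromosomes.
#' @param hsr_local_cis fraction of HSR-amplicon cis contacts drawn near the
#'   amplicon (tandem-repeat-like local enrichment).
#' @param hotspot optional preferred trans partner region for ecDNA-amplicon
#'   contacts: list with `chrom`, `start`, `end`, `weight` (the fraction of
#'   ecDNA-amplicon trans contacts redirected into the region). Off
#'   (`NULL`) by default; used as a positive control for the binomial
#'   trans-interaction test.
#' @param seed RNG seed; identical specs give byte-identical output.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_chroms = 4, chrom_length = 2e7, resolution = 1e6,
                     n_cells = c(none = 100, ecdna = 100, hsr = 100),
                     amplicon_chrom = "chr1", amplicon_start = 8e6 + 1,
                     amplicon_end = 13e6, amplicon_copies = 20,
                     copy_dispersion = 5,
                     depth = 3000, depth_exact = FALSE,
                     decay_exponent = 1, min_cis_dist = 500,
                     max_cis_dist = NULL,
                     trans_rate = 0.10, ecdna_trans_rate = 0.5,
                     ecdna_chrom_alpha = 5, ecdna_intra_rate = 0.5,
                     hsr_trans_rate = 0.10, hsr_target_chroms = 1,
                     hsr_concentration = 0.9, hsr_local_cis = 0.5,
                     hotspot = NULL, seed = 1) {
  spec <- as.list(environment())
  if (is.null(spec$max_cis_dist)) spec$max_cis_dist <- chrom_length / 2
  spec$genome <- sc_genome(paste0("chr", seq_len(n_chroms)),
                           rep(chrom_length, n_chroms), resolution)
  if (!amplicon_chrom %in% spec$genome$chrom_names) {
    stop("amplicon chromosome not in the toy genome")
  }
  if (amplicon_end > chrom_length || amplicon_start < 1) {
    stop("amplicon locus outside the genome")
  }
  class(spec) <- "sim_spec"
  spec
}

#' Global amplicon bins of a simulation spec (at the spec resolution)
#' @param spec a `sim_spec`.
#' @return integer vector of global bins covered by the amplicon.
#' @export
amplicon_bins <- function(spec) {
  gb <- genome_bins(spec$genome)
  gb$bin[gb$chrom == spec$amplicon_chrom &
           gb$end >= spec$amplicon_start & gb$start <= spec$amplicon_end]
}

# power-law distance sampler on [dmin, dmax], density ~ d^-a
sample_decay_dist <- function(n, a, dmin, dmax) {
  u <- stats::runif(n)
  if (abs(a - 1) < 1e-9) {
    dmin * (dmax / dmin)^u
  } else {
    (dmin^(1 - a) + u * (dmax^(1 - a) - dmin^(1 - a)))^(1 / (1 - a))
  }
}

#' Simulate barcoded single-cell contacts with planted amplicons
#'
#' @param spec a [sim_spec()].
#' @return list with `pairs` (an `sc_pairs` tibble: `barcode`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`), `truth` (per cell: `barcode`, `population`,
#'   `mode`, `copies`), and `genome`.
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  g <- spec$genome
  pops <- names(spec$n_cells)
  stopifnot(all(pops %in% c("none", "ecdna", "hsr")))
  out <- list(); truth <- list()
  for (pop in pops) {
    n <- spec$n_cells[[pop]]
    if (n == 0) next
    barcodes <- sprintf("%s_%04d", pop, seq_len(n))
    copies <- if (pop == "none") rep(2, n) else
      pmax(1, stats::rnbinom(n, mu = spec$amplicon_copies,
                             size = spec$copy_dispersion))
    truth[[pop]] <- tibble::tibble(
      barcode = barcodes, population = pop,
      mode = ifelse(pop == "none", "none", pop), copies = copies
    )
    out[[pop]] <- simulate_population(spec, pop, barcodes, copies)
  }
  pairs <- dplyr::bind_rows(out)
  pairs <- normalize_pairs(pairs, g)
  attr(pairs, "genome") <- g
  class(pairs) <- c("sc_pairs", class(pairs))
  list(pairs = pairs, truth = dplyr::bind_rows(truth), genome = g)
}

simulate_population <- function(spec, pop, barcodes, copies) {
  g <- spec$genome
  gb <- genome_bins(g)
  B <- nrow(gb)
  n <- length(barcodes)
  amp <- amplicon_bins(spec)
  amp_chrom <- spec$amplicon_chrom
  amplified <- pop != "none"
  depth <- if (spec$depth_exact) rep(spec$depth, n) else
    stats::rpois(n, spec$depth)
  cell_idx <- rep(seq_len(n), depth)
  m <- length(cell_idx)
  # anchor-1 bin: emission proportional to per-cell copy number
  base_w <- rep(2, B)
  if (amplified) {
    # per-cell weight only differs on amplicon bins; sample in two stages
    p_amp <- (copies[cell_idx] * length(amp)) /
      (copies[cell_idx] * length(amp) + 2 * (B - length(amp)))
    on_amp <- stats::runif(m) < p_amp
    b1 <- integer(m)
    b1[on_amp] <- sample(amp, sum(on_amp), replace = TRUE)
    b1[!on_amp] <- sample(setdiff(seq_len(B), amp), sum(!on_amp),
                          replace = TRUE)
  } else {
    b1 <- sample.int(B, m, replace = TRUE)
    on_amp <- rep(FALSE, m)
  }
  chrom1 <- gb$chrom[b1]
  pos1 <- floor(gb$start[b1] + stats::runif(m) * (gb$end[b1] - gb$start[b1]))
  # trans decision
  t_rate <- rep(spec$trans_rate, m)
  if (amplified && pop == "ecdna") t_rate[on_amp] <- spec$ecdna_trans_rate
  if (amplified && pop == "hsr") t_rate[on_amp] <- spec$hsr_trans_rate
  is_trans <- stats::runif(m) < t_rate
  chrom2 <- character(m); pos2 <- numeric(m)
  chroms <- g$chrom_names
  len <- spec$chrom_length

  # ---- trans partners -----------------------------------------------------
  ti <- which(is_trans)
  if (length(ti) > 0) {
    pick <- integer(length(ti))
    amp_t <- on_amp[ti]
    # background trans: uniform over the other chromosomes
    bg <- which(!amp_t | pop == "none")
    if (pop == "hsr") bg <- which(!amp_t)
    if (pop == "ecdna") bg <- which(!amp_t)
    u <- stats::runif(length(ti))
    n_other <- length(chroms) - 1
    pick[bg] <- ceiling(u[bg] * n_other)
    if (pop == "ecdna" && any(amp_t)) {
      # per-cell Dirichlet preference over the non-amplicon chromosomes
      al <- spec$ecdna_chrom_alpha
      pref <- matrix(stats::rgamma(n * n_other, shape = al), n, n_other)
      pref <- pref / rowSums(pref)
      cp <- t(apply(pref, 1, cumsum))
      rows <- cell_idx[ti][amp_t]
      uu <- u[amp_t]
      pick[amp_t] <- 1L + rowSums(uu > cp[rows, , drop = FALSE])
    }
    if (pop == "hsr" && any(amp_t)) {
      # concentrated on the first hsr_target_chroms non-amplicon chromosomes
      k <- spec$hsr_target_chroms
      conc <- spec$hsr_concentration
      uu <- u[amp_t]
      on_target <- uu < conc
      pick_a <- integer(sum(amp_t))
      pick_a[on_target] <- ceiling(stats::runif(sum(on_target)) * k)
      pick_a[!on_target] <- k +
        ceiling(stats::runif(sum(!on_target)) * (n_other - k))
      pick[amp_t] <- pick_a
    }
    pick <- pmin(pmax(pick, 1L), n_other)
    # the k-th "other" chromosome of chromosome c is k when k < c, else k + 1
    c1i <- match(chrom1[ti], chroms)
    chrom2[ti] <- chroms[pick + (pick >= c1i)]
    pos2[ti] <- floor(1 + stats::runif(length(ti)) * (len - 1))
    if (pop == "ecdna" && !is.null(spec$hotspot) && any(amp_t)) {
      hs <- spec$hotspot
      cand <- which(amp_t & chrom1[ti] != hs$chrom)
      redo <- cand[stats::runif(length(cand)) < hs$weight]
      chrom2[ti[redo]] <- hs$chrom
      pos2[ti[redo]] <- floor(hs$start +
                                stats::runif(length(redo)) *
                                  (hs$end - hs$start))
    }
  }

  # ---- cis partners -------------------------------------------------------
  ci <- which(!is_trans)
  if (length(ci) > 0) {
    chrom2[ci] <- chrom1[ci]
    amp_c <- on_amp[ci]
    special <- rep(FALSE, length(ci))
    if (amplified && pop == "ecdna") {
      special <- amp_c & stats::runif(length(ci)) < spec$ecdna_intra_rate
      # distance-free intra-amplicon partner (circular contact)
      pos2[ci][special] <- floor(spec$amplicon_start +
        stats::runif(sum(special)) *
          (spec$amplicon_end - spec$amplicon_start))
    }
    if (amplified && pop == "hsr") {
      special <- amp_c & stats::runif(length(ci)) < spec$hsr_local_cis
      # local partner around the amplicon (tandem repeat array)
      margin <- 2e6
      lo <- max(1, spec$amplicon_start - margin)
      hi <- min(len, spec$amplicon_end + margin)
      pos2[ci][special] <- floor(lo + stats::runif(sum(special)) * (hi - lo))
    }
    reg <- !special
    d <- sample_decay_dist(sum(reg), spec$decay_exponent,
                           spec$min_cis_dist, spec$max_cis_dist)
    sgn <- sample(c(-1, 1), sum(reg), replace = TRUE)
    p2 <- pos1[ci][reg] + sgn * d
    flip <- p2 < 1 | p2 > len
    p2[flip] <- pos1[ci][reg][flip] - (sgn * d)[flip]
    pos2[ci][reg] <- floor(pmin(pmax(p2, 1), len))
  }
  tibble::tibble(
    barcode = barcodes[cell_idx],
    chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2
  )
}

#' Simulate walk-aware pairs with planted multi-way hub bins
#'
#' Each cell type gets `n_hub_bins` planted hub bins (disjoint across
#' types). For every (cell, planted hub bin of its type) a qualifying
#' multi-way read containing the bin is emitted with probability `p_hub`,
#' so planted bins have indicator frequency ~ `p_hub` plus a small
#' background. `reads_per_cell` additional background walks touch random
#' bins.
#'
#' @param genome an `sc_genome` (walks are binned at `resolution`).
#' @param cell_types named vector: cells per type.
#' @param n_hub_bins planted hub bins per type.
#' @param p_hub per-cell probability that a planted bin is visited.
#' @param reads_per_cell background walks per cell.
#' @param walk_len possible walk lengths (unique bins per read).
#' @param resolution multiway bin width (default 10 kb).
#' @param seed RNG seed.
#' @return list with `pairs` (barcoded, read-ID-tagged pairs tibble),
#'   `truth` (tibble `cell_type`, `bin` of planted hubs), `cell_types`
#'   (tibble `barcode`, `cell_type`), and the rebinned `genome`.
#' @export
simulate_multiway <- function(genome, cell_types = c(A = 100, B = 100),
                              n_hub_bins = 600, p_hub = 0.5,
                              reads_per_cell = 50, walk_len = 3:5,
                              resolution = 1e4, seed = 1) {
  set.seed(seed)
  g <- with_resolution(genome, resolution)
  gb <- genome_bins(g)
  B <- nrow(gb)
  types <- names(cell_types)
  hub_pool <- sample.int(B, n_hub_bins * length(types))
  hubs <- split(hub_pool, rep(types, each = n_hub_bins))
  truth <- dplyr::bind_rows(lapply(types, function(tp)
    tibble::tibble(cell_type = tp, bin = sort(hubs[[tp]]))))
  all_pairs <- list()
  ct_rows <- list()
  rid <- 0L
  for (tp in types) {
    n <- cell_types[[tp]]
    barcodes <- sprintf("%s_%04d", tp, seq_len(n))
    ct_rows[[tp]] <- tibble::tibble(barcode = barcodes, cell_type = tp)
    reads <- list()
    for (i in seq_len(n)) {
      planted <- hubs[[tp]][stats::runif(n_hub_bins) < p_hub]
      walks <- c(
        lapply(planted, function(hb) {
          k <- sample(walk_len, 1)
          unique(c(hb, sample.int(B, k - 1)))
        }),
        lapply(seq_len(reads_per_cell), function(z) {
          unique(sample.int(B, sample(walk_len, 1)))
        })
      )
      walks <- walks[lengths(walks) >= 2]
      nw <- length(walks)
      if (nw == 0) next
      ids <- sprintf("read_%07d", rid + seq_len(nw))
      rid <- rid + nw
      b_from <- unlist(lapply(walks, function(w) w[-length(w)]))
      b_to <- unlist(lapply(walks, function(w) w[-1]))
      rd <- rep(ids, lengths(walks) - 1L)
      reads[[i]] <- tibble::tibble(
        barcode = barcodes[i], read_id = rd,
        chrom1 = gb$chrom[b_from],
        pos1 = gb$start[b_from] + 100,
        chrom2 = gb$chrom[b_to],
        pos2 = gb$start[b_to] + 100
      )
    }
    all_pairs[[tp]] <- dplyr::bind_rows(reads)
  }
  pairs <- dplyr::bind_rows(all_pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(barcode = character(), read_id = character(),
                            chrom1 = character(), pos1 = numeric(),
                            chrom2 = character(), pos2 = numeric())
  }
  pairs <- normalize_pairs(pairs, g)
  attr(pairs, "genome") <- g
  class(pairs) <- c("sc_pairs", class(pairs))
  list(pairs = pairs, truth = truth,
       cell_types = dplyr::bind_rows(ct_rows), genome = g)
}

#' Simulate a matched cell-by-gene expression matrix
#'
#' Negative-binomial counts on a log-normal baseline. Cells carrying an
#' amplicon (per `truth$copies`) express `amplicon_genes` scaled by
#' `(copies / 2) ^ dosage_slope` (linear dosage at slope 1); cells with a
#' planted `state` express that state's signature genes shifted by
#' `effect` log2 units.
#'
#' @param truth per-cell tibble with `barcode`, optionally `copies` and
#'   `state`.
#' @param genes character vector of gene names (the matrix columns).
#' @param amplicon_genes genes residing on the amplicon.
#' @param gene_sets named list state -> signature genes.
#' @param effect log2 shift applied to signature genes in their state's
#'   cells.
#' @param dosage_slope exponent linking copy ratio to expression.
#' @param base_mean mean baseline expression.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param seed RNG seed.
#' @return numeric count matrix, cells x genes, dimnames set.
#' @export
simulate_expression <- function(truth, genes, amplicon_genes = character(0),
                                gene_sets = NULL, effect = 1,
                                dosage_slope = 1, base_mean = 5,
                                nb_size = 10, seed = 1) {
  set.seed(seed)
  n <- nrow(truth); p <- length(genes)
  base <- stats::rlnorm(p, meanlog = log(base_mean), sdlog = 0.4)
  mu <- matrix(base, n, p, byrow = TRUE,
               dimnames = list(truth$barcode, genes))
  if (length(amplicon_genes) > 0 && "copies" %in% names(truth)) {
    sel <- genes %in% amplicon_genes
    mu[, sel] <- mu[, sel] * (truth$copies / 2)^dosage_slope
  }
  if (!is.null(gene_sets) && "state" %in% names(truth)) {
    for (st in names(gene_sets)) {
      rows <- which(truth$state == st)
      cols <- which(genes %in% gene_sets[[st]])
      if (length(rows) && length(cols)) {
        mu[rows, cols] <- mu[rows, cols] * 2^effect
      }
    }
  }
  cnt <- matrix(stats::rnbinom(n * p, mu = mu, size = nb_size), n, p,
                dimnames = dimnames(mu))
  cnt
}

#' Random non-overlapping gene annotation on a genome
#' @param genome an `sc_genome`.
#' @param n_genes number of genes.
#' @param width gene-body width in bp.
#' @param seed RNG seed.
#' @return tibble `chrom`, `start`, `end`, `gene` (1-based inclusive).
#' @export
make_gene_annotation <- function(genome, n_genes = 100, width = 2e4,
                                 seed = 1) {
  set.seed(seed)
  chrom <- sample(genome$chrom_names, n_genes, replace = TRUE,
                  prob = genome$chrom_lengths / sum(genome$chrom_lengths))
  len <- genome$chrom_lengths[match(chrom, genome$chrom_names)]
  start <- floor(stats::runif(n_genes) * (len - width)) + 1
  tibble::tibble(chrom = chrom, start = start, end = start + width - 1,
                 gene = sprintf("gene_%04d", seq_len(n_genes))) |>
    dplyr::arrange(.data$chrom, .data$start)
}
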