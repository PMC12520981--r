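test_that("binomial trans significance equals exact tail enumeration", {
  # upper tail P(X >= 5), X ~ Binomial(20, 0.05), is about 2.6e-3
  expect_equal(binom_upper_tail_enum(5, 20, 0.05), 2.6e-3, tolerance = 0.02)
  g <- sc_genome(c("chrA", "chrB"), c(4e6, 4e6), 5e5)
  # pseudobulk: locus = chrA bin 1; contacts to chrB bins
  bulk <- tibble::tibble(
    bin1 = c(1L, 1L, 1L, 1L),
    bin2 = c(9L, 10L, 11L, 12L),
    count = c(5, 6, 4, 5)
  )
  attr(bulk, "genome") <- g
  cnv <- infer_cnv(tibble::tibble(bin = 1:16, marginal = 10), g)
  res <- significant_trans_partners(bulk, cnv, ecdna_bins = 1L)
  expect_equal(nrow(res), 8) # all chrB bins tested
  tot <- sum(res$n_contacts)
  for (k in seq_len(nrow(res))) {
    expect_equal(res$p_value[k],
                 binom_upper_tail_enum(res$n_contacts[k], tot, res$e_exp[k]),
                 tolerance = 1e-12)
  }
  # N_i = 0 -> p = 1; P_i and E_i are per-chromosome distributions
  expect_equal(res$p_value[res$n_contacts == 0], rep(1, 4))
  expect_equal(sum(res$p_obs), 1)
  expect_equal(sum(res$e_exp), 1)
  # Bonferroni multiplies by the number of emitted rows
  expect_equal(res$p_adj, pmin(1, res$p_value * nrow(res)))
})

test_that("contacts proportional to copy number yield no significant intervals", {
  g <- sc_genome(c("chrA", "chrB"), c(4e6, 4e6), 5e5)
  copy <- c(rep(2, 8), 2, 2, 8, 2, 2, 4, 2, 2) # chrB bins 9..16
  counts <- round(copy[9:16] / sum(copy[9:16]) * 400)
  bulk <- tibble::tibble(bin1 = 1L, bin2 = 9:16, count = counts)
  attr(bulk, "genome") <- g
  cnv <- infer_cnv(tibble::tibble(bin = 1:16, marginal = copy * 5), g,
                   smooth_window = 1)
  res <- significant_trans_partners(bulk, cnv, ecdna_bins = 1L)
  expect_equal(sum(res$significant), 0)
})

test_that("a planted trans hotspot is detected above its copy expectation", {
  spec <- sim_spec(n_cells = c(ecdna = 40), depth = 3000, seed = 42,
                   hotspot = list(chrom = "chr3", start = 5e6 + 1,
                                  end = 5.5e6, weight = 0.15))
  sim <- simulate_cells(spec)
  set <- bin_contacts(sim$pairs, sim$genome, 5e5)
  bulk <- aggregate_pseudobulk(set)
  prof <- infer_cnv(bulk_marginals(bulk), set$genome)
  gb <- genome_bins(set$genome)
  amp <- gb$bin[gb$chrom == spec$amplicon_chrom &
                  gb$end >= spec$amplicon_start & gb$start <= spec$amplicon_end]
  res <- significant_trans_partners(bulk, prof, amp)
  hot <- gb$bin[gb$chrom == "chr3" & gb$start == 5e6 + 1]
  expect_true(res$significant[res$bin == hot])
  # the hotspot bin should dominate the significant set
  expect_lte(sum(res$significant), 3)
})

test_that("the shuffle null preserves totals, is seeded, and flags concentrated bins", {
  spec <- sim_spec(n_cells = c(hsr = 25), depth = 3000, seed = 13)
  sim <- simulate_cells(spec)
  set <- bin_contacts(sim$pairs, sim$genome, 1e6)
  ctr <- amplicon_bins(spec)[3]
  sh1 <- shuffle_hub_null(set, ctr, n_shuffles = 30, seed = 99)
  sh2 <- shuffle_hub_null(set, ctr, n_shuffles = 30, seed = 99)
  expect_identical(sh1$null, sh2$null)
  # conservation: shuffling only relabels chromosomes
  obs_tot <- vapply(set$barcodes, function(bc)
    sum(trans_counts_by_chrom(set, bc, ctr)), numeric(1))
  expect_equal(unname(sh1$null_trans_totals), unname(obs_tot[obs_tot > 0]))
  # HSR concentration sits far above the uniform shuffle null
  expect_gt(sh1$observed_median, sh1$null_median)
  expect_lt(sh1$p_value, 0.01)
  expect_error(shuffle_hub_null(set, ctr, n_shuffles = 0), "n_shuffles")
})

test_that("uniformly dispersed trans contacts match their shuffle null", {
  g <- toy_genome()
  set.seed(21)
  # cells whose bin-5 trans contacts are spread uniformly over chromosomes
  rows <- lapply(1:20, function(i) {
    partners <- sample(c(21, 41, 61), 60, replace = TRUE) +
      sample(0:19, 60, replace = TRUE)
    tibble::tibble(barcode = sprintf("c%02d", i), bin1 = 5L,
                   bin2 = as.integer(partners)) |>
      dplyr::count(.data$barcode, .data$bin1, .data$bin2, name = "count")
  })
  set <- structure(list(contacts = dplyr::bind_rows(rows), genome = g,
                        resolution = 1e6,
                        barcodes = sprintf("c%02d", 1:20)),
                   class = "sc_cellset")
  sh <- shuffle_hub_null(set, 5L, n_shuffles = 50, seed = 3)
  expect_gt(sh$p_value, 0.05)
  # closed form: all mass on 1 of 3 eligible chromosomes gives 2/3
  one <- structure(list(
    contacts = tibble::tibble(barcode = "c1", bin1 = 5L, bin2 = 30L,
                              count = 40),
    genome = g, resolution = 1e6, barcodes = "c1"), class = "sc_cellset")
  sh1 <- shuffle_hub_null(one, 5L, n_shuffles = 200, seed = 5)
  expect_equal(sh1$observed, 2 / 3, ignore_attr = TRUE)
  expect_gt(sh1$observed_median, sh1$null_median)
})

test_that("boundary refinement recovers a clean planted amplicon exactly", {
  g10 <- sc_genome("chr1", 2e7, 1e4)
  bins <- 1:100 # candidate region: first 1 Mb
  # amplicon occupies bins 10..59 ([10, 60) in half-open terms), 10x contacts
  inside <- 10:59
  bulk <- tidyr::expand_grid(bin1 = bins, bin2 = bins) |>
    dplyr::filter(.data$bin1 <= .data$bin2) |>
    dplyr::mutate(count = ifelse(.data$bin1 %in% inside &
                                   .data$bin2 %in% inside, 10, 1))
  attr(bulk, "genome") <- g10
  bd <- refine_ecdna_boundary(bulk, bins, smooth_w = 3)
  expect_true(bd$refined)
  expect_equal(bd$start_bin, 10L)
  expect_equal(bd$end_bin, 59L)
  # flat profile: flagged, interval unchanged
  flat <- dplyr::mutate(bulk, count = 2)
  attr(flat, "genome") <- g10
  bdf <- refine_ecdna_boundary(flat, bins)
  expect_false(bdf$refined)
  expect_equal(c(bdf$start_bin, bdf$end_bin), c(1L, 100L))
})

test_that("boundary refinement stays accurate under Poisson noise at SNR 5", {
  g10 <- sc_genome("chr1", 2e7, 1e4)
  bins <- 1:100
  inside <- 10:59
  grid <- tidyr::expand_grid(bin1 = bins, bin2 = bins) |>
    dplyr::filter(.data$bin1 <= .data$bin2)
  lam <- ifelse(grid$bin1 %in% inside & grid$bin2 %in% inside, 5, 1)
  jac <- vapply(1:20, function(s) {
    set.seed(s)
    bulk <- dplyr::mutate(grid, count = rpois(nrow(grid), lam))
    attr(bulk, "genome") <- g10
    bd <- refine_ecdna_boundary(bulk, bins, smooth_w = 3)
    interval_jaccard(c(bd$start_bin, bd$end_bin), c(10, 59))
  }, numeric(1))
  expect_gte(mean(jac), 0.8)
})

test_that("gene classification against refined boundaries follows strict containment", {
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(20e4, 95e4, 30e4, 185e4, 55e4),
    end = c(25e4, 105e4, 35e4, 195e4, 65e4),
    gene = c("inA_only_left", "straddle", "shared", "inB_only_right", "shared2")
  )
  a <- list(chrom = "chr1", start = 10e4, end = 100e4)
  b <- list(chrom = "chr1", start = 28e4, end = 200e4)
  single <- ecdna_genes(genes, a)
  expect_equal(single$class,
               c("ecdna", "none", "ecdna", "none", "ecdna"))
  both <- ecdna_genes(genes, a, b)
  expect_equal(both$class[both$gene == "shared"], "shared")
  expect_equal(both$class[both$gene == "inA_only_left"], "variable_5prime")
  expect_equal(both$class[both$gene == "inB_only_right"], "variable_3prime")
  # fully inside B but straddling A's right boundary: variable, 3' side
  expect_equal(both$class[both$gene == "straddle"], "variable_3prime")
  expect_equal(both$class[both$gene == "shared2"], "shared")
})

test_that("copy-expression correlation is 1 for monotone dosage and near 0 for noise", {
  g10 <- sc_genome("chr1", 1e6, 1e4)
  genes <- tibble::tibble(chrom = "chr1", start = 1e4 + 1, end = 5e4,
                          gene = "g1")
  n <- 200
  bcs <- sprintf("c%03d", 1:n)
  set.seed(12)
  copies <- runif(n, 2, 30)
  cnv <- tidyr::expand_grid(barcode = bcs, bin = 2:5) |>
    dplyr::mutate(inferred_copy = rep(copies, each = 4))
  expr <- matrix(3 * copies, ncol = 1, dimnames = list(bcs, "g1"))
  out <- copy_expression_correlation(expr, cnv, genes, g10)
  expect_equal(out$scc, 1)
  # independent expression: |SCC| small
  expr2 <- matrix(rnorm(n), ncol = 1, dimnames = list(bcs, "g1"))
  out2 <- copy_expression_correlation(expr2, cnv, genes, g10)
  expect_lt(abs(out2$scc), 0.2)
  # constant copy: undefined with flag
  cnv3 <- dplyr::mutate(cnv, inferred_copy = 2)
  out3 <- copy_expression_correlation(expr2, cnv3, genes, g10)
  expect_true(is.na(out3$scc))
  expect_true(out3$constant)
})
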