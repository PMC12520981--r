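mw_pairs <- function(rows, genome = toy_genome(1e4)) {
  p <- tibble::tibble(
    barcode = rows$barcode, read_id = rows$read_id,
    chrom1 = rows$chrom1, pos1 = rows$pos1,
    chrom2 = rows$chrom2, pos2 = rows$pos2
  )
  normalize_pairs(p, genome)
}

test_that("multi-way extraction needs >= 3 surviving unique 10 kb bins", {
  g <- toy_genome(1e4)
  # read r1: two bins only -> not multiway
  # read r2: three bins, all trans -> multiway
  # read r3: third anchor cis at 8 kb -> filtered, degrades to 2 bins
  rows <- tibble::tibble(
    barcode = "c1",
    read_id = c("r1", "r2", "r2", "r3", "r3"),
    chrom1 = c("chr1", "chr1", "chr2", "chr1", "chr1"),
    pos1 = c(1e5, 1e5, 5e5, 1e5, 3e5),
    chrom2 = c("chr2", "chr2", "chr3", "chr1", "chr1"),
    pos2 = c(5e5, 5e5, 7e5, 3e5, 3.08e5)
  )
  ex <- extract_multiway(mw_pairs(rows, g), g)
  expect_equal(ex$reads$n_bins[ex$reads$read_id == "r2"], 3L)
  bins_r2 <- c(bin_index(g, "chr1", 1e5), bin_index(g, "chr2", 5e5),
               bin_index(g, "chr3", 7e5))
  expect_setequal(ex$indicators$bin, bins_r2)
  expect_false("r1" %in%
                 ex$reads$read_id[ex$reads$n_bins >= 3])
  expect_equal(ex$reads$n_bins[ex$reads$read_id == "r3"], 2L)
  expect_error(extract_multiway(dplyr::select(mw_pairs(rows, g), -read_id), g),
               "read_id")
})

test_that("indicators ignore read order and duplicated walks", {
  g <- toy_genome(1e4)
  rows <- tibble::tibble(
    barcode = "c1", read_id = c("r1", "r1"),
    chrom1 = c("chr1", "chr2"), pos1 = c(1e5, 5e5),
    chrom2 = c("chr2", "chr3"), pos2 = c(5e5, 7e5)
  )
  ex1 <- extract_multiway(mw_pairs(rows, g), g)
  shuffled <- rows[2:1, ]
  ex2 <- extract_multiway(mw_pairs(shuffled, g), g)
  dup <- dplyr::bind_rows(rows, dplyr::mutate(rows, read_id = "r2"))
  ex3 <- extract_multiway(mw_pairs(dup, g), g)
  key <- function(e) dplyr::arrange(e$indicators, barcode, bin)
  expect_equal(key(ex1), key(ex2))
  expect_equal(key(ex1), key(ex3))
})

test_that("hub Z-scores behave at the threshold and standardize over estimation bins", {
  g <- sc_genome("chr1", 2e6, 1e4) # 200 bins
  set.seed(5)
  n_cells <- 50
  p_bg <- rep(0.2, 200)
  p_bg[7] <- 0.9 # one strongly elevated bin
  ind <- lapply(seq_len(n_cells), function(i) {
    on <- which(runif(200) < p_bg)
    tibble::tibble(barcode = sprintf("c%02d", i), bin = on)
  }) |> dplyr::bind_rows()
  ct <- tibble::tibble(barcode = sprintf("c%02d", 1:n_cells), cell_type = "T")
  hubs <- call_hubs(ind, ct, g, bins = 1:200)
  # z of the elevated bin clears 1.96; bins at the mean have z near 0
  expect_true(hubs$hub[hubs$bin == 7])
  mu <- mean(hubs$frequency[!hubs$excluded])
  nearest <- which.min(abs(hubs$frequency - mu))
  expect_lt(abs(hubs$z_score[nearest]), 0.5)
  # standardization: mean ~ 0, sd ~ 1 over the estimation (non-excluded) bins
  z_est <- hubs$z_score[!hubs$excluded]
  expect_lt(abs(mean(z_est)), 0.05)
  expect_equal(sd(z_est), 1, tolerance = 0.05)
  # low-mappability bins leave estimation
  mp <- rep(1, 200); mp[1:50] <- 0.5
  hubs2 <- call_hubs(ind, ct, g, mappability = mp, bins = 1:200)
  expect_true(all(hubs2$excluded[hubs2$bin <= 50]))
  # degenerate SD warns and calls nothing
  ind_all <- tidyr::expand_grid(barcode = ct$barcode, bin = 1:200)
  expect_warning(h3 <- call_hubs(ind_all, ct, g, bins = 1:200), "SD")
  expect_equal(sum(h3$hub), 0)
})

test_that("planted multiway hubs are recovered with high recall and low FDR", {
  g <- toy_genome()
  mw <- simulate_multiway(g, cell_types = c(A = 200, B = 200), seed = 42)
  ex <- extract_multiway(mw$pairs, mw$genome)
  hubs <- call_hubs(ex$indicators, mw$cell_types, mw$genome)
  for (tp in c("A", "B")) {
    called <- hubs$bin[hubs$cell_type == tp & hubs$hub]
    truth <- mw$truth$bin[mw$truth$cell_type == tp]
    expect_gte(mean(truth %in% called), 0.9)
    expect_lte(mean(!(called %in% truth)), 0.1)
  }
  # planted frequency is p_hub plus the independent background visit rate
  hA <- hubs[hubs$cell_type == "A", ]
  planted <- hA$bin %in% mw$truth$bin[mw$truth$cell_type == "A"]
  f_bg <- mean(hA$frequency[!planted])
  expected <- 1 - (1 - 0.5) * (1 - f_bg)
  expect_lt(abs(mean(hA$frequency[planted]) - expected), 0.03)
})

test_that("enrichment odds ratios match direct computation and favour matched types", {
  # oracle: [[10, 90], [5, 895]] -> OR = (10*895)/(90*5) = 19.89
  hubs <- tibble::tibble(
    cell_type = "A",
    bin = 1:1000,
    frequency = 0, z_score = 0, excluded = FALSE,
    hub = c(rep(TRUE, 100), rep(FALSE, 900))
  )
  ann <- tibble::tibble(cell_type = "A", bin = c(1:10, 101:105))
  he <- hub_enrichment(hubs, ann)
  expect_equal(he$odds_ratio, (10 * 895) / (90 * 5), tolerance = 1e-12)
  expect_equal(he$log2_or, log2(19.88889), tolerance = 1e-4)
  # matched vs unmatched on planted data
  g <- toy_genome()
  mw <- simulate_multiway(g, cell_types = c(A = 120, B = 120), seed = 9)
  ex <- extract_multiway(mw$pairs, mw$genome)
  h <- call_hubs(ex$indicators, mw$cell_types, mw$genome)
  he2 <- hub_enrichment(h, mw$truth)
  matched <- he2$log2_or[he2$matched]
  unmatched <- he2$log2_or[!he2$matched]
  expect_gt(min(matched), max(unmatched))
  # independent random sets: log2 OR near zero
  set.seed(3)
  hubs_r <- tibble::tibble(cell_type = "A", bin = 1:2000,
                           frequency = 0, z_score = 0, excluded = FALSE,
                           hub = sample(c(TRUE, FALSE), 2000, TRUE,
                                        prob = c(0.1, 0.9)))
  lo <- vapply(1:20, function(s) {
    set.seed(s)
    ann_r <- tibble::tibble(cell_type = "A",
                            bin = sample(1:2000, 200))
    hub_enrichment(hubs_r, ann_r)$log2_or
  }, numeric(1))
  expect_lt(abs(mean(lo)), 0.5)
})
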