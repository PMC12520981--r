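test_that("scGAD scores count gene-body-anchored contacts linearly", {
  g <- sc_genome("chr1", 1e6, 1e4)
  genes <- tibble::tibble(chrom = "chr1", start = 1e5 + 1, end = 1.5e5,
                          gene = "gA")
  p <- tibble::tibble(
    barcode = "c1", chrom1 = "chr1",
    pos1 = rep(1.2e5, 7), chrom2 = "chr1", pos2 = rep(8e5, 7)
  )
  set <- bin_contacts(p, g, 1e4)
  sc <- gad_scores(set, genes)
  expect_equal(sc$score[sc$gene == "gA"], 7)
  # a gene with no overlapping contacts is absent (score 0)
  genes2 <- dplyr::add_row(genes, chrom = "chr1", start = 5e5 + 1,
                           end = 5.2e5, gene = "gB")
  sc2 <- gad_scores(set, genes2)
  expect_false("gB" %in% sc2$gene)
  expect_equal(gad_matrix(sc2, barcodes = "c1",
                          genes = c("gA", "gB"))["c1", "gB"], 0)
  # doubling the cell's contacts doubles its row
  set2 <- bin_contacts(dplyr::bind_rows(p, p), g, 1e4)
  expect_equal(gad_scores(set2, genes)$score, 14)
})

test_that("standardized neighbour scores sum to one and decrease with distance", {
  ref <- matrix(c(0, 0, 3, 0, 0, 4, 5, 5), 4, 2, byrow = TRUE)
  qry <- matrix(c(0, 0), 1, 2, dimnames = list("q1", NULL))
  tr <- transfer_labels(qry, ref, c("a", "a", "b", "b"), k = 4)
  nb <- tr$neighbors
  expect_equal(sum(nb$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(nb$weight[order(nb$distance)]) <= 0))
  # all-one-label neighbourhood scores 1.0
  tr2 <- transfer_labels(qry, ref, rep("a", 4), k = 4)
  expect_equal(tr2$assignments$score, 1, tolerance = 1e-12)
  expect_equal(tr2$assignments$label, "a")
  # equal distances share weight 1/k
  ref_eq <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), 4, 2, byrow = TRUE)
  tr3 <- transfer_labels(qry, ref_eq, rep(c("a", "b"), 2), k = 4)
  expect_equal(tr3$neighbors$weight, rep(0.25, 4), tolerance = 1e-9)
  expect_error(transfer_labels(qry, ref, rep("a", 4), k = 10), "exceeds")
})

test_that("well-separated planted clusters transfer almost perfectly", {
  set.seed(8)
  n <- 200
  ref <- rbind(matrix(rnorm(2 * n, 0), n, 2), matrix(rnorm(2 * n, 8), n, 2))
  lab <- rep(c("T1", "T2"), each = n)
  qry <- rbind(matrix(rnorm(2 * n, 0), n, 2), matrix(rnorm(2 * n, 8), n, 2))
  rownames(qry) <- sprintf("q%03d", seq_len(2 * n))
  truth <- rep(c("T1", "T2"), each = n)
  tr <- transfer_labels(qry, ref, lab, k = 15)
  acc <- mean(tr$assignments$label ==
                truth[match(tr$assignments$barcode, rownames(qry))])
  expect_gte(acc, 0.99)
})

test_that("overlap coefficients are 1 on identical partitions and 0 on disjoint clusters", {
  cells <- sprintf("c%02d", 1:40)
  a <- setNames(rep(c("x", "y"), each = 20), cells)
  o1 <- overlap_coefficients(a, a, a)
  expect_equal(diag(o1), c(x = 1, y = 1))
  expect_true(all(o1[upper.tri(o1)] == 0, o1[lower.tri(o1)] == 0))
  # clusters disjoint from both annotations' cells -> coefficient 0
  clus <- setNames(rep(c("k1", "k2"), 20), cells) # interleaved
  b <- setNames(rep(c("x", "y"), 20), cells)
  o2 <- overlap_coefficients(a, b, clus)
  expect_true(all(o2 <= 0.5 + 1e-12))
  # random clusters over many types keep off-diagonal overlap low
  set.seed(10)
  cells2 <- sprintf("d%04d", 1:1000)
  a2 <- setNames(rep(sprintf("t%02d", 1:10), each = 100), cells2)
  k2 <- setNames(sample(sprintf("k%02d", 1:10), 1000, TRUE), cells2)
  o3 <- overlap_coefficients(a2, a2, k2)
  expect_lt(mean(o3[row(o3) != col(o3)]), 0.3)
})

test_that("state scores are centred by matched controls and shift equivariantly", {
  set.seed(11)
  n_genes <- 400
  genes <- sprintf("g%03d", seq_len(n_genes))
  expr <- matrix(rnorm(100 * n_genes, 5, 0.01), 100, n_genes,
                 dimnames = list(sprintf("c%03d", 1:100), genes))
  gs <- list(OPC = genes[1:20])
  sc0 <- state_scores(expr, gs, seed = 2)
  # identical distributions: score ~ 0
  expect_lt(max(abs(sc0$OPC)), 0.05)
  # +1 shift of the signature genes in a subset of cells raises exactly
  # those cells' scores by 1 (control bias cancels in the cell contrast)
  expr1 <- matrix(rnorm(100 * n_genes, 5, 1), 100, n_genes,
                  dimnames = dimnames(expr))
  shifted <- 1:30
  expr1[shifted, gs$OPC] <- expr1[shifted, gs$OPC] + 1
  sc1 <- state_scores(expr1, gs, seed = 2)
  expect_equal(mean(sc1$OPC[shifted]) - mean(sc1$OPC[-shifted]), 1,
               tolerance = 0.15)
  expect_warning(state_scores(expr, list(OPC = c(genes[1:5], "missing")),
                              seed = 2), "absent")
})

test_that("planted single-state cells score highest for their own state and project to it", {
  genes <- sprintf("g%03d", 1:400)
  gs <- list(OPC = genes[1:25], NPC = genes[26:50],
             AC = genes[51:75], MES = genes[76:100])
  truth <- tibble::tibble(barcode = sprintf("c%03d", 1:200),
                          state = rep(names(gs), each = 50))
  expr <- log1p(simulate_expression(truth, genes, gene_sets = gs,
                                    effect = 2, seed = 3))
  sc <- state_scores(expr, gs, seed = 4)
  own_highest <- vapply(seq_len(nrow(sc)), function(i) {
    names(which.max(unlist(sc[i, names(gs)]))) == truth$state[i]
  }, logical(1))
  expect_gte(mean(own_highest), 0.95)
  pj <- state_projection(sc)
  expect_gte(mean(pj$quadrant == truth$state), 0.95)
})

test_that("the (D, identity) projection follows its closed form", {
  sc <- tibble::tibble(barcode = c("a", "b", "c"),
                       OPC = c(1.0, 0.4, 0.5), NPC = c(0.5, 0.4, 0.3),
                       AC = c(0.2, 0.1, 0.9), MES = c(0.1, 0.0, 0.2))
  pj <- state_projection(sc)
  expect_equal(pj$D, c(1.0 - 0.2, 0.3, -0.4))
  expect_equal(pj$quadrant, c("OPC", "OPC", "AC"))
  # equal pair scores give identity 0; |identity| = log2(1 + |diff|)
  expect_equal(pj$identity[2], 0)
  expect_equal(abs(pj$identity[1]), log2(1.5))
  sc2 <- tibble::tibble(barcode = "d", OPC = 0.5, NPC = 0.3,
                        AC = 0, MES = 0)
  expect_equal(abs(state_projection(sc2)$identity), log2(1.2),
               tolerance = 1e-12)
})

test_that("Hi-C state scores are convex combinations of neighbour scores", {
  nb <- tibble::tibble(
    barcode = rep("q1", 3), neighbor = c(1L, 2L, 3L),
    distance = c(0.1, 0.2, 0.3), weight = c(0.5, 0.3, 0.2),
    neighbor_label = "x"
  )
  ns <- data.frame(OPC = c(1, 2, 3), NPC = c(5, 5, 5),
                   AC = c(0, 1, 0), MES = c(-1, 0, 1))
  hs <- hic_state_scores(nb, ns)
  expect_equal(hs$OPC, 0.5 * 1 + 0.3 * 2 + 0.2 * 3)
  expect_equal(hs$NPC, 5) # constant neighbours reproduce the constant
  for (s in c("OPC", "AC", "MES")) {
    expect_gte(hs[[s]], min(ns[[s]]))
    expect_lte(hs[[s]], max(ns[[s]]))
  }
  # a single full-weight neighbour passes its score through
  nb1 <- dplyr::mutate(nb, weight = c(1, 0, 0))
  expect_equal(hic_state_scores(nb1, ns)$OPC, 1)
})
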