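test_that("bootstrapped cross-entropy reduces exactly to cross-entropy at beta = 1", {
  set.seed(4)
  K <- 3; N <- 40
  logits <- matrix(rnorm(K * N), K, N)
  probs <- exp(logits); probs <- sweep(probs, 2, colSums(probs), "/")
  y <- sample(0:(K - 1), N, replace = TRUE)
  w <- runif(N, 0.5, 2)
  got <- bootstrap_ce_loss(probs, y, beta = 1, weights = w)
  expect_equal(got$loss, cross_entropy_oracle(probs, y, w), tolerance = 1e-12)
  got1 <- bootstrap_ce_loss(probs, y, beta = 1)
  expect_equal(got1$loss, cross_entropy_oracle(probs, y), tolerance = 1e-12)
  # at beta < 1 a confidently *wrong* prediction partially bootstraps onto
  # itself, lowering the loss relative to pure cross-entropy
  conf <- matrix(c(0.05, 0.9, 0.05), 3, 5)
  l99 <- bootstrap_ce_loss(conf, rep(0L, 5), beta = 0.99)$loss
  l1 <- bootstrap_ce_loss(conf, rep(0L, 5), beta = 1)$loss
  expect_lt(l99, l1)
  # and when the prediction matches the truth it changes nothing
  ok <- matrix(c(0.9, 0.05, 0.05), 3, 5)
  expect_equal(bootstrap_ce_loss(ok, rep(0L, 5), beta = 0.99)$loss,
               bootstrap_ce_loss(ok, rep(0L, 5), beta = 1)$loss)
})

test_that("forward shapes follow the B -> B/2 -> B/4 audit, including hg38's 3,044 bins", {
  hp <- cnn_hyperparams(seed = 1)
  for (B in c(80L, 3044L)) {
    set.seed(1)
    params <- scontact:::cnn_init_params(B, hp)
    # first dense layer input = 16 * (B/4) + 25 + 1 + 5
    expect_equal(ncol(params$Wf1), 16 * (B / 4) + 31)
    expect_equal(nrow(params$Wf1), 223)
    expect_equal(nrow(params$Wf2), 64)
    expect_equal(nrow(params$Wf3), 3)
    buffers <- scontact:::cnn_init_buffers(hp)
    X <- array(rbinom(5 * B * 2, 1, 0.05), c(5, B, 2))
    E <- matrix(runif(31 * 2), 31, 2)
    fwd <- scontact:::cnn_forward(params, buffers, X, E, hp, training = FALSE)
    expect_equal(dim(fwd$probs), c(3, 2))
    expect_equal(colSums(fwd$probs), c(1, 1), tolerance = 1e-12)
    expect_equal(dim(fwd$caches$p1$y), c(8, B / 2, 2))
    expect_equal(dim(fwd$caches$p2$y), c(16, B / 4, 2))
  }
})

test_that("backpropagation matches numeric gradients", {
  hp <- cnn_hyperparams(dropout = 0, seed = 2)
  B <- 16L
  set.seed(2)
  params <- scontact:::cnn_init_params(B, hp)
  buffers <- scontact:::cnn_init_buffers(hp)
  X <- array(rbinom(5 * B * 4, 1, 0.3), c(5, B, 4))
  E <- matrix(runif(31 * 4), 31, 4)
  y <- c(0L, 1L, 2L, 0L)
  loss_of <- function(p) {
    fwd <- scontact:::cnn_forward(p, buffers, X, E, hp, training = TRUE)
    bootstrap_ce_loss(fwd$probs, y, beta = 1)$loss
  }
  fwd <- scontact:::cnn_forward(params, buffers, X, E, hp, training = TRUE)
  ls <- bootstrap_ce_loss(fwd$probs, y, beta = 1)
  grads <- scontact:::cnn_backward(params, fwd, ls$grad, hp)
  eps <- 1e-5
  for (nm in c("W1", "b1", "g1", "W2", "be2", "Wf1", "gf", "Wf2", "Wf3", "bf3")) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("CNN inputs binarize counts, keep the local 5x5 symmetric, and respect margins", {
  g <- toy_genome()
  p <- tibble::tibble(
    barcode = "c1",
    chrom1 = c("chr1", "chr1", "chr1"),
    pos1 = c(9.5e6, 9.5e6, 10.5e6),
    chrom2 = c("chr1", "chr3", "chr1"),
    pos2 = c(10.5e6, 2.5e6, 10.5e6)
  )
  p <- dplyr::bind_rows(p, p, p, p, p, p, p) # count 7 at each pair
  set <- bin_contacts(p, g, 1e6)
  q <- bin_index(g, "chr1", 10.2e6)
  inp <- build_cnn_input(set, "c1", q)
  expect_equal(dim(inp$neighborhood), c(5, 80))
  expect_true(all(inp$neighborhood %in% c(0, 1))) # binarization idempotent
  expect_equal(inp$local5x5, t(inp$local5x5))
  expect_equal(sum(inp$row_means), 1, tolerance = 1e-12)
  # intra-bin contact appears on the local diagonal
  expect_equal(inp$local5x5[3, 3], 1)
  # margins: first two and last two global bins are refused
  expect_error(build_cnn_input(set, "c1", 2L), "margin")
  expect_error(build_cnn_input(set, "c1", 79L), "margin")
  # an empty cell yields all-zero neighborhood and zero row_means
  set_empty <- set; set_empty$contacts <- set$contacts[0, ]
  inp0 <- scontact:::cnn_input_from_matrix(
    scontact:::cell_sparse_matrix(set_empty, "c1"), q, g)
  expect_equal(sum(inp0$neighborhood), 0)
  expect_equal(inp0$row_means, rep(0, 5))
  expect_equal(inp0$hub_index, 0)
})

test_that("training is bit-reproducible and scanning covers B - 4 bins with argmax calls", {
  spec <- sim_spec(n_cells = c(none = 15, ecdna = 15, hsr = 15),
                   depth = 2000, seed = 8)
  sim <- simulate_cells(spec)
  set <- bin_contacts(sim$pairs, sim$genome, 1e6)
  ctr <- amplicon_bins(spec)[3]
  labels <- tibble::tibble(
    barcode = sim$truth$barcode, bin = ctr,
    label = c(none = 0L, ecdna = 1L, hsr = 2L)[sim$truth$population]
  )
  ds <- cnn_dataset(set, labels)
  hp <- cnn_hyperparams(epochs = 3, seed = 5)
  m1 <- train_cnn(ds, hp)
  m2 <- train_cnn(ds, hp)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$params, m2$params)
  # genome-wide scan: B - 4 predictions per cell, argmax-consistent classes
  calls <- predict_cnn(m1, set, barcodes = set$barcodes[1:2])
  expect_equal(nrow(calls), 2 * (n_bins(set$genome) - 4))
  pm <- as.matrix(calls[, c("p_none", "p_ecdna", "p_hsr")])
  expect_equal(calls$class, max.col(pm, ties.method = "first") - 1L)
  expect_equal(rowSums(pm), rep(1, nrow(pm)), tolerance = 1e-9)
  # aggregation partitions cells across the three classes at every bin
  agg <- aggregate_calls(calls)
  expect_equal(agg$per_bin$frac_none + agg$per_bin$frac_ecdna +
                 agg$per_bin$frac_hsr, rep(1, nrow(agg$per_bin)))
  # genome mismatch is refused
  g2 <- sc_genome(c("chr1", "chr2"), c(2e7, 2e7), 1e6)
  set_small <- set; set_small$genome <- g2
  expect_error(predict_cnn(m1, set_small), "bin count")
  # single-class data is refused
  expect_error(train_cnn(cnn_dataset(set, labels[labels$label == 0L, ]), hp),
               "classes")
})
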