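#' CNN ecDNA caller hyperparameters
#'
#' Defaults: two convolutional modules with 8 then 16 channels, kernels
#' 5 x 45 and 1 x 45 (stride 1; no height padding so the first module
#' collapses the 5 neighbourhood rows; width padding 22 keeps the width),
#' each followed by batch normalisation, ReLU and a width-2 max pool;
#' dropout 0.5 between the modules and after the first dense block; dense
#' head 223 -> 64 -> 3 with batch norm + GELU after the first layer;
#' 40 epochs of minibatch (32) AdamW (learning rate 0.001, weight decay
#' 0.001); hard bootstrapped cross-entropy with beta = 0.99; class weights
#' from inverse training frequency with an extra penalty factor on rows the
#' model currently calls positive, biasing it toward 'none'; 90% of cells
#' train, 10% validate.
#'
#' @param channels conv channels per module.
#' @param kernel_w conv kernel widths.
#' @param conv_pad width padding per module.
#' @param dropout dropout probability (both sites).
#' @param fc_hidden hidden sizes of the dense head.
#' @param n_classes number of output classes (none/ecDNA/HSR).
#' @param epochs,batch_size training schedule.
#' @param lr,weight_decay AdamW settings.
#' @param beta bootstrapped cross-entropy mixing parameter.
#' @param class_weights optional fixed per-class weights; default inverse
#'   training-class frequency.
#' @param positive_penalty loss multiplier applied when the current
#'   prediction is a positive class (ecDNA/HSR).
#' @param train_fraction fraction of cells used for training.
#' @param seed seed driving the split, initialisation, shuffling and dropout.
#' @return list of hyperparameters.
#' @export
cnn_hyperparams <- function(channels = c(8, 16), kernel_w = c(45, 45),
                            conv_pad = c(22, 22), dropout = 0.5,
                            fc_hidden = c(223, 64), n_classes = 3,
                            epochs = 40, batch_size = 32, lr = 0.001,
                            weight_decay = 0.001, beta = 0.99,
                            class_weights = NULL, positive_penalty = 2,
                            train_fraction = 0.9, seed = 1) {
  as.list(environment())
}

#' Build the CNN input for one (cell, bin)
#'
#' The input is the binarized 5 Mb neighbourhood of the query bin: the five
#' contact-matrix rows for bins q-2..q+2 over all B global bins (entry 1 iff
#' the raw count is positive), plus three side features: the binarized 5 x 5
#' local matrix among the five neighbourhood bins (diagonal = intra-bin
#' contacts), the hub index of the centre bin computed from raw counts, and
#' the L1-normalised row means of the binarized neighbourhood. The first two
#' and last two global bins have no full neighbourhood and are skipped.
#'
#' @param set an `sc_cellset` at the feature resolution.
#' @param barcode cell identifier.
#' @param bin global query bin (must satisfy `2 < bin <= B - 2`).
#' @return list with `neighborhood` (5 x B 0/1 matrix), `local5x5`,
#'   `hub_index`, `row_means`, `barcode`, `bin`.
#' @export
build_cnn_input <- function(set, barcode, bin) {
  B <- n_bins(set$genome)
  if (bin <= 2 || bin > B - 2) {
    stop("bin ", bin, " is in the two-bin genome margin; no 5 Mb neighbourhood",
         call. = FALSE)
  }
  M <- cell_sparse_matrix(set, barcode)
  cnn_input_from_matrix(M, bin, set$genome)
}

# symmetric sparse contact matrix of one cell
cell_sparse_matrix <- function(set, barcode) {
  tr <- set$contacts[set$contacts$barcode == barcode, ]
  B <- n_bins(set$genome)
  off <- tr$bin1 != tr$bin2
  Matrix::sparseMatrix(
    i = c(tr$bin1, tr$bin2[off]),
    j = c(tr$bin2, tr$bin1[off]),
    x = c(tr$count, tr$count[off]),
    dims = c(B, B)
  )
}

cnn_input_from_matrix <- function(M, bin, genome) {
  rows <- (bin - 2):(bin + 2)
  raw <- as.matrix(M[rows, , drop = FALSE])
  nb <- (raw > 0) * 1
  local5 <- nb[, rows, drop = FALSE]
  # hub index of the centre bin on raw counts aggregated per chromosome
  chrom_of <- bin_chrom(genome)
  own <- chrom_of[bin]
  eligible <- setdiff(genome$chrom_names, c(own, genome$excluded_chroms))
  ctr <- raw[3, ]
  agg <- tapply(ctr, factor(chrom_of, levels = eligible), sum)
  agg[is.na(agg)] <- 0
  hi <- if (sum(agg) > 0) hub_index(as.numeric(agg)) else 0
  rm_ <- rowMeans(nb)
  s <- sum(rm_)
  if (s > 0) rm_ <- rm_ / s
  list(neighborhood = nb, local5x5 = local5, hub_index = hi,
       row_means = rm_, bin = bin)
}

#' Assemble a training/prediction dataset of CNN inputs
#'
#' @param set an `sc_cellset`.
#' @param labels tibble with `barcode`, `bin` and (optionally) `label`
#'   (integer 0 none / 1 ecDNA / 2 HSR).
#' @param drop_empty drop rows whose neighbourhood holds no contact
#'   (default TRUE for training sets).
#' @return a `cnn_dataset`: list with array `X` (5, B, N), matrix `extras`
#'   (25 + 1 + 5, N), `labels`, `barcode`, `bin`, `genome`.
#' @export
cnn_dataset <- function(set, labels, drop_empty = TRUE) {
  B <- n_bins(set$genome)
  n <- nrow(labels)
  X <- array(0, c(5, B, n))
  E <- matrix(0, 31, n)
  keep <- rep(TRUE, n)
  for (bc in unique(labels$barcode)) {
    M <- cell_sparse_matrix(set, bc)
    for (r in which(labels$barcode == bc)) {
      inp <- cnn_input_from_matrix(M, labels$bin[r], set$genome)
      X[, , r] <- inp$neighborhood
      E[, r] <- c(as.numeric(inp$local5x5), inp$hub_index, inp$row_means)
      if (drop_empty && sum(inp$neighborhood) == 0) keep[r] <- FALSE
    }
  }
  structure(
    list(X = X[, , keep, drop = FALSE], extras = E[, keep, drop = FALSE],
         labels = if ("label" %in% names(labels)) as.integer(labels$label[keep]),
         barcode = labels$barcode[keep], bin = labels$bin[keep],
         genome = set$genome),
    class = "cnn_dataset"
  )
}

# width padded to a multiple of 4 with zero columns on the right
pad_width <- function(B) as.integer(ceiling(B / 4) * 4)

cnn_init_params <- function(B, hp) {
  Bp <- pad_width(B)
  c1 <- hp$channels[1]; c2 <- hp$channels[2]
  f_in <- c2 * (Bp / 4) + 31
  list(
    W1 = init_mat(c1, 5 * hp$kernel_w[1]), b1 = numeric(c1),
    g1 = rep(1, c1), be1 = numeric(c1),
    W2 = init_mat(c2, c1 * hp$kernel_w[2]), b2 = numeric(c2),
    g2 = rep(1, c2), be2 = numeric(c2),
    Wf1 = init_mat(hp$fc_hidden[1], f_in), bf1 = numeric(hp$fc_hidden[1]),
    gf = rep(1, hp$fc_hidden[1]), bef = numeric(hp$fc_hidden[1]),
    Wf2 = init_mat(hp$fc_hidden[2], hp$fc_hidden[1]),
    bf2 = numeric(hp$fc_hidden[2]),
    Wf3 = init_mat(hp$n_classes, hp$fc_hidden[2]), bf3 = numeric(hp$n_classes)
  )
}

cnn_init_buffers <- function(hp) {
  list(
    rm1 = numeric(hp$channels[1]), rv1 = rep(1, hp$channels[1]),
    rm2 = numeric(hp$channels[2]), rv2 = rep(1, hp$channels[2]),
    rmf = numeric(hp$fc_hidden[1]), rvf = rep(1, hp$fc_hidden[1])
  )
}

# Forward pass. X: (5, B, N) (unpadded); returns probs, caches, buffers.
cnn_forward <- function(params, buffers, X, E, hp, training) {
  B <- dim(X)[2]; N <- dim(X)[3]
  Bp <- pad_width(B)
  if (Bp > B) {
    Xp <- array(0, c(5, Bp, N)); Xp[, seq_len(B), ] <- X; X <- Xp
  }
  ca <- list()
  ca$c1 <- conv1d_forward(X, params$W1, params$b1, hp$conv_pad[1])
  bn1 <- bn_forward(matrix(ca$c1$y, nrow = hp$channels[1]),
                    list(gamma = params$g1, beta = params$be1,
                         running_mean = buffers$rm1, running_var = buffers$rv1),
                    training)
  buffers$rm1 <- bn1$p$running_mean; buffers$rv1 <- bn1$p$running_var
  ca$bn1 <- bn1
  r1 <- relu_forward(bn1$y)
  ca$r1 <- r1
  ca$p1 <- pool2_forward(array(r1$y, c(hp$channels[1], Bp, N)))
  ca$d1 <- dropout_forward(ca$p1$y, hp$dropout, training)
  ca$c2 <- conv1d_forward(ca$d1$y, params$W2, params$b2, hp$conv_pad[2])
  bn2 <- bn_forward(matrix(ca$c2$y, nrow = hp$channels[2]),
                    list(gamma = params$g2, beta = params$be2,
                         running_mean = buffers$rm2, running_var = buffers$rv2),
                    training)
  buffers$rm2 <- bn2$p$running_mean; buffers$rv2 <- bn2$p$running_var
  ca$bn2 <- bn2
  r2 <- relu_forward(bn2$y)
  ca$r2 <- r2
  ca$p2 <- pool2_forward(array(r2$y, c(hp$channels[2], Bp / 2, N)))
  flat <- matrix(ca$p2$y, nrow = hp$channels[2] * Bp / 4)
  z <- rbind(flat, E)
  ca$z <- z
  f1 <- params$Wf1 %*% z + params$bf1
  bnf <- bn_forward(f1,
                    list(gamma = params$gf, beta = params$bef,
                         running_mean = buffers$rmf, running_var = buffers$rvf),
                    training)
  buffers$rmf <- bnf$p$running_mean; buffers$rvf <- bnf$p$running_var
  ca$bnf <- bnf
  ca$g1a <- gelu_forward(bnf$y)
  ca$df <- dropout_forward(ca$g1a$y, hp$dropout, training)
  f2 <- params$Wf2 %*% ca$df$y + params$bf2
  ca$g2a <- gelu_forward(f2)
  logits <- params$Wf3 %*% ca$g2a$y + params$bf3
  list(probs = softmax_cols(logits), caches = ca, buffers = buffers,
       Bp = Bp, N = N)
}

cnn_backward <- function(params, fwd, dlogits, hp) {
  ca <- fwd$caches
  g <- list()
  g$Wf3 <- dlogits %*% t(ca$g2a$y); g$bf3 <- rowSums(dlogits)
  d <- (t(params$Wf3) %*% dlogits) * ca$g2a$grad
  g$Wf2 <- d %*% t(ca$df$y); g$bf2 <- rowSums(d)
  d <- t(params$Wf2) %*% d
  if (!is.null(ca$df$mask)) d <- d * ca$df$mask
  d <- d * ca$g1a$grad
  bb <- bn_backward(d, ca$bnf, params$gf)
  g$gf <- bb$dgamma; g$bef <- bb$dbeta
  d <- bb$dx
  g$Wf1 <- d %*% t(ca$z); g$bf1 <- rowSums(d)
  dz <- t(params$Wf1) %*% d
  F1 <- hp$channels[2] * fwd$Bp / 4
  dflat <- array(dz[seq_len(F1), , drop = FALSE],
                 c(hp$channels[2], fwd$Bp / 4, fwd$N))
  d <- pool2_backward(dflat, ca$p2)
  d <- relu_backward(matrix(d, nrow = hp$channels[2]), ca$r2)
  bb <- bn_backward(d, ca$bn2, params$g2)
  g$g2 <- bb$dgamma; g$be2 <- bb$dbeta
  cb <- conv1d_backward(array(bb$dx, c(hp$channels[2], fwd$Bp / 2, fwd$N)),
                        params$W2, ca$c2)
  g$W2 <- cb$dW; g$b2 <- cb$db
  d <- cb$dx
  if (!is.null(ca$d1$mask)) d <- d * ca$d1$mask
  d <- pool2_backward(d, ca$p1)
  d <- relu_backward(matrix(d, nrow = hp$channels[1]), ca$r1)
  bb <- bn_backward(d, ca$bn1, params$g1)
  g$g1 <- bb$dgamma; g$be1 <- bb$dbeta
  cb <- conv1d_backward(array(bb$dx, c(hp$channels[1], fwd$Bp, fwd$N)),
                        params$W1, ca$c1)
  g$W1 <- cb$dW; g$b1 <- cb$db
  g
}

#' Train the CNN ecDNA caller
#'
#' Cells (not rows) are split 90/10 into training and validation; the model
#' is trained with minibatch AdamW under the hard bootstrapped cross-entropy
#' loss with class weights biased toward the negative class. Everything
#' random (split, initialisation, shuffling, dropout) derives from
#' `hyperparams$seed`, so runs are bit-reproducible.
#'
#' @param dataset a `cnn_dataset` with labels 0/1/2 (all classes present).
#' @param hyperparams from [cnn_hyperparams()].
#' @return a `cnn_model`: parameters, batch-norm buffers, hyperparameters,
#'   genome signature, per-epoch `loss_log`, and validation metrics
#'   (`confusion`, `metrics`, `cell_metrics`).
#' @export
train_cnn <- function(dataset, hyperparams = cnn_hyperparams()) {
  hp <- hyperparams
  y <- dataset$labels
  if (is.null(y)) stop("dataset has no labels")
  if (length(unique(y)) < hp$n_classes) {
    stop("all ", hp$n_classes, " classes must be present in the dataset")
  }
  set.seed(hp$seed)
  cells <- unique(dataset$barcode)
  tr_cells <- sample(cells, floor(hp$train_fraction * length(cells)))
  tr <- dataset$barcode %in% tr_cells
  if (length(unique(y[tr])) < hp$n_classes) {
    stop("all classes must be present in the training split")
  }
  B <- dim(dataset$X)[2]
  params <- cnn_init_params(B, hp)
  buffers <- cnn_init_buffers(hp)
  opt <- adamw_init(params)
  decay_set <- c("W1", "W2", "Wf1", "Wf2", "Wf3")
  cw <- hp$class_weights
  if (is.null(cw)) {
    freq <- tabulate(y[tr] + 1L, nbins = hp$n_classes)
    cw <- sum(freq) / (hp$n_classes * pmax(freq, 1))
  }
  idx_tr <- which(tr)
  loss_log <- numeric(hp$epochs)
  for (ep in seq_len(hp$epochs)) {
    ord <- sample(idx_tr)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = hp$batch_size)) {
      bi <- ord[start:min(start + hp$batch_size - 1, length(ord))]
      Xb <- dataset$X[, , bi, drop = FALSE]
      Eb <- dataset$extras[, bi, drop = FALSE]
      yb <- y[bi]
      fwd <- cnn_forward(params, buffers, Xb, Eb, hp, training = TRUE)
      buffers <- fwd$buffers
      pred <- max.col(t(fwd$probs), ties.method = "first") - 1L
      w <- cw[yb + 1L] * ifelse(pred > 0, hp$positive_penalty, 1)
      ls <- bootstrap_ce_loss(fwd$probs, yb, hp$beta, w)
      grads <- cnn_backward(params, fwd, ls$grad, hp)
      st <- adamw_step(params, grads, opt, lr = hp$lr,
                       weight_decay = hp$weight_decay, decay_set = decay_set)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    loss_log[ep] <- ep_loss / nb
  }
  model <- structure(
    list(params = params, buffers = buffers, hyperparams = hp,
         genome = dataset$genome, loss_log = loss_log,
         train_cells = tr_cells, class_weights = cw),
    class = "cnn_model"
  )
  # validation
  va <- which(!tr)
  if (length(va) > 0) {
    pv <- cnn_predict_arrays(model, dataset$X[, , va, drop = FALSE],
                             dataset$extras[, va, drop = FALSE])
    model$validation <- cnn_validation_metrics(
      truth = y[va], pred = pv$class, barcode = dataset$barcode[va]
    )
  }
  model
}

cnn_validation_metrics <- function(truth, pred, barcode) {
  K <- 3
  confusion <- table(factor(truth, levels = 0:(K - 1)),
                     factor(pred, levels = 0:(K - 1)),
                     dnn = c("truth", "predicted"))
  per_class <- dplyr::bind_rows(lapply(0:(K - 1), function(k) {
    m <- binary_metrics(truth == k, pred == k)
    dplyr::bind_cols(tibble::tibble(class = k), m)
  }))
  cell <- tibble::tibble(barcode = barcode, truth = truth, pred = pred) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(truth = max(.data$truth), pred = max(.data$pred),
                     .groups = "drop")
  list(
    confusion = confusion,
    ternary_accuracy = mean(truth == pred),
    per_class = per_class,
    binary = binary_metrics(truth > 0, pred > 0),
    cell_accuracy = mean(cell$truth == cell$pred)
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> B = %d bins, %d epochs, final loss %.4f\n",
              n_bins(x$genome), length(x$loss_log),
              x$loss_log[length(x$loss_log)]))
  if (!is.null(x$validation)) {
    cat(sprintf("validation ternary accuracy: %.3f\n",
                x$validation$ternary_accuracy))
  }
  invisible(x)
}

#' @method tidy cnn_model
#' @export
tidy.cnn_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_log), loss = x$loss_log)
}

#' @method glance cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  out <- tibble::tibble(
    epochs = length(x$loss_log), final_loss = x$loss_log[length(x$loss_log)],
    n_train_cells = length(x$train_cells)
  )
  if (!is.null(x$validation)) {
    out$ternary_accuracy <- x$validation$ternary_accuracy
    out <- dplyr::bind_cols(out, x$validation$binary)
  }
  out
}

# eval-mode prediction on prepared arrays
cnn_predict_arrays <- function(model, X, E, batch = 256) {
  N <- dim(X)[3]
  probs <- matrix(0, model$hyperparams$n_classes, N)
  for (start in seq(1, N, by = batch)) {
    bi <- start:min(start + batch - 1, N)
    fwd <- cnn_forward(model$params, model$buffers,
                       X[, , bi, drop = FALSE], E[, bi, drop = FALSE],
                       model$hyperparams, training = FALSE)
    probs[, bi] <- fwd$probs
  }
  list(probs = probs,
       class = max.col(t(probs), ties.method = "first") - 1L)
}

#' Scan cells genome-wide with a trained CNN
#'
#' Applies the model to every non-margin bin (bins 3..B-2, i.e. B - 4
#' predictions per cell) of every requested cell. The predicted class is the
#' argmax of the softmax probabilities, ties resolved toward the lowest
#' class index ('none').
#'
#' @param model a `cnn_model`.
#' @param set an `sc_cellset` with the same bin count as the training genome.
#' @param barcodes cells to scan (default all).
#' @return an `ecdna_calls` tibble: `barcode`, `bin`, `p_none`, `p_ecdna`,
#'   `p_hsr`, `class` (0/1/2).
#' @export
predict_cnn <- function(model, set, barcodes = set$barcodes) {
  B <- n_bins(set$genome)
  if (B != n_bins(model$genome)) {
    stop("genome bin count (", B, ") differs from the training genome (",
         n_bins(model$genome), ")")
  }
  bins <- 3:(B - 2)
  out <- lapply(barcodes, function(bc) {
    M <- cell_sparse_matrix(set, bc)
    X <- array(0, c(5, B, length(bins)))
    E <- matrix(0, 31, length(bins))
    for (k in seq_along(bins)) {
      inp <- cnn_input_from_matrix(M, bins[k], set$genome)
      X[, , k] <- inp$neighborhood
      E[, k] <- c(as.numeric(inp$local5x5), inp$hub_index, inp$row_means)
    }
    pv <- cnn_predict_arrays(model, X, E)
    tibble::tibble(barcode = bc, bin = bins,
                   p_none = pv$probs[1, ], p_ecdna = pv$probs[2, ],
                   p_hsr = pv$probs[3, ], class = pv$class)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("ecdna_calls", class(res))
  res
}

#' Aggregate per-(cell, bin) ecDNA calls over the population
#'
#' @param result an `ecdna_calls` tibble from [predict_cnn()] (or any tibble
#'   with `barcode`, `bin`, `class`).
#' @return list with `per_bin` (fraction of cells in each class per bin;
#'   fractions over the three classes sum to 1) and `per_cell` (any-positive
#'   flags per cell).
#' @export
aggregate_calls <- function(result) {
  n_cells <- dplyr::n_distinct(result$barcode)
  per_bin <- result |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      frac_none = mean(.data$class == 0),
      frac_ecdna = mean(.data$class == 1),
      frac_hsr = mean(.data$class == 2),
      .groups = "drop"
    )
  per_cell <- result |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      any_ecdna = any(.data$class == 1),
      any_hsr = any(.data$class == 2),
      any_positive = any(.data$class > 0),
      .groups = "drop"
    )
  list(per_bin = per_bin, per_cell = per_cell, n_cells = n_cells)
}
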