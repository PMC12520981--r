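# Minimal deterministic neural-network primitives used by the CNN ecDNA
# caller: 1-D multi-channel convolution (im2col), batch normalization,
# ReLU/GELU, width-2 max pooling, inverted dropout, dense layers, softmax,
# hard bootstrapped cross-entropy, and AdamW. All randomness flows through
# R's global RNG so a single set.seed() makes training bit-reproducible.

# x: array (C_in, L, N); W: (C_out, C_in*KL); returns y (C_out, Lout, N)
conv1d_forward <- function(x, W, b, pad) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  KL <- ncol(W) / C
  xp <- array(0, c(C, L + 2 * pad, N))
  xp[, pad + seq_len(L), ] <- x
  Lout <- L + 2 * pad - KL + 1
  K <- array(0, c(C * KL, Lout, N))
  for (k in seq_len(KL)) {
    K[((k - 1) * C + 1):(k * C), , ] <- xp[, k:(k + Lout - 1), , drop = FALSE]
  }
  Km <- matrix(K, nrow = C * KL)
  y <- W %*% Km + b
  list(y = array(y, c(nrow(W), Lout, N)),
       Km = Km, C = C, L = L, N = N, KL = KL, pad = pad, Lout = Lout)
}

conv1d_backward <- function(dy, W, cache) {
  dym <- matrix(dy, nrow = dim(dy)[1])
  dW <- dym %*% t(cache$Km)
  db <- rowSums(dym)
  dKm <- t(W) %*% dym
  dK <- array(dKm, c(cache$C * cache$KL, cache$Lout, cache$N))
  dxp <- array(0, c(cache$C, cache$L + 2 * cache$pad, cache$N))
  for (k in seq_len(cache$KL)) {
    idx <- k:(k + cache$Lout - 1)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] +
      dK[((k - 1) * cache$C + 1):(k * cache$C), , , drop = FALSE]
  }
  list(dW = dW, db = db,
       dx = dxp[, cache$pad + seq_len(cache$L), , drop = FALSE])
}

# Batch normalization over rows (channels/features); x given as matrix
# (C, M) where M pools width and batch. p holds gamma/beta and running stats.
bn_forward <- function(xm, p, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    p$running_mean <- (1 - momentum) * p$running_mean + momentum * mu
    p$running_var <- (1 - momentum) * p$running_var + momentum * v
  } else {
    mu <- p$running_mean
    v <- p$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  list(y = p$gamma * xhat + p$beta, xhat = xhat, inv = inv, p = p)
}

bn_backward <- function(dy, cache, gamma) {
  M <- ncol(dy)
  dxhat <- dy * gamma
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  # dx in the fused form
  dx <- (cache$inv / M) *
    (M * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

gelu_forward <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, grad = ph + x * stats::dnorm(x))
}

# halve the width (second dim) keeping per-pair maxima; ties take the left
pool2_forward <- function(x) {
  L <- dim(x)[2]
  a <- x[, seq(1, L, 2), , drop = FALSE]
  b <- x[, seq(2, L, 2), , drop = FALSE]
  list(y = pmax(a, b), takea = a >= b, L = L)
}

pool2_backward <- function(dy, cache) {
  dx <- array(0, c(dim(dy)[1], cache$L, dim(dy)[3]))
  dx[, seq(1, cache$L, 2), ] <- dy * cache$takea
  dx[, seq(2, cache$L, 2), ] <- dy * !cache$takea
  dx
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) > p) / (1 - p), dim(x) %||% length(x))
  list(y = x * mask, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Hard bootstrapped cross-entropy loss
#'
#' Per sample, with softmax probabilities p, one-hot truth t and one-hot
#' current argmax prediction z:
#' \deqn{L = -\sum_c (\beta t_c + (1-\beta) z_c) \log p_c,}
#' optionally scaled by a per-sample weight. At `beta = 1` this is exactly
#' the (weighted) cross-entropy. Used with class weights indexed by the true
#' class times a penalty factor applied whenever the model's current
#' prediction is a positive class, which biases training toward negative
#' ('none') predictions.
#'
#' @param probs matrix of class probabilities, classes in rows, samples in
#'   columns (each column sums to 1).
#' @param labels integer vector of true classes in `0:(nrow(probs)-1)`.
#' @param beta bootstrap mixing parameter in [0, 1] (default 0.99).
#' @param weights optional per-sample weights (default 1).
#' @return list with `loss` (mean over samples) and `grad` (d loss / d
#'   logits, same shape as `probs`).
#' @export
bootstrap_ce_loss <- function(probs, labels, beta = 0.99, weights = NULL) {
  K <- nrow(probs); N <- ncol(probs)
  if (is.null(weights)) weights <- rep(1, N)
  t_oh <- matrix(0, K, N); t_oh[cbind(labels + 1L, seq_len(N))] <- 1
  pred <- max.col(t(probs), ties.method = "first")
  z_oh <- matrix(0, K, N); z_oh[cbind(pred, seq_len(N))] <- 1
  q <- beta * t_oh + (1 - beta) * z_oh
  logp <- log(pmax(probs, 1e-12))
  loss <- mean(-colSums(q * logp) * weights)
  grad <- sweep(probs - q, 2, weights, "*") / N
  list(loss = loss, grad = grad)
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

# decay_set: names of parameters receiving weight decay (weights, not biases
# or batch-norm scales)
adamw_step <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       decay_set = character(0)) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (nm %in% decay_set) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# He-uniform initialisation
init_mat <- function(nout, nin) {
  a <- sqrt(6 / nin)
  matrix(stats::runif(nout * nin, -a, a), nout, nin)
}
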