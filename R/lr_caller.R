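#' Fit the logistic-regression ecDNA caller
#'
#' Multivariate logistic regression (via [stats::glm()]) of a binary ecDNA
#' label on the per-(cell, bin) feature triplet: inferred copy number, hub
#' index and trans-to-cis contacting-bin ratio. Rows with an undefined ratio
#' are dropped from fitting; at prediction time they are imputed with the
#' per-bin population median (see [predict_lr()]).
#'
#' @param features tibble from [build_feature_table()].
#' @param labels logical/0-1 vector, one per feature row (TRUE = ecDNA).
#' @param holdout_fraction fraction of rows held out to report apparent
#'   performance (0 disables; default 0.2).
#' @param threshold probability cutoff for the held-out metrics.
#' @param seed seed for the holdout split.
#' @return an `lr_caller`: list with the `glm` fit, `threshold`, and
#'   `metrics` (held-out sensitivity/specificity/precision/accuracy).
#' @export
fit_lr <- function(features, labels, holdout_fraction = 0.2, threshold = 0.5,
                   seed = 1) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(y) == nrow(features))
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  df <- dplyr::transmute(features,
                         inferred_copy = .data$inferred_copy,
                         hub_index = .data$hub_index,
                         trans_cis_ratio = .data$trans_cis_ratio)
  df$y <- y
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$y)) < 2) stop("labels must contain both classes after dropping incomplete rows")
  metrics <- NULL
  test_idx <- integer(0)
  if (holdout_fraction > 0) {
    set.seed(seed)
    n <- nrow(df)
    test_idx <- sample.int(n, max(1, round(holdout_fraction * n)))
    if (length(unique(df$y[-test_idx])) < 2) test_idx <- integer(0)
  }
  train <- if (length(test_idx)) df[-test_idx, ] else df
  fit <- stats::glm(y ~ inferred_copy + hub_index + trans_cis_ratio,
                    family = stats::binomial(), data = train)
  if (length(test_idx)) {
    p <- stats::predict(fit, df[test_idx, ], type = "response")
    metrics <- binary_metrics(df$y[test_idx] == 1, p >= threshold)
  }
  structure(list(fit = fit, threshold = threshold, metrics = metrics),
            class = "lr_caller")
}

binary_metrics <- function(truth, call) {
  tp <- sum(truth & call); fn <- sum(truth & !call)
  fp <- sum(!truth & call); tn <- sum(!truth & !call)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    accuracy = (tp + tn) / length(truth)
  )
}

#' @export
print.lr_caller <- function(x, ...) {
  cat("<lr_caller> logistic ecDNA caller, threshold", x$threshold, "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy lr_caller
#' @export
tidy.lr_caller <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @method glance lr_caller
#' @export
glance.lr_caller <- function(x, ...) {
  out <- tibble::tibble(
    threshold = x$threshold,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    n = length(x$fit$y)
  )
  if (!is.null(x$metrics)) out <- dplyr::bind_cols(out, x$metrics)
  out
}

#' Predict ecDNA presence with a fitted logistic caller
#'
#' Rows with an undefined trans-to-cis ratio are imputed with the per-bin
#' median ratio of the supplied table (falling back to the global median).
#' The binary call is `probability >= threshold`; the default threshold is
#' 0.5, and stricter values (e.g. 0.95) suit noisier libraries.
#'
#' @param model an `lr_caller`.
#' @param features tibble from [build_feature_table()].
#' @param threshold probability cutoff; default the model's.
#' @return `features` with added `probability` and `call` columns.
#' @export
predict_lr <- function(model, features, threshold = model$threshold) {
  df <- features |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(trans_cis_ratio = impute_median(.data$trans_cis_ratio)) |>
    dplyr::ungroup() |>
    dplyr::mutate(trans_cis_ratio = impute_median(.data$trans_cis_ratio),
                  hub_index = impute_median(.data$hub_index))
  p <- stats::predict(model$fit, df, type = "response")
  dplyr::mutate(features, probability = as.numeric(p),
                call = .data$probability >= threshold)
}

impute_median <- function(x) {
  if (all(is.na(x))) return(x)
  x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  x
}
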