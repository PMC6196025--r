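#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, with ties counted
#' one half.
#'
#' @param scores numeric predictions.
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated split-sample AUC for smoking-status prediction
#'
#' Per repeat: a stratified random training set of fixed composition
#' (default 27 current and 145 never smokers) is drawn, a logistic
#' regression fit on it, and the AUC of the predicted probabilities
#' evaluated on all held-out subjects. Reports the mean over repeats.
#' A training fit with complete separation is refit with a small ridge
#' penalty (iteratively reweighted least squares with an L2 term) and
#' counted in `n_regularized`.
#'
#' @param features numeric matrix or data frame, subjects x features
#'   (complete cases required).
#' @param labels binary smoking status (`TRUE`/1/`"current"` = positive).
#' @param n_train_pos,n_train_neg training-set composition.
#' @param n_repeats number of random splits (default 1000).
#' @param seed integer seed making the split sequence deterministic.
#' @return A `prediction_result` list: `mean_auc`, `aucs` (per repeat),
#'   `n_repeats`, `n_regularized`.
#' @export
repeated_split_auc <- function(features, labels,
                               n_train_pos = 27, n_train_neg = 145,
                               n_repeats = 1000, seed = 1L) {
  X <- as.matrix(features)
  if (anyNA(X)) stop("features must be complete cases", call. = FALSE)
  colnames(X) <- paste0("f", seq_len(ncol(X)))  # stable model-frame names
  if (is.character(labels)) labels <- labels == "current"
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  y <- as.integer(as.logical(labels))
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (n_train_pos > length(pos) || n_train_neg > length(neg)) {
    stop("training composition exceeds available group sizes",
         call. = FALSE)
  }
  stopifnot(n_repeats >= 1)
  set.seed(seed)
  n_reg <- 0L
  aucs <- vapply(seq_len(n_repeats), function(r) {
    tr <- c(sample(pos, n_train_pos), sample(neg, n_train_neg))
    te <- setdiff(seq_along(y), tr)
    df <- data.frame(y = y[tr], as.data.frame(X[tr, , drop = FALSE]))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    # glm can converge quietly on separated data (the deviance flattens
    # before the fitted-probability check fires); a huge linear predictor
    # on the training set is the reliable symptom
    if (!sep && (!fit$converged ||
                 max(abs(stats::predict(fit, type = "link"))) > 20)) {
      sep <- TRUE
    }
    if (sep) {
      n_reg <<- n_reg + 1L
      b <- ridge_logistic(cbind(1, X[tr, , drop = FALSE]), y[tr],
                          lambda = 1e-3)
      eta <- cbind(1, X[te, , drop = FALSE]) %*% b
      pr <- stats::plogis(drop(eta))
    } else {
      pr <- stats::predict(fit,
                           newdata = as.data.frame(X[te, , drop = FALSE]),
                           type = "response")
    }
    auc(pr, y[te])
  }, numeric(1))
  structure(list(mean_auc = mean(aucs), aucs = aucs,
                 n_repeats = n_repeats, n_regularized = n_reg),
            class = "prediction_result")
}

# small-ridge logistic regression by IRLS; stabilises separated fits
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 50) {
  b <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X))
  pen[1, 1] <- 0  # do not penalise the intercept
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    b_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(b_new - b)) < 1e-8) { b <- b_new; break }
    b <- b_new
  }
  drop(b)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> mean AUC %.3f over %d splits",
              x$mean_auc, x$n_repeats))
  if (x$n_regularized > 0) {
    cat(sprintf(" (%d regularized fits)", x$n_regularized))
  }
  cat("\n")
  invisible(x)
}

#' @export
glance.prediction_result <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc,
                 sd_auc = stats::sd(x$aucs),
                 n_repeats = x$n_repeats,
                 n_regularized = x$n_regularized)
}

#' Histogram of per-split AUC values
#'
#' @param object a `prediction_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(auc = object$aucs),
                  ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_auc,
                        linetype = "dashed") +
    ggplot2::labs(x = "validation AUC", y = "splits") +
    ggplot2::theme_minimal()
}
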