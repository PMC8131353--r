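# Sparse partial least squares regression for a univariate response.
# Per component the cross-covariance z = X'y is soft-thresholded at
# eta * max|z| to give a sparse direction; the active set accumulates the
# nonzero supports, an ordinary PLS fit with the current number of
# components is refit on the active set, and the response is deflated.
# The concavity parameter kappa of the general objective is inert for a
# univariate response and is recorded for fidelity only.

# Ordinary univariate-response PLS (NIPALS), X assumed centered/scaled,
# y centered. Returns regression coefficients on the given scale and the
# number of components actually fit (components stop early when the
# scores degenerate, i.e. K exceeds the rank).
pls1 <- function(X, y, K) {
  p <- ncol(X)
  W <- matrix(0, p, 0)
  P <- matrix(0, p, 0)
  qvec <- numeric(0)
  Xd <- X; yd <- y
  for (k in seq_len(K)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tsc <- Xd %*% w
    tt <- sum(tsc^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xd, tsc) / tt
    qk <- sum(yd * tsc) / tt
    Xd <- Xd - tcrossprod(tsc, pvec)
    yd <- yd - qk * tsc
    W <- cbind(W, w); P <- cbind(P, pvec); qvec <- c(qvec, qk)
  }
  if (length(qvec) == 0) return(list(beta = rep(0, p), K_used = 0L))
  beta <- W %*% solve(crossprod(P, W), qvec)
  list(beta = as.vector(beta), K_used = length(qvec))
}

#' Fit a sparse PLS regression model
#'
#' Sparse partial least squares for a single numeric response (here, the
#' numeric disease-stage target). The sparsity parameter `eta` in
#' `[0, 1)` soft-thresholds each component's cross-covariance vector at
#' `eta * max|z|`; `K` is the number of latent components. Columns are
#' standardized internally and coefficients are returned on the original
#' scale. Selected features are the accumulated active set.
#'
#' @param X Numeric matrix, samples x features (named columns).
#' @param y Numeric response.
#' @param eta Sparsity parameter in `[0, 1)`.
#' @param K Number of latent components; reduced with a warning when it
#'   exceeds the rank of the active set.
#' @param kappa Recorded constant (default 0.5); has no effect for a
#'   univariate response.
#' @param scale Standardize columns (default `TRUE`).
#' @param warn_rank Warn when `K` exceeds the informative rank (set to
#'   `FALSE` inside routine hyperparameter search).
#' @return An `spls_fit`: coefficients, intercept, selected features,
#'   hyperparameters and training RMSE.
#' @export
fit_spls <- function(X, y, eta, K, kappa = 0.5, scale = TRUE, warn_rank = TRUE) {
  stop_if_not(eta >= 0 && eta < 1, "eta must lie in [0, 1)")
  stop_if_not(K >= 1, "K must be >= 1")
  n <- nrow(X); p <- ncol(X)
  stop_if_not(length(y) == n, "length(y) must match nrow(X)")
  mx <- colMeans(X)
  sx <- if (scale) col_sds(X) else rep(1, p)
  sx[sx < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y)
  yc <- y - my

  A <- integer(0)
  beta_std <- rep(0, p)
  y1 <- yc
  K_used <- 0L
  for (k in seq_len(K)) {
    z <- crossprod(Xs, y1)
    zmax <- max(abs(z))
    if (zmax < 1e-12) {
      # residual orthogonal to the feature space: K exceeds the
      # informative rank of the data
      if (k > 1 && warn_rank) warning("K exceeds the rank of the data; using K = ", K_used)
      break
    }
    w <- sign(z) * pmax(abs(z) - eta * zmax, 0)
    sel <- which(w != 0)
    if (length(sel) == 0) {
      if (k == 1) stop("eta too large: empty direction vector", call. = FALSE)
      break
    }
    A <- union(A, union(sel, which(beta_std != 0)))
    fit <- pls1(Xs[, A, drop = FALSE], yc, k)
    if (fit$K_used < k) {
      if (warn_rank) warning("K exceeds the rank of the active set; using K = ", fit$K_used)
      K_used <- fit$K_used
      beta_std <- rep(0, p); beta_std[A] <- fit$beta
      break
    }
    beta_std <- rep(0, p); beta_std[A] <- fit$beta
    y1 <- yc - Xs[, A, drop = FALSE] %*% fit$beta
    K_used <- k
  }
  beta <- beta_std / sx
  intercept <- my - sum(beta * mx)
  fitted <- intercept + as.vector(X %*% beta)
  structure(list(
    coefficients = setNames(beta, colnames(X)),
    intercept = intercept,
    selected_features = colnames(X)[sort(A)],
    eta = eta, K = K, K_used = K_used, kappa = kappa,
    center = mx, scale = sx,
    training_rmse = sqrt(mean((y - fitted)^2)),
    n = n, p = p
  ), class = "spls_fit")
}

#' @export
predict.spls_fit <- function(object, newdata, ...) {
  stop_if_not(is.matrix(newdata) && ncol(newdata) == length(object$coefficients),
              "newdata must be a matrix with the training feature columns")
  object$intercept + as.vector(newdata %*% object$coefficients)
}

#' @export
print.spls_fit <- function(x, ...) {
  cat(sprintf("<spls_fit> K = %d (used %d), eta = %.3f, %d/%d features selected, training RMSE %.4f\n",
              x$K, x$K_used, x$eta, length(x$selected_features), x$p, x$training_rmse))
  invisible(x)
}

#' Tidy a sparse PLS fit
#'
#' @param x An `spls_fit`.
#' @param ... Unused.
#' @return Tibble of selected features with their coefficients.
#' @export
tidy.spls_fit <- function(x, ...) {
  sel <- x$selected_features
  tibble::tibble(
    term = sel,
    estimate = unname(x$coefficients[sel])
  ) |> dplyr::arrange(dplyr::desc(abs(.data$estimate)))
}

#' One-row summary of a sparse PLS fit
#'
#' @param x An `spls_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.spls_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, K = x$K, K_used = x$K_used, eta = x$eta,
    n_selected = length(x$selected_features),
    training_rmse = x$training_rmse
  )
}
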