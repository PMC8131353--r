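# Disease-progression transcript identification: ordinal stage encoding
# with learnable intermediate positions, leakage-free Spearman feature
# ranking, repeated stratified cross-validation of the sparse PLS model,
# and scatter-search optimization of the five hyperparameters
# (d_Diabetic, d_NPDR, n, eta, K).

#' Encode disease groups as numeric stage positions
#'
#' Healthy maps to 0 and NPDR_DME to 3; the intermediate positions of the
#' Diabetic and NPDR groups are free parameters in `[0.1, 2.9]` (no
#' ordering between them is imposed). PDR_DME samples are excluded from
#' the regression (mask `FALSE`).
#'
#' @param metadata Sample metadata with a `group` column.
#' @param d_diabetic,d_npdr Stage positions of the intermediate groups.
#' @return List: `y` (numeric target for included samples), `included`
#'   (logical mask over the metadata rows).
#' @export
encode_stages <- function(metadata, d_diabetic, d_npdr) {
  stop_if_not(d_diabetic >= 0.1 && d_diabetic <= 2.9, "d_diabetic out of [0.1, 2.9]")
  stop_if_not(d_npdr >= 0.1 && d_npdr <= 2.9, "d_npdr out of [0.1, 2.9]")
  map <- c(Healthy = 0, Diabetic = d_diabetic, NPDR = d_npdr, NPDR_DME = 3, PDR_DME = NA_real_)
  stop_if_not(all(metadata$group %in% names(map)), "unknown disease group label")
  y_all <- unname(map[metadata$group])
  included <- !is.na(y_all)
  list(y = y_all[included], included = included)
}

#' Rank features by absolute Spearman correlation with the target
#'
#' Features are sorted by decreasing `|rho|`; ties are broken
#' deterministically by feature name. Constant features get `rho = 0`.
#'
#' @param X Numeric matrix, samples x features (named columns).
#' @param y Numeric target (non-constant).
#' @return Tibble: feature, rho, ordered by rank.
#' @export
rank_features_spearman <- function(X, y) {
  stop_if_not(sd(y) > 0, "target must be non-constant")
  rho <- spearman_to_target(X, y)
  ord <- order(-abs(rho), colnames(X))
  tibble::tibble(feature = colnames(X)[ord], rho = rho[ord])
}

# Fast Spearman correlation of each column of X with y (ties broken by
# first occurrence; exact for tie-free columns). Constant columns get 0.
spearman_to_target <- function(X, y) {
  rho <- as.vector(cor(col_ranks(X), rank(y)))
  rho[col_sds(X) < 1e-12] <- 0
  rho
}

#' Cross-validation specification
#'
#' @param folds Number of folds (>= 2).
#' @param repeats Number of repeated fold assignments.
#' @param seed Seed controlling the fold assignments (fixed folds make the
#'   cross-validated error a deterministic function of the
#'   hyperparameters).
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(folds = 5, repeats = 20, seed = 1L) {
  stop_if_not(folds >= 2, "need >= 2 folds")
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed)),
            class = "cv_spec")
}

# Stratified fold assignment: every group is spread evenly over folds.
stratified_folds <- function(groups, k) {
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[idx] <- sample(rep_len(sample(k), length(idx)))
  }
  fold
}

#' Repeated cross-validated RMSE of the sparse PLS progression model
#'
#' For each repeat, samples included in the stage encoding are split into
#' stratified folds (every disease group represented in every training
#' fold). Feature ranking and model fitting use the training folds only:
#' features are ranked by |Spearman rho| with the training target, the top
#' `n` enter the sparse PLS fit, and held-out samples are predicted. The
#' per-repeat RMSE is pooled over folds and averaged over repeats.
#'
#' @param X Numeric matrix, samples x features, rows aligned to
#'   `metadata`.
#' @param metadata Sample metadata (`group` column used).
#' @param hyper List with `d_diabetic`, `d_npdr`, `n`, `eta`, `K`.
#' @param cvspec A [cv_spec()].
#' @return Mean RMSE over repeats.
#' @export
cv_rmse <- function(X, metadata, hyper, cvspec = cv_spec()) {
  enc <- encode_stages(metadata, hyper$d_diabetic, hyper$d_npdr)
  Xi <- X[enc$included, , drop = FALSE]
  y <- enc$y
  grp <- metadata$group[enc$included]
  n_top <- min(max(1L, round(hyper$n)), ncol(Xi))
  rmse_rep <- numeric(cvspec$repeats)
  for (r in seq_len(cvspec$repeats)) {
    set.seed(cvspec$seed + r)
    fold <- stratified_folds(grp, cvspec$folds)
    bump <- 0L
    while (any(vapply(seq_len(cvspec$folds), function(f) {
      length(unique(y[fold != f])) < 2
    }, TRUE)) && bump < 100) {
      bump <- bump + 1L
      set.seed(cvspec$seed + r + 1000L * bump)
      fold <- stratified_folds(grp, cvspec$folds)
    }
    sq_err <- numeric(0)
    for (f in seq_len(cvspec$folds)) {
      tr <- fold != f
      if (sum(!tr) == 0) next
      if (length(unique(y[tr])) < 2) {
        # degenerate training target: fall back to the mean predictor
        sq_err <- c(sq_err, (mean(y[tr]) - y[!tr])^2)
        next
      }
      rho <- spearman_to_target(Xi[tr, , drop = FALSE], y[tr])
      top <- order(-abs(rho), colnames(Xi))[seq_len(n_top)]
      fit <- fit_spls(Xi[tr, top, drop = FALSE], y[tr],
                      eta = hyper$eta, K = round(hyper$K), warn_rank = FALSE)
      pred <- predict(fit, Xi[!tr, top, drop = FALSE])
      sq_err <- c(sq_err, (pred - y[!tr])^2)
    }
    rmse_rep[r] <- sqrt(mean(sq_err))
  }
  mean(rmse_rep)
}

#' Identify disease-progression transcripts
#'
#' Minimizes the repeated cross-validated RMSE of the stage-encoded sparse
#' PLS model over the five hyperparameters (intermediate stage positions
#' `d_Diabetic` and `d_NPDR`, number of top-ranked features `n`, sparsity
#' `eta`, components `K`) by scatter search, then refits the model on all
#' included samples at the optimum. The selected features of the refit are
#' the disease-progression (DP) transcripts.
#'
#' @param norm Normalized (and typically residualized) expression matrix,
#'   transcripts x samples.
#' @param metadata Sample metadata.
#' @param site Sample site to analyse, or `NULL` for all samples.
#' @param cvspec A [cv_spec()]; the full-scale setting is 5 folds x 20
#'   repeats, the desk-scale default here is 5 x 5.
#' @param optconfig A [scatter_search_config()]; the full-scale budget is
#'   1,000 evaluations, the desk-scale default 300.
#' @param n_min Minimum number of ranked features (default 50, capped at
#'   the number available).
#' @param eta_range,K_range,d_range Hyperparameter bounds.
#' @return A `dp_result`: site, `dp_transcripts`, best hyperparameters,
#'   best CV RMSE, the improvement trace (evaluation, rmse, d_diabetic,
#'   d_npdr, n, eta, K) and the refit `spls_fit`.
#' @export
find_dp_transcripts <- function(norm, metadata, site = NULL,
                                cvspec = cv_spec(folds = 5, repeats = 5),
                                optconfig = scatter_search_config(max_evaluations = 300),
                                n_min = 50,
                                eta_range = c(0.1, 0.9),
                                K_range = c(1, 12),
                                d_range = c(0.1, 2.9)) {
  meta <- if (is.null(site)) metadata else metadata[metadata$site == site, ]
  stop_if_not(nrow(meta) > 0, "no samples for the requested site")
  X <- t(norm[, meta$sample_id, drop = FALSE])
  p <- ncol(X)
  n_min <- min(n_min, p)

  objective <- function(theta) {
    cv_rmse(X, meta, list(
      d_diabetic = theta[1], d_npdr = theta[2],
      n = theta[3], eta = theta[4], K = theta[5]
    ), cvspec)
  }
  opt <- scatter_search(
    objective,
    lower = c(d_range[1], d_range[1], n_min, eta_range[1], K_range[1]),
    upper = c(d_range[2], d_range[2], p, eta_range[2], K_range[2]),
    integer = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    config = optconfig
  )

  best <- list(d_diabetic = opt$par[1], d_npdr = opt$par[2],
               n = as.integer(opt$par[3]), eta = opt$par[4], K = as.integer(opt$par[5]))
  enc <- encode_stages(meta, best$d_diabetic, best$d_npdr)
  Xi <- X[enc$included, , drop = FALSE]
  rho <- spearman_to_target(Xi, enc$y)
  top <- order(-abs(rho), colnames(Xi))[seq_len(min(best$n, p))]
  model <- fit_spls(Xi[, top, drop = FALSE], enc$y, eta = best$eta, K = best$K)

  trace <- opt$trace
  if (nrow(trace) > 0) {
    names(trace) <- c("evaluation", "rmse", "d_diabetic", "d_npdr", "n", "eta", "K")
  }
  structure(list(
    site = if (is.null(site)) "all" else site,
    dp_transcripts = model$selected_features,
    best = best,
    cv_rmse = opt$value,
    n_evals = opt$n_evals,
    trace = trace,
    model = model
  ), class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf("<dp_result> site %s: %d DP transcripts (CV RMSE %.4f; d_Diabetic %.2f, d_NPDR %.2f, n %d, eta %.2f, K %d)\n",
              x$site, length(x$dp_transcripts), x$cv_rmse,
              x$best$d_diabetic, x$best$d_npdr, x$best$n, x$best$eta, x$best$K))
  invisible(x)
}

#' @export
tidy.dp_result <- function(x, ...) {
  tidy(x$model)
}

#' @export
glance.dp_result <- function(x, ...) {
  tibble::tibble(
    site = x$site, n_dp = length(x$dp_transcripts),
    cv_rmse = x$cv_rmse, n_evals = x$n_evals,
    d_diabetic = x$best$d_diabetic, d_npdr = x$best$d_npdr,
    n = x$best$n, eta = x$best$eta, K = x$best$K
  )
}

#' Combine progression sets from the two sample sites
#'
#' Union and intersection by inclusion-exclusion, with the overlap tested
#' for enrichment against the expressed background by the upper-tail
#' hypergeometric test (fold enrichment `k / (K * n / N)`).
#'
#' @param dp_a,dp_b Character vectors of transcript ids (or `dp_result`
#'   objects).
#' @param background_size Size of the expressed-transcript background.
#' @return One-row tibble: n_a, n_b, n_intersect, n_union,
#'   fold_enrichment, p.
#' @export
combine_dp_sets <- function(dp_a, dp_b, background_size) {
  if (inherits(dp_a, "dp_result")) dp_a <- dp_a$dp_transcripts
  if (inherits(dp_b, "dp_result")) dp_b <- dp_b$dp_transcripts
  stop_if_not(length(dp_a) <= background_size && length(dp_b) <= background_size,
              "sets cannot exceed the background")
  k <- length(intersect(dp_a, dp_b))
  K <- length(unique(dp_a)); n <- length(unique(dp_b)); N <- background_size
  tibble::tibble(
    n_a = K, n_b = n, n_intersect = k, n_union = K + n - k,
    fold_enrichment = fold_enrichment(k, K, n, N),
    p = hypergeom_test(k, K, n, N)
  )
}
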