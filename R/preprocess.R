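# Normalization, expression filtering, technical-replicate removal,
# surrogate-variable estimation and residuals-plus-intercept confounder
# correction.

#' Log2 counts-per-million normalization
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, the standard offset form.
#' Library sizes default to column sums of `counts` but can be supplied
#' explicitly (e.g. when normalizing a filtered submatrix with the
#' original library sizes).
#'
#' @param counts Non-negative integer matrix, transcripts x samples.
#' @param lib_sizes Optional per-sample library sizes.
#' @return Numeric matrix of log2 CPM values with attribute
#'   `library_sizes`.
#' @export
log2_cpm <- function(counts, lib_sizes = NULL) {
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  zero <- lib_sizes == 0
  if (any(zero)) {
    stop("all-zero library for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  out <- log2(sweep(counts + 0.5, 2, lib_sizes + 1, "/") * 1e6)
  attr(out, "library_sizes") <- setNames(lib_sizes, colnames(counts))
  out
}

#' Two-stage expressed-mRNA filter
#'
#' Stage 1 mirrors the documented default logic of count-based expression
#' filters: keep transcripts with CPM at or above `cpm_min` in at least
#' `min_group_size` samples, where `cpm_min = 10 / (median libsize / 1e6)`
#' and `min_group_size` is the smallest disease-group size. Stage 2 fits a
#' two-component Gaussian mixture to the mean log2 CPM of stage-1
#' survivors and keeps transcripts assigned (posterior >= 0.5) to the
#' higher-mean component; if the mixture fit fails the stage-1 set is
#' returned with a warning.
#'
#' @param counts Integer matrix, transcripts x samples.
#' @param metadata Tibble with `sample_id` and `group` columns matching
#'   the count columns.
#' @param cpm_min,min_group_size Stage-1 parameters; computed from the
#'   data when `NULL`.
#' @param gmm Apply the stage-2 mixture filter (default `TRUE`).
#' @return List with `kept` (character vector of transcript ids) and
#'   `report` (tibble: stage, n_kept).
#' @export
filter_mrna <- function(counts, metadata, cpm_min = NULL, min_group_size = NULL, gmm = TRUE) {
  stop_if_not(length(unique(metadata$group)) >= 2, "need >= 2 disease groups")
  lib <- colSums(counts)
  if (is.null(cpm_min)) cpm_min <- 10 / (median(lib) / 1e6)
  if (is.null(min_group_size)) min_group_size <- min(table(metadata$group))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep1 <- rowSums(cpm >= cpm_min) >= min_group_size
  kept <- rownames(counts)[keep1]
  report <- tibble::tibble(stage = c("input", "min_count"),
                           n_kept = c(nrow(counts), length(kept)))
  if (gmm && length(kept) > 2) {
    mean_l2 <- rowMeans(log2_cpm(counts, lib)[kept, , drop = FALSE])
    fit <- tryCatch(
      Mclust(mean_l2, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning("Gaussian mixture fit failed; keeping stage-1 filter result")
    } else {
      hi <- which.max(fit$parameters$mean)
      kept <- kept[fit$z[, hi] >= 0.5]
    }
    report <- dplyr::bind_rows(report, tibble::tibble(stage = "gaussian_mixture",
                                                      n_kept = length(kept)))
  }
  list(kept = kept, report = report)
}

#' Expressed-miRNA filter
#'
#' Keeps miRNA whose expression exceeds `cpm_threshold` CPM (i.e. log2 CPM
#' above `log2(cpm_threshold)`) in at least one sample. Activity
#' thresholds of this kind are sometimes quoted on the log2 CPM scale,
#' where a value of 100 is unreachable; the threshold is therefore
#' interpreted on the CPM scale and kept configurable.
#'
#' @param norm Log2 CPM matrix from [log2_cpm()].
#' @param cpm_threshold CPM cutoff (default 100).
#' @return Character vector of kept miRNA ids.
#' @export
filter_mirna <- function(norm, cpm_threshold = 100) {
  rownames(norm)[rowSums(norm > log2(cpm_threshold)) >= 1]
}

#' Detect technical replicate samples to remove
#'
#' Among sample pairs from the same donor and site but different eyes,
#' flags members of pairs whose Pearson correlation of normalized
#' expression exceeds `r_threshold`. Within each connected group of
#' correlated replicates the sample with the largest library size is kept
#' and the rest are flagged. Samples from different donors are never
#' compared.
#'
#' @param norm Log2 CPM matrix (attribute `library_sizes` used when
#'   present; column sums of `2^norm` otherwise).
#' @param metadata Tibble with `sample_id`, `donor_id`, `site`, `eye`.
#' @param r_threshold Pearson correlation threshold (default 0.98).
#' @return Character vector of sample ids to remove (possibly empty).
#' @export
detect_replicates <- function(norm, metadata, r_threshold = 0.98) {
  lib <- attr(norm, "library_sizes")
  if (is.null(lib)) lib <- setNames(colSums(2^norm), colnames(norm))
  cand <- metadata |>
    dplyr::group_by(.data$donor_id, .data$site) |>
    dplyr::filter(dplyr::n() > 1, length(unique(.data$eye)) > 1) |>
    dplyr::ungroup()
  if (nrow(cand) == 0) return(character(0))
  remove <- character(0)
  for (key in unique(paste(cand$donor_id, cand$site))) {
    ids <- cand$sample_id[paste(cand$donor_id, cand$site) == key]
    pairs <- utils::combn(ids, 2)
    linked <- ids[FALSE]
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      if (metadata$eye[metadata$sample_id == a] == metadata$eye[metadata$sample_id == b]) next
      if (cor(norm[, a], norm[, b]) > r_threshold) linked <- union(linked, c(a, b))
    }
    if (length(linked) > 1) {
      keep <- linked[which.max(lib[linked])]
      remove <- c(remove, setdiff(linked, keep))
    }
  }
  remove
}

#' Estimate a surrogate variable for unmodeled technical variation
#'
#' Regresses each transcript on the protected covariates (disease group
#' and sample site by default) and takes the leading right singular vector
#' of the residual matrix as the surrogate variable: a unit-norm,
#' per-sample loading vector capturing the dominant unmodeled structure.
#'
#' @param norm Log2 CPM matrix, transcripts x samples.
#' @param metadata Sample metadata; columns named in `protected` must be
#'   present.
#' @param protected Covariates whose effects are removed before the SVD.
#' @param n_sv Number of surrogate variables (default 1).
#' @return A `surrogate_variable` list: `loadings` (samples x n_sv matrix,
#'   unit-norm columns), `variance_explained`, `method`.
#' @export
estimate_surrogate_variable <- function(norm, metadata, protected = c("group", "site"),
                                        n_sv = 1) {
  stop_if_not(ncol(norm) >= 5, "need at least 5 samples")
  protected <- intersect(protected, names(metadata))
  form <- stats::as.formula(paste("~", paste(protected, collapse = " + ")))
  X <- stats::model.matrix(form, data = metadata)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient protected design", call. = FALSE)
  H <- X %*% solve(crossprod(X), t(X))
  R <- norm - norm %*% H                      # per-transcript residuals
  sv <- svd(R, nu = 0, nv = n_sv)
  load <- sv$v[, seq_len(n_sv), drop = FALSE]
  for (j in seq_len(n_sv)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(norm)
  colnames(load) <- paste0("SV", seq_len(n_sv))
  structure(list(
    loadings = load,
    variance_explained = sv$d[seq_len(n_sv)]^2 / sum(sv$d^2),
    method = "residual-svd"
  ), class = "surrogate_variable")
}

#' Residuals-plus-intercept covariate correction
#'
#' Per transcript, fits the joint linear model
#' `expression ~ covariates` and, whenever any covariate coefficient has a
#' t-test p-value below `alpha`, replaces the transcript's values by the
#' model residuals plus the model intercept. Transcripts with no
#' significant covariate are left untouched. Applying the correction a
#' second time changes nothing (the corrected transcripts no longer show
#' significant covariate effects).
#'
#' @param norm Log2 CPM matrix, transcripts x samples.
#' @param covariates Data frame of numeric per-sample covariates (e.g.
#'   age and the surrogate-variable loadings). Constant covariates are
#'   dropped with a warning.
#' @param alpha Significance threshold for the per-covariate t-test.
#' @return Corrected matrix with attribute `corrected` listing the
#'   replaced transcript ids (the `library_sizes` attribute is carried
#'   over).
#' @export
residualize <- function(norm, covariates, alpha = 0.05) {
  covariates <- as.data.frame(covariates)
  stop_if_not(all(vapply(covariates, is.numeric, TRUE)), "covariates must be numeric")
  stop_if_not(!anyNA(covariates), "covariates must be complete")
  const <- vapply(covariates, function(x) var(x) == 0, TRUE)
  if (any(const)) {
    warning("dropping constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[!const]
  }
  if (ncol(covariates) == 0) return(norm)
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  XtXi <- solve(crossprod(X))
  B <- norm %*% X %*% XtXi                    # transcripts x coefficients
  fitted <- B %*% t(X)
  resid <- norm - fitted
  n <- ncol(norm); p <- ncol(X)
  sigma2 <- rowSums(resid^2) / (n - p)
  se <- sqrt(outer(sigma2, diag(XtXi)))
  tt <- B / se
  pv <- 2 * pt(abs(tt), df = n - p, lower.tail = FALSE)
  pv[!is.finite(pv)] <- 1
  hit <- rowSums(pv[, -1, drop = FALSE] < alpha, na.rm = TRUE) > 0
  out <- norm
  out[hit, ] <- resid[hit, , drop = FALSE] + B[hit, 1]
  attr(out, "library_sizes") <- attr(norm, "library_sizes")
  attr(out, "corrected") <- rownames(norm)[hit]
  out
}

#' PCA of the most variable features
#'
#' Selects the `n_features` highest-variance transcripts, centers, and
#' returns sample scores plus the cumulative variance fraction of the
#' first two principal components.
#'
#' @param norm Log2 CPM matrix, transcripts x samples.
#' @param n_features Number of top-variance features (default 100); capped
#'   at the number available with a warning.
#' @param n_pc Number of score columns returned.
#' @return List: `scores` (tibble sample_id, PC1..), `cum_r2` (cumulative
#'   variance fraction of 2 PCs), `sdev`.
#' @export
pca_top_variable <- function(norm, n_features = 100, n_pc = 2) {
  stop_if_not(ncol(norm) >= 2, "need at least 2 samples")
  if (n_features > nrow(norm)) {
    warning("n_features exceeds available transcripts; using all")
    n_features <- nrow(norm)
  }
  v <- apply(norm, 1, var)
  top <- order(v, decreasing = TRUE)[seq_len(n_features)]
  pc <- prcomp(t(norm[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(n_pc), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(norm)), scores)
  list(
    scores = scores,
    cum_r2 = sum(pc$sdev[seq_len(min(2, length(pc$sdev)))]^2) / sum(pc$sdev^2),
    sdev = pc$sdev
  )
}
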