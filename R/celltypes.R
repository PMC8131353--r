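# Single-cell integration: unique marker identification (one-vs-rest
# rank-sum), marker over-representation of disease genes, MuSiC-style
# weighted iterative NNLS deconvolution of bulk samples, and cell-type
# specific pathway over-representation.

#' Log-normalize single-cell counts
#'
#' `log2(1 + count / libsize * 1e4)`, the usual per-10k log normalization.
#'
#' @param counts Genes x cells count matrix.
#' @return Normalized matrix.
#' @export
sc_lognormalize <- function(counts) {
  lib <- colSums(counts)
  stop_if_not(all(lib > 0), "cells with zero counts present")
  log2(1 + sweep(counts, 2, lib, "/") * 1e4)
}

# Vectorized one-vs-rest rank-sum test (normal approximation with tie
# correction and continuity correction, upregulated side). Matches
# wilcox.test(exact = FALSE) on individual genes.
rank_sum_greater <- function(R, tie_term, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  U <- rowSums(R[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
  z <- (U - mu - 0.5) / pmax(sigma, 1e-12)
  pnorm(z, lower.tail = FALSE)
}

#' Identify unique cell-type marker genes
#'
#' Per cell type, a one-vs-rest Wilcoxon rank-sum test on log-normalized
#' expression (upregulated side only), Bonferroni-corrected over the full
#' genes x types family. Genes significant for more than one type are
#' dropped (uniqueness filter); types with fewer than `min_cells` cells
#' are skipped with a warning. Genes can be restricted to the bulk
#' universe so markers are comparable with the bulk analysis.
#'
#' @param sc_ref List with `counts` (genes x cells) and `cells` (tibble
#'   with `cell_id`, `type`).
#' @param bulk_gene_universe Optional character vector restricting the
#'   genes tested.
#' @param alpha Bonferroni-corrected significance threshold (default
#'   0.01).
#' @param min_cells Minimum cells per type (default 3).
#' @return Tibble: gene, celltype, effect (mean log2 difference one vs
#'   rest), p, p_bonferroni; at most one row per gene.
#' @export
find_markers <- function(sc_ref, bulk_gene_universe = NULL, alpha = 0.01, min_cells = 3) {
  cells <- sc_ref$cells
  counts <- sc_ref$counts
  if (!is.null(bulk_gene_universe)) {
    counts <- counts[intersect(rownames(counts), bulk_gene_universe), , drop = FALSE]
  }
  types <- unique(cells$type)
  stop_if_not(length(types) >= 2, "need >= 2 cell types")
  small <- types[vapply(types, function(t) sum(cells$type == t) < min_cells, TRUE)]
  if (length(small) > 0) {
    warning("skipping type(s) with < ", min_cells, " cells: ", paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  M <- sc_lognormalize(counts)
  R <- t(apply(M, 1, rank))
  tie_term <- apply(M, 1, function(x) {
    r <- rle(sort(x))$lengths
    sum(r^3 - r)
  })
  n_tests <- nrow(M) * length(types)
  res <- purrr::map_dfr(types, function(t) {
    in_g <- cells$type == t
    p <- rank_sum_greater(R, tie_term, in_g)
    tibble::tibble(
      gene = rownames(M), celltype = t,
      effect = rowMeans(M[, in_g, drop = FALSE]) - rowMeans(M[, !in_g, drop = FALSE]),
      p = p,
      p_bonferroni = pmin(p * n_tests, 1)
    )
  })
  sig <- res[res$p_bonferroni < alpha, ]
  dup <- unique(sig$gene[duplicated(sig$gene)])
  sig <- sig[!sig$gene %in% dup, ]
  dplyr::arrange(sig, .data$celltype, .data$p_bonferroni)
}

#' Downsample the single-cell reference per cell type
#'
#' Uniform sampling without replacement down to at most `cap` cells per
#' type; types at or below the cap are untouched. Deterministic given the
#' seed.
#'
#' @param sc_ref List with `counts` and `cells`.
#' @param cap Maximum cells per type (default 500).
#' @param seed Integer seed.
#' @return A downsampled `sc_ref` list.
#' @export
downsample_cells <- function(sc_ref, cap = 500, seed = 1L) {
  stop_if_not(cap >= 1, "cap must be >= 1")
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(sc_ref$cells)), sc_ref$cells$type), function(idx) {
    if (length(idx) <= cap) idx else sort(sample(idx, cap))
  }))
  keep <- sort(unname(keep))
  list(counts = sc_ref$counts[, keep, drop = FALSE], cells = sc_ref$cells[keep, ])
}

#' Over-representation of disease genes in cell-type markers
#'
#' Hypergeometric test per cell type of the disease gene set against that
#' type's marker genes, over the shared bulk/single-cell background; BH
#' across cell types.
#'
#' @param disease_genes Character vector of disease-associated gene ids.
#' @param marker_table Tibble from [find_markers()].
#' @param background Character vector (bulk-and-single-cell expressed
#'   genes).
#' @return Tibble: celltype, k, K, n, N, fold_enrichment, p, q.
#' @export
marker_ora <- function(disease_genes, marker_table, background) {
  background <- unique(background)
  q_set <- intersect(unique(disease_genes), background)
  types <- unique(marker_table$celltype)
  res <- purrr::map_dfr(types, function(t) {
    mk <- intersect(marker_table$gene[marker_table$celltype == t], background)
    tibble::tibble(
      celltype = t,
      k = length(intersect(mk, q_set)), K = length(mk),
      n = length(q_set), N = length(background)
    )
  })
  res$fold_enrichment <- unname(mapply(fold_enrichment, res$k, res$K, res$n, res$N))
  res$p <- unname(mapply(hypergeom_test, res$k, res$K, res$n, res$N))
  res$q <- bh_adjust(res$p)
  dplyr::arrange(res, .data$p)
}

# Per-type signature profiles on the relative (per-10k) scale, plus the
# cross-subject variance of the subject-level signatures.
build_signatures <- function(sc_ref) {
  counts <- sc_ref$counts
  cells <- sc_ref$cells
  rel <- sweep(counts, 2, colSums(counts), "/") * 1e4
  types <- sort(unique(cells$type))
  subjects <- unique(cells$subject %||% "subj1")
  sig <- matrix(0, nrow(counts), length(types), dimnames = list(rownames(counts), types))
  v <- matrix(0, nrow(counts), length(types), dimnames = list(rownames(counts), types))
  for (ti in seq_along(types)) {
    subj_means <- vapply(subjects, function(s) {
      sel <- cells$type == types[ti] & (cells$subject %||% "subj1") == s
      if (sum(sel) == 0) return(rep(NA_real_, nrow(counts)))
      rowMeans(rel[, sel, drop = FALSE])
    }, numeric(nrow(counts)))
    subj_means <- matrix(subj_means, nrow = nrow(counts))
    sig[, ti] <- rowMeans(subj_means, na.rm = TRUE)
    v[, ti] <- if (ncol(subj_means) > 1) apply(subj_means, 1, var) else 0
  }
  v[is.na(v)] <- 0
  list(signatures = sig, subject_var = rowMeans(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate cell-type proportions in bulk samples
#'
#' Weighted iterative non-negative least squares of each bulk expression
#' profile on cell-type signature profiles derived from the single-cell
#' reference. Per-gene weights
#' `1 / (nu + c * mu^2 + subject_variance + residual^2)` shrink genes with
#' high cross-subject variance or poor fit, and model the multiplicative
#' noise of expression data through the relative-noise term `c * mu^2`
#' (`mu` is the mean signature level; `c` is self-calibrated per sample as
#' the median squared relative residual of an unweighted first fit). The
#' reweighted NNLS step is a majorize-minimize iteration for the robust
#' objective `sum(log(nu + c * mu^2 + subject_variance + residual^2))`, so
#' that objective is non-increasing across iterations (recorded in
#' `residual_trace`); iteration stops at `tol` relative improvement or
#' `max_iter`. Proportions are normalized to sum to 1 and are invariant
#' to global scaling of the bulk profile.
#'
#' @param bulk Bulk expression matrix, genes x samples; log2 CPM by
#'   default (`bulk_scale = "log2cpm"`), or linear (`"linear"`).
#' @param sc_ref Single-cell reference list (`counts`, `cells` with
#'   `type` and optionally `subject`).
#' @param bulk_scale Scale of `bulk`.
#' @param nu Weight regularizer (default 1e-4 on the per-10k scale).
#' @param tol Relative residual-change convergence tolerance.
#' @param max_iter Maximum reweighting iterations (default 50).
#' @return A `deconv_result`: `proportions` (samples x types matrix),
#'   `residual_norm` (final unweighted residual norm per sample),
#'   `residual_trace` (per-sample robust-objective values across
#'   reweighting iterations; non-increasing), `signatures`.
#' @export
deconvolve <- function(bulk, sc_ref, bulk_scale = c("log2cpm", "linear"),
                       nu = 1e-4, tol = 1e-6, max_iter = 50) {
  bulk_scale <- match.arg(bulk_scale)
  B <- if (bulk_scale == "log2cpm") 2^bulk else bulk
  sgn <- build_signatures(sc_ref)
  shared <- intersect(rownames(B), rownames(sgn$signatures))
  stop_if_not(length(shared) >= 1, "no shared genes between bulk and reference")
  S <- sgn$signatures[shared, , drop = FALSE]
  S <- sweep(S, 2, colSums(S), "/") * 1e4
  vsub <- sgn$subject_var[shared]

  n_types <- ncol(S)
  props <- matrix(0, ncol(B), n_types, dimnames = list(colnames(B), colnames(S)))
  resnorm <- numeric(ncol(B))
  traces <- vector("list", ncol(B))
  for (s in seq_len(ncol(B))) {
    b <- B[shared, s]
    stop_if_not(sum(b) > 0, paste0("all-zero bulk sample: ", colnames(B)[s]))
    b <- b / sum(b) * 1e4
    mu <- rowMeans(S)
    theta <- pracma::lsqnonneg(S, b)$x       # unweighted pilot fit
    r <- as.vector(b - S %*% theta)
    cc <- median(r^2 / pmax(mu^2, 1e-12))    # relative-noise calibration
    base <- nu + cc * mu^2 + vsub
    robust_loss <- function(theta) {
      sum(log(base + as.vector(b - S %*% theta)^2))
    }
    loss <- robust_loss(theta)
    res_trace <- loss
    for (it in seq_len(max_iter)) {
      r <- as.vector(b - S %*% theta)
      w <- 1 / (base + r^2)
      theta_new <- pracma::lsqnonneg(sqrt(w) * S, sqrt(w) * b)$x
      loss_new <- robust_loss(theta_new)     # MM step: never increases
      theta <- theta_new
      res_trace <- c(res_trace, loss_new)
      if (loss - loss_new < tol * max(abs(loss), 1e-12)) break
      loss <- loss_new
    }
    stop_if_not(sum(theta) > 0, paste0("deconvolution degenerate for sample ", colnames(B)[s]))
    props[s, ] <- theta / sum(theta)
    resnorm[s] <- sqrt(sum((b - S %*% theta)^2))
    traces[[s]] <- res_trace
  }
  structure(list(
    proportions = props,
    residual_norm = setNames(resnorm, colnames(B)),
    residual_trace = setNames(traces, colnames(B)),
    signatures = S
  ), class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d samples x %d cell types; mean residual norm %.4g\n",
              nrow(x$proportions), ncol(x$proportions), mean(x$residual_norm)))
  invisible(x)
}

#' Tidy cell-type proportion estimates
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return Long tibble: sample_id, celltype, proportion.
#' @export
tidy.deconv_result <- function(x, ...) {
  tibble::as_tibble(x$proportions, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "celltype", values_to = "proportion")
}

#' Pathway over-representation of cell-type specific disease genes
#'
#' For each cell type, the intersection of the disease genes with that
#' type's markers is tested against the gene-set collection by [ora()]
#' (min-overlap and category exclusion rules apply); the BH family is the
#' sets tested within the cell type.
#'
#' @param disease_genes Character vector of disease-associated gene ids.
#' @param marker_table Tibble from [find_markers()].
#' @param collection A `gene_set_collection`.
#' @param background Character vector of background gene ids.
#' @param alpha Significance threshold on q (default 0.01).
#' @param ... Passed to [ora()].
#' @return Tibble: celltype + [ora()] columns + `significant`.
#' @export
celltype_pathway_ora <- function(disease_genes, marker_table, collection,
                                 background, alpha = 0.01, ...) {
  types <- unique(marker_table$celltype)
  purrr::map_dfr(types, function(t) {
    q_set <- intersect(intersect(disease_genes, marker_table$gene[marker_table$celltype == t]),
                       background)
    if (length(q_set) == 0) return(NULL)
    res <- ora(q_set, collection, background, ...)
    dplyr::bind_cols(tibble::tibble(celltype = t), res) |>
      dplyr::mutate(significant = .data$q < alpha)
  })
}
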