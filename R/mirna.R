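# miRNA-centric integration: miRNA representation in disease-associated
# transcripts, target over-representation, Spearman correlation-skew
# testing against a sampled non-target background, and the triple
# evidence filter.

#' Enrichment of miRNA among disease-associated transcripts
#'
#' Hypergeometric test of the miRNA count in a disease-associated
#' transcript set against the expressed-transcript universe;
#' fold-enrichment is the ratio of observed to expected miRNA.
#'
#' @param disease_set Character vector of transcript ids (subset of the
#'   universe).
#' @param universe Tibble with columns `id` and `kind` (`"mRNA"` or
#'   `"miRNA"`) describing every expressed transcript.
#' @return One-row tibble: k, K, n, N, fold_enrichment, p.
#' @export
mirna_fraction_enrichment <- function(disease_set, universe) {
  stop_if_not(all(disease_set %in% universe$id), "disease_set must be a subset of the universe")
  disease_set <- unique(disease_set)
  mir <- universe$id[universe$kind == "miRNA"]
  k <- length(intersect(disease_set, mir))
  K <- length(mir)
  n <- length(disease_set)
  N <- nrow(universe)
  tibble::tibble(
    k = k, K = K, n = n, N = N,
    fold_enrichment = fold_enrichment(k, K, n, N),
    p = hypergeom_test(k, K, n, N)
  )
}

#' Over-representation of miRNA targets in disease gene sets
#'
#' For every miRNA with at least `min_targets` targets among the expressed
#' mRNA, tests the overlap of its target set with each disease-associated
#' mRNA set by the upper-tail hypergeometric test over the expressed-mRNA
#' background. BH adjustment is applied across the tested miRNA within
#' each disease set.
#'
#' @param target_map Tibble with columns `mirna`, `target`.
#' @param disease_sets Named list of disease-associated mRNA id vectors.
#' @param background Character vector of expressed mRNA ids.
#' @param min_targets Minimum expressed-target count (default 10).
#' @return Tibble: set, mirna, k, K, n, N, fold_enrichment, p, q.
#' @export
target_ora <- function(target_map, disease_sets, background, min_targets = 10) {
  background <- unique(background)
  map <- target_map[target_map$target %in% background, c("mirna", "target")]
  map <- dplyr::distinct(map)
  targets <- split(map$target, map$mirna)
  targets <- targets[lengths(targets) >= min_targets]
  N <- length(background)
  purrr::imap_dfr(disease_sets, function(dset, set_name) {
    dset <- intersect(unique(dset), background)
    res <- tibble::tibble(
      set = set_name,
      mirna = names(targets),
      k = unname(vapply(targets, function(tg) length(intersect(tg, dset)), 0L)),
      K = unname(lengths(targets)),
      n = length(dset),
      N = N
    )
    res$fold_enrichment <- unname(mapply(fold_enrichment, res$k, res$K, res$n, res$N))
    res$p <- unname(mapply(hypergeom_test, res$k, res$K, res$n, res$N))
    res$q <- bh_adjust(res$p)
    res
  })
}

# Spearman correlation of every (miRNA, mRNA) pair across the given
# samples: Pearson correlation of row ranks, computed as one matrix
# product. Rows with zero variance are dropped with a warning.
all_pair_spearman <- function(mirna_norm, mrna_norm) {
  row_rank_std <- function(M) {
    keep <- apply(M, 1, sd) > 0
    if (any(!keep)) {
      warning(sum(!keep), " constant transcript(s) excluded from correlation analysis")
      M <- M[keep, , drop = FALSE]
    }
    R <- t(col_ranks(t(M)))
    R <- R - rowMeans(R)
    R / sqrt(rowSums(R^2))
  }
  A <- row_rank_std(mirna_norm)
  B <- row_rank_std(mrna_norm)
  tcrossprod(A, B)                            # miRNA x mRNA correlations
}

#' Negative correlation skew of miRNA targets
#'
#' For each miRNA with at least `min_targets` expressed targets, compares
#' the distribution of Spearman correlations between the miRNA and its
#' targets (across the samples of one site) against a background of
#' `n_background` correlations of uniformly sampled non-interacting
#' (miRNA, mRNA) pairs, using a one-sided two-sample Kolmogorov-Smirnov
#' test with the alternative that target correlations are stochastically
#' smaller. BH adjustment across tested miRNA.
#'
#' @param mirna_norm,mrna_norm Normalized expression matrices
#'   (transcripts x samples) of expressed miRNA and mRNA.
#' @param target_map Tibble with columns `mirna`, `target`.
#' @param metadata Sample metadata; needed when `site` is given.
#' @param site Restrict to one sample site (`NULL` uses all columns).
#' @param n_background Background sample size (default 100,000, drawn with
#'   replacement, known interacting pairs excluded).
#' @param min_targets Minimum expressed-target count (default 10).
#' @param seed Seed for the background sampling.
#' @return Tibble: mirna, site, n_targets, ks_d, p, q.
#' @export
correlation_skew <- function(mirna_norm, mrna_norm, target_map, metadata = NULL,
                             site = NULL, n_background = 100000, min_targets = 10,
                             seed = 1L) {
  if (!is.null(site)) {
    stop_if_not(!is.null(metadata), "metadata required when site is given")
    ids <- metadata$sample_id[metadata$site == site]
    mirna_norm <- mirna_norm[, intersect(colnames(mirna_norm), ids), drop = FALSE]
    mrna_norm <- mrna_norm[, intersect(colnames(mrna_norm), ids), drop = FALSE]
  }
  stop_if_not(ncol(mirna_norm) >= 5, "need >= 5 samples")
  C <- all_pair_spearman(mirna_norm, mrna_norm)
  mirnas <- rownames(C); mrnas <- colnames(C)

  known <- matrix(FALSE, nrow(C), ncol(C), dimnames = dimnames(C))
  tm <- target_map[target_map$mirna %in% mirnas & target_map$target %in% mrnas, ]
  known[cbind(match(tm$mirna, mirnas), match(tm$target, mrnas))] <- TRUE

  set.seed(seed)
  bg <- numeric(0)
  while (length(bg) < n_background) {
    need <- n_background - length(bg)
    i <- sample.int(nrow(C), ceiling(need * 1.1), replace = TRUE)
    j <- sample.int(ncol(C), ceiling(need * 1.1), replace = TRUE)
    ok <- !known[cbind(i, j)]
    bg <- c(bg, C[cbind(i, j)][ok])
  }
  bg <- bg[seq_len(n_background)]

  targets <- split(tm$target, tm$mirna)
  targets <- targets[lengths(targets) >= min_targets]
  out <- purrr::imap_dfr(targets, function(tg, m) {
    x <- C[m, tg]
    ks <- suppressWarnings(ks.test(x, bg, alternative = "greater"))
    tibble::tibble(mirna = m, site = if (is.null(site)) "all" else site,
                   n_targets = length(tg),
                   ks_d = unname(ks$statistic), p = ks$p.value)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(mirna = character(0), site = character(0),
                          n_targets = integer(0), ks_d = numeric(0),
                          p = numeric(0), q = numeric(0)))
  }
  out$q <- bh_adjust(out$p)
  out
}

#' Integrate miRNA evidence into a final call
#'
#' A miRNA is called disease-relevant when it (a) is itself
#' disease-associated (differentially expressed at BH q below `alpha` in
#' some contrast/site, or in a progression set), (b) shows significant
#' target over-representation in some disease gene set, and (c) shows a
#' significant negative correlation skew with its targets in some site.
#'
#' @param de_results Tibble from [fit_de()] (any number of sites bound
#'   together); only rows whose `transcript_id` is a miRNA matter.
#' @param dp_sets Named list (site -> transcript id vector) of progression
#'   sets, or `dp_result` objects.
#' @param target_ora_results Tibble from [target_ora()].
#' @param skew_results Tibble from [correlation_skew()] (sites bound
#'   together).
#' @param mirna_ids miRNA universe to report on.
#' @param alpha Significance threshold on BH q (default 0.05).
#' @return Tibble: mirna, de, dp, target_enriched, negative_skew,
#'   final_call.
#' @export
integrate_evidence <- function(de_results, dp_sets, target_ora_results,
                               skew_results, mirna_ids, alpha = 0.05) {
  dp_sets <- lapply(dp_sets, function(x) if (inherits(x, "dp_result")) x$dp_transcripts else x)
  dp_all <- unique(unlist(dp_sets))
  de_hits <- if (nrow(de_results) > 0) {
    unique(de_results$transcript_id[!is.na(de_results$q) & de_results$q < alpha])
  } else character(0)
  tgt_hits <- if (nrow(target_ora_results) > 0) {
    unique(target_ora_results$mirna[target_ora_results$q < alpha])
  } else character(0)
  skew_hits <- if (nrow(skew_results) > 0) {
    unique(skew_results$mirna[skew_results$q < alpha])
  } else character(0)
  tibble::tibble(
    mirna = mirna_ids,
    de = mirna_ids %in% de_hits,
    dp = mirna_ids %in% dp_all,
    target_enriched = mirna_ids %in% tgt_hits,
    negative_skew = mirna_ids %in% skew_hits
  ) |>
    dplyr::mutate(final_call = (.data$de | .data$dp) & .data$target_enriched & .data$negative_skew)
}
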