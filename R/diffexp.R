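# Group-vs-healthy differential expression with empirical-Bayes variance
# moderation, Benjamini-Hochberg control and fold-change flagging.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values, preserving input order. `NA`/`NaN` inputs
#' propagate and are excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  stop_if_not(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Differential expression against healthy controls within a site
#'
#' Per transcript, ordinary least squares on the disease-group factor of
#' one sample site; residual variances are shrunk toward a common prior by
#' the standard empirical-Bayes hierarchical model (prior parameters
#' estimated by a method-of-moments fit to the scaled-F distribution of
#' the sample variances), and moderated t-statistics are formed on the
#' augmented degrees of freedom. Each group with at least `min_n` samples
#' is contrasted against Healthy; in addition the pooled late-stage group
#' `NPDR_PDR_DME` (NPDR_DME plus PDR_DME samples) is tested. BH adjustment
#' is applied within each contrast x site family.
#'
#' @param norm Log2 CPM matrix, transcripts x samples.
#' @param metadata Sample metadata (`sample_id`, `group`, `site`).
#' @param site Sample site to analyse (`"macula"` or `"periphery"`), or
#'   `NULL` to use all samples as one family.
#' @param moderate Apply empirical-Bayes moderation (default `TRUE`;
#'   `FALSE` gives the plain OLS t-test).
#' @param d0,s0_sq Optional explicit prior degrees of freedom and prior
#'   variance, overriding the method-of-moments estimates. `d0 = Inf`
#'   forces every residual variance to `s0_sq`; `d0 = 0` recovers the
#'   ordinary t-test.
#' @param fc_threshold Fold-change threshold for [flag_fold_change()].
#' @param min_n Minimum group size; smaller groups are skipped with a
#'   warning.
#' @return Tibble: transcript_id, contrast, site, log2fc, t_stat, p, q,
#'   passes_fc.
#' @export
fit_de <- function(norm, metadata, site = NULL, moderate = TRUE,
                   d0 = NULL, s0_sq = NULL, fc_threshold = 1.5, min_n = 2) {
  meta <- if (is.null(site)) metadata else metadata[metadata$site == site, ]
  site_label <- if (is.null(site)) "all" else site
  Y <- norm[, meta$sample_id, drop = FALSE]
  grp <- meta$group
  stop_if_not(sum(grp == "Healthy") >= min_n, "need >= 2 Healthy samples")

  groups <- unique(grp)
  X <- stats::model.matrix(~ 0 + factor(grp, levels = groups))
  n <- ncol(Y); g <- length(groups)
  df_resid <- n - g
  stop_if_not(df_resid >= 1, "no residual degrees of freedom")
  means <- Y %*% X %*% diag(1 / colSums(X), g)
  colnames(means) <- groups
  s2 <- rowSums((Y - means[, grp, drop = FALSE])^2) / df_resid

  cap_df <- FALSE
  if (!is.null(d0) || !is.null(s0_sq)) {
    # explicit prior supplied by the caller; used as given
    stop_if_not(!is.null(d0) && !is.null(s0_sq), "supply both d0 and s0_sq or neither")
    stop_if_not(d0 >= 0 && s0_sq > 0, "need d0 >= 0 and s0_sq > 0")
  } else if (moderate) {
    sq <- limma::squeezeVar(s2, df = df_resid)
    d0 <- sq$df.prior
    s0_sq <- sq$var.prior
    cap_df <- TRUE   # cap the total df at the pooled residual df, as limma does
  } else {
    d0 <- 0
    s0_sq <- mean(s2)   # unused when d0 = 0
  }
  var_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  df_total <- d0 + df_resid
  if (cap_df) df_total <- min(df_total, df_resid * nrow(Y))

  contrast_defs <- list()
  for (gname in intersect(c("Diabetic", "NPDR", "NPDR_DME", "PDR_DME"), groups)) {
    if (sum(grp == gname) >= min_n) {
      contrast_defs[[paste0(gname, "_vs_Healthy")]] <- grp == gname
    } else {
      warning("skipping contrast for group ", gname, " (fewer than ", min_n, " samples)")
    }
  }
  dme <- grp %in% c("NPDR_DME", "PDR_DME")
  if (sum(dme) >= min_n && any(grp == "PDR_DME")) {
    contrast_defs[["NPDR_PDR_DME_vs_Healthy"]] <- dme
  }

  healthy <- grp == "Healthy"
  mu_h <- rowMeans(Y[, healthy, drop = FALSE])
  res <- purrr::imap_dfr(contrast_defs, function(sel, cname) {
    lfc <- unname(rowMeans(Y[, sel, drop = FALSE]) - mu_h)
    se <- sqrt(var_post * (1 / sum(sel) + 1 / sum(healthy)))
    tt <- unname(lfc / se)
    p <- 2 * pt(abs(tt), df = df_total, lower.tail = FALSE)
    tibble::tibble(
      transcript_id = rownames(Y), contrast = cname, site = site_label,
      log2fc = lfc, t_stat = tt, p = p, q = bh_adjust(p)
    )
  })
  flag_fold_change(res, threshold = fc_threshold)
}

#' Flag fold changes above a threshold
#'
#' `passes_fc` is `TRUE` when `|log2fc| >= log2(threshold)`; a threshold
#' of 1.5 corresponds to a 50% change in either direction.
#'
#' @param results Tibble with a `log2fc` column.
#' @param threshold Linear fold-change threshold (default 1.5).
#' @return `results` with a `passes_fc` column.
#' @export
flag_fold_change <- function(results, threshold = 1.5) {
  dplyr::mutate(results, passes_fc = abs(.data$log2fc) >= log2(threshold))
}
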