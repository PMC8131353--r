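# End-to-end orchestration: preprocess -> differential expression ->
# progression -> enrichment -> miRNA integration -> cell types, with a
# single seed and an aggregated report.

#' Preprocess a study's bulk expression
#'
#' Runs the full preprocessing chain: log2 CPM normalization, technical
#' replicate removal, the two-stage expressed-mRNA filter, the miRNA
#' expression filter, surrogate-variable estimation on the filtered mRNA,
#' and residuals-plus-intercept correction (age + surrogate variable for
#' mRNA; age only for miRNA).
#'
#' @param study A `retina_study` (or any list with `counts_mrna`,
#'   `counts_mirna`, `metadata`).
#' @param n_sv Number of surrogate variables (default 1).
#' @param alpha Covariate-significance threshold for [residualize()].
#' @param gmm Apply the Gaussian-mixture stage of the mRNA filter.
#' @return List: `norm_mrna`, `norm_mirna` (residualized log2 CPM),
#'   `metadata` (replicates removed), `sv`, `removed_samples`,
#'   `filter_report`, `universe` (tibble id/kind of expressed
#'   transcripts).
#' @export
preprocess_study <- function(study, n_sv = 1, alpha = 0.05, gmm = TRUE) {
  meta <- study$metadata
  norm_all <- log2_cpm(study$counts_mrna)
  removed <- detect_replicates(norm_all, meta)
  keep_samples <- setdiff(meta$sample_id, removed)
  meta <- meta[meta$sample_id %in% keep_samples, ]
  counts_mrna <- study$counts_mrna[, keep_samples, drop = FALSE]
  counts_mirna <- study$counts_mirna[, keep_samples, drop = FALSE]

  filt <- filter_mrna(counts_mrna, meta, gmm = gmm)
  norm_mrna <- log2_cpm(counts_mrna)[filt$kept, , drop = FALSE]
  attr(norm_mrna, "library_sizes") <- colSums(counts_mrna)

  sv <- estimate_surrogate_variable(norm_mrna, meta, n_sv = n_sv)
  covs <- data.frame(age = meta$age, sv$loadings)
  norm_mrna <- residualize(norm_mrna, covs, alpha = alpha)

  norm_mirna <- NULL
  kept_mirna <- character(0)
  if (nrow(counts_mirna) > 0) {
    nm <- log2_cpm(counts_mirna)
    kept_mirna <- filter_mirna(nm)
    norm_mirna <- nm[kept_mirna, , drop = FALSE]
    attr(norm_mirna, "library_sizes") <- colSums(counts_mirna)
    if (length(kept_mirna) > 0) {
      norm_mirna <- residualize(norm_mirna, data.frame(age = meta$age), alpha = alpha)
    }
  }
  list(
    norm_mrna = norm_mrna,
    norm_mirna = norm_mirna,
    metadata = meta,
    sv = sv,
    removed_samples = removed,
    filter_report = filt$report,
    universe = tibble::tibble(
      id = c(filt$kept, kept_mirna),
      kind = c(rep("mRNA", length(filt$kept)), rep("miRNA", length(kept_mirna)))
    )
  )
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulates (or accepts) a study, preprocesses it, and runs differential
#' expression, progression modelling, gene-set enrichment, miRNA evidence
#' integration and the single-cell analyses, returning an aggregated
#' report. All randomness derives from the configuration seed, so a rerun
#' with the same configuration reproduces the report.
#'
#' @param config A [simulation_config()], or an already simulated
#'   `retina_study`.
#' @param cvspec Cross-validation specification for the progression model
#'   (desk default 5 x 3).
#' @param budget Scatter-search evaluation budget per site (desk default
#'   150; the full-scale setting is 1,000).
#' @param n_background Background correlations for the skew test.
#' @param sc_cap Per-type cell cap for the reference.
#' @param alpha Significance threshold used throughout (BH q).
#' @return A `pipeline_report` list; see element names.
#' @export
run_pipeline <- function(config,
                         cvspec = cv_spec(folds = 5, repeats = 3, seed = NULL),
                         budget = 150,
                         n_background = 20000,
                         sc_cap = 500,
                         alpha = 0.05) {
  study <- if (inherits(config, "retina_study")) config else simulate_study(config)
  seed <- study$config$seed
  if (is.null(cvspec$seed)) cvspec$seed <- seed
  prep <- preprocess_study(study)
  norm_all <- rbind(prep$norm_mrna, prep$norm_mirna)
  sites <- unique(prep$metadata$site)

  de <- purrr::map_dfr(sites, function(s) fit_de(norm_all, prep$metadata, site = s))
  de_sets <- lapply(setNames(sites, sites), function(s) {
    cn <- if (any(de$contrast == "NPDR_PDR_DME_vs_Healthy")) "NPDR_PDR_DME_vs_Healthy" else "NPDR_DME_vs_Healthy"
    de$transcript_id[de$site == s & de$contrast == cn & !is.na(de$q) & de$q < alpha]
  })

  dp <- lapply(setNames(sites, sites), function(s) {
    find_dp_transcripts(norm_all, prep$metadata, site = s,
                        cvspec = cvspec,
                        optconfig = scatter_search_config(max_evaluations = budget,
                                                          seed = seed))
  })
  dp_sets <- lapply(dp, `[[`, "dp_transcripts")
  dp_combined <- if (length(sites) == 2) {
    combine_dp_sets(dp_sets[[1]], dp_sets[[2]], nrow(norm_all))
  } else NULL

  mrna_bg <- prep$universe$id[prep$universe$kind == "mRNA"]
  query_sets <- c(setNames(de_sets, paste0("DE_", names(de_sets))),
                  setNames(dp_sets, paste0("DP_", names(dp_sets))))
  enrichment <- purrr::imap_dfr(query_sets, function(q, nm) {
    res <- ora(intersect(q, mrna_bg), study$gene_sets, mrna_bg)
    dplyr::bind_cols(tibble::tibble(query = nm), res)
  })
  gage <- purrr::map_dfr(sites, function(s) {
    purrr::map_dfr(unique(de$contrast[de$site == s]), function(cn) {
      d <- de[de$site == s & de$contrast == cn, ]
      stats <- setNames(d$log2fc, d$transcript_id)[mrna_bg]
      stats <- stats[!is.na(stats)]
      dplyr::bind_cols(tibble::tibble(site = s, contrast = cn),
                       gage_test(stats, study$gene_sets))
    })
  })

  mirna_report <- NULL
  if (!is.null(prep$norm_mirna) && nrow(prep$norm_mirna) >= 2 && nrow(study$target_map) > 0) {
    disease_union <- unique(c(unlist(de_sets), unlist(dp_sets)))
    frac <- mirna_fraction_enrichment(intersect(disease_union, prep$universe$id), prep$universe)
    mrna_sets <- lapply(query_sets, intersect, mrna_bg)
    t_ora <- target_ora(study$target_map, mrna_sets, mrna_bg)
    skew <- purrr::map_dfr(sites, function(s) {
      correlation_skew(prep$norm_mirna, prep$norm_mrna, study$target_map,
                       prep$metadata, site = s,
                       n_background = n_background, seed = seed)
    })
    evidence <- integrate_evidence(de, dp_sets, t_ora, skew,
                                   mirna_ids = rownames(prep$norm_mirna), alpha = alpha)
    mirna_report <- list(fraction = frac, target_ora = t_ora, skew = skew,
                         evidence = evidence)
  }

  sc <- downsample_cells(study$sc_ref, cap = sc_cap, seed = seed)
  markers <- find_markers(sc, bulk_gene_universe = mrna_bg)
  sc_bg <- intersect(mrna_bg, rownames(sc$counts))
  disease_genes <- intersect(unique(c(unlist(de_sets), unlist(dp_sets))), sc_bg)
  m_ora <- marker_ora(disease_genes, markers, sc_bg)
  deconv <- deconvolve(prep$norm_mrna[intersect(rownames(prep$norm_mrna), sc_bg), , drop = FALSE], sc)
  ct_pathways <- celltype_pathway_ora(disease_genes, markers, study$gene_sets, sc_bg)

  structure(list(
    seed = seed,
    metadata = prep$metadata,
    removed_samples = prep$removed_samples,
    filter_report = prep$filter_report,
    universe = prep$universe,
    de = de,
    de_counts = de |>
      dplyr::filter(!is.na(.data$q), .data$q < alpha) |>
      dplyr::count(.data$site, .data$contrast, name = "n_significant"),
    dp = dp,
    dp_combined = dp_combined,
    enrichment = enrichment,
    gage = gage,
    mirna = mirna_report,
    markers = markers,
    marker_ora = m_ora,
    deconvolution = deconv,
    celltype_pathways = ct_pathways
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  samples kept: %d (removed %d technical replicates)\n",
              nrow(x$metadata), length(x$removed_samples)))
  cat(sprintf("  expressed transcripts: %d\n", nrow(x$universe)))
  dpn <- vapply(x$dp, function(d) length(d$dp_transcripts), 0L)
  cat(sprintf("  DP transcripts: %s\n",
              paste(sprintf("%s %d", names(dpn), dpn), collapse = ", ")))
  if (!is.null(x$dp_combined)) {
    cat(sprintf("  DP union %d, intersect %d, fold-enrichment %.2f\n",
                x$dp_combined$n_union, x$dp_combined$n_intersect,
                x$dp_combined$fold_enrichment))
  }
  invisible(x)
}
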