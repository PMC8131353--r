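# Synthetic study generator. Emulates a staged retinal disease cohort:
# four main disease groups x two sample sites x ~10 donors, bulk mRNA and
# miRNA negative-binomial counts built as mixtures of cell-type signatures,
# with planted disease-progression trends, late-stage-only effects, a
# technical confounder, an age covariate, miRNA-target inhibitory coupling,
# technical replicate pairs, and a matching single-cell reference.

#' Cell type names used by the simulator
#'
#' RGC (retinal ganglion cells) always comes first; its proportion is the
#' one that declines with disease stage.
#'
#' @param n Number of cell types.
#' @return Character vector of length `n`.
#' @export
celltype_names <- function(n) {
  base <- c(
    "RGC", "Rod", "Cone", "Bipolar", "Amacrine", "Horizontal",
    "Mueller", "Microglia", "Endothelial", "Pericyte"
  )
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("CellType", seq_len(n - length(base)) + length(base)))
}

#' Configuration for the synthetic study generator
#'
#' Defaults describe the cohort the pipeline is designed for: four main
#' disease groups (Healthy, Diabetic, NPDR, NPDR_DME) times two retinal
#' sample sites (macula, periphery) with 10 donors each, a handful of
#' PDR_DME samples that are excluded from the progression regression,
#' around 4,000 mRNA and 250 miRNA, and a 10-cell-type reference with a
#' declining retinal ganglion cell fraction.
#'
#' @param n_mrna,n_mirna Number of mRNA and miRNA transcripts.
#' @param n_per_group_site Donors per main disease group (each donor
#'   contributes one macula and one periphery sample). Must be >= 3.
#' @param n_pdr_dme Named integer vector `c(macula=, periphery=)` of extra
#'   PDR_DME samples per site.
#' @param true_stage_positions Strictly increasing numeric positions of the
#'   four main groups on the 0..3 disease-stage axis.
#' @param frac_dp Fraction of transcripts with a monotone disease-progression
#'   effect: the latent log2 mean shifts by
#'   `effect_size_log2 * stage_position / 3` (random sign), i.e. the full
#'   Healthy-to-NPDR_DME span equals `effect_size_log2`. Scaling by the
#'   stage span keeps planted fold changes in a realistic range and avoids
#'   the library-composition distortion that unbounded per-stage shifts
#'   would create.
#' @param frac_de_late Fraction with a late-stage-only effect (shift of
#'   `effect_size_log2` in DME groups only).
#' @param effect_size_log2 Planted effect size on the log2 scale.
#' @param nb_dispersion Negative-binomial dispersion of the count noise
#'   (Var = mu + mu^2 * dispersion). Represents technical/counting noise;
#'   donor-level variability is controlled separately by `bio_sd`.
#' @param bio_sd Standard deviation (log2) of per-donor biological noise.
#'   Technical replicate samples share this noise; independent samples do
#'   not, which is what separates replicate pairs (Pearson r > 0.98) from
#'   independent pairs in the replicate detector.
#' @param libsize_log_mean,libsize_log_sd Log-normal mRNA library sizes.
#' @param mirna_libsize_log_mean,mirna_libsize_log_sd Log-normal miRNA
#'   library sizes.
#' @param confounder_frac Fraction of mRNA hit by the technical batch term.
#' @param confounder_strength Batch shift in log2 units (0 disables).
#' @param age_mean,age_sd Donor age distribution (years).
#' @param age_effect_frac Fraction of transcripts with an age slope.
#' @param age_effect_slope Age slope magnitude, log2 units per year.
#' @param n_celltypes,markers_per_type Cell types and unique marker genes
#'   planted per type.
#' @param cells_per_type Single-cell reference cells per type per subject.
#' @param sc_subjects Pseudo-subjects in the reference (>= 2 so deconvolution
#'   can estimate cross-subject variance weights).
#' @param sc_dispersion NB dispersion of single-cell counts.
#' @param rgc_decline Length-2 vector: RGC proportion at stage 0 and stage 3.
#' @param mirna_coupling_strength Loading (<= 0) of the shared latent factor
#'   on coupled target mRNA; the factor enters the miRNA with loading +1.
#' @param targets_per_mirna Targets per miRNA in the generated target map.
#' @param n_evidence_mirna Number of planted "complete-evidence" miRNA:
#'   progression-associated themselves, with down-regulated progression
#'   targets and negative miRNA-target coupling.
#' @param n_replicate_pairs Same-donor / other-eye technical replicate
#'   samples added to the macula arm of the Healthy group.
#' @param n_gene_sets Random gene sets written to the GMT collection (two
#'   planted sets are added when progression/late effects are present).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_mrna = 4000,
                              n_mirna = 250,
                              n_per_group_site = 10,
                              n_pdr_dme = c(macula = 3, periphery = 2),
                              true_stage_positions = c(healthy = 0, diabetic = 0.8, npdr = 1.8, npdr_dme = 3),
                              frac_dp = 0.05,
                              frac_de_late = 0.05,
                              effect_size_log2 = 2,
                              nb_dispersion = 0.02,
                              bio_sd = 0.5,
                              libsize_log_mean = log(8e6),
                              libsize_log_sd = 0.25,
                              mirna_libsize_log_mean = log(2e6),
                              mirna_libsize_log_sd = 0.25,
                              confounder_frac = 0.3,
                              confounder_strength = 1,
                              age_mean = 70,
                              age_sd = 8,
                              age_effect_frac = 0.1,
                              age_effect_slope = 0.03,
                              n_celltypes = 10,
                              markers_per_type = 20,
                              cells_per_type = 80,
                              sc_subjects = 2,
                              sc_dispersion = 0.3,
                              rgc_decline = c(start = 0.12, end = 0.05),
                              mirna_coupling_strength = -0.8,
                              targets_per_mirna = 30,
                              n_evidence_mirna = 5,
                              n_replicate_pairs = 2,
                              n_gene_sets = 50,
                              seed = 1L) {
  fracs <- c(frac_dp = frac_dp, frac_de_late = frac_de_late,
             confounder_frac = confounder_frac, age_effect_frac = age_effect_frac)
  stop_if_not(all(fracs >= 0 & fracs <= 1), "all fractions must lie in [0, 1]")
  stop_if_not(length(true_stage_positions) == 4 && all(diff(true_stage_positions) > 0),
              "true_stage_positions must be 4 strictly increasing values")
  stop_if_not(all(true_stage_positions >= 0 & true_stage_positions <= 3),
              "true_stage_positions must lie in [0, 3]")
  stop_if_not(nb_dispersion > 0, "nb_dispersion must be > 0")
  stop_if_not(n_per_group_site >= 3, "n_per_group_site must be >= 3")
  stop_if_not(mirna_coupling_strength <= 0, "mirna_coupling_strength must be <= 0")
  stop_if_not(length(rgc_decline) == 2 && all(rgc_decline > 0 & rgc_decline < 1),
              "rgc_decline must be two proportions in (0, 1)")
  cfg <- as.list(environment())
  cfg$fracs <- NULL
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Null configuration: no planted structure
#'
#' All effect fractions and strengths set to zero and the RGC decline
#' flattened, so transcripts are exchangeable across disease groups.
#' Used for calibration checks of the downstream tests.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
null_simulation_config <- function(...) {
  simulation_config(
    frac_dp = 0, frac_de_late = 0,
    confounder_frac = 0, confounder_strength = 0,
    age_effect_frac = 0,
    rgc_decline = c(start = 0.08, end = 0.08),
    n_evidence_mirna = 0,
    ...
  )
}

#' Desk-scale progression study preset
#'
#' The configuration used to validate stage-position recovery of the sparse
#' PLS progression model: 1,000 mRNA transcripts, exactly 80 samples (four
#' main groups x two sites x 10, no PDR extras, no replicate pairs), planted
#' stage positions 0 / 0.8 / 1.8 / 3 and a 5% progression fraction at effect
#' size 2. The planted progression transcripts are the only stage-linked
#' structure: late-stage-only effects are disabled and the cell-composition
#' trend is flattened. Because the stage encoding leaves the intermediate
#' positions free, any competing stage-linked structure (e.g. genes shifted
#' only in the DME group) defines an alternative, equally legitimate
#' solution - the encoding can collapse toward a binary late-vs-rest
#' contrast - which would make recovery of the planted set unmeasurable.
#' The technical confounder and the age effect stay on; the preprocessing
#' chain is expected to remove them.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
progression_demo_config <- function(seed = 1L, ...) {
  args <- list(
    n_mrna = 1000, n_mirna = 0,
    n_pdr_dme = c(macula = 0, periphery = 0),
    n_replicate_pairs = 0,
    n_evidence_mirna = 0,
    frac_dp = 0.05, frac_de_late = 0, effect_size_log2 = 2,
    rgc_decline = c(start = 0.08, end = 0.08),
    true_stage_positions = c(healthy = 0, diabetic = 0.8, npdr = 1.8, npdr_dme = 3),
    seed = seed
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' Simulate a complete synthetic retina study
#'
#' Generates bulk mRNA and miRNA counts, sample metadata, a single-cell
#' reference, a miRNA target map, a gene-set collection and the ground
#' truth of everything planted. Bulk mean profiles are mixtures of
#' cell-type signatures weighted by per-sample cell proportions; planted
#' progression transcripts shift their latent log2 mean by
#' `effect_size_log2 * stage_position`; late-stage transcripts shift only
#' in the DME groups; coupled miRNA-target pairs share a latent factor with
#' negative loading on the target.
#'
#' @param config A [simulation_config()] object.
#' @return A `retina_study` list with elements `counts_mrna`, `counts_mirna`
#'   (integer matrices, transcripts x samples), `metadata` (tibble),
#'   `sc_ref` (list: `counts`, `cells`), `target_map` (tibble),
#'   `gene_sets` (see [read_gmt()]), `truth` (list) and `config`.
#' @export
simulate_study <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must come from simulation_config()")
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("gene%05d", seq_len(cfg$n_mrna))
  mirnas <- if (cfg$n_mirna > 0) sprintf("mir%04d", seq_len(cfg$n_mirna)) else character(0)
  types <- celltype_names(cfg$n_celltypes)

  ## ---- sample sheet -------------------------------------------------
  main_groups <- c("Healthy", "Diabetic", "NPDR", "NPDR_DME")
  stage_pos <- c(setNames(unname(cfg$true_stage_positions), main_groups), PDR_DME = 3)

  donors <- tibble::tibble(
    donor_id = sprintf("donor%03d", seq_len(4L * cfg$n_per_group_site)),
    group = rep(main_groups, each = cfg$n_per_group_site)
  )
  n_pdr <- cfg$n_pdr_dme
  n_pdr_donors <- max(n_pdr, 0)
  if (n_pdr_donors > 0) {
    donors <- dplyr::bind_rows(donors, tibble::tibble(
      donor_id = sprintf("donorP%02d", seq_len(n_pdr_donors)),
      group = "PDR_DME"
    ))
  }
  donors$age <- pmax(40, rnorm(nrow(donors), cfg$age_mean, cfg$age_sd))

  meta <- dplyr::bind_rows(lapply(c("macula", "periphery"), function(site) {
    d <- donors[donors$group != "PDR_DME", ]
    if (n_pdr_donors > 0 && n_pdr[[site]] > 0) {
      d <- dplyr::bind_rows(d, donors[donors$group == "PDR_DME", ][seq_len(n_pdr[[site]]), ])
    }
    tibble::tibble(
      donor_id = d$donor_id, group = d$group, age = d$age,
      site = site, eye = "L"
    )
  }))

  # technical replicate samples: same donor + site, other eye
  if (cfg$n_replicate_pairs > 0) {
    healthy_mac <- which(meta$group == "Healthy" & meta$site == "macula")
    rep_of <- healthy_mac[seq_len(min(cfg$n_replicate_pairs, length(healthy_mac)))]
    reps <- meta[rep_of, ]
    reps$eye <- "R"
    meta <- dplyr::bind_rows(meta, reps)
  } else {
    rep_of <- integer(0)
  }
  n_samples <- nrow(meta)
  meta$sample_id <- sprintf("S%03d", seq_len(n_samples))
  meta$stage <- unname(stage_pos[meta$group])
  # copies holds, for each sample, the row index of the sample whose latent
  # profile it duplicates (itself for ordinary samples)
  copies <- seq_len(n_samples)
  if (length(rep_of) > 0) copies[(n_samples - length(rep_of) + 1L):n_samples] <- rep_of

  meta$batch <- rbinom(n_samples, 1, 0.5)
  meta$batch[copies != seq_len(n_samples)] <- meta$batch[rep_of]
  meta$seq_metric <- 50 + 15 * meta$batch + rnorm(n_samples, 0, 3)

  ## ---- gene architecture --------------------------------------------
  low <- runif(cfg$n_mrna) < 0.15
  base_log2 <- ifelse(low, rnorm(cfg$n_mrna, -1, 1), rnorm(cfg$n_mrna, 5, 1.5))
  high_idx <- which(!low)

  n_markers <- cfg$n_celltypes * cfg$markers_per_type
  stop_if_not(n_markers + round(cfg$frac_dp * cfg$n_mrna) + round(cfg$frac_de_late * cfg$n_mrna) <= length(high_idx),
              "not enough well-expressed genes for the requested markers and planted effects")
  marker_idx <- sample(high_idx, n_markers)
  marker_type <- rep(types, each = cfg$markers_per_type)
  pool <- setdiff(high_idx, marker_idx)

  n_dp <- round(cfg$frac_dp * cfg$n_mrna)
  dp_idx <- sample(pool, n_dp)
  dp_sign <- sample(c(-1, 1), n_dp, replace = TRUE)
  pool <- setdiff(pool, dp_idx)

  n_late <- round(cfg$frac_de_late * cfg$n_mrna)
  late_idx <- sample(pool, n_late)
  late_sign <- sample(c(-1, 1), n_late, replace = TRUE)

  conf_idx <- if (cfg$confounder_strength > 0 && cfg$confounder_frac > 0) {
    sample(cfg$n_mrna, round(cfg$confounder_frac * cfg$n_mrna))
  } else integer(0)
  age_idx <- if (cfg$age_effect_frac > 0) sample(high_idx, round(cfg$age_effect_frac * length(high_idx))) else integer(0)
  age_slope <- sample(c(-1, 1), length(age_idx), replace = TRUE) * cfg$age_effect_slope

  ## ---- cell-type signatures and proportions -------------------------
  sig_log2 <- matrix(rnorm(cfg$n_mrna * cfg$n_celltypes, 0, 0.3),
                     cfg$n_mrna, cfg$n_celltypes,
                     dimnames = list(genes, types)) + base_log2
  for (t in seq_along(types)) {
    m <- marker_idx[marker_type == types[t]]
    sig_log2[m, t] <- sig_log2[m, t] + 3
  }
  sig_lin <- 2^sig_log2

  other_w <- rgamma(cfg$n_celltypes - 1L, shape = 5)
  other_w <- other_w / sum(other_w)
  props <- matrix(0, n_samples, cfg$n_celltypes, dimnames = list(meta$sample_id, types))
  for (s in seq_len(n_samples)) {
    rgc <- cfg$rgc_decline[[1]] + (cfg$rgc_decline[[2]] - cfg$rgc_decline[[1]]) * meta$stage[s] / 3
    target <- c(rgc, (1 - rgc) * other_w)
    props[s, ] <- rdirichlet1(300 * target)
  }
  props[copies != seq_len(n_samples), ] <- props[rep_of, , drop = FALSE]

  ## ---- bulk mRNA latent log2 means ----------------------------------
  logM <- log2(sig_lin %*% t(props))
  logM <- logM + matrix(rnorm(length(logM), 0, cfg$bio_sd), nrow(logM))
  if (n_dp > 0) logM[dp_idx, ] <- logM[dp_idx, ] + outer(dp_sign * cfg$effect_size_log2, meta$stage / 3)
  is_dme <- as.numeric(meta$group %in% c("NPDR_DME", "PDR_DME"))
  if (n_late > 0) logM[late_idx, ] <- logM[late_idx, ] + outer(late_sign * cfg$effect_size_log2, is_dme)
  if (length(conf_idx) > 0) {
    logM[conf_idx, ] <- logM[conf_idx, ] + cfg$confounder_strength * matrix(meta$batch, length(conf_idx), n_samples, byrow = TRUE)
  }
  if (length(age_idx) > 0) logM[age_idx, ] <- logM[age_idx, ] + outer(age_slope, meta$age - cfg$age_mean)

  ## ---- miRNA latents, coupling, target map --------------------------
  coupled_pairs <- tibble::tibble(mirna = character(0), target = character(0))
  target_map <- tibble::tibble(mirna = character(0), target = character(0), evidence = character(0))
  mir_dp <- character(0); logMir <- NULL
  if (cfg$n_mirna > 0) {
    mir_low <- runif(cfg$n_mirna) < 0.15
    mir_base <- ifelse(mir_low, rnorm(cfg$n_mirna, 1, 1), rnorm(cfg$n_mirna, 9, 1.5))
    logMir <- matrix(mir_base, cfg$n_mirna, n_samples, dimnames = list(mirnas, meta$sample_id))
    logMir <- logMir + matrix(rnorm(length(logMir), 0, cfg$bio_sd), cfg$n_mirna)

    mir_high <- which(!mir_low)
    n_ev <- min(cfg$n_evidence_mirna, length(mir_high))
    ev_idx <- if (n_ev > 0) mir_high[seq_len(n_ev)] else integer(0)
    # evidence miRNA go up with stage; a few additional miRNA get ordinary
    # progression / late effects with random signs
    extra_pool <- setdiff(mir_high, ev_idx)
    n_mir_dp <- min(round(cfg$frac_dp * cfg$n_mirna), length(extra_pool))
    mir_dp_idx <- if (n_mir_dp > 0) sample(extra_pool, n_mir_dp) else integer(0)
    mir_dp_sign <- sample(c(-1, 1), length(mir_dp_idx), replace = TRUE)
    if (n_ev > 0) logMir[ev_idx, ] <- logMir[ev_idx, ] + outer(rep(cfg$effect_size_log2, n_ev), meta$stage / 3)
    if (length(mir_dp_idx) > 0) {
      logMir[mir_dp_idx, ] <- logMir[mir_dp_idx, ] + outer(mir_dp_sign * cfg$effect_size_log2, meta$stage / 3)
    }
    mir_dp <- mirnas[c(ev_idx, mir_dp_idx)]

    # target map; evidence miRNA point at down-regulated progression genes
    # and share a latent factor with them (negative loading on the target)
    n_half <- ceiling(cfg$targets_per_mirna / 2)
    dp_down_pool <- dp_idx
    for (i in seq_along(ev_idx)) {
      take <- dp_down_pool[seq_len(min(n_half, length(dp_down_pool)))]
      dp_down_pool <- setdiff(dp_down_pool, take)
      # flip these progression targets to down-regulation (repression
      # consistent with a rising miRNA) by adjusting the effect in place
      old_sign <- dp_sign[match(take, dp_idx)]
      if (length(take) > 0) {
        logM[take, ] <- logM[take, ] + outer((-1 - old_sign) * cfg$effect_size_log2, meta$stage / 3)
        dp_sign[match(take, dp_idx)] <- -1
      }
      z <- rnorm(n_samples)
      logMir[ev_idx[i], ] <- logMir[ev_idx[i], ] + z
      if (length(take) > 0) {
        logM[take, ] <- logM[take, ] + cfg$mirna_coupling_strength * matrix(z, length(take), n_samples, byrow = TRUE)
      }
      others <- sample(setdiff(seq_len(cfg$n_mrna), take), cfg$targets_per_mirna - length(take))
      target_map <- dplyr::bind_rows(target_map, tibble::tibble(
        mirna = mirnas[ev_idx[i]], target = genes[c(take, others)],
        evidence = c(rep("planted", length(take)), rep("db", length(others)))
      ))
      coupled_pairs <- dplyr::bind_rows(coupled_pairs, tibble::tibble(
        mirna = mirnas[ev_idx[i]], target = genes[take]
      ))
    }
    for (i in setdiff(seq_len(cfg$n_mirna), ev_idx)) {
      target_map <- dplyr::bind_rows(target_map, tibble::tibble(
        mirna = mirnas[i],
        target = genes[sample(cfg$n_mrna, min(cfg$targets_per_mirna, cfg$n_mrna))],
        evidence = "db"
      ))
    }
  }

  ## ---- technical replicates duplicate the full latent profile --------
  is_rep <- which(copies != seq_len(n_samples))
  if (length(is_rep) > 0) {
    logM[, is_rep] <- logM[, copies[is_rep], drop = FALSE]
    if (!is.null(logMir)) logMir[, is_rep] <- logMir[, copies[is_rep], drop = FALSE]
  }

  ## ---- counts --------------------------------------------------------
  draw_counts <- function(logX, log_mean, log_sd, ids) {
    lib <- rlnorm(n_samples, log_mean, log_sd)
    rel <- 2^logX
    rel <- sweep(rel, 2, colSums(rel), "/")
    mu <- sweep(rel, 2, lib, "*")
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                  nrow(mu), dimnames = list(ids, meta$sample_id))
    storage.mode(cnt) <- "integer"
    cnt
  }
  counts_mrna <- draw_counts(logM, cfg$libsize_log_mean, cfg$libsize_log_sd, genes)
  counts_mirna <- if (cfg$n_mirna > 0) {
    draw_counts(logMir, cfg$mirna_libsize_log_mean, cfg$mirna_libsize_log_sd, mirnas)
  } else {
    matrix(integer(0), 0, n_samples, dimnames = list(character(0), meta$sample_id))
  }

  ## ---- single-cell reference ----------------------------------------
  n_cells <- cfg$cells_per_type * cfg$n_celltypes * cfg$sc_subjects
  cells <- tibble::tibble(
    cell_id = sprintf("cell%05d", seq_len(n_cells)),
    type = rep(rep(types, each = cfg$cells_per_type), cfg$sc_subjects),
    subject = rep(sprintf("subj%d", seq_len(cfg$sc_subjects)), each = cfg$cells_per_type * cfg$n_celltypes)
  )
  sc_counts <- matrix(0L, cfg$n_mrna, n_cells, dimnames = list(genes, cells$cell_id))
  for (subj in unique(cells$subject)) {
    subj_shift <- matrix(rnorm(cfg$n_mrna * cfg$n_celltypes, 0, 0.25), cfg$n_mrna)
    for (t in seq_along(types)) {
      sel <- which(cells$subject == subj & cells$type == types[t])
      rel <- 2^(sig_log2[, t] + subj_shift[, t])
      rel <- rel / sum(rel)
      lib <- rlnorm(length(sel), log(5000), 0.3)
      mu <- outer(rel, lib)
      sc_counts[, sel] <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$sc_dispersion), cfg$n_mrna)
    }
  }
  storage.mode(sc_counts) <- "integer"

  ## ---- gene sets -----------------------------------------------------
  categories <- c("Metabolism", "Signaling", "Cellular Processes", "Human Diseases")
  set_sizes <- sample(20:150, cfg$n_gene_sets, replace = TRUE)
  sets <- lapply(set_sizes, function(k) genes[sample(cfg$n_mrna, min(k, cfg$n_mrna))])
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(cfg$n_gene_sets))
  set_cat <- sample(categories, cfg$n_gene_sets, replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  if (n_dp >= 20) {
    sets$PLANTED_DP_PATHWAY <- genes[c(sample(dp_idx, 20), sample(setdiff(seq_len(cfg$n_mrna), dp_idx), 40))]
    set_cat <- c(set_cat, "Signaling")
  }
  if (n_late >= 20) {
    sets$PLANTED_LATE_PATHWAY <- genes[c(sample(late_idx, 20), sample(setdiff(seq_len(cfg$n_mrna), late_idx), 40))]
    set_cat <- c(set_cat, "Signaling")
  }
  gene_sets <- new_gene_set_collection(sets, category = set_cat, source = "synthetic")

  truth <- list(
    dp_transcripts = c(genes[dp_idx], mir_dp),
    dp_signs = setNames(c(dp_sign, rep(NA_real_, length(mir_dp))), c(genes[dp_idx], mir_dp)),
    de_late_transcripts = genes[late_idx],
    confounded_transcripts = genes[conf_idx],
    age_affected = genes[age_idx],
    coupled_pairs = coupled_pairs,
    evidence_mirna = if (cfg$n_mirna > 0 && length(coupled_pairs$mirna) > 0) unique(coupled_pairs$mirna) else character(0),
    cell_proportions = props,
    marker_assignment = setNames(marker_type, genes[marker_idx]),
    batch = setNames(meta$batch, meta$sample_id),
    replicate_of = setNames(meta$sample_id[copies], meta$sample_id),
    stage_positions = stage_pos
  )

  structure(list(
    counts_mrna = counts_mrna,
    counts_mirna = counts_mirna,
    metadata = meta[, c("sample_id", "donor_id", "eye", "site", "group", "age", "seq_metric")],
    sc_ref = list(counts = sc_counts, cells = cells),
    target_map = target_map,
    gene_sets = gene_sets,
    truth = truth,
    config = cfg
  ), class = "retina_study")
}

#' @export
print.retina_study <- function(x, ...) {
  cat("<retina_study>\n")
  cat(sprintf("  mRNA:  %d transcripts x %d samples\n", nrow(x$counts_mrna), ncol(x$counts_mrna)))
  cat(sprintf("  miRNA: %d transcripts\n", nrow(x$counts_mirna)))
  cat(sprintf("  single-cell reference: %d genes x %d cells (%d types)\n",
              nrow(x$sc_ref$counts), ncol(x$sc_ref$counts), length(unique(x$sc_ref$cells$type))))
  cat(sprintf("  planted progression transcripts: %d\n", length(x$truth$dp_transcripts)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Counts go out as MatrixMarket plus row/column TSV files, metadata and the
#' target map as TSV, gene sets as GMT, ground truth as JSON. A manifest
#' with MD5 checksums of every file is returned (and written as
#' `manifest.tsv`). The round trip through [read_study()] is lossless for
#' the count matrices.
#'
#' @param study A `retina_study`.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Tibble manifest (file, md5), invisibly.
#' @export
write_study <- function(study, dir, overwrite = FALSE) {
  stop_if_not(inherits(study, "retina_study"), "study must be a retina_study")
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("directory ", dir, " is not empty; set overwrite = TRUE to replace", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(study$counts_mrna) == 0 && nrow(study$counts_mirna) == 0) {
    warning("writing an empty study (0 transcripts)")
  }
  write_mtx <- function(mat, stem, kind) {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), file.path(dir, paste0(stem, ".mtx")))
    readr::write_tsv(tibble::tibble(transcript_id = rownames(mat), kind = kind),
                     file.path(dir, paste0(stem, "_rows.tsv")))
    readr::write_tsv(tibble::tibble(sample_id = colnames(mat)),
                     file.path(dir, paste0(stem, "_cols.tsv")))
  }
  write_mtx(study$counts_mrna, "mrna_counts", "mRNA")
  write_mtx(study$counts_mirna, "mirna_counts", "miRNA")
  readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(study$target_map, file.path(dir, "target_map.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  Matrix::writeMM(Matrix::Matrix(study$sc_ref$counts, sparse = TRUE), file.path(dir, "sc_counts.mtx"))
  readr::write_tsv(tibble::tibble(gene_id = rownames(study$sc_ref$counts)), file.path(dir, "sc_genes.tsv"))
  readr::write_tsv(study$sc_ref$cells, file.path(dir, "sc_cells.tsv"))
  truth <- study$truth
  truth$cell_proportions <- list(
    sample_id = rownames(truth$cell_proportions),
    celltype = colnames(truth$cell_proportions),
    values = unname(truth$cell_proportions)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), digits = NA)
  jsonlite::write_json(list(seed = study$config$seed), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  files <- setdiff(list.files(dir), "manifest.tsv")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read back the on-disk parts of a study written by [write_study()]
#'
#' @param dir Directory written by [write_study()].
#' @return List with `counts_mrna`, `counts_mirna`, `metadata`, `sc_ref`,
#'   `target_map`, `gene_sets`.
#' @export
read_study <- function(dir) {
  read_mtx <- function(stem) {
    m <- as.matrix(Matrix::readMM(file.path(dir, paste0(stem, ".mtx"))))
    rows <- readr::read_tsv(file.path(dir, paste0(stem, "_rows.tsv")), show_col_types = FALSE)
    cols <- readr::read_tsv(file.path(dir, paste0(stem, "_cols.tsv")), show_col_types = FALSE)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(rows$transcript_id, cols$sample_id)
    m
  }
  sc <- as.matrix(Matrix::readMM(file.path(dir, "sc_counts.mtx")))
  storage.mode(sc) <- "integer"
  sc_genes <- readr::read_tsv(file.path(dir, "sc_genes.tsv"), show_col_types = FALSE)
  sc_cells <- readr::read_tsv(file.path(dir, "sc_cells.tsv"), show_col_types = FALSE)
  dimnames(sc) <- list(sc_genes$gene_id, sc_cells$cell_id)
  list(
    counts_mrna = read_mtx("mrna_counts"),
    counts_mirna = read_mtx("mirna_counts"),
    metadata = readr::read_tsv(file.path(dir, "metadata.tsv"), show_col_types = FALSE),
    sc_ref = list(counts = sc, cells = sc_cells),
    target_map = readr::read_tsv(file.path(dir, "target_map.tsv"), show_col_types = FALSE),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt"))
  )
}
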