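test_that("miRNA fraction enrichment reproduces the printed ratio arithmetic", {
  universe <- tibble::tibble(
    id = c(sprintf("g%05d", 1:15073), sprintf("m%03d", 1:256)),
    kind = c(rep("mRNA", 15073), rep("miRNA", 256))
  )
  expect_equal(nrow(universe), 15329)
  disease <- c(sprintf("g%05d", 1:2240), sprintf("m%03d", 1:75))
  res <- mirna_fraction_enrichment(disease, universe)
  expect_equal(res$k, 75); expect_equal(res$K, 256)
  expect_equal(res$n, 2315); expect_equal(res$N, 15329)
  expect_equal(res$fold_enrichment, (75 / 2315) / (256 / 15329), tolerance = 1e-12)
  expect_equal(round(res$fold_enrichment, 2), 1.94)

  # no miRNA in the disease set
  res0 <- mirna_fraction_enrichment(sprintf("g%05d", 1:100), universe)
  expect_equal(res0$fold_enrichment, 0); expect_equal(res0$p, 1)

  # the disease set being all miRNA gives the maximal enrichment N / K
  resA <- mirna_fraction_enrichment(sprintf("m%03d", 1:256), universe)
  expect_equal(resA$fold_enrichment, 15329 / 256)
})

test_that("target over-representation applies the minimum-target rule", {
  background <- sprintf("g%04d", 1:2000)
  disease <- sprintf("g%04d", 1:200)
  map <- dplyr::bind_rows(
    tibble::tibble(mirna = "mir_few", target = sprintf("g%04d", 1:9)),       # excluded
    tibble::tibble(mirna = "mir_hit", target = sprintf("g%04d", c(1:15, 1001:1015))),
    tibble::tibble(mirna = "mir_null", target = sprintf("g%04d", 1501:1530))
  )
  res <- target_ora(map, list(DE = disease), background)
  expect_false("mir_few" %in% res$mirna)
  # 15 of 30 targets inside a 200-gene set over a 2000-gene background
  hit <- res[res$mirna == "mir_hit", ]
  expect_equal(hit$k, 15L); expect_equal(hit$K, 30L)
  expect_equal(hit$p, hypergeom_test(15, 30, 200, 2000))
  expect_lt(hit$q, 0.05)
  expect_equal(res$p[res$mirna == "mir_null"], 1)  # disjoint targets

  # invariant to target-list ordering
  res2 <- target_ora(map[sample(nrow(map)), ], list(DE = disease), background)
  expect_equal(dplyr::arrange(res, mirna), dplyr::arrange(res2, mirna))

  # empty disease set: all p = 1
  res3 <- target_ora(map, list(EMPTY = character(0)), background)
  expect_true(all(res3$p == 1))
})

test_that("correlation skew detects planted repression and nothing else", {
  st <- default_study()
  prep <- default_prep()
  skew <- correlation_skew(prep$norm_mirna, prep$norm_mrna, st$target_map,
                           prep$metadata, site = "macula",
                           n_background = 50000, seed = 5)
  ev <- intersect(st$truth$evidence_mirna, skew$mirna)
  expect_gte(length(ev), 4)
  expect_true(all(skew$q[skew$mirna %in% ev] < 0.05))
  # very few non-planted miRNA reach significance
  expect_lt(mean(skew$q[!skew$mirna %in% ev] < 0.05), 0.05)
  expect_true(all(skew$ks_d >= 0 & skew$ks_d <= 1))

  # determinism given the seed
  skew2 <- correlation_skew(prep$norm_mirna, prep$norm_mrna, st$target_map,
                            prep$metadata, site = "macula",
                            n_background = 50000, seed = 5)
  expect_identical(skew, skew2)
})

test_that("the sampled background excludes known pairs and an extreme target maxes the statistic", {
  set.seed(44)
  n_s <- 12
  # one miRNA whose single-target correlation is the sample minimum
  mirna <- matrix(rnorm(2 * n_s), 2, n_s, dimnames = list(c("mA", "mB"), paste0("s", 1:n_s)))
  mrna <- rbind(anti = -mirna["mA", ],                      # rho = -1 with mA
                matrix(rnorm(30 * n_s), 30, n_s))
  rownames(mrna)[-1] <- paste0("g", 1:30)
  colnames(mrna) <- paste0("s", 1:n_s)
  map <- tibble::tibble(mirna = "mA", target = c("anti", paste0("g", 1:9)))
  res <- correlation_skew(mirna, mrna, map, min_targets = 10,
                          n_background = 5000, seed = 1)
  expect_equal(res$n_targets, 10L)
  # one of ten targets sits at the extreme low end of the scale
  expect_gte(res$ks_d, 0.1)

  single <- correlation_skew(mirna, mrna, map[1, ], min_targets = 1,
                             n_background = 5000, seed = 1)
  expect_gt(single$ks_d, 0.95)   # one target at the minimum of the scale

  # a map covering every pair except one leaves only that pair available
  # for background sampling
  full_map <- tidyr::expand_grid(mirna = c("mA", "mB"),
                                 target = rownames(mrna))
  full_map <- full_map[-1, ]     # (mA, anti) stays non-interacting
  res2 <- correlation_skew(mirna, mrna, full_map[full_map$mirna == "mB", ],
                           min_targets = 5, n_background = 1000, seed = 2)
  expect_s3_class(res2, "tbl_df")
})

test_that("evidence integration requires all three lines of evidence", {
  de <- tibble::tibble(transcript_id = c("m1", "m2"), site = "macula",
                       q = c(0.001, 0.4))
  t_ora <- tibble::tibble(set = "DE", mirna = c("m1", "m3"), q = c(0.01, 0.01))
  skew <- tibble::tibble(mirna = c("m1", "m4"), q = c(0.02, 0.01))
  ev <- integrate_evidence(de, list(macula = c("m4")), t_ora, skew,
                           mirna_ids = c("m1", "m2", "m3", "m4"))
  expect_identical(ev$final_call, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(ev$dp[ev$mirna == "m4"])     # skew + dp but no target enrichment

  # empty inputs give an empty table
  e0 <- integrate_evidence(de[0, ], list(), t_ora[0, ], skew[0, ], character(0))
  expect_equal(nrow(e0), 0)

  # the planted complete-evidence miRNA pass end-to-end, planted
  # single-evidence miRNA do not
  st <- default_study()
  prep <- default_prep()
  de_full <- default_de()
  mrna_bg <- prep$universe$id[prep$universe$kind == "mRNA"]
  de_sets <- lapply(c(macula = "macula", periphery = "periphery"), function(s) {
    de_full$transcript_id[de_full$site == s &
                            de_full$contrast == "NPDR_PDR_DME_vs_Healthy" &
                            de_full$q < 0.05]
  })
  t_ora2 <- target_ora(st$target_map,
                       lapply(de_sets, intersect, mrna_bg), mrna_bg)
  skew2 <- correlation_skew(prep$norm_mirna, prep$norm_mrna, st$target_map,
                            prep$metadata, site = "macula",
                            n_background = 50000, seed = 5)
  evt <- integrate_evidence(de_full, list(), t_ora2, skew2,
                            mirna_ids = rownames(prep$norm_mirna))
  planted <- intersect(st$truth$evidence_mirna, evt$mirna)
  expect_gte(length(planted), 4)
  expect_true(all(evt$final_call[evt$mirna %in% planted]))
  # miRNA with progression evidence only (planted ordinary DP miRNA) fail
  dp_only <- setdiff(intersect(st$truth$dp_transcripts, evt$mirna), planted)
  expect_false(any(evt$final_call[evt$mirna %in% dp_only]))
})
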