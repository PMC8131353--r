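test_that("stage encoding maps groups and masks late proliferative samples", {
  meta <- tibble::tibble(group = c("Healthy", "Diabetic", "NPDR", "NPDR_DME", "PDR_DME"))
  enc <- encode_stages(meta, d_diabetic = 1, d_npdr = 2)
  expect_equal(enc$y, c(0, 1, 2, 3))
  expect_identical(enc$included, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  # no ordering is imposed between the two free positions
  enc2 <- encode_stages(meta, d_diabetic = 2.5, d_npdr = 0.5)
  expect_equal(enc2$y, c(0, 2.5, 0.5, 3))

  expect_error(encode_stages(meta, d_diabetic = 0.05, d_npdr = 1), "out of")
  expect_error(encode_stages(meta, d_diabetic = 1, d_npdr = 3), "out of")
})

test_that("Spearman ranking matches the brute-force oracle", {
  set.seed(17)
  X <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rnorm(10)
  rk <- rank_features_spearman(X, y)
  brute <- vapply(colnames(X), function(j) cor(X[, j], y, method = "spearman"), 0)
  expect_equal(setNames(rk$rho, rk$feature), brute[rk$feature], tolerance = 1e-12)
  expect_identical(rk$feature, names(sort(-abs(brute))))

  # a feature equal to the target ranks first with |rho| = 1, sign ignored
  X2 <- cbind(X, hit = y, anti = -y)
  rk2 <- rank_features_spearman(X2, y)
  expect_setequal(rk2$feature[1:2], c("hit", "anti"))
  expect_equal(abs(rk2$rho[1:2]), c(1, 1))

  # constant features are treated as uncorrelated
  X3 <- cbind(X, flat = rep(3, 10))
  rk3 <- rank_features_spearman(X3, y)
  expect_equal(rk3$rho[rk3$feature == "flat"], 0)
})

test_that("cross-validated RMSE is sane on degenerate, null and planted data", {
  set.seed(23)
  n <- 40
  meta <- tibble::tibble(sample_id = paste0("s", 1:n),
                         group = rep(c("Healthy", "Diabetic", "NPDR", "NPDR_DME"), each = 10))
  hyper <- list(d_diabetic = 1, d_npdr = 2, n = 30, eta = 0.5, K = 2)
  spec <- cv_spec(folds = 5, repeats = 3, seed = 7)

  # pure-noise features cannot beat the mean-only predictor by much
  Xn <- matrix(rnorm(n * 60), n, 60, dimnames = list(meta$sample_id, paste0("f", 1:60)))
  rn <- cv_rmse(Xn, meta, hyper, spec)
  y <- c(0, 1, 2, 3)[match(meta$group, c("Healthy", "Diabetic", "NPDR", "NPDR_DME"))]
  baseline <- sqrt(mean((y - mean(y))^2))
  expect_gte(rn, baseline * 0.95)

  # planted signal cuts the error well below the baseline
  Xs <- Xn
  Xs[, 1:10] <- Xs[, 1:10] + outer(y, rep(2, 10))
  rs <- cv_rmse(Xs, meta, hyper, spec)
  expect_lt(rs, baseline * 0.7)

  # feature order permutation leaves the objective unchanged exactly
  perm <- sample(ncol(Xs))
  expect_identical(cv_rmse(Xs[, perm], meta, hyper, spec), rs)

  # constant target: the model backs off to the mean predictor
  meta0 <- tibble::tibble(sample_id = paste0("s", 1:20), group = rep("Healthy", 20))
  X0 <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(meta0$sample_id, paste0("f", 1:10)))
  expect_equal(cv_rmse(X0, meta0, hyper, cv_spec(4, 2, seed = 1)), 0)
})

test_that("progression search respects its budget and selection contracts", {
  st <- simulate_study(progression_demo_config(seed = 2, n_mrna = 250,
                                               n_celltypes = 4, markers_per_type = 5,
                                               cells_per_type = 10))
  prep <- preprocess_study(st, gmm = FALSE)
  dp <- find_dp_transcripts(prep$norm_mrna, prep$metadata, site = "macula",
                            cvspec = cv_spec(folds = 3, repeats = 2, seed = 2),
                            optconfig = scatter_search_config(max_evaluations = 60, seed = 2))
  expect_lte(dp$n_evals, 60)
  expect_true(all(dp$dp_transcripts %in% rownames(prep$norm_mrna)))
  expect_lte(length(dp$dp_transcripts), dp$best$n)

  # selected features lie within the top-n Spearman-ranked features of the
  # full fit
  enc <- encode_stages(prep$metadata[prep$metadata$site == "macula", ],
                       dp$best$d_diabetic, dp$best$d_npdr)
  Xs <- t(prep$norm_mrna[, prep$metadata$sample_id[prep$metadata$site == "macula"]])
  rk <- rank_features_spearman(Xs[enc$included, ], enc$y)
  expect_true(all(dp$dp_transcripts %in% rk$feature[seq_len(dp$best$n)]))

  # the trace carries the hyperparameters of every improvement
  expect_named(dp$trace, c("evaluation", "rmse", "d_diabetic", "d_npdr", "n", "eta", "K"))
  expect_true(all(diff(dp$trace$rmse) < 0))
  expect_s3_class(glance(dp), "tbl_df")
  expect_s3_class(autoplot(dp), "gg")
})

test_that("combining site sets reproduces printed identities", {
  # sizes as printed for the two sample sites of the retinal study
  N <- 15329
  A <- sprintf("t%05d", 1:1322)
  B <- c(sprintf("t%05d", 1:105), sprintf("u%05d", 1:180))
  comb <- combine_dp_sets(A, B, N)
  expect_equal(comb$n_union, 1502)
  expect_equal(comb$n_intersect, 105)
  expect_equal(round(comb$fold_enrichment, 2), 4.27)
  expect_lt(comb$p, 1e-39)

  # disjoint sets
  d <- combine_dp_sets(c("a", "b"), c("c", "d"), 100)
  expect_equal(d$n_union, 4)
  expect_equal(d$fold_enrichment, 0)

  # identical sets: fold-enrichment is N / |A|
  s <- combine_dp_sets(c("a", "b", "c", "d"), c("a", "b", "c", "d"), 100)
  expect_equal(s$fold_enrichment, 100 / 4)
})
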