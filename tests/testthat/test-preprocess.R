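test_that("log2 CPM matches direct arithmetic and its invariants", {
  counts <- matrix(c(0L, 999999L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  # single sample, library ~1e6
  norm <- log2_cpm(counts)
  expect_equal(norm["a", 1], log2(0.5 / (999999 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(norm["a", 1], -1, tolerance = 1e-4)
  expect_equal(norm["b", 1], log2((999999 + 0.5) / (999999 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(norm["b", 1], 19.93, tolerance = 1e-2)

  # near-invariance to doubling counts and libraries
  set.seed(1)
  m <- matrix(rpois(300, 40), 30, 10, dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  expect_equal(log2_cpm(2L * m), log2_cpm(m), tolerance = 1e-3, ignore_attr = TRUE)

  # additive-offset column identity: sum of linear values is determined
  # exactly by the library size and transcript count
  lin <- 2^log2_cpm(m)
  lib <- colSums(m)
  expect_equal(colSums(lin), (lib + 0.5 * nrow(m)) / (lib + 1) * 1e6,
               tolerance = 1e-9, ignore_attr = TRUE)

  m[, 3] <- 0L
  expect_error(log2_cpm(m), "s3")
})

test_that("mRNA filter removes silent and low-mode transcripts deterministically", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:20),
                         group = rep(c("Healthy", "NPDR_DME"), each = 10))
  # planted bimodal means: low mode around 1 CPM, high mode around 256 CPM
  set.seed(7)
  n_low <- 150; n_high <- 350
  mu_cpm <- c(2^rnorm(n_low, 1, 0.5), 2^rnorm(n_high, 8, 0.5))
  counts <- t(vapply(mu_cpm, function(mu) rpois(20, mu), numeric(20)))
  counts <- rbind(counts, 0)   # an all-zero transcript
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  colnames(counts) <- meta$sample_id
  # scale columns to ~1e6 reads so CPM ~ count
  storage.mode(counts) <- "integer"
  f1 <- filter_mrna(counts, meta, cpm_min = 10, min_group_size = 10, gmm = TRUE)
  f2 <- filter_mrna(counts, meta, cpm_min = 10, min_group_size = 10, gmm = TRUE)

  expect_false(paste0("g", nrow(counts)) %in% f1$kept)        # all-zero removed
  high_ids <- paste0("g", (n_low + 1):(n_low + n_high))
  expect_gte(mean(high_ids %in% f1$kept), 0.99)               # high mode survives
  expect_lt(mean(paste0("g", 1:n_low) %in% f1$kept), 0.2)     # low mode dropped
  expect_identical(f1$kept, f2$kept)                          # deterministic
  expect_equal(f1$report$stage, c("input", "min_count", "gaussian_mixture"))
})

test_that("miRNA filter applies the CPM > 100 rule", {
  lib <- 1e6
  counts <- matrix(as.integer(c(101, 50, 95, 99, 2000, 1500)), 3, 2, byrow = TRUE,
                   dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  # make library sizes ~1e6 by adding a filler row
  filler <- matrix(as.integer(lib - colSums(counts)), 1, 2,
                   dimnames = list("filler", colnames(counts)))
  norm <- log2_cpm(rbind(counts, filler))
  kept <- filter_mirna(norm[1:3, , drop = FALSE])
  expect_true("m1" %in% kept)     # 101 CPM in one sample is enough
  expect_false("m2" %in% kept)    # never above 100 CPM
  expect_true("m3" %in% kept)

  # kept count agrees with a brute-force recount on the synthetic study
  st <- default_study()
  nm <- log2_cpm(st$counts_mirna)
  kept2 <- filter_mirna(nm)
  brute <- rownames(nm)[apply(nm, 1, function(x) any(x > log2(100)))]
  expect_identical(kept2, brute)
})

test_that("replicate detection flags one sample per correlated pair", {
  set.seed(3)
  base <- matrix(rnorm(200 * 4, 5, 2), 200, 4)
  norm <- cbind(base[, 1], base[, 1],               # exact duplicates (r = 1)
                base[, 2] + rnorm(200, 0, 1.5),     # independent-ish pair
                base[, 2] + rnorm(200, 0, 1.5),
                base[, 3], base[, 3], base[, 3])    # triple of duplicates
  colnames(norm) <- paste0("s", 1:7)
  attr(norm, "library_sizes") <- setNames(c(10, 20, 10, 10, 10, 30, 10), colnames(norm))
  meta <- tibble::tibble(
    sample_id = colnames(norm),
    donor_id = c("d1", "d1", "d2", "d2", "d3", "d3", "d3"),
    site = "macula",
    eye = c("L", "R", "L", "R", "L", "R", "R")
  )
  rm <- detect_replicates(norm, meta)
  expect_identical(sort(rm[startsWith(rm, "s1") | rm %in% c("s1", "s2")]), "s1")  # keeps larger library
  expect_false(any(c("s3", "s4") %in% rm))            # below threshold
  expect_identical(sort(intersect(rm, c("s5", "s6", "s7"))), c("s5", "s7"))  # two of three flagged

  # different donors are never flagged even when identical
  meta2 <- meta; meta2$donor_id <- paste0("d", 1:7)
  expect_length(detect_replicates(norm, meta2), 0)

  # on the synthetic study, exactly the planted replicates are removed
  st <- default_study(); prep <- default_prep()
  planted <- names(st$truth$replicate_of)[st$truth$replicate_of != names(st$truth$replicate_of)]
  partners <- unname(st$truth$replicate_of[planted])
  expect_length(prep$removed_samples, length(planted))
  expect_true(all(prep$removed_samples %in% c(planted, partners)))
})

test_that("the surrogate variable recovers a planted batch effect", {
  st <- default_study()
  prep <- default_prep()
  sv <- prep$sv
  expect_equal(sum(sv$loadings[, 1]^2), 1, tolerance = 1e-9)
  batch <- st$truth$batch[prep$metadata$sample_id]
  expect_gt(abs(cor(sv$loadings[, 1], batch)), 0.9)

  # paired comparison: without a confounder the leading residual direction
  # explains less variance
  st0 <- simulate_study(simulation_config(seed = 5, confounder_strength = 0))
  prep0 <- preprocess_study(st0)
  expect_gt(sv$variance_explained[1], prep0$sv$variance_explained[1])

  expect_error(
    estimate_surrogate_variable(prep$norm_mrna,
                                dplyr::mutate(prep$metadata, dupe = group),
                                protected = c("group", "dupe")),
    "rank-deficient"
  )
})

test_that("residualization removes significant covariate effects and is idempotent", {
  set.seed(11)
  n <- 40
  age <- rnorm(n, 70, 8)
  sv <- rnorm(n)
  norm <- rbind(
    exact = 2 + 0.1 * age,                       # perfect age fit
    indep = rnorm(n, 5, 1),                      # independent of covariates
    hit = 3 + 0.5 * sv + rnorm(n, 0, 0.2)        # strong SV effect
  )
  colnames(norm) <- paste0("s", 1:n)
  covs <- data.frame(age = age, sv = sv)
  out <- residualize(norm, covs)
  expect_equal(unname(out["exact", ]), rep(2, n), tolerance = 1e-9)
  expect_identical(unname(out["indep", ]), unname(norm["indep", ]))
  expect_true(all(c("exact", "hit") %in% attr(out, "corrected")))

  # refitting on corrected values: slopes are (numerically) zero
  X <- cbind(1, age, sv)
  b <- solve(crossprod(X), crossprod(X, out["hit", ]))
  expect_equal(unname(b[2:3]), c(0, 0), tolerance = 1e-10)

  # idempotence of the corrected values
  out2 <- residualize(out, covs)
  expect_equal(unname(out2), unname(out), tolerance = 1e-9, ignore_attr = TRUE)
  expect_false("hit" %in% attr(out2, "corrected"))

  expect_warning(residualize(norm, data.frame(age = age, const = rep(1, n))),
                 "constant")
})

test_that("top-variance PCA separates planted clusters and matches the eigen oracle", {
  set.seed(9)
  n <- 30
  shift <- rep(c(0, 6), each = n / 2)
  norm <- rbind(
    matrix(rnorm(20 * n), 20, n) + matrix(shift, 20, n, byrow = TRUE),  # separating axis
    matrix(rnorm(60 * n, 0, 0.5), 60, n)
  )
  rownames(norm) <- paste0("g", 1:80); colnames(norm) <- paste0("s", 1:n)
  pca <- pca_top_variable(norm, n_features = 25)
  g1 <- pca$scores$PC1[1:(n / 2)]; g2 <- pca$scores$PC1[(n / 2 + 1):n]
  # the two clouds are fully separated on PC1
  expect_true(max(range(g1)) < min(range(g2)) || min(range(g1)) > max(range(g2)))

  # cumulative R2 equals the brute-force eigenvalue ratio
  v <- apply(norm, 1, var)
  top <- order(v, decreasing = TRUE)[1:25]
  ev <- eigen(stats::cov(t(norm[top, ])), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pca$cum_r2, sum(ev[1:2]) / sum(ev), tolerance = 1e-9)
  expect_lte(pca$cum_r2, 1)

  # duplicated sample gives identical scores
  norm2 <- cbind(norm, dup = norm[, 1])
  pca2 <- pca_top_variable(norm2, n_features = 25)
  expect_equal(unname(unlist(pca2$scores[n + 1, -1])),
               unname(unlist(pca2$scores[1, -1])), tolerance = 1e-9)

  expect_warning(pca_top_variable(norm, n_features = 500), "using all")
})
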