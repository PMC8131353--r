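test_that("the vectorized rank-sum test matches wilcox.test", {
  sc <- toy_sc_ref()
  M <- sc_lognormalize(sc$counts)
  in_g <- sc$cells$type == "T1"
  R <- t(apply(M[1:5, ], 1, rank))
  tie_term <- apply(M[1:5, ], 1, function(x) { r <- rle(sort(x))$lengths; sum(r^3 - r) })
  p_fast <- retinaprog:::rank_sum_greater(R, tie_term, in_g)
  p_ref <- vapply(1:5, function(i) {
    wilcox.test(M[i, in_g], M[i, !in_g], alternative = "greater", exact = FALSE)$p.value
  }, 0)
  expect_equal(unname(p_fast), p_ref, tolerance = 1e-10)
})

test_that("unique markers are recovered from a planted reference", {
  sc <- toy_sc_ref()
  mk <- find_markers(sc)
  # no gene is claimed by two types
  expect_equal(anyDuplicated(mk$gene), 0L)
  # planted markers are recovered for their own type
  recovered <- vapply(names(sc$markers), function(t) {
    mean(sc$markers[[t]] %in% mk$gene[mk$celltype == t])
  }, 0)
  expect_true(all(recovered >= 0.9))
  # uniform genes are not markers
  expect_lt(mean(setdiff(rownames(sc$counts), unlist(sc$markers)) %in% mk$gene), 0.05)

  # restricting to a bulk universe restricts the result
  mk2 <- find_markers(sc, bulk_gene_universe = rownames(sc$counts)[1:100])
  expect_true(all(mk2$gene %in% rownames(sc$counts)[1:100]))

  # a gene expressed in one type only is that type's marker
  counts <- sc$counts
  counts["g300", ] <- 0L
  counts["g300", sc$cells$type == "T2"] <- 50L
  mk3 <- find_markers(list(counts = counts, cells = sc$cells))
  expect_identical(mk3$celltype[mk3$gene == "g300"], "T2")

  # tiny types are skipped with a warning
  cells_small <- sc$cells
  cells_small$type[cells_small$type == "T4"] <- "T1"
  cells_small$type[1:2] <- "T4"
  expect_warning(find_markers(list(counts = sc$counts, cells = cells_small)),
                 "skipping type")
})

test_that("downsampling caps each type deterministically", {
  sc <- toy_sc_ref(cells_per_type = 30, subjects = 1)
  # T1 gets 98 cells in total via relabeling, others keep 30
  cells <- sc$cells
  down <- downsample_cells(list(counts = sc$counts, cells = cells), cap = 500, seed = 1)
  expect_identical(down$cells, cells)          # all types below the cap

  down2 <- downsample_cells(list(counts = sc$counts, cells = cells), cap = 10, seed = 1)
  expect_true(all(table(down2$cells$type) == 10))
  down3 <- downsample_cells(list(counts = sc$counts, cells = cells), cap = 10, seed = 1)
  expect_identical(down2$cells$cell_id, down3$cells$cell_id)
  expect_identical(colnames(down2$counts), down2$cells$cell_id)
})

test_that("marker over-representation counts match brute-force set algebra", {
  mk <- tibble::tibble(gene = c("g1", "g2", "g3", "g4", "g5"),
                       celltype = c("A", "A", "A", "B", "B"))
  background <- paste0("g", 1:50)
  disease <- c("g1", "g2", "g10", "g11")
  res <- marker_ora(disease, mk, background)
  a <- res[res$celltype == "A", ]
  expect_equal(a$k, 2L); expect_equal(a$K, 3L); expect_equal(a$n, 4L); expect_equal(a$N, 50L)
  expect_equal(a$p, hypergeom_test(2, 3, 4, 50))
  expect_equal(res$q, bh_adjust(res$p))

  # disjoint disease genes: all p = 1
  res0 <- marker_ora(c("g40", "g41"), mk, background)
  expect_true(all(res0$p == 1))
})

test_that("deconvolution recovers constructed mixtures exactly", {
  sc <- toy_sc_ref()
  sig <- retinaprog:::build_signatures(sc)$signatures

  # pure pseudo-bulk of one type: indicator proportions
  pure <- matrix(sig[, "T2"], ncol = 1, dimnames = list(rownames(sig), "pure"))
  d1 <- deconvolve(pure, sc, bulk_scale = "linear")
  expect_equal(unname(d1$proportions["pure", ]), c(0, 1, 0, 0), tolerance = 1e-6)
  expect_lt(d1$residual_norm, 1e-8)

  # noiseless 60/40 mixture recovered within 0.01
  mix <- matrix(0.6 * sig[, "T1"] + 0.4 * sig[, "T3"], ncol = 1,
                dimnames = list(rownames(sig), "mix"))
  d2 <- deconvolve(mix, sc, bulk_scale = "linear")
  expect_equal(unname(d2$proportions["mix", ]), c(0.6, 0, 0.4, 0), tolerance = 0.01)

  # proportions are invariant to global scaling of the bulk profile
  d3 <- deconvolve(1000 * mix, sc, bulk_scale = "linear")
  expect_equal(d3$proportions, d2$proportions, tolerance = 1e-9)

  # rows are a simplex and the residual trace never increases
  expect_equal(unname(rowSums(d2$proportions)), 1, tolerance = 1e-6)
  expect_true(all(vapply(d2$residual_trace, function(tr) all(diff(tr) <= 1e-12), TRUE)))

  expect_error(deconvolve(matrix(0, nrow(sig), 1, dimnames = list(rownames(sig), "z")),
                          sc, bulk_scale = "linear"), "all-zero")
})

test_that("the synthetic cohort shows the planted decline in ganglion cell abundance", {
  st <- default_study()
  prep <- default_prep()
  dec <- deconvolve(prep$norm_mrna, st$sc_ref)
  est <- dec$proportions
  grp <- prep$metadata$group[match(rownames(est), prep$metadata$sample_id)]
  rgc_means <- tapply(est[, "RGC"], grp, mean)[c("Healthy", "Diabetic", "NPDR", "NPDR_DME")]
  expect_true(all(diff(rgc_means) < 0))
  expect_true(all(vapply(dec$residual_trace, function(tr) all(diff(tr) <= 1e-12), TRUE)))
})

test_that("cell-type pathway analysis tests within-type families", {
  mk <- tibble::tibble(gene = sprintf("g%03d", 1:40),
                       celltype = rep(c("A", "B"), each = 20))
  background <- sprintf("g%03d", 1:200)
  sets <- list(
    PW1 = sprintf("g%03d", c(1:10, 101:110)),     # overlaps A's markers
    PW2 = sprintf("g%03d", 111:130),
    PW3 = sprintf("g%03d", c(21:30, 131:140))     # overlaps B's markers
  )
  disease <- sprintf("g%03d", c(1:10, 21:25))
  res <- celltype_pathway_ora(disease, mk, new_gene_set_collection(sets),
                              background, alpha = 0.01, min_overlap = 10)
  a <- res[res$celltype == "A", ]
  expect_equal(a$q, bh_adjust(a$p))   # BH within the cell type
  expect_true(res$significant[res$celltype == "A" & res$set == "PW1"])
  expect_false(any(res$significant[res$celltype == "B" & res$set == "PW1"]))

  # a type whose disease intersection is empty contributes no rows
  res2 <- celltype_pathway_ora(sprintf("g%03d", 150:160), mk,
                               new_gene_set_collection(sets), background,
                               min_overlap = 10)
  expect_equal(nrow(res2), 0)
})
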