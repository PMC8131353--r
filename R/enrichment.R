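# Gene-set statistics: GMT I/O, the exact hypergeometric tail,
# over-representation analysis with the min-overlap and category exclusion
# rules, and a bidirectional fold-change-distribution ("GAGE-style") test.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene ids; duplicates within
#'   a set are removed with a warning).
#' @param category Optional character vector, one category per set.
#' @param source Free-text source tag.
#' @return A `gene_set_collection`: list with `sets` (named list) and
#'   `meta` (tibble: set, category, size, source).
#' @export
new_gene_set_collection <- function(sets, category = NULL, source = "unknown") {
  stop_if_not(is.list(sets) && !is.null(names(sets)), "sets must be a named list")
  dup <- vapply(sets, anyDuplicated, 0L) > 0
  if (any(dup)) {
    warning("duplicate gene ids removed in set(s): ", paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (is.null(category)) category <- rep(NA_character_, length(sets))
  structure(list(
    sets = sets,
    meta = tibble::tibble(
      set = names(sets),
      category = category,
      size = unname(lengths(sets)),
      source = source
    )
  ), class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then gene ids. A
#' description of the form `category=...` is parsed into the category
#' column.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("malformed GMT line(s) (need name, description, >=1 gene): line ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  desc <- vapply(parts, `[[`, "", 2)
  category <- ifelse(grepl("^category=", desc), sub("^category=", "", desc), NA_character_)
  new_gene_set_collection(sets, category = category, source = path)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stop_if_not(inherits(collection, "gene_set_collection"), "need a gene_set_collection")
  desc <- ifelse(is.na(collection$meta$category), "na",
                 paste0("category=", collection$meta$category))
  lines <- mapply(function(name, d, genes) {
    paste(c(name, d, genes), collapse = "\t")
  }, names(collection$sets), desc, collection$sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Upper-tail hypergeometric test P[X >= k]
#'
#' Probability of drawing at least `k` marked elements when `n` elements
#' are drawn without replacement from a background of `N` containing `K`
#' marked ones. Computed in log space via the exact tail sum.
#'
#' @param k Observed overlap.
#' @param K Marked elements in the background (set size within background).
#' @param n Draw (query) size.
#' @param N Background size.
#' @return p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  stop_if_not(all(c(k, K, n, N) >= 0) && K <= N && n <= N && k <= min(K, n),
              "inconsistent hypergeometric counts: need k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of an overlap
#'
#' Observed overlap divided by its hypergeometric expectation `K * n / N`.
#'
#' @inheritParams hypergeom_test
#' @return Fold-enrichment (0 when the expectation is 0).
#' @export
fold_enrichment <- function(k, K, n, N) {
  expected <- K * n / N
  if (expected == 0) return(0)
  k / expected
}

#' Over-representation analysis of a query gene set
#'
#' Hypergeometric upper-tail test of a query set against each gene set,
#' over a fixed background. Sets whose overlap with the background is
#' below `min_overlap` and sets in `excluded_categories` are removed
#' before testing; the Benjamini-Hochberg family is exactly the surviving
#' sets.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param collection A `gene_set_collection` (or named list of sets).
#' @param background Character vector of background gene ids.
#' @param min_overlap Minimum set-background overlap for a set to be
#'   tested (default 10).
#' @param excluded_categories Category labels excluded from testing.
#' @return Tibble: set, category, k, K, n, N, fold_enrichment, p, q,
#'   sorted by p.
#' @export
ora <- function(query, collection, background, min_overlap = 10,
                excluded_categories = c("Human Diseases", "Drug Development")) {
  if (!inherits(collection, "gene_set_collection")) {
    collection <- new_gene_set_collection(collection)
  }
  extra <- setdiff(query, background)
  if (length(extra) > 0) {
    stop("query ids missing from background: ", paste(head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ..." else "", call. = FALSE)
  }
  background <- unique(background)
  query <- unique(query)
  keep_cat <- is.na(collection$meta$category) | !(collection$meta$category %in% excluded_categories)
  sets_bg <- lapply(collection$sets, intersect, background)
  keep <- keep_cat & lengths(sets_bg) >= min_overlap
  sets_bg <- sets_bg[keep]
  N <- length(background)
  n <- length(query)
  res <- tibble::tibble(
    set = names(sets_bg),
    category = collection$meta$category[keep],
    k = unname(vapply(sets_bg, function(s) length(intersect(s, query)), 0L)),
    K = unname(lengths(sets_bg)),
    n = n,
    N = N
  )
  res$fold_enrichment <- unname(mapply(fold_enrichment, res$k, res$K, res$n, res$N))
  res$p <- unname(mapply(hypergeom_test, res$k, res$K, res$n, res$N))
  res$q <- bh_adjust(res$p)
  dplyr::arrange(res, .data$p)
}

#' Bidirectional fold-change-distribution gene-set test
#'
#' For each set, tests whether the absolute per-gene statistics (e.g. log2
#' fold changes vs control) of set members are larger than those of the
#' background, via a one-sided two-sample Wilcoxon rank-sum test. Testing
#' `|stat|` makes the test bidirectional: coherent shifts in either
#' direction count (the `same.dir = FALSE` contract); the rank-sum form
#' keeps the null exactly calibrated for the skewed distribution of
#' absolute statistics. Sets overlapping the background in more than
#' `max_size` genes or fewer than 2 are excluded.
#'
#' @param stats Named numeric vector of per-gene statistics (the names are
#'   the background universe).
#' @param collection A `gene_set_collection` (or named list).
#' @param max_size Maximum set-background overlap (default 2000).
#' @param min_size Minimum overlap to test (default 2).
#' @return Tibble: set, size_used, stat (rank-sum statistic), p, q,
#'   sorted by p.
#' @export
gage_test <- function(stats, collection, max_size = 2000, min_size = 2) {
  if (!inherits(collection, "gene_set_collection")) {
    collection <- new_gene_set_collection(collection)
  }
  stop_if_not(!is.null(names(stats)), "stats must be a named vector")
  universe <- names(stats)
  a <- abs(stats)
  sets_bg <- lapply(collection$sets, intersect, universe)
  keep <- lengths(sets_bg) >= min_size & lengths(sets_bg) <= max_size
  sets_bg <- sets_bg[keep]
  out <- purrr::map2_dfr(names(sets_bg), sets_bg, function(nm, members) {
    x <- a[members]
    y <- a[setdiff(universe, members)]
    if (sd(x) == 0 && sd(y) == 0) {
      return(tibble::tibble(set = nm, size_used = length(x), stat = 0, p = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater", exact = FALSE))
    tibble::tibble(set = nm, size_used = length(x),
                   stat = unname(wt$statistic), p = wt$p.value)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(set = character(0), size_used = integer(0),
                          stat = numeric(0), p = numeric(0), q = numeric(0)))
  }
  out$q <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p)
}

#' Direction of change of significant set members
#'
#' For each significant member of a gene set (BH q below `alpha` in the
#' supplied differential-expression results), reports the sign of its log2
#' fold change per site.
#'
#' @param set Character vector of gene ids.
#' @param de_results Tibble from [fit_de()] (one contrast).
#' @param alpha Significance threshold on `q`.
#' @return Tibble: transcript_id, site, log2fc, direction ("up"/"down").
#' @export
direction_summary <- function(set, de_results, alpha = 0.05) {
  de_results |>
    dplyr::filter(.data$transcript_id %in% set, .data$q < alpha) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    dplyr::select("transcript_id", "site", "log2fc", "direction")
}
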