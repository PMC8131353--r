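# Shared fixtures, built lazily and cached for the whole test session so
# the more expensive simulations run once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Default synthetic study with every planted structure, plus its
# preprocessing result.
default_study <- function() {
  fixture("default_study", function() simulate_study(simulation_config(seed = 5)))
}

default_prep <- function() {
  fixture("default_prep", function() preprocess_study(default_study()))
}

default_de <- function() {
  fixture("default_de", function() {
    prep <- default_prep()
    norm_all <- rbind(prep$norm_mrna, prep$norm_mirna)
    dplyr::bind_rows(
      fit_de(norm_all, prep$metadata, site = "macula"),
      fit_de(norm_all, prep$metadata, site = "periphery")
    )
  })
}

# Brute-force hypergeometric upper tail by exhaustive enumeration of all
# draws of size n from N elements of which the first K are marked.
enum_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# A small deterministic single-cell reference with planted unique markers:
# `markers_per_type` genes per type boosted 8-fold in their own type.
toy_sc_ref <- function(n_genes = 300, n_types = 4, cells_per_type = 60,
                       markers_per_type = 10, subjects = 2, seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  types <- paste0("T", seq_len(n_types))
  base <- rnorm(n_genes, 4, 1)
  sig <- matrix(base, n_genes, n_types, dimnames = list(genes, types))
  marker_genes <- split(genes[seq_len(n_types * markers_per_type)],
                        rep(types, each = markers_per_type))
  for (t in types) sig[marker_genes[[t]], t] <- sig[marker_genes[[t]], t] + 3
  n_cells <- n_types * cells_per_type * subjects
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n_cells)),
    type = rep(rep(types, each = cells_per_type), subjects),
    subject = rep(paste0("s", seq_len(subjects)), each = n_types * cells_per_type)
  )
  counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells$cell_id))
  for (i in seq_len(n_cells)) {
    rel <- 2^sig[, cells$type[i]]
    rel <- rel / sum(rel)
    counts[, i] <- rnbinom(n_genes, mu = rel * 4000, size = 1 / 0.3)
  }
  list(counts = counts, cells = cells, markers = marker_genes, signatures = sig)
}
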