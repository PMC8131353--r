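# Internal helpers shared across modules.

#' Disease group labels in stage order
#'
#' The five clinical groups used throughout the package. `PDR_DME` carries
#' the most severe grading but is excluded from the progression regression
#' (too few donors to anchor a stage position).
#'
#' @return Character vector of the five group labels.
#' @export
disease_groups <- function() {
  c("Healthy", "Diabetic", "NPDR", "NPDR_DME", "PDR_DME")
}

# Column ranks of a numeric matrix, ties broken by first occurrence.
# Single radix sort over all entries; orders of magnitude faster than
# apply(X, 2, rank) inside the cross-validation hot loop. Equals rank()
# exactly when columns have no ties (continuous expression values).
col_ranks <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  o <- order(rep.int(seq_len(p), rep.int(n, p)), as.vector(X))
  r <- integer(n * p)
  r[o] <- rep.int(seq_len(n), p)
  matrix(r, n, p, dimnames = dimnames(X))
}

# Column standard deviations without apply().
col_sds <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - m^2, 0) * n / (n - 1))
}

# Draw one Dirichlet vector with concentration vector alpha.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x <- alpha
  x / sum(x)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
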