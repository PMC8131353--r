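# Population-based scatter search for mixed integer/continuous
# box-constrained minimization: Latin-hypercube diversification, a
# reference set of best plus diverse members, pairwise convex
# (integer-rounded) recombination, replacement by quality and restart on
# stagnation. Built for expensive noisy objectives such as repeated
# cross-validation error; no local solver is used.

#' Scatter-search configuration
#'
#' @param max_evaluations Objective-call budget (never exceeded).
#' @param population LHS diversification size (default `10 * n_dim`,
#'   set at run time when `NULL`).
#' @param ref_size Reference-set size (best + diverse members).
#' @param stagnation Evaluations without improvement before the diverse
#'   part of the reference set is re-seeded.
#' @param seed Integer seed for the optimizer's randomness.
#' @return An `ss_config` list.
#' @export
scatter_search_config <- function(max_evaluations = 1000, population = NULL,
                                  ref_size = 10, stagnation = 50, seed = 1L) {
  structure(list(
    max_evaluations = max_evaluations, population = population,
    ref_size = ref_size, stagnation = stagnation, seed = as.integer(seed)
  ), class = "ss_config")
}

#' Minimize an objective by scatter search
#'
#' @param objective Function of a numeric vector returning a finite scalar.
#' @param lower,upper Numeric bounds per dimension.
#' @param integer Logical vector: which dimensions are integer-valued
#'   (rounded before every evaluation).
#' @param config An [scatter_search_config()].
#' @return List: `par` (best point), `value`, `n_evals`, and `trace`
#'   (tibble of every improvement: evaluation index, value, and the point).
#' @export
scatter_search <- function(objective, lower, upper, integer = NULL,
                           config = scatter_search_config()) {
  d <- length(lower)
  stop_if_not(length(upper) == d && all(upper >= lower), "invalid bounds")
  stop_if_not(all(is.finite(c(lower, upper))), "bounds must be finite")
  if (is.null(integer)) integer <- rep(FALSE, d)
  pop_size <- if (is.null(config$population)) 10L * d else config$population
  stop_if_not(config$max_evaluations >= pop_size,
              "evaluation budget must cover the initial population")
  set.seed(config$seed)

  clamp <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    x[integer] <- round(x[integer])
    x
  }
  n_evals <- 0L
  best_f <- Inf; best_x <- NULL
  last_improvement <- 0L
  trace <- list()
  evaluate <- function(x) {
    n_evals <<- n_evals + 1L
    f <- objective(x)
    if (f < best_f) {
      best_f <<- f; best_x <<- x
      last_improvement <<- n_evals
      trace[[length(trace) + 1L]] <<- c(evaluation = n_evals, value = f, x)
    }
    f
  }

  lhs_points <- function(m) {
    U <- lhs::randomLHS(m, d)
    t(apply(U, 1, function(u) clamp(lower + u * (upper - lower))))
  }

  # diversification + initial reference set
  P <- lhs_points(pop_size)
  fP <- apply(P, 1, evaluate)
  ref_size <- min(config$ref_size, pop_size)
  n_best <- ceiling(ref_size / 2)
  ord <- order(fP)
  ref_idx <- ord[seq_len(n_best)]
  # fill the diverse half by maximin distance to the current reference set
  scale_rng <- pmax(upper - lower, 1e-12)
  while (length(ref_idx) < ref_size) {
    cand <- setdiff(seq_len(pop_size), ref_idx)
    dmin <- vapply(cand, function(i) {
      min(vapply(ref_idx, function(j) {
        sqrt(sum(((P[i, ] - P[j, ]) / scale_rng)^2))
      }, 0))
    }, 0)
    ref_idx <- c(ref_idx, cand[which.max(dmin)])
  }
  refX <- P[ref_idx, , drop = FALSE]
  refF <- fP[ref_idx]

  while (n_evals < config$max_evaluations) {
    pairs <- utils::combn(nrow(refX), 2)
    # recombine the most promising pairs first so each generation spends
    # most of its budget refining around good members
    ord_pairs <- order(refF[pairs[1, ]] + refF[pairs[2, ]])
    n_pairs <- min(ncol(pairs), max(8, nrow(refX)))
    children <- matrix(NA_real_, 0, d)
    for (j in ord_pairs[seq_len(n_pairs)]) {
      if (n_evals + nrow(children) >= config$max_evaluations) break
      a <- refX[pairs[1, j], ]; b <- refX[pairs[2, j], ]
      u <- runif(d, -0.25, 1.25)
      children <- rbind(children, clamp(a + u * (b - a)))
    }
    # intensification around the incumbent: perturbations scaled by the
    # current reference-set spread, so steps shrink as the set collapses
    spread <- pmax(apply(refX, 2, function(col) diff(range(col))),
                   0.005 * (upper - lower))
    for (j in seq_len(max(0, min(4, config$max_evaluations - n_evals - nrow(children))))) {
      children <- rbind(children, clamp(best_x + spread * runif(d, -0.75, 0.75)))
    }
    if (nrow(children) == 0) break
    fC <- apply(children, 1, evaluate)
    allX <- rbind(refX, children)
    allF <- c(refF, fC)
    dup <- duplicated(round(allX, 10))
    allX <- allX[!dup, , drop = FALSE]; allF <- allF[!dup]
    ord <- order(allF)[seq_len(min(ref_size, length(allF)))]
    refX <- allX[ord, , drop = FALSE]; refF <- allF[ord]

    if (n_evals - last_improvement >= config$stagnation &&
        n_evals + ref_size - 1 <= config$max_evaluations) {
      # restart: keep the incumbent, re-seed the rest from a fresh LHS
      fresh <- lhs_points(ref_size - 1)
      fF <- apply(fresh, 1, evaluate)
      refX <- rbind(best_x, fresh)
      refF <- c(best_f, fF)
      last_improvement <- n_evals
    }
  }

  trace_tbl <- if (length(trace) > 0) {
    tm <- do.call(rbind, trace)
    colnames(tm) <- c("evaluation", "value", paste0("x", seq_len(d)))
    tibble::as_tibble(tm)
  } else {
    tibble::tibble(evaluation = integer(0), value = numeric(0))
  }
  list(par = best_x, value = best_f, n_evals = n_evals, trace = trace_tbl)
}
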