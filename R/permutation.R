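#' Permutation screen configuration
#'
#' @param S number of Monte-Carlo permutations per pair (5000 by default).
#' @param mode `"weighted"` for the complexity-corrected null (carriers
#'   redrawn proportional to [sample_weights()]), `"uniform"` for the
#'   complexity-independent variant (all samples equally likely).
#' @param seed root integer seed; every pair gets a deterministic
#'   substream keyed by `(seed, cat_a, cat_b)`, so results do not depend
#'   on pair-processing order.
#' @param min_cooccurrence pair-universe threshold, see [enumerate_pairs()].
#' @param alpha p-value cutoff used for the significance flag and the
#'   empirical FDR.
#' @param smooth_p if `TRUE`, report `(C + 1) / (S + 1)` instead of the
#'   plain `C / S` (off by default: `p = C/S` exactly, so `p` may be 0).
#' @return list of class `permutation_config`.
#' @export
permutation_config <- function(S = 5000L, mode = c("weighted", "uniform"),
                               seed = 1L, min_cooccurrence = 1L,
                               alpha = 0.02, smooth_p = FALSE) {
  mode <- match.arg(mode)
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("S must be >= 1")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  structure(list(S = S, mode = mode, seed = as.integer(seed),
                 min_cooccurrence = as.integer(min_cooccurrence),
                 alpha = alpha, smooth_p = isTRUE(smooth_p)),
            class = "permutation_config")
}

# deterministic 31-bit substream seed from root seed + category ids
pair_seed <- function(seed, j, k) {
  key <- utf8ToInt(paste(j, k, sep = "\r"))
  h <- as.numeric(seed) %% 2147483647
  for (c in key) h <- (h * 31 + c) %% 2147483647
  h + 1
}

# Monte-Carlo exceedance count with the pair in canonical (lexicographic)
# orientation, so the result is invariant to column order in the matrix
pair_exceedance <- function(weights, id_a, id_b, f_a, f_b, n11, S, seed) {
  if (id_b < id_a) {
    tmp <- id_a; id_a <- id_b; id_b <- tmp
    tmp <- f_a; f_a <- f_b; f_b <- tmp
  }
  cpp_pair_exceedance(weights, f_a, f_b, n11, S, pair_seed(seed, id_a, id_b))
}

#' Simulate one status column under the permutation null
#'
#' Redistributes a category's carriers over the cohort: `F_j` distinct
#' samples are drawn sequentially without replacement, each draw
#' proportional to the remaining samples' (renormalized) weights. The
#' simulated column preserves the observed carrier count exactly. With
#' `weights = NULL` all samples are equally likely (uniform mode).
#'
#' @param F_j carrier count to place.
#' @param weights per-sample probability weights, or `NULL` for uniform.
#' @param n cohort size (needed when `weights` is `NULL`).
#' @return integer 0/1 vector with exactly `F_j` ones; zero-weight samples
#'   are never selected. Uses R's global RNG stream.
#' @export
simulate_column <- function(F_j, weights = NULL, n = length(weights)) {
  F_j <- as.integer(F_j)
  if (is.null(weights)) {
    if (F_j > n) stop("carrier count exceeds cohort size")
    idx <- sample.int(n, F_j)
  } else {
    eligible <- sum(weights > 0)
    if (F_j > eligible) stop("carrier count exceeds eligible (positive-weight) samples")
    idx <- sample.int(n, F_j, prob = weights)
  }
  out <- integer(n)
  out[idx] <- 1L
  out
}

#' Permutation p-value for one category pair
#'
#' Runs the Monte-Carlo null for categories j and k: per iteration both
#' columns are simulated independently with their observed carrier counts,
#' the Jaccard index is recomputed, and the counter C records how often
#' the simulated overlap reaches the observed one (`J* >= J`). The p-value
#' is `C / S`.
#'
#' @param D a `cna_matrix`.
#' @param j,k category ids or column indices.
#' @param config a [permutation_config()].
#' @param weights per-sample weights; computed from `D` when `NULL` and
#'   mode is `"weighted"`.
#' @return list of class `association_result`: the [pair_statistics()]
#'   fields plus `C`, `p_value` and `significant`.
#' @export
pair_pvalue <- function(D, j, k, config = permutation_config(),
                        weights = NULL) {
  st <- pair_statistics(D, j, k)
  if (config$mode == "weighted") {
    if (is.null(weights)) weights <- sample_weights(D)
  } else {
    weights <- rep(1 / nrow(D), nrow(D))
  }
  C <- pair_exceedance(weights, st$cat_a, st$cat_b, st$F_a, st$F_b,
                       st$N11, config$S, config$seed)
  p <- if (config$smooth_p) (C + 1) / (config$S + 1) else C / config$S
  structure(c(st, list(C = C, p_value = p, significant = p <= config$alpha)),
            class = "association_result")
}

#' Exact null distribution oracle for tiny instances
#'
#' Independent reference implementation of the permutation null: every
#' ordered draw sequence for both columns is enumerated with its exact
#' probability (product of successively renormalized weights; uniform over
#' subsets in uniform mode) and the exceedance probability
#' `P(J* >= J_obs)` is summed exactly. Tractable only for small cohorts;
#' used to validate the Monte-Carlo engine.
#'
#' @param D a `cna_matrix` with at most 7 samples.
#' @param j,k category ids or column indices with carrier counts <= 3.
#' @param mode `"weighted"` or `"uniform"`.
#' @return exact p as a numeric scalar.
#' @export
exact_null_oracle <- function(D, j, k, mode = c("weighted", "uniform")) {
  mode <- match.arg(mode)
  st <- pair_statistics(D, j, k)
  w <- if (mode == "weighted") unname(sample_weights(D)) else
    rep(1 / nrow(D), nrow(D))
  exact_pair_null(w, st$F_a, st$F_b, st$N11)
}

#' @param weights per-sample weights (uniform mode: equal weights).
#' @param F_j,F_k carrier counts of the two columns.
#' @param N11_obs observed co-occurrence count.
#' @rdname exact_null_oracle
#' @export
exact_pair_null <- function(weights, F_j, F_k, N11_obs) {
  n <- length(weights)
  if (n > 7L || F_j > 3L || F_k > 3L) {
    stop("instance too large for exact enumeration (n <= 7, F <= 3)")
  }
  qa <- subset_probabilities(weights, F_j)
  qb <- subset_probabilities(weights, F_k)
  dobs <- F_j + F_k - N11_obs
  p <- 0
  for (ia in seq_along(qa$sets)) {
    A <- qa$sets[[ia]]
    for (ib in seq_along(qb$sets)) {
      n11 <- length(intersect(A, qb$sets[[ib]]))
      if (n11 * dobs >= N11_obs * (F_j + F_k - n11)) {
        p <- p + qa$prob[ia] * qb$prob[ib]
      }
    }
  }
  min(1, p) # guard float overshoot from summed enumeration
}

# distribution over carrier subsets under sequential weighted draws:
# enumerate every ordered tuple, accumulate probability per subset
subset_probabilities <- function(weights, f) {
  sets <- list()
  prob <- numeric(0)
  key <- character(0)
  recurse <- function(chosen, w, acc) {
    if (length(chosen) == f) {
      k <- paste(sort(chosen), collapse = ",")
      hit <- match(k, key)
      if (is.na(hit)) {
        sets[[length(sets) + 1L]] <<- sort(chosen)
        prob[length(prob) + 1L] <<- acc
        key[length(key) + 1L] <<- k
      } else {
        prob[hit] <<- prob[hit] + acc
      }
      return()
    }
    tot <- sum(w)
    for (i in which(w > 0)) {
      w2 <- w
      w2[i] <- 0
      recurse(c(chosen, i), w2, acc * w[i] / tot)
    }
  }
  if (f == 0L) return(list(sets = list(integer(0)), prob = 1))
  recurse(integer(0), weights, 1)
  list(sets = sets, prob = prob)
}

#' Run a full co-occurrence screen
#'
#' Computes the complexity weights once, enumerates the pair universe, and
#' evaluates every pair's permutation p-value with a deterministic per-pair
#' RNG substream. Output order and content are reproducible given
#' `(matrix, config)` and invariant to pair-processing order.
#'
#' @param D a `cna_matrix`.
#' @param config a [permutation_config()].
#' @return data.frame of class `association_table` with columns `cat_a`,
#'   `cat_b`, `N11`, `N10`, `N01`, `F_a`, `F_b`, `jaccard`, `frequency`,
#'   `class`, `bidirectional`, `p_value`, `significant`; the config is
#'   attached as attribute `config`.
#' @export
run_screen <- function(D, config = permutation_config()) {
  validate_status_matrix(D)
  weights <- if (config$mode == "weighted") unname(sample_weights(D)) else
    rep(1 / nrow(D), nrow(D))
  pairs <- enumerate_pairs(D, config$min_cooccurrence)
  M <- unclass(D)
  Fj <- colSums(M)
  n <- nrow(M)
  m <- nrow(pairs)
  out <- pairs
  out$N10 <- as.integer(Fj[pairs$cat_a] - pairs$N11)
  out$N01 <- as.integer(Fj[pairs$cat_b] - pairs$N11)
  out$F_a <- as.integer(Fj[pairs$cat_a])
  out$F_b <- as.integer(Fj[pairs$cat_b])
  den <- out$N11 + out$N10 + out$N01
  out$jaccard <- ifelse(den > 0, out$N11 / den, 0)
  out$frequency <- out$N11 / n
  pa <- parse_category(pairs$cat_a)
  pb <- parse_category(pairs$cat_b)
  intra <- pa$chrom == pb$chrom
  out$class <- ifelse(intra, "intra", "inter")
  out$bidirectional <- intra & (pa$direction != pb$direction)
  C <- integer(m)
  for (i in seq_len(m)) {
    C[i] <- pair_exceedance(weights, out$cat_a[i], out$cat_b[i],
                            out$F_a[i], out$F_b[i], out$N11[i],
                            config$S, config$seed)
  }
  out$p_value <- if (config$smooth_p) (C + 1) / (config$S + 1) else C / config$S
  out$significant <- out$p_value <= config$alpha
  out <- out[, c("cat_a", "cat_b", "N11", "N10", "N01", "F_a", "F_b",
                 "jaccard", "frequency", "class", "bidirectional",
                 "p_value", "significant")]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("association_table", class(out))
  out
}

#' Empirical false discovery rate at a p-value cutoff
#'
#' With M tested pairs and R of them at or below cutoff `alpha`, the
#' expected number of null pairs passing is `alpha * M`, giving
#' `FDR = alpha * M / R`, capped at 1. With no discoveries (R = 0) the
#' estimate is undefined and `NA` is returned.
#'
#' @param alpha p-value cutoff in (0, 1].
#' @param M total number of tested pairs.
#' @param R number of pairs with `p <= alpha`.
#' @return FDR estimate in \[0, 1\], or `NA`.
#' @export
estimate_fdr <- function(alpha, M, R) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (M < 0 || R < 0) stop("counts must be non-negative")
  if (R > M) stop("R cannot exceed M")
  if (R == 0) return(NA_real_)
  min(1, alpha * M / R)
}
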