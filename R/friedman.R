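#' Friedman test for paired (repeated-measures) frequency tables
#'
#' Nonparametric one-way ANOVA for repeated measures, implemented from the
#' rank formulas. Rows are blocks (duct segments), columns are conditions
#' (e.g. Spont and each drug). Each row is ranked with mid-ranks on ties;
#' with rank sums `R_j`,
#' \deqn{Q = \frac{\frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)}{C},
#'   \quad C = 1 - \frac{\sum (t^3 - t)}{n (k^3 - k)},}
#' the sum running over tie groups of size `t` within rows. The p-value uses
#' the chi-square approximation with `k - 1` degrees of freedom (the common
#' practice even at small `n`); an exact permutation p-value, obtained by
#' enumerating all within-row rank permutations, is available with
#' `exact = TRUE`. When every row is fully tied, `C = 0` and the convention
#' `Q = 0`, `p = 1` applies.
#'
#' @param table numeric matrix or data.frame, blocks x conditions, complete
#'   (missing cells are an error; no imputation).
#' @param exact also compute the exact permutation p-value
#'   (`Pr(Q* >= Q)` over all products of within-row rank permutations).
#' @param max_exact refuse exact enumeration beyond this many permutation
#'   states (guards against `k! ^ n` blow-up).
#' @return object of class `friedman_test`: `statistic` (Q), `df`,
#'   `p.value` (chi-square), `p.exact` (if requested), `n`, `k`,
#'   `rank_sums`, `mean_ranks`, `tie_correction`.
#' @seealso [dunns_posthoc()] for the pairwise follow-up.
#' @export
friedman_test <- function(table, exact = FALSE, max_exact = 2e6) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stopf("frequency table must be numeric")
  if (anyNA(x)) stopf("frequency table has missing cells; the paired test needs complete blocks (no imputation)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stopf("need at least 2 blocks and 2 conditions, got %d x %d", n, k)
  ranks <- t(apply(x, 1, rank))
  Rj <- colSums(ranks)
  ties <- sum(apply(x, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  C <- 1 - ties / (n * (k^3 - k))
  Q <- if (C <= 0) 0 else (12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)) / C
  out <- structure(list(
    statistic = Q,
    df = k - 1,
    p.value = if (C <= 0) 1 else stats::pchisq(Q, k - 1, lower.tail = FALSE),
    n = n, k = k,
    rank_sums = Rj,
    mean_ranks = Rj / n,
    tie_correction = C,
    method = "Friedman rank sum test for paired samples"
  ), class = "friedman_test")
  if (exact) out$p.exact <- friedman_exact_p(ranks, Q, C, max_exact)
  out
}

# Exact permutation p by dynamic programming over rank-sum states: for each
# row, every distinct permutation of its (possibly tied) rank vector is
# equally likely under H0; states are accumulated column-sum vectors with
# multiplicities. Inclusive tail: Pr(Q* >= Q - 1e-9).
friedman_exact_p <- function(ranks, Q_obs, C, max_exact) {
  n <- nrow(ranks); k <- ncol(ranks)
  states <- matrix(0, 1, k)
  counts <- 1
  for (r in seq_len(n)) {
    perms <- distinct_permutations(ranks[r, ])
    m <- nrow(states) * nrow(perms)
    if (m > max_exact) {
      stopf("exact permutation enumeration too large (> %g states); use the chi-square p-value", max_exact)
    }
    new_states <- states[rep(seq_len(nrow(states)), each = nrow(perms)), , drop = FALSE] +
      perms[rep(seq_len(nrow(perms)), nrow(states)), , drop = FALSE]
    new_counts <- rep(counts, each = nrow(perms))
    key <- apply(new_states, 1, paste, collapse = ",")
    agg <- rowsum(new_counts, key)
    ukey <- rownames(agg)
    states <- do.call(rbind, lapply(strsplit(ukey, ","), as.numeric))
    counts <- as.numeric(agg[, 1])
  }
  if (C <= 0) return(1)
  Qs <- (12 / (n * k * (k + 1)) * rowSums(states^2) - 3 * n * (k + 1)) / C
  sum(counts[Qs >= Q_obs - 1e-9]) / sum(counts)
}

distinct_permutations <- function(v) {
  k <- length(v)
  idx <- permutations_of(k)
  m <- matrix(v[idx], nrow(idx), k)
  unique(m)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1L
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("%s\n  Q = %.4g, df = %d, chi-square p = %.4g", x$method,
              x$statistic, x$df, x$p.value))
  if (!is.null(x$p.exact)) cat(sprintf(", exact permutation p = %.4g", x$p.exact))
  cat(sprintf("\n  n = %d blocks, k = %d conditions, tie correction C = %.3f\n",
              x$n, x$k, x$tie_correction))
  invisible(x)
}

#' Dunn's multiple comparisons after a Friedman test
#'
#' Rank-based pairwise post hoc: for conditions `i, j` with mean within-row
#' ranks `Rbar`, \deqn{z = (\bar R_i - \bar R_j) / \sqrt{k (k+1) / (6 n)},}
#' two-sided `p = 2 (1 - Phi(|z|))`, adjusted over the `m` comparisons
#' actually performed (Bonferroni by default, Holm available). Stars mark
#' adjusted p < 0.05 (`*`) and < 0.01 (`**`).
#'
#' @param table the blocks x conditions table handed to [friedman_test()].
#' @param comparisons list of length-2 vectors of column names or indices;
#'   default: every other condition against `"Spont"` when such a column
#'   exists, otherwise all pairs.
#' @param p_adjust `"bonferroni"` (default) or `"holm"`.
#' @return data.frame with columns `group1`, `group2`, `mean_rank_diff`,
#'   `z`, `p_value`, `p_adjusted`, `stars`.
#' @export
dunns_posthoc <- function(table, comparisons = NULL,
                          p_adjust = c("bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  x <- as.matrix(table)
  if (anyNA(x)) stopf("frequency table has missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stopf("need at least 2 blocks and 2 conditions")
  cn <- colnames(x) %||% as.character(seq_len(k))
  colnames(x) <- cn
  ranks <- t(apply(x, 1, rank))
  rbar <- colSums(ranks) / n
  if (is.null(comparisons)) {
    comparisons <- if ("Spont" %in% cn) {
      lapply(setdiff(cn, "Spont"), function(g) c("Spont", g))
    } else {
      utils::combn(cn, 2, simplify = FALSE)
    }
  }
  resolve <- function(g) {
    if (is.character(g)) {
      if (!g %in% cn) stopf("unknown condition \"%s\" (columns: %s)", g, paste(cn, collapse = ", "))
      g
    } else {
      if (g < 1 || g > k) stopf("condition index %s out of range 1..%d", g, k)
      cn[g]
    }
  }
  pairs <- lapply(comparisons, function(p) c(resolve(p[[1]]), resolve(p[[2]])))
  sigma <- sqrt(k * (k + 1) / (6 * n))
  rows <- lapply(pairs, function(p) {
    d <- rbar[p[1]] - rbar[p[2]]
    z <- d / sigma
    data.frame(group1 = p[1], group2 = p[2], mean_rank_diff = unname(d),
               z = unname(z), p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$stars <- ifelse(out$p_adjusted < 0.01, "**",
                      ifelse(out$p_adjusted < 0.05, "*", ""))
  rownames(out) <- NULL
  out
}
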