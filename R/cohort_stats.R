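#' Two-sided Wilcoxon / Mann-Whitney rank-sum test
#'
#' Ties take midranks. When both groups have at most `exact_max`
#' observations the null distribution of the rank sum is enumerated exactly
#' over all choose(n1 + n2, n1) assignments of the observed (mid)ranks —
#' i.e. a permutation-exact test that remains valid under ties. Larger
#' samples use the normal approximation with the usual tie-corrected
#' variance (no continuity correction).
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Enumerate exactly when `max(n1, n2) <= exact_max`
#'   (default 10).
#' @return An object of class `group_comparison`: list with `method`,
#'   `statistic` (rank sum of `x`), `p_value`, `effect` (difference of
#'   means, x - y), `n` (group sizes).
#' @export
rank_sum_test <- function(x, y, exact_max = 10L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(structure(list(method = "rank-sum (degenerate)",
                          statistic = sum(rank(pooled)[seq_len(n1)]),
                          p_value = 1, effect = 0, n = c(n1, n2)),
                     class = "group_comparison"))
  }
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  if (max(n1, n2) <= exact_max) {
    method <- "rank-sum (exact permutation)"
    sums <- utils::combn(r, n1, sum)
    p_low <- mean(sums <= W + 1e-9)
    p_high <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    method <- "rank-sum (normal approximation, tie-corrected)"
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(method = method, statistic = W, p_value = p,
                 effect = mean(x) - mean(y), n = c(n1, n2)),
            class = "group_comparison")
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value by hypergeometric tail summation: the sum of the
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table. The effect is the sample odds
#' ratio ad/bc with a Woolf (log-normal) 95% CI.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @param conf Confidence level for the odds-ratio CI (default 0.95).
#' @return A `group_comparison` with `statistic` (observed count \[1,1\]),
#'   `p_value`, `effect` (odds ratio; NA when undefined), `or_ci`
#'   (Woolf CI; NA with a zero cell), `n` (margins).
#' @export
fisher_exact_2x2 <- function(tab, conf = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2 x 2 table of non-negative integer counts")
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  n <- sum(tab)
  if (m1 == 0L || m2 == 0L || k == 0L || (b + d) == 0L) {
    return(structure(list(method = "Fisher exact (degenerate margin)",
                          statistic = a, p_value = 1, effect = NA_real_,
                          or_ci = c(NA_real_, NA_real_),
                          n = c(row1 = m1, row2 = m2)),
                     class = "group_comparison"))
  }
  support <- max(0L, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b == 0L || c_ == 0L) {
    if (a == 0L || d == 0L) NA_real_ else Inf
  } else (a * d) / (b * c_)
  or_ci <- if (any(tab == 0L)) c(NA_real_, NA_real_) else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    exp(log(or) + c(-1, 1) * z * se)
  }
  structure(list(method = "Fisher exact (hypergeometric)", statistic = a,
                 p_value = p, effect = or, or_ci = or_ci,
                 n = c(row1 = m1, row2 = m2)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic), ", p = ",
      format.pval(x$p_value, digits = 3), ", effect = ",
      format(x$effect, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tukey HSD all-pairs comparison with compact letter display
#'
#' One-way layout: pooled within-group mean square with N - k degrees of
#' freedom; each pair's family-wise adjusted p-value comes from the
#' studentized-range distribution (Tukey-Kramer standard error for unequal
#' group sizes). Groups that cannot be distinguished share a letter; the
#' letter display uses the insert-and-absorb algorithm on the significance
#' graph with deterministic ordering by group label.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations).
#' @param alpha Family-wise significance level (default 0.05).
#' @return An object of class `tukey_comparison`: list with `pairs`
#'   (data.frame: group1, group2, diff, se, p_adj, significant), `letters`
#'   (named character vector), `mse`, `df`, `degenerate` flag.
#' @export
all_pairs_mean_comparison <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 observations")
  labs <- sort(names(groups))
  groups <- groups[labs]
  k <- length(groups)
  ni <- vapply(groups, length, integer(1))
  N <- sum(ni)
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- N - k
  mse <- sse / df
  degenerate <- mse <= 0
  if (degenerate)
    warning("zero within-group variance everywhere; p-values are 0/1 ",
            "indicators of any mean difference")
  cmb <- utils::combn(labs, 2L)
  pairs <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
                      diff = NA_real_, se = NA_real_, p_adj = NA_real_)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$group1[r]; j <- pairs$group2[r]
    dd <- means[i] - means[j]
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    p <- if (degenerate) as.numeric(abs(dd) < 1e-12) else
      stats::ptukey(abs(dd) / se, nmeans = k, df = df, lower.tail = FALSE)
    pairs$diff[r] <- dd; pairs$se[r] <- se; pairs$p_adj[r] <- p
  }
  pairs$significant <- pairs$p_adj < alpha
  letters <- .letter_display(labs, pairs)
  structure(list(pairs = pairs, letters = letters, mse = mse, df = df,
                 alpha = alpha, degenerate = degenerate),
            class = "tukey_comparison")
}

# insert-and-absorb compact letter display (Piepho-style): start from one
# column of all groups, split columns at each significant pair, absorb
# subset columns; deterministic by label order.
.letter_display <- function(labs, pairs) {
  cols <- list(labs)
  sig <- pairs[pairs$significant, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$group1, sig$group2), , drop = FALSE]
    for (r in seq_len(nrow(sig))) {
      i <- sig$group1[r]; j <- sig$group2[r]
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)),
                        list(setdiff(col, j)))
        } else new_cols <- c(new_cols, list(col))
      }
      # absorb: drop any column whose set is a subset of another column
      keep <- rep(TRUE, length(new_cols))
      for (ci in seq_along(new_cols)) {
        for (cj in seq_along(new_cols)) {
          if (ci != cj && keep[ci] && keep[cj] &&
              all(new_cols[[ci]] %in% new_cols[[cj]]) &&
              !(all(new_cols[[cj]] %in% new_cols[[ci]]) && ci < cj))
            keep[ci] <- FALSE
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by their first (alphabetical) member for stable lettering
  cols <- cols[order(vapply(cols, function(cc) min(match(cc, labs)),
                            numeric(1)))]
  out <- stats::setNames(rep("", length(labs)), labs)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

#' @export
print.tukey_comparison <- function(x, ...) {
  cat("Tukey HSD all-pairs comparison (alpha =", x$alpha, ")\n")
  print(x$pairs, row.names = FALSE)
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}
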