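# Fixture builders and independent oracles used across the suite.
# Everything is generated in code; no data files.

# Build a sample_set from a list of genotypes. Each genotype is an L x 2
# matrix (or a length-2L vector, interleaved per locus). Samples are laid
# out on distinct grid cells row-major in a single quadrat.
make_ss <- function(genotypes, quadrat = "Q1", stage = "on_floor",
                    rows = NULL, cols = NULL, grid = 10L,
                    forest_type = NA_character_) {
  gl <- lapply(genotypes, function(g) {
    if (is.null(dim(g))) matrix(g, ncol = 2L, byrow = TRUE) else g
  })
  L <- nrow(gl[[1L]])
  n <- length(gl)
  loci <- sprintf("L%02d", seq_len(L))
  if (is.null(rows)) rows <- ((seq_len(n) - 1L) %/% grid) + 1L
  if (is.null(cols)) cols <- ((seq_len(n) - 1L) %% grid) + 1L
  geno <- do.call(rbind, lapply(gl, function(g) as.vector(t(g))))
  geno <- as.data.frame(geno)
  names(geno) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  df <- cbind(
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               quadrat_id = quadrat, row = rows, col = cols,
               stage = rep_len(stage, n), stringsAsFactors = FALSE),
    geno)
  sample_set(marker_panel(loci),
             quadrat_layout(quadrat, forest_type, grid, grid), df)
}

# A quick random sample set of n unique-ish genotypes at L loci.
random_ss <- function(n, L = 3L, seed = 1L, grid = 10L) {
  set.seed(seed)
  gs <- lapply(seq_len(n), function(i) {
    m <- matrix(sort(c(sample(seq(100, 120, 2), 2L, replace = TRUE))),
                1L, 2L)
    for (l in seq_len(L - 1L))
      m <- rbind(m, sort(sample(seq(100, 120, 2), 2L, replace = TRUE)))
    m
  })
  make_ss(gs, grid = grid)
}

# --- independent geometry oracle -------------------------------------------
# Strict point-in-convex-polygon written from scratch (sign of cross
# products), independent of the package's kernel.
oracle_point_strictly_inside <- function(px, py, poly) {
  n <- nrow(poly)
  res <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1L] - poly[i, 1L]
    ey <- poly[j, 2L] - poly[i, 2L]
    cr <- ex * (py - poly[i, 2L]) - ey * (px - poly[i, 1L])
    res <- res & (cr > 1e-12)
  }
  res
}

# Rasterization oracle for polygon-polygon overlap: sample a 0.01-m point
# grid over the intersection of the two bounding boxes and ask whether any
# point lies strictly inside both hulls.
oracle_overlap_raster <- function(h1, h2, step = 0.01) {
  lo <- pmax(apply(h1, 2L, min), apply(h2, 2L, min))
  hi <- pmin(apply(h1, 2L, max), apply(h2, 2L, max))
  if (any(lo >= hi)) return(FALSE)
  gx <- seq(lo[1L] + step / 2, hi[1L], by = step)
  gy <- seq(lo[2L] + step / 2, hi[2L], by = step)
  if (!length(gx) || !length(gy)) return(FALSE)
  pts <- expand.grid(x = gx, y = gy)
  any(oracle_point_strictly_inside(pts$x, pts$y, h1) &
        oracle_point_strictly_inside(pts$x, pts$y, h2))
}

# All partitions of n into exactly k positive non-increasing parts.
partitions_nk <- function(n, k, maxpart = n) {
  if (k == 1L) {
    if (n <= maxpart) return(list(n)) else return(list())
  }
  out <- list()
  for (first in seq(min(maxpart, n - k + 1L), 1L)) {
    for (rest in partitions_nk(n - first, k - 1L, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

# Exact two-sided Fisher p for a 2x2 table by explicit enumeration of all
# tables with the observed margins, probabilities from factorials.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c_ + d; k <- a + c_; n <- m1 + m2
  prob_tab <- function(x) {
    exp(lfactorial(m1) + lfactorial(m2) + lfactorial(k) +
          lfactorial(n - k) - lfactorial(n) - lfactorial(x) -
          lfactorial(m1 - x) - lfactorial(k - x) -
          lfactorial(m2 - k + x))
  }
  xs <- max(0, k - m2):min(k, m1)
  ps <- vapply(xs, prob_tab, numeric(1))
  sum(ps[ps <= prob_tab(a) * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by explicit enumeration of group-label
# assignments (independent of the package's combn-over-ranks shortcut):
# statistic recomputed per assignment from pooled midranks.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  idx_sets <- utils::combn(length(pooled), n1)
  Ws <- apply(idx_sets, 2L, function(ii) sum(r[ii]))
  min(1, 2 * min(mean(Ws <= W_obs + 1e-9), mean(Ws >= W_obs - 1e-9)))
}
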