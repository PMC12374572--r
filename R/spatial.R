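#' Count overlapping genet pairs
#'
#' An unordered pair of genets counts as overlapping when their convex hulls
#' intersect with positive area (boundary touching does not count as
#' intermingling). A degenerate hull (single point or collinear segment)
#' overlaps a polygon iff it intersects the polygon's closure; two
#' degenerate hulls never overlap.
#'
#' @param geometries List of `genet_geometry` objects (one quadrat).
#' @return Integer count of overlapping pairs.
#' @export
count_overlaps <- function(geometries) {
  sum(overlap_matrix(geometries)) / 2L
}

#' Pairwise overlap indicator matrix
#'
#' @param geometries List of `genet_geometry`.
#' @return Symmetric logical matrix (FALSE diagonal).
#' @export
overlap_matrix <- function(geometries) {
  G <- length(geometries)
  if (G < 1L) stop("need at least one genet")
  M <- matrix(FALSE, G, G)
  if (G >= 2L) {
    for (i in seq_len(G - 1L)) {
      for (j in (i + 1L):G) {
        M[i, j] <- M[j, i] <- .hulls_overlap(geometries[[i]],
                                             geometries[[j]])
      }
    }
  }
  ids <- vapply(geometries, function(g) as.character(g$genet_id),
                character(1))
  dimnames(M) <- list(ids, ids)
  M
}

#' Leave-one-genet-out (jackknife) overlap statistics
#'
#' The total overlap count is recomputed G times, each time excluding one
#' genet ("all combinations of genets"). The jackknife mean and variance
#' Var = (G - 1)/G * sum((theta_i - mean)^2) give a 95% normal-quantile CI
#' mean +/- 1.96 * SE; quadrats are declared different when their CIs do
#' not overlap (see [ci_nonoverlap()]). A percentile CI over the
#' leave-one-out values is available as an alternative.
#'
#' @param geometries List of `genet_geometry` (G >= 2 for a CI).
#' @param conf Confidence level (default 0.95).
#' @param type `"jackknife"` (default) or `"percentile"`.
#' @return An object of class `overlap_stats`: list with `total_overlaps`,
#'   `loo` (the G leave-one-out totals), `jk_mean`, `jk_se`, `ci_low`,
#'   `ci_high`, `conf`, `type`.
#' @export
jackknife_overlaps <- function(geometries, conf = 0.95,
                               type = c("jackknife", "percentile")) {
  type <- match.arg(type)
  M <- overlap_matrix(geometries)
  G <- nrow(M)
  total <- sum(M) / 2L
  if (G < 2L) {
    return(structure(list(total_overlaps = total, loo = numeric(0),
                          jk_mean = NA_real_, jk_se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          conf = conf, type = type),
                     class = "overlap_stats"))
  }
  loo <- vapply(seq_len(G), function(i) total - sum(M[i, ]), numeric(1))
  m <- mean(loo)
  v <- (G - 1) / G * sum((loo - m)^2)
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (type == "jackknife") {
    ci <- c(m - z * se, m + z * se)
  } else {
    ci <- unname(stats::quantile(loo, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 type = 7))
  }
  structure(list(total_overlaps = total, loo = loo, jk_mean = m, jk_se = se,
                 ci_low = ci[1L], ci_high = ci[2L], conf = conf,
                 type = type),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "Genet overlaps: total %d | jackknife mean %.2f, %d%% CI [%.2f, %.2f]\n",
    x$total_overlaps, x$jk_mean, round(100 * x$conf), x$ci_low, x$ci_high))
  invisible(x)
}

#' Non-overlap decision between two overlap CIs
#'
#' @param a,b `overlap_stats` objects.
#' @return TRUE when the two confidence intervals do not overlap (the
#'   criterion used to call quadrats significantly different).
#' @export
ci_nonoverlap <- function(a, b) {
  stopifnot(inherits(a, "overlap_stats"), inherits(b, "overlap_stats"))
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}

#' Probability of clonal identity by distance
#'
#' Bins all C(N, 2) ramet pairs of a quadrat by Euclidean cell-center
#' distance into half-open bins [k*w, (k+1)*w) and reports the fraction of
#' pairs within each bin that share a genet. Bin width defaults to the 1-m
#' sampling grain.
#'
#' @param mll An `mll_partition`.
#' @param ss The matching `sample_set`.
#' @param quadrat_id Quadrat to process.
#' @param bin_width Bin width in meters (default 1).
#' @param max_distance Optional truncation; pairs at or beyond it are
#'   dropped.
#' @return data.frame of class `distance_identity_curve` with `bin_low`,
#'   `bin_high`, `n_pairs`, `n_same`, `fraction`.
#' @export
identity_by_distance <- function(mll, ss, quadrat_id, bin_width = 1,
                                 max_distance = NULL) {
  sel <- ss$data$quadrat_id == quadrat_id
  if (sum(sel) < 2L) stop("need at least 2 ramets in quadrat ", quadrat_id)
  xy <- ramet_positions(ss)[sel, , drop = FALSE]
  genets <- mll$genet_of_sample[sel]
  d <- as.vector(stats::dist(xy))
  n <- length(genets)
  same <- outer(genets, genets, "==")[lower.tri(matrix(0, n, n))]
  if (!is.null(max_distance)) {
    keep <- d < max_distance
    d <- d[keep]; same <- same[keep]
  }
  bin <- floor(d / bin_width)
  bins <- sort(unique(bin))
  out <- data.frame(
    bin_low = bins * bin_width,
    bin_high = (bins + 1) * bin_width,
    n_pairs = as.integer(vapply(bins, function(b) sum(bin == b), numeric(1))),
    n_same = as.integer(vapply(bins, function(b) sum(same[bin == b]),
                               numeric(1)))
  )
  out$fraction <- out$n_same / out$n_pairs
  class(out) <- c("distance_identity_curve", "data.frame")
  out
}

#' Aggregate identity-by-distance curves across quadrats
#'
#' Forest-type summary: per bin, the mean and sample SD of the per-quadrat
#' fractions (bins missing from a quadrat are skipped, not zero-filled).
#'
#' @param curves Named list of `distance_identity_curve` (names = quadrats).
#' @return data.frame with `bin_low`, `bin_high`, `n_quadrats`, `mean`,
#'   `sd`.
#' @export
aggregate_identity_curves <- function(curves) {
  all_lows <- sort(unique(unlist(lapply(curves, `[[`, "bin_low"))))
  rows <- lapply(all_lows, function(b) {
    f <- unlist(lapply(curves, function(cu) cu$fraction[cu$bin_low == b]))
    data.frame(bin_low = b,
               bin_high = b + (curves[[1L]]$bin_high[1L] -
                                 curves[[1L]]$bin_low[1L]),
               n_quadrats = length(f), mean = mean(f),
               sd = if (length(f) >= 2L) stats::sd(f) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Stem density from sub-quadrat counts
#'
#' The field protocol counts all stems within `n` randomly placed 1 x 1 m
#' sub-quadrats of each quadrat (default 10) and reports the mean count per
#' square meter.
#'
#' @param counts Integer vector of per-sub-quadrat stem counts.
#' @param n_subquadrats Expected vector length (default 10); mismatch is an
#'   error.
#' @return List with `counts`, `mean_density` (stems per m^2).
#' @export
stem_density <- function(counts, n_subquadrats = 10L) {
  if (length(counts) != n_subquadrats)
    stop("expected ", n_subquadrats, " sub-quadrat counts, got ",
         length(counts))
  if (any(counts < 0)) stop("stem counts must be non-negative")
  list(counts = as.integer(counts), mean_density = mean(counts))
}
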