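# Deterministic agglomerative clustering on a distance matrix.
#
# Merge rule: repeatedly merge the cluster pair with the smallest
# inter-cluster distance (complete linkage under "farthest", single linkage
# under "nearest") while that distance is <= threshold. Ties are broken by
# the lowest pair of cluster keys (key = smallest original item id in the
# cluster), so the result is reproducible regardless of input permutations
# of equal-distance merges. Merge heights are recorded for the cutoff
# predictor.
.agglomerate <- function(d, threshold, linkage = c("farthest", "nearest")) {
  linkage <- match.arg(linkage)
  comb <- if (linkage == "farthest") max else min
  n <- nrow(d)
  members <- as.list(seq_len(n))
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  heights <- numeric(0)
  while (sum(active) > 1L) {
    idx <- which(active)
    Dsub <- D[idx, idx, drop = FALSE]
    m <- min(Dsub)
    if (m > threshold) break
    # tie-break: lowest (key_i, key_j); keys are ascending in `idx` because
    # merged clusters keep the smaller index slot
    hit <- which(Dsub == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- idx[hit[1L, 1L]]
    j <- idx[hit[1L, 2L]]
    heights <- c(heights, m)
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    for (k in which(active)) {
      if (k == i) next
      D[i, k] <- D[k, i] <- comb(D[i, k], D[j, k])
    }
  }
  cluster <- integer(n)
  live <- which(active)
  for (ci in seq_along(live)) cluster[members[[live[ci]]]] <- ci
  list(cluster = cluster, heights = heights)
}

#' Predict the MLG-to-MLL distance threshold (gap-based cutoff predictor)
#'
#' Separates the small genetic distances produced by somatic mutation or
#' genotyping error from the large distances between distinct genets.
#' Candidate thresholds are the sorted distinct distances at which the
#' agglomerative MLL count changes when sweeping the cutoff upward from 0
#' (i.e. the distinct merge heights of the full agglomeration). Only the
#' first `ceiling(clonal_fraction * n_candidates)` candidates are retained
#' (the putatively clonal, small-distance part of the spectrum), and the
#' returned threshold is the midpoint of the largest gap between consecutive
#' retained candidates (ties go to the lowest-distance gap). With fewer than
#' two candidates there is no gap to exploit and 0 is returned (no
#' collapsing).
#'
#' @param distances MLG distance matrix from [pairwise_mlg_distances()].
#' @param clonal_fraction Fraction of the candidate spectrum assumed to be
#'   mutation-scale (default 0.5).
#' @param linkage Agglomeration linkage, as in [assign_mlls()].
#' @return The threshold (numeric scalar >= 0), with attributes `candidates`
#'   (all merge heights), `retained`, and `gap` (the exploited gap's
#'   endpoints), for reporting.
#' @export
predict_mll_threshold <- function(distances, clonal_fraction = 0.5,
                                  linkage = c("farthest", "nearest")) {
  linkage <- match.arg(linkage)
  if (nrow(distances) < 2L)
    return(structure(0, candidates = numeric(0), retained = numeric(0),
                     gap = c(NA_real_, NA_real_)))
  res <- .agglomerate(distances, Inf, linkage)
  cand <- sort(unique(res$heights))
  keep <- cand[seq_len(ceiling(clonal_fraction * length(cand)))]
  if (length(keep) < 2L)
    return(structure(0, candidates = cand, retained = keep,
                     gap = c(NA_real_, NA_real_)))
  gaps <- diff(keep)
  g <- which(gaps == max(gaps))[1L]
  structure((keep[g] + keep[g + 1L]) / 2,
            candidates = cand, retained = keep,
            gap = c(keep[g], keep[g + 1L]))
}

#' Cluster MLGs into multilocus lineages (MLLs = genets)
#'
#' Agglomerative clustering of MLGs under the given linkage: clusters are
#' merged while the inter-cluster distance is at or below the threshold.
#' Farthest-neighbor (complete) linkage is the conservative default — it
#' cannot chain two distinct genets through a shared mutant. Threshold 0
#' makes MLLs identical to MLGs. Genet ids are dense integers ordered by
#' first sample occurrence.
#'
#' @param partition An `mlg_partition`.
#' @param distances Matrix from [pairwise_mlg_distances()].
#' @param threshold Distance cutoff (>= 0), e.g. from
#'   [predict_mll_threshold()].
#' @param linkage `"farthest"` (complete, default) or `"nearest"` (single).
#' @return An object of class `mll_partition`: list with `genet_of_mlg`,
#'   `genet_of_sample`, `sample_id`, `n_genets`, `threshold`, `linkage`.
#' @export
assign_mlls <- function(partition, distances, threshold,
                        linkage = c("farthest", "nearest")) {
  linkage <- match.arg(linkage)
  if (threshold < 0) stop("threshold must be >= 0")
  n <- partition$n_mlgs
  raw <- if (n == 1L) rep(1L, 1L) else
    .agglomerate(distances, threshold, linkage)$cluster
  # renumber genets densely by first sample occurrence
  raw_of_sample <- raw[partition$mlg_id]
  genet_of_sample <- match(raw_of_sample, unique(raw_of_sample))
  genet_of_mlg <- match(raw, unique(raw_of_sample))
  structure(
    list(genet_of_mlg = genet_of_mlg,
         genet_of_sample = genet_of_sample,
         sample_id = partition$sample_id,
         n_genets = max(genet_of_sample),
         threshold = threshold,
         linkage = linkage),
    class = "mll_partition"
  )
}

#' @export
print.mll_partition <- function(x, ...) {
  cat("MLL partition:", length(x$sample_id), "samples ->", x$n_genets,
      "genets (threshold", x$threshold, ",", x$linkage, "linkage)\n")
  invisible(x)
}

#' One-call clone discrimination
#'
#' Convenience wrapper: collapse MLGs, compute distances, predict the
#' threshold, assign MLLs, and compute round-robin Pgen / Psex for repeated
#' MLGs.
#'
#' @param ss A `sample_set` (strict mode).
#' @param threshold Distance cutoff; `NULL` (default) predicts it with
#'   [predict_mll_threshold()].
#' @param clonal_fraction Passed to the cutoff predictor.
#' @param linkage Passed to [assign_mlls()].
#' @return A list with `mlg` (`mlg_partition`), `distances`, `threshold`,
#'   `mll` (`mll_partition`), `freqs`, and `psex_table` (per repeated MLG:
#'   copies n, Pgen, Psex).
#' @export
discriminate_clones <- function(ss, threshold = NULL, clonal_fraction = 0.5,
                                linkage = c("farthest", "nearest")) {
  linkage <- match.arg(linkage)
  mlg <- collapse_mlgs(ss)
  d <- pairwise_mlg_distances(ss, mlg)
  if (is.null(threshold))
    threshold <- predict_mll_threshold(d, clonal_fraction, linkage)
  mll <- assign_mlls(mlg, d, as.numeric(threshold), linkage)
  freqs <- allele_freqs(ss, if (n_loci(ss) > 1L) "round_robin" else "plain")
  gm <- genotype_matrix(ss)
  N <- mlg$n_samples
  copies <- tabulate(mlg$mlg_id, mlg$n_mlgs)
  ptab <- data.frame(mlg_id = seq_len(mlg$n_mlgs), n = copies,
                     p_gen = NA_real_, p_sex = NA_real_)
  for (m in seq_len(mlg$n_mlgs)) {
    g <- matrix(gm[mlg$representative[m], ], ncol = 2L, byrow = TRUE)
    # an allele seen only in non-representative samples (e.g. a somatic
    # mutant) has no round-robin frequency; Pgen is then undefined (NA)
    ptab$p_gen[m] <- tryCatch(pgen(g, freqs), error = function(e) NA_real_)
    ptab$p_sex[m] <- if (is.na(ptab$p_gen[m])) NA_real_ else
      psex(ptab$p_gen[m], copies[m], N)
  }
  list(mlg = mlg, distances = d, threshold = threshold, mll = mll,
       freqs = freqs, psex_table = ptab)
}
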