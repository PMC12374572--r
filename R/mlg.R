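#' Collapse samples into multilocus genotypes (MLGs)
#'
#' Two samples share an MLG iff their canonicalized genotypes are identical
#' at every chosen locus. MLG ids are dense integers 1..n_mlgs assigned by
#' first occurrence in sample (file) order.
#'
#' @param ss A `sample_set` with no missing data at the chosen loci
#'   (strict mode; see [drop_incomplete_samples()]).
#' @param loci Optional subset of locus names; default all panel loci.
#' @return An object of class `mlg_partition`: list with `sample_id`,
#'   `mlg_id` (integer vector parallel to samples), `n_samples`, `n_mlgs`,
#'   `representative` (index of the first sample of each MLG), `loci`.
#' @export
collapse_mlgs <- function(ss, loci = NULL) {
  if (n_samples(ss) == 0L) stop("cannot collapse an empty sample set")
  loci <- if (is.null(loci)) ss$panel$loci else
    match.arg(loci, ss$panel$loci, several.ok = TRUE)
  gm <- genotype_matrix(ss, loci)
  if (anyNA(gm))
    stop("missing genotypes present; run drop_incomplete_samples() first")
  key <- apply(gm, 1L, paste, collapse = "/")
  mlg_id <- match(key, unique(key))
  structure(
    list(sample_id = ss$data$sample_id,
         mlg_id = mlg_id,
         n_samples = length(mlg_id),
         n_mlgs = max(mlg_id),
         representative = match(seq_len(max(mlg_id)), mlg_id),
         loci = loci),
    class = "mlg_partition"
  )
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat("MLG partition:", x$n_samples, "samples ->", x$n_mlgs, "MLGs (",
      length(x$loci), "loci )\n")
  invisible(x)
}

# allele mismatches at one locus between two canonical (ascending) pairs,
# under optimal within-locus pairing: 2 - multiset intersection size
.locus_mismatch <- function(a1, a2, b1, b2) {
  if (a1 == b1 && a2 == b2) return(0L)
  shared <- 0L
  bb <- c(b1, b2)
  for (a in c(a1, a2)) {
    hit <- match(a, bb)
    if (!is.na(hit)) {
      shared <- shared + 1L
      bb <- bb[-hit]
    }
  }
  2L - shared
}

#' Pairwise genetic distances between MLGs
#'
#' Distance = total number of allele differences across loci, counting 0, 1
#' or 2 mismatches per locus under the optimal within-locus allele pairing
#' (the standard dissimilarity for co-dominant markers). Symmetric with a
#' zero diagonal.
#'
#' @param ss A `sample_set`.
#' @param partition An `mlg_partition` from [collapse_mlgs()].
#' @return Integer matrix `n_mlgs` x `n_mlgs`.
#' @export
pairwise_mlg_distances <- function(ss, partition) {
  gm <- genotype_matrix(ss, partition$loci)[partition$representative, ,
                                            drop = FALSE]
  n <- nrow(gm)
  L <- length(partition$loci)
  d <- matrix(0L, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        tot <- 0L
        for (l in seq_len(L)) {
          c1 <- 2L * l - 1L
          tot <- tot + .locus_mismatch(gm[i, c1], gm[i, c1 + 1L],
                                       gm[j, c1], gm[j, c1 + 1L])
        }
        d[i, j] <- tot
        d[j, i] <- tot
      }
    }
  }
  dimnames(d) <- list(seq_len(n), seq_len(n))
  d
}

#' Genotype accumulation curve
#'
#' Marker-resolution check: for every subset size k = 1..L, count the MLGs
#' distinguished by each k-locus subset. Subsets are enumerated exhaustively
#' while `choose(L, k) <= max_exhaustive`, otherwise sampled uniformly
#' without replacement. The plateau statistic is the smallest k whose
#' maximal subset count already equals the full-panel MLG count.
#'
#' @param ss A `sample_set` (strict mode).
#' @param max_exhaustive Enumerate exhaustively up to this many subsets per k
#'   (default 1000; the classic 11-locus panel is always exhaustive).
#' @param rng_seed Seed used only when sampling subsets.
#' @return An object of class `accumulation_curve`: per-k data.frame with
#'   `k`, `n_subsets`, `mode`, `min`, `mean`, `max`; attributes `plateau_k`
#'   and `n_mlgs`.
#' @export
accumulation_curve <- function(ss, max_exhaustive = 1000L, rng_seed = NULL) {
  L <- n_loci(ss)
  full <- collapse_mlgs(ss)$n_mlgs
  rows <- vector("list", L)
  counts_by_k <- vector("list", L)
  for (k in seq_len(L)) {
    n_total <- choose(L, k)
    if (n_total <= max_exhaustive) {
      subs <- utils::combn(ss$panel$loci, k, simplify = FALSE)
      mode <- "exhaustive"
    } else {
      if (!is.null(rng_seed)) set.seed(rng_seed + k)
      seen <- new.env(hash = TRUE)
      subs <- list()
      while (length(subs) < max_exhaustive) {
        s <- sort(sample(ss$panel$loci, k))
        key <- paste(s, collapse = "|")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          subs[[length(subs) + 1L]] <- s
        }
      }
      mode <- "sampled"
    }
    cnt <- vapply(subs, function(s) collapse_mlgs(ss, s)$n_mlgs, integer(1))
    counts_by_k[[k]] <- cnt
    rows[[k]] <- data.frame(k = k, n_subsets = length(cnt), mode = mode,
                            min = min(cnt), mean = mean(cnt), max = max(cnt))
  }
  out <- do.call(rbind, rows)
  plateau <- min(out$k[out$max == full])
  structure(out, class = c("accumulation_curve", "data.frame"),
            plateau_k = plateau, n_mlgs = full, counts = counts_by_k)
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat("Genotype accumulation curve (", attr(x, "n_mlgs"), "MLGs at full",
      "panel; plateau at k =", attr(x, "plateau_k"), ")\n")
  print.data.frame(x)
  invisible(x)
}
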