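#' Per-quadrat clonal census
#'
#' Counts ramets (N), genets (G), the clone-size multiset, multi-ramet
#' genets, the largest clone, per-stage sample counts and per-stage occupied
#' grid-cell counts, and the clonal-ramet percentage 100 * (1 - G/N).
#'
#' @param mll An `mll_partition` over the full sample set.
#' @param ss The `sample_set` the partition was computed from.
#' @param quadrat_id Quadrat to census.
#' @return An object of class `clonal_census`.
#' @export
census <- function(mll, ss, quadrat_id) {
  if (!quadrat_id %in% ss$layouts$quadrat_id)
    stop("unknown quadrat id: ", quadrat_id)
  sel <- ss$data$quadrat_id == quadrat_id
  if (!any(sel)) stop("quadrat ", quadrat_id, " has no genotyped ramets")
  genets <- mll$genet_of_sample[sel]
  sizes <- as.integer(table(genets))
  N <- length(genets)
  G <- length(sizes)
  df <- ss$data[sel, , drop = FALSE]
  occupied <- vapply(.stages, function(st) {
    length(unique(paste(df$row[df$stage == st], df$col[df$stage == st])))
  }, integer(1))
  structure(
    list(quadrat_id = quadrat_id,
         n_ramets = N,
         n_genets = G,
         clone_sizes = sort(sizes, decreasing = TRUE),
         n_multi = sum(sizes >= 2L),
         max_clone = max(sizes),
         stage_counts = c(on_floor = sum(df$stage == "on_floor"),
                          on_tree = sum(df$stage == "on_tree")),
         occupied_cells = occupied,
         clonal_ramet_pct = 100 * (1 - G / N)),
    class = "clonal_census"
  )
}

#' @export
print.clonal_census <- function(x, ...) {
  cat("Quadrat ", x$quadrat_id, ": N = ", x$n_ramets, ", G = ", x$n_genets,
      ", clonal ramets = ", sprintf("%.1f%%", x$clonal_ramet_pct), "\n",
      sep = "")
  cat("  clone sizes:", paste(x$clone_sizes, collapse = " "), "\n")
  invisible(x)
}

#' Clonal (genotypic) richness R
#'
#' R = (G - 1) / (N - 1): 0 for a monoclonal stand, 1 when every ramet is a
#' distinct genet.
#'
#' @param N Number of ramets (>= 2).
#' @param G Number of genets (1 <= G <= N).
#' @return Numeric scalar in \[0, 1\].
#' @export
clonal_richness <- function(N, G) {
  if (N < 2) stop("clonal richness is undefined for N < 2")
  if (G < 1 || G > N) stop("need 1 <= G <= N")
  (G - 1) / (N - 1)
}

#' Simpson diversity and evenness of clonal membership
#'
#' D = 1 - sum n_i (n_i - 1) / (N (N - 1)) over clone sizes n_i, with its
#' theoretical range at the observed N and G:
#' D_min = ((2N - G)(G - 1) / N^2) * (N / (N - 1)) (most skewed partition,
#' one dominant clone and G - 1 singletons) and
#' D_max = ((G - 1) / G) * (N / (N - 1)) (perfectly even partition).
#' Evenness V = (D - D_min) / (D_max - D_min); undefined (NA) when G = 1,
#' where the range degenerates.
#'
#' @param clone_sizes Integer vector of ramets per genet.
#' @param N Total ramets; default `sum(clone_sizes)` (checked if supplied).
#' @return List with `D`, `D_min`, `D_max`, `V`.
#' @export
simpson_evenness <- function(clone_sizes, N = sum(clone_sizes)) {
  if (sum(clone_sizes) != N)
    stop("clone sizes sum to ", sum(clone_sizes), ", not N = ", N)
  if (N < 2) stop("Simpson index is undefined for N < 2")
  G <- length(clone_sizes)
  D <- 1 - sum(clone_sizes * (clone_sizes - 1)) / (N * (N - 1))
  D_min <- ((2 * N - G) * (G - 1) / N^2) * (N / (N - 1))
  D_max <- ((G - 1) / G) * (N / (N - 1))
  V <- if (G == 1L) NA_real_ else (D - D_min) / (D_max - D_min)
  list(D = D, D_min = D_min, D_max = D_max, V = V)
}

#' Pareto index of the clone-size distribution
#'
#' Fits the power law N_{>=X} = alpha * X^(-beta), where N_{>=X} is the
#' number of genets containing X or more ramets, by ordinary least squares
#' of log10(N_{>=X}) on log10(X) over the distinct observed clone sizes.
#' beta (the negative slope) is larger when clones are many and evenly
#' sized. The fit is refused (all values NA, `defined = FALSE`) with fewer
#' than 3 distinct clone sizes, where a two-parameter line is meaningless.
#'
#' @param clone_sizes Integer vector of ramets per genet (non-empty).
#' @return List with `beta`, `p_value` (two-sided test of slope != 0),
#'   `alpha` (intercept on the natural scale), `n_points`, `defined`.
#' @export
pareto_index <- function(clone_sizes) {
  if (!length(clone_sizes)) stop("clone_sizes must be non-empty")
  X <- sort(unique(clone_sizes))
  if (length(X) < 3L)
    return(list(beta = NA_real_, p_value = NA_real_, alpha = NA_real_,
                n_points = length(X), defined = FALSE))
  NgeX <- vapply(X, function(x) sum(clone_sizes >= x), integer(1))
  lx <- log10(X)
  ly <- log10(NgeX)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  # exactly collinear points: slope is exact, p-value limit is 0
  p <- if (rss < 1e-24) 0 else
    summary(fit)$coefficients[2L, "Pr(>|t|)"]
  list(beta = -slope, p_value = unname(p),
       alpha = 10^unname(stats::coef(fit)[1L]),
       n_points = length(X), defined = TRUE)
}

#' Full diversity report for a quadrat
#'
#' @param cen A `clonal_census`.
#' @return An object of class `diversity_report`: list with `quadrat_id`,
#'   `N`, `G`, `R`, `D`, `D_min`, `D_max`, `V`, `pareto_beta`, `pareto_p`,
#'   `clonal_ramet_pct`.
#' @export
diversity_report <- function(cen) {
  sim <- simpson_evenness(cen$clone_sizes, cen$n_ramets)
  par <- pareto_index(cen$clone_sizes)
  structure(
    list(quadrat_id = cen$quadrat_id, N = cen$n_ramets, G = cen$n_genets,
         R = clonal_richness(cen$n_ramets, cen$n_genets),
         D = sim$D, D_min = sim$D_min, D_max = sim$D_max, V = sim$V,
         pareto_beta = par$beta, pareto_p = par$p_value,
         clonal_ramet_pct = cen$clonal_ramet_pct),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("Quadrat %s: N=%d G=%d R=%.3f V=%s Pareto=%s clonal=%.1f%%\n",
              x$quadrat_id, x$N, x$G, x$R,
              if (is.na(x$V)) "NA" else sprintf("%.3f", x$V),
              if (is.na(x$pareto_beta)) "-" else
                sprintf("%.2f (p=%.3g)", x$pareto_beta, x$pareto_p),
              x$clonal_ramet_pct))
  invisible(x)
}

#' Cross-quadrat mean and sample SD
#'
#' Summarises a statistic across the quadrats of each forest type as
#' arithmetic mean +/- sample standard deviation (n - 1 denominator, the
#' convention of the reference tables). A single-quadrat group gets SD = NA.
#'
#' @param values Named numeric vector (names = quadrat ids).
#' @param groups Named character vector mapping quadrat id to group label
#'   (e.g. forest type).
#' @return data.frame with `group`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(values, groups) {
  g <- groups[names(values)]
  out <- do.call(rbind, lapply(split(values, g), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
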