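#' Run configuration for the full analysis pipeline
#'
#' @param input Path to the genotype CSV ([read_genotype_table()] layout).
#' @param layouts Optional quadrat-layout data.frame or JSON sidecar path.
#' @param outdir Output directory (created if absent).
#' @param missing_mode `"strict"` (drop samples with any missing locus,
#'   default).
#' @param linkage MLL agglomeration linkage (default `"farthest"`).
#' @param clonal_fraction Cutoff-predictor clonal fraction (default 0.5).
#' @param bin_width Identity-by-distance bin width in meters (default 1).
#' @param alpha Significance level for group comparisons (default 0.05).
#' @param seed Single seed fanned out to every stochastic stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input, layouts = NULL, outdir = "clonalarch_out",
                       missing_mode = c("strict", "pairwise"),
                       linkage = c("farthest", "nearest"),
                       clonal_fraction = 0.5, bin_width = 1,
                       alpha = 0.05, seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  linkage <- match.arg(linkage)
  if (clonal_fraction <= 0 || clonal_fraction > 1)
    stop("clonal_fraction must be in (0, 1]")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(input = input, layouts = layouts, outdir = outdir,
                 missing_mode = missing_mode, linkage = linkage,
                 clonal_fraction = clonal_fraction, bin_width = bin_width,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full clonal-structure analysis
#'
#' Orchestrates the whole workflow on a genotype table (real or simulated):
#' read + validate, drop incomplete samples, clone discrimination
#' (MLG -> threshold -> MLL), per-quadrat census and diversity indices,
#' spatial architecture (hulls, overlap jackknife, identity-by-distance),
#' forest-type summaries and group comparisons where both forest types are
#' present. All tables are written as CSV, the threshold report and a run
#' manifest (config, seed, per-stage counts, md5 of every output) as JSON.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results (`sample_set`,
#'   `clones`, `censuses`, `diversity`, `geometries`, `overlaps`,
#'   `identity_curves`, `summaries`, `comparisons`, `manifest`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  message("[io] reading ", config$input)
  ss0 <- read_genotype_table(config$input, layouts = config$layouts)
  if (n_samples(ss0) == 0L) stop("stage genotype_io: input has no records")
  dropped <- drop_incomplete_samples(ss0)
  ss <- dropped$sample_set
  message("[io] ", n_samples(ss0), " records read, ", dropped$n_dropped,
          " dropped (missing loci), ", dropped$n_retained, " retained")
  if (n_samples(ss) == 0L)
    stop("stage genotype_io: no fully genotyped samples remain")

  message("[clones] collapsing MLGs and assigning MLLs")
  clones <- discriminate_clones(ss, clonal_fraction = config$clonal_fraction,
                                linkage = config$linkage)
  message("[clones] ", clones$mlg$n_mlgs, " MLGs -> ", clones$mll$n_genets,
          " genets at threshold ", as.numeric(clones$threshold))

  quads <- ss$layouts$quadrat_id
  censuses <- lapply(quads, function(q) census(clones$mll, ss, q))
  names(censuses) <- quads
  diversity <- lapply(censuses, diversity_report)

  message("[spatial] hulls, overlaps, identity-by-distance")
  geometries <- lapply(quads, function(q)
    genet_geometries(clones$mll, ss, q))
  names(geometries) <- quads
  overlaps <- lapply(geometries, jackknife_overlaps)
  identity_curves <- lapply(quads, function(q) {
    if (sum(ss$data$quadrat_id == q) >= 2L)
      identity_by_distance(clones$mll, ss, q, config$bin_width)
  })
  names(identity_curves) <- quads
  identity_curves <- Filter(Negate(is.null), identity_curves)

  ft <- stats::setNames(ss$layouts$forest_type, ss$layouts$quadrat_id)
  summaries <- NULL
  comparisons <- list()
  if (length(unique(stats::na.omit(ft))) >= 1L && !all(is.na(ft))) {
    stats_tab <- data.frame(
      quadrat = quads,
      N = vapply(censuses, `[[`, numeric(1), "n_ramets"),
      G = vapply(censuses, `[[`, numeric(1), "n_genets"),
      R = vapply(diversity, `[[`, numeric(1), "R"),
      clonal_pct = vapply(censuses, `[[`, numeric(1), "clonal_ramet_pct"))
    summaries <- do.call(rbind, lapply(c("N", "G", "R", "clonal_pct"),
      function(st) {
        s <- summarize_groups(stats::setNames(stats_tab[[st]],
                                              stats_tab$quadrat), ft)
        cbind(statistic = st, s)
      }))
    if (length(unique(stats::na.omit(ft))) == 2L) {
      areas <- lapply(split(quads, ft[quads]), function(qs) {
        unlist(lapply(geometries[qs], function(gl)
          vapply(gl, `[[`, numeric(1), "area")))
      })
      if (all(lengths(areas) > 0L))
        comparisons$genet_area_rank_sum <-
          rank_sum_test(areas[[1L]], areas[[2L]])
    }
  }

  # serialized outputs
  files <- character(0)
  files["assignments"] <- .write_csv(
    data.frame(sample_id = clones$mll$sample_id,
               mlg_id = clones$mlg$mlg_id,
               genet_id = clones$mll$genet_of_sample),
    file.path(config$outdir, "clone_assignments.csv"))
  utils::write.table(clones$distances,
                     file.path(config$outdir, "mlg_distances.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  files["distances"] <- file.path(config$outdir, "mlg_distances.tsv")
  thr <- clones$threshold
  jsonlite::write_json(
    list(threshold = as.numeric(thr),
         candidates = as.numeric(attr(thr, "candidates")),
         retained = as.numeric(attr(thr, "retained")),
         gap = as.numeric(attr(thr, "gap")),
         linkage = config$linkage,
         clonal_fraction = config$clonal_fraction),
    file.path(config$outdir, "threshold_report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  files["threshold"] <- file.path(config$outdir, "threshold_report.json")
  files["diversity"] <- .write_csv(
    do.call(rbind, lapply(diversity, function(d)
      data.frame(quadrat = d$quadrat_id, N = d$N, G = d$G,
                 R = round(d$R, 3), D = round(d$D, 4), V = round(d$V, 3),
                 pareto_beta = round(d$pareto_beta, 2),
                 pareto_p = signif(d$pareto_p, 3),
                 clonal_pct = round(d$clonal_ramet_pct, 1)))),
    file.path(config$outdir, "diversity_report.csv"))
  files["geometry"] <- .write_csv(
    do.call(rbind, lapply(quads, function(q) {
      do.call(rbind, lapply(geometries[[q]], function(g)
        data.frame(quadrat = q, genet_id = g$genet_id,
                   n_ramets = g$n_ramets, kind = g$kind,
                   area_m2 = round(g$area, 4),
                   hull_wkt = .hull_wkt(g))))
    })),
    file.path(config$outdir, "genet_geometry.csv"))
  jsonlite::write_json(
    lapply(overlaps, function(o)
      list(total_overlaps = o$total_overlaps, jk_mean = o$jk_mean,
           jk_se = o$jk_se, ci = c(o$ci_low, o$ci_high))),
    file.path(config$outdir, "overlap_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  files["overlaps"] <- file.path(config$outdir, "overlap_report.json")
  if (length(identity_curves))
    files["identity"] <- .write_csv(
      do.call(rbind, lapply(names(identity_curves), function(q)
        cbind(quadrat = q, as.data.frame(identity_curves[[q]])))),
      file.path(config$outdir, "identity_by_distance.csv"))
  if (!is.null(summaries))
    files["summaries"] <- .write_csv(
      summaries, file.path(config$outdir, "forest_type_summary.csv"))

  manifest <- list(
    package = "clonalarch",
    version = as.character(utils::packageVersion("clonalarch")),
    config = unclass(config),
    counts = list(read = n_samples(ss0), dropped = dropped$n_dropped,
                  retained = dropped$n_retained,
                  mlgs = clones$mlg$n_mlgs, genets = clones$mll$n_genets),
    threshold = as.numeric(clones$threshold),
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[done] %d outputs in %s (%.1f s)", length(files) + 1L,
                  config$outdir,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(sample_set = ss, clones = clones, censuses = censuses,
                 diversity = diversity, geometries = geometries,
                 overlaps = overlaps, identity_curves = identity_curves,
                 summaries = summaries, comparisons = comparisons,
                 manifest = manifest))
}

.hull_wkt <- function(g) {
  v <- g$hull
  switch(g$kind,
    point = sprintf("POINT (%g %g)", v[1L, 1L], v[1L, 2L]),
    segment = sprintf("LINESTRING (%g %g, %g %g)", v[1L, 1L], v[1L, 2L],
                      v[2L, 1L], v[2L, 2L]),
    polygon = sprintf("POLYGON ((%s))",
                      paste(sprintf("%g %g", c(v[, 1L], v[1L, 1L]),
                                    c(v[, 2L], v[1L, 2L])),
                            collapse = ", ")))
}
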