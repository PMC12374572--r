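#' Simulation scenario for a clonal population on a sampling grid
#'
#' A spatially explicit stolon-spread model with known ground truth.
#' Founders (sexually recruited genets) are placed uniformly in the quadrat
#' and receive Hardy-Weinberg genotypes drawn from Dirichlet population
#' allele frequencies; each founder then grows a branching stolon random
#' walk (exponential step lengths, uniform turning angles) that deposits a
#' negative-binomially distributed number of ramets, reflected at the
#' quadrat boundary. Noise enters as stepwise somatic mutation (+/- one
#' repeat unit per allele per ramet) and genotyping miscalls (re-draw from
#' the locus allele pool). Sampling follows the field protocol: one ramet
#' per grid cell per life stage, chosen uniformly among the cell's
#' occupants.
#'
#' @param seed RNG seed; all randomness in [simulate_quadrat()] flows from
#'   it.
#' @param quadrat_id,forest_type Labels for the generated quadrat.
#' @param grid_rows,grid_cols,cell_size Quadrat geometry (default 10 x 10 m
#'   of 1-m cells).
#' @param n_founders Number of founder genets (>= 1).
#' @param n_loci Number of SSR loci (default 11, the classic panel size).
#' @param alleles_per_locus Alleles segregating per locus (default 8).
#' @param dirichlet_conc Symmetric Dirichlet concentration for population
#'   allele frequencies (default 1, a flat prior).
#' @param motif Repeat-motif length in bp (default 2); the unit of somatic
#'   mutation steps.
#' @param ramets_per_founder Mean ramets per founder (negative binomial).
#' @param nb_dispersion Negative-binomial size (dispersion) parameter.
#' @param stolon_step_mean Mean stolon internode length in meters.
#' @param branch_prob Probability that a deposited ramet also starts a new
#'   stolon branch.
#' @param on_tree_prob Probability that a ramet is at the climbing
#'   ("on-tree") stage; the field data show roughly 4-5x more on-floor
#'   occupancy, hence the 0.2 default.
#' @param somatic_mutation_rate Per-allele per-ramet probability of a +/- 1
#'   repeat-unit change (default 0).
#' @param genotyping_error_rate Per-allele probability of a miscall,
#'   re-drawn from the locus allele pool (default 0).
#' @param min_founder_distance Minimum pairwise genetic distance (allele
#'   mismatches) enforced between founder genotypes by redrawing, so that
#'   founder-scale and mutation-scale distances are separable (default 4).
#' @param n_subquadrats Sub-quadrats for stem-density estimation
#'   (default 10).
#' @return An object of class `sim_scenario` (a validated parameter list).
#' @export
sim_scenario <- function(seed = 1L,
                         quadrat_id = "SIM1",
                         forest_type = NA_character_,
                         grid_rows = 10L, grid_cols = 10L, cell_size = 1,
                         n_founders = 4L,
                         n_loci = 11L,
                         alleles_per_locus = 8L,
                         dirichlet_conc = 1,
                         motif = 2L,
                         ramets_per_founder = 250,
                         nb_dispersion = 5,
                         stolon_step_mean = 0.8,
                         branch_prob = 0.2,
                         on_tree_prob = 0.2,
                         somatic_mutation_rate = 0,
                         genotyping_error_rate = 0,
                         min_founder_distance = 4L,
                         n_subquadrats = 10L) {
  sc <- as.list(environment())
  probs <- c(sc$branch_prob, sc$on_tree_prob, sc$somatic_mutation_rate,
             sc$genotyping_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (sc$n_founders < 1L) stop("need at least one founder")
  if (sc$n_loci < 1L) stop("need at least one locus")
  if (sc$alleles_per_locus < 2L) stop("need >= 2 alleles per locus")
  if (sc$stolon_step_mean <= 0) stop("stolon step mean must be positive")
  if (sc$ramets_per_founder <= 0) stop("ramets_per_founder must be positive")
  structure(sc, class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario '", x$quadrat_id, "': ", x$n_founders,
      " founders, ", x$n_loci, " loci, mu=", x$ramets_per_founder,
      " ramets/founder, mutation=", x$somatic_mutation_rate,
      ", error=", x$genotyping_error_rate, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Scenario presets for the two forest endpoints
#'
#' `"young"` emulates early-succession stands: few founders (2-5) with
#' large, little-intermingled clones and roughly 10 stems per square meter.
#' `"old_growth"` emulates mature stands: many founders (14-30), dense
#' intermingled ramets, roughly 145 stems per square meter. The preset
#' draws the founder count uniformly from the stated range (seeded) and
#' scales the per-founder ramet budget to the target density.
#'
#' @param name `"young"` or `"old_growth"`.
#' @param seed RNG seed stored in the scenario.
#' @param ... Overrides passed to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
preset <- function(name = c("young", "old_growth"), seed = 1L, ...) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "young") {
    nf <- sample(2:5, 1L)
    args <- list(seed = seed, quadrat_id = paste0("Y", seed),
                 forest_type = "young", n_founders = nf,
                 ramets_per_founder = round(1000 / nf),
                 stolon_step_mean = 0.8, branch_prob = 0.2)
  } else {
    nf <- sample(14:30, 1L)
    args <- list(seed = seed, quadrat_id = paste0("O", seed),
                 forest_type = "old_growth", n_founders = nf,
                 ramets_per_founder = round(14500 / nf),
                 stolon_step_mean = 0.6, branch_prob = 0.3)
  }
  args <- utils::modifyList(args, list(...))
  do.call(sim_scenario, args)
}

#' Draw population allele frequencies for a scenario
#'
#' Per locus, a symmetric Dirichlet(`dirichlet_conc`) draw over
#' `alleles_per_locus` allele classes. Allele fragment sizes are spaced one
#' repeat motif apart from a per-locus base size.
#'
#' @param scenario A `sim_scenario`; its seed makes the draw reproducible.
#' @return An `allele_freq_table` (estimation mode `"population"`).
#' @export
draw_population_freqs <- function(scenario) {
  set.seed(scenario$seed)
  .draw_freqs(scenario)
}

.draw_freqs <- function(sc) {
  out <- vector("list", sc$n_loci)
  names(out) <- sprintf("L%02d", seq_len(sc$n_loci))
  for (i in seq_len(sc$n_loci)) {
    g <- stats::rgamma(sc$alleles_per_locus, shape = sc$dirichlet_conc)
    # guard against an all-but-degenerate draw
    g <- pmax(g, 1e-12)
    sizes <- 100L + 20L * (i - 1L) + sc$motif * (seq_len(sc$alleles_per_locus) - 1L)
    out[[i]] <- stats::setNames(g / sum(g), sizes)
  }
  structure(out, class = "allele_freq_table", estimation_mode = "population")
}

# draw one HWE diploid genotype (L x 2 matrix, canonical order)
.draw_genotype <- function(freqs) {
  t(vapply(freqs, function(f) {
    a <- sort(sample(as.integer(names(f)), 2L, replace = TRUE, prob = f))
    a
  }, integer(2)))
}

.genotype_distance <- function(g1, g2) {
  sum(vapply(seq_len(nrow(g1)), function(l) {
    .locus_mismatch(g1[l, 1L], g1[l, 2L], g2[l, 1L], g2[l, 2L])
  }, integer(1)))
}

# fold a coordinate into [0, w] by reflection
.reflect <- function(x, w) {
  x <- x %% (2 * w)
  ifelse(x > w, 2 * w - x, x)
}

#' Simulate one quadrat
#'
#' Runs the full generative model of a [sim_scenario()] and applies the
#' one-ramet-per-cell-per-stage sampling protocol. Deterministic under the
#' scenario seed.
#'
#' @param scenario A `sim_scenario`.
#' @return List with `sample_set` (the sampled, genotyped records in the
#'   standard interchange layout) and `truth` (class `sim_truth`: founder
#'   genotypes and positions, all ramet positions with true genet ids and
#'   stages, per-cell stem counts, true genet id and mutation/error flags
#'   per sampled record).
#' @export
simulate_quadrat <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  W <- sc$grid_cols * sc$cell_size
  H <- sc$grid_rows * sc$cell_size

  freqs <- .draw_freqs(sc)

  # founder genotypes, enforced pairwise-distinct beyond mutation scale
  founders <- vector("list", sc$n_founders)
  for (f in seq_len(sc$n_founders)) {
    for (try in seq_len(1000L)) {
      g <- .draw_genotype(freqs)
      ok <- f == 1L || all(vapply(founders[seq_len(f - 1L)],
                                  function(prev) .genotype_distance(g, prev),
                                  integer(1)) >= sc$min_founder_distance)
      if (ok) break
      if (try == 1000L)
        stop("could not draw genetically distinct founders; increase ",
             "alleles_per_locus or n_loci, or lower min_founder_distance")
    }
    founders[[f]] <- g
  }
  founder_xy <- cbind(x = stats::runif(sc$n_founders, 0, W),
                      y = stats::runif(sc$n_founders, 0, H))

  # branching stolon walks
  pos_list <- vector("list", sc$n_founders)
  for (f in seq_len(sc$n_founders)) {
    n_r <- max(1L, stats::rnbinom(1L, size = sc$nb_dispersion,
                                  mu = sc$ramets_per_founder))
    pos <- matrix(NA_real_, n_r, 2L)
    tips <- matrix(founder_xy[f, ], 1L, 2L)
    for (r in seq_len(n_r)) {
      ti <- sample.int(nrow(tips), 1L)
      step <- stats::rexp(1L, rate = 1 / sc$stolon_step_mean)
      ang <- stats::runif(1L, 0, 2 * pi)
      p <- c(.reflect(tips[ti, 1L] + step * cos(ang), W),
             .reflect(tips[ti, 2L] + step * sin(ang), H))
      pos[r, ] <- p
      if (stats::runif(1L) < sc$branch_prob) {
        tips <- rbind(tips, p)          # branch: old tip stays active too
      } else {
        tips[ti, ] <- p                 # linear growth: tip advances
      }
    }
    pos_list[[f]] <- pos
  }
  all_pos <- do.call(rbind, pos_list)
  if (!nrow(all_pos))
    stop("no ramets generated; increase ramets_per_founder")
  all_genet <- rep(seq_len(sc$n_founders),
                   vapply(pos_list, nrow, integer(1)))
  all_stage <- ifelse(stats::runif(nrow(all_pos)) < sc$on_tree_prob,
                      "on_tree", "on_floor")

  cs <- sc$cell_size
  cell_row <- pmin(sc$grid_rows, floor(all_pos[, 2L] / cs) + 1L)
  cell_col <- pmin(sc$grid_cols, floor(all_pos[, 1L] / cs) + 1L)
  cell_counts <- matrix(0L, sc$grid_rows, sc$grid_cols)
  for (i in seq_along(cell_row))
    cell_counts[cell_row[i], cell_col[i]] <-
      cell_counts[cell_row[i], cell_col[i]] + 1L

  # sampling protocol: one ramet per (cell, stage), uniform among occupants
  sel <- integer(0)
  for (rr in seq_len(sc$grid_rows)) {
    for (cc in seq_len(sc$grid_cols)) {
      for (st in .stages) {
        occ <- which(cell_row == rr & cell_col == cc & all_stage == st)
        if (length(occ))
          sel <- c(sel, occ[sample.int(length(occ), 1L)])
      }
    }
  }

  loci <- names(freqs)
  panel <- marker_panel(loci, motif = sc$motif)
  n_s <- length(sel)
  geno <- matrix(NA_integer_, n_s, 2L * sc$n_loci)
  mutated <- logical(n_s)
  miscalled <- logical(n_s)
  for (k in seq_len(n_s)) {
    g <- founders[[all_genet[sel[k]]]]
    # somatic mutation: stepwise +/- one repeat unit
    if (sc$somatic_mutation_rate > 0) {
      hit <- stats::runif(2L * sc$n_loci) < sc$somatic_mutation_rate
      if (any(hit)) {
        mutated[k] <- TRUE
        gv <- as.vector(g)
        gv[hit] <- gv[hit] + sample(c(-1L, 1L), sum(hit),
                                    replace = TRUE) * sc$motif
        g <- matrix(gv, ncol = 2L)
      }
    }
    # genotyping error: re-draw the allele from the locus pool
    if (sc$genotyping_error_rate > 0) {
      hit <- stats::runif(2L * sc$n_loci) < sc$genotyping_error_rate
      if (any(hit)) {
        miscalled[k] <- TRUE
        for (idx in which(hit)) {
          l <- (idx - 1L) %% sc$n_loci + 1L
          g[l, (idx - 1L) %/% sc$n_loci + 1L] <-
            sample(as.integer(names(freqs[[l]])), 1L, prob = freqs[[l]])
        }
      }
    }
    g <- t(apply(g, 1L, sort))
    geno[k, ] <- as.vector(t(g))
  }
  geno_df <- as.data.frame(geno)
  names(geno_df) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))

  ord <- order(cell_row[sel], cell_col[sel], match(all_stage[sel], .stages))
  df <- cbind(
    data.frame(sample_id = sprintf("%s_%03d", sc$quadrat_id, seq_len(n_s)),
               quadrat_id = sc$quadrat_id,
               row = cell_row[sel], col = cell_col[sel],
               stage = all_stage[sel], stringsAsFactors = FALSE),
    geno_df
  )[ord, , drop = FALSE]
  df$sample_id <- sprintf("%s_%03d", sc$quadrat_id, seq_len(n_s))
  rownames(df) <- NULL

  layouts <- quadrat_layout(sc$quadrat_id, sc$forest_type, sc$grid_rows,
                            sc$grid_cols, sc$cell_size)
  ss <- sample_set(panel, layouts, df)

  truth <- structure(
    list(scenario = sc,
         population_freqs = freqs,
         founder_genotypes = founders,
         founder_positions = founder_xy,
         ramet_positions = all_pos,
         ramet_genet = all_genet,
         ramet_stage = all_stage,
         cell_counts = cell_counts,
         sampled_index = sel[ord],
         genet_of_sample = stats::setNames(all_genet[sel][ord],
                                           df$sample_id),
         mutated = stats::setNames(mutated[ord], df$sample_id),
         miscalled = stats::setNames(miscalled[ord], df$sample_id)),
    class = "sim_truth"
  )
  list(sample_set = ss, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", x$scenario$n_founders, "founders,",
      nrow(x$ramet_positions), "ramets generated,",
      length(x$genet_of_sample), "sampled\n")
  invisible(x)
}

#' Sub-quadrat stem counts from simulation truth
#'
#' Emulates the density protocol: `n` grid cells are drawn at random
#' without replacement and their true stem counts reported.
#'
#' @param truth A `sim_truth`.
#' @param n Number of sub-quadrats (default from the scenario).
#' @param seed Optional seed for the cell draw.
#' @return Integer vector of length `n`, usable with [stem_density()].
#' @export
subquadrat_counts <- function(truth, n = truth$scenario$n_subquadrats,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- sample.int(length(truth$cell_counts), n)
  as.integer(truth$cell_counts[cells])
}
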