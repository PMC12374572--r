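#' Marker panel description
#'
#' A panel of co-dominant microsatellite (SSR) loci scored as diploid
#' fragment-size genotypes. Allele calls are integer fragment sizes in base
#' pairs; the repeat-motif length is used by the simulator's stepwise
#' somatic-mutation model.
#'
#' @param loci Character vector of unique locus names (length L >= 1).
#' @param motif Integer repeat-motif length in bp (default 2, i.e.
#'   dinucleotide repeats).
#' @param allele_range Optional 2-column matrix/data.frame of per-locus
#'   min/max fragment sizes; purely descriptive.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(loci, motif = 2L, allele_range = NULL) {
  loci <- as.character(loci)
  if (length(loci) < 1L) stop("a marker panel needs at least one locus")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (motif < 1L) stop("motif length must be a positive integer")
  structure(
    list(loci = loci, ploidy = 2L, motif = as.integer(motif),
         allele_range = allele_range),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", length(x$loci), "diploid SSR loci (motif",
      x$motif, "bp)\n")
  cat(" ", paste(x$loci, collapse = ", "), "\n")
  invisible(x)
}

#' Quadrat layout table
#'
#' Describes the sampling quadrats: a rectangular grid of square cells (the
#' field protocol used 10 x 10 m quadrats divided into 1 x 1 m grid cells).
#'
#' @param quadrat_id Character vector of quadrat identifiers.
#' @param forest_type Character vector, one of `"young"`, `"old_growth"`, or
#'   `NA` when the grouping is not known.
#' @param grid_rows,grid_cols Grid dimensions (default 10 x 10).
#' @param cell_size Cell edge length in meters (default 1).
#' @return A data.frame with one row per quadrat.
#' @export
quadrat_layout <- function(quadrat_id, forest_type = NA_character_,
                           grid_rows = 10L, grid_cols = 10L, cell_size = 1) {
  quadrat_id <- as.character(quadrat_id)
  if (anyDuplicated(quadrat_id)) stop("quadrat ids must be unique")
  ft <- rep_len(as.character(forest_type), length(quadrat_id))
  bad <- !is.na(ft) & !ft %in% c("young", "old_growth")
  if (any(bad)) stop("forest_type must be 'young', 'old_growth' or NA")
  out <- data.frame(
    quadrat_id = quadrat_id,
    forest_type = ft,
    grid_rows = as.integer(rep_len(grid_rows, length(quadrat_id))),
    grid_cols = as.integer(rep_len(grid_cols, length(quadrat_id))),
    cell_size = as.numeric(rep_len(cell_size, length(quadrat_id))),
    stringsAsFactors = FALSE
  )
  if (any(out$grid_rows < 1L) || any(out$grid_cols < 1L))
    stop("grid dimensions must be >= 1")
  if (any(out$cell_size <= 0)) stop("cell_size must be positive")
  out
}

.stages <- c("on_floor", "on_tree")

#' Construct and validate a grid-referenced genotype sample set
#'
#' The central container: one row per sampled ramet with its quadrat, 1-based
#' grid cell, life stage, and a diploid genotype at every panel locus stored
#' as two integer columns `<locus>_1`, `<locus>_2` (canonical ascending
#' order; `NA` for missing — both alleles or neither).
#'
#' Row order is preserved and is the canonical order for all deterministic
#' tie-breaking downstream (MLG ids, round-robin representatives, genet ids).
#'
#' @param panel A [marker_panel()].
#' @param layouts A [quadrat_layout()] data.frame.
#' @param data A data.frame with columns `sample_id`, `quadrat_id`, `row`,
#'   `col`, `stage`, then `<locus>_1`, `<locus>_2` for each panel locus.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(panel, layouts, data) {
  stopifnot(inherits(panel, "marker_panel"))
  allele_cols <- as.vector(rbind(paste0(panel$loci, "_1"),
                                 paste0(panel$loci, "_2")))
  need <- c("sample_id", "quadrat_id", "row", "col", "stage", allele_cols)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("sample data is missing columns: ", paste(miss, collapse = ", "))
  data <- data[, need, drop = FALSE]
  data$sample_id <- as.character(data$sample_id)
  data$quadrat_id <- as.character(data$quadrat_id)
  data$row <- as.integer(data$row)
  data$col <- as.integer(data$col)
  data$stage <- as.character(data$stage)
  rownames(data) <- NULL

  if (anyDuplicated(data$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(data$sample_id[duplicated(data$sample_id)]),
               collapse = ", "))
  if (!all(data$stage %in% .stages))
    stop("unknown stage token: ",
         paste(unique(setdiff(data$stage, .stages)), collapse = ", "))
  unknown_q <- setdiff(data$quadrat_id, layouts$quadrat_id)
  if (length(unknown_q))
    stop("records reference quadrats with no layout: ",
         paste(unknown_q, collapse = ", "))
  li <- match(data$quadrat_id, layouts$quadrat_id)
  bad_cell <- data$row < 1L | data$col < 1L |
    data$row > layouts$grid_rows[li] | data$col > layouts$grid_cols[li]
  if (any(bad_cell))
    stop("grid cell outside quadrat for sample(s): ",
         paste(data$sample_id[bad_cell], collapse = ", "))
  key <- paste(data$quadrat_id, data$row, data$col, data$stage)
  if (anyDuplicated(key))
    stop("more than one record per (quadrat, cell, stage): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  # canonicalize allele pairs: ascending, both-or-neither missing
  for (loc in panel$loci) {
    a <- as.integer(data[[paste0(loc, "_1")]])
    b <- as.integer(data[[paste0(loc, "_2")]])
    a[!is.na(a) & a == 0L] <- NA_integer_
    b[!is.na(b) & b == 0L] <- NA_integer_
    half <- xor(is.na(a), is.na(b))
    if (any(half))
      stop("half-missing genotype at locus ", loc, " for sample(s): ",
           paste(data$sample_id[half], collapse = ", "))
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    data[[paste0(loc, "_1")]] <- lo
    data[[paste0(loc, "_2")]] <- hi
  }

  structure(list(panel = panel, layouts = layouts, data = data),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("Grid-referenced genotype sample set\n")
  cat("  ", nrow(x$data), "ramets |", length(x$panel$loci), "loci |",
      nrow(x$layouts), "quadrat(s)\n")
  tab <- table(x$data$quadrat_id, x$data$stage)
  print(tab)
  invisible(x)
}

n_samples <- function(ss) nrow(ss$data)
n_loci <- function(ss) length(ss$panel$loci)

#' Genotype matrix of a sample set
#'
#' @param ss A `sample_set`.
#' @param loci Optional subset of locus names.
#' @return Integer matrix with one row per sample and two columns per locus
#'   (`<locus>_1`, `<locus>_2`), alleles in canonical ascending order.
#' @export
genotype_matrix <- function(ss, loci = NULL) {
  loci <- if (is.null(loci)) ss$panel$loci else match.arg(loci, ss$panel$loci,
                                                          several.ok = TRUE)
  cols <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  m <- as.matrix(ss$data[, cols, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ss$data$sample_id
  m
}

#' Metric ramet positions (cell centers)
#'
#' The field protocol records presence per grid cell, not sub-cell
#' coordinates, so the metric position of a ramet is its cell center:
#' x = (col - 1/2) * cell_size east of the quadrat origin,
#' y = (row - 1/2) * cell_size north of it.
#'
#' @param ss A `sample_set`.
#' @return Numeric matrix with columns `x`, `y` (meters), one row per sample.
#' @export
ramet_positions <- function(ss) {
  li <- match(ss$data$quadrat_id, ss$layouts$quadrat_id)
  cs <- ss$layouts$cell_size[li]
  cbind(x = (ss$data$col - 0.5) * cs, y = (ss$data$row - 0.5) * cs)
}

#' Read a genotype table from CSV
#'
#' Flat GenAlEx-style layout: header `sample_id, quadrat_id, row, col, stage`
#' followed by two columns per locus named `<locus>_1`, `<locus>_2`. Missing
#' alleles are encoded as 0 or an empty field (both alleles of a locus must
#' be missing together). Quadrat metadata (forest types, grid dimensions)
#' travels in a sidecar JSON config, not in the CSV.
#'
#' @param path CSV file path.
#' @param panel Optional [marker_panel()]; inferred from the header when
#'   `NULL` (motif defaults to 2 bp).
#' @param layouts Optional [quadrat_layout()] data.frame or path to a JSON
#'   sidecar written by [write_layouts()]; defaults to 10 x 10 quadrats with
#'   unknown forest type.
#' @return A validated `sample_set`; row order of the file is preserved.
#' @export
read_genotype_table <- function(path, panel = NULL, layouts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  meta_cols <- c("sample_id", "quadrat_id", "row", "col", "stage")
  if (!all(meta_cols %in% names(df)))
    stop("genotype table must have columns ",
         paste(meta_cols, collapse = ", "))
  if (is.null(panel)) {
    geno_cols <- setdiff(names(df), meta_cols)
    l1 <- grep("_1$", geno_cols, value = TRUE)
    loci <- sub("_1$", "", l1)
    if (!length(loci) || !all(paste0(loci, "_2") %in% geno_cols))
      stop("cannot infer locus columns: need paired <locus>_1/<locus>_2")
    panel <- marker_panel(loci)
  }
  for (cc in setdiff(names(df), c("sample_id", "quadrat_id", "stage"))) {
    v <- df[[cc]]
    v[v == ""] <- NA
    df[[cc]] <- suppressWarnings(as.integer(v))
  }
  if (is.null(layouts)) {
    layouts <- quadrat_layout(unique(df$quadrat_id))
  } else if (is.character(layouts)) {
    layouts <- read_layouts(layouts)
  }
  sample_set(panel, layouts, df)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]: the written file re-reads to an
#' identical `sample_set`, and write/read/write is byte-stable. Missing
#' alleles are written as 0.
#'
#' @param ss A `sample_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ss, path) {
  df <- ss$data
  for (loc in ss$panel$loci) {
    for (suf in c("_1", "_2")) {
      v <- df[[paste0(loc, suf)]]
      v[is.na(v)] <- 0L
      df[[paste0(loc, suf)]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the quadrat-layout sidecar config (JSON)
#'
#' @param layouts A [quadrat_layout()] data.frame.
#' @param path JSON file path.
#' @return `read_layouts` returns the layout data.frame.
#' @export
write_layouts <- function(layouts, path) {
  jsonlite::write_json(layouts, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_layouts
#' @export
read_layouts <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  quadrat_layout(df$quadrat_id, df$forest_type, df$grid_rows, df$grid_cols,
                 df$cell_size)
}

#' Drop samples with any missing locus
#'
#' Strict missing-data policy (the default throughout): clone discrimination
#' sees only fully genotyped samples, mirroring the usual retention rule in
#' SSR clonality studies. Retained genotypes are untouched.
#'
#' @param ss A `sample_set`.
#' @return A list with elements `sample_set` (the retained records, original
#'   order), `dropped` (character vector of removed sample ids), `n_dropped`
#'   and `n_retained`.
#' @export
drop_incomplete_samples <- function(ss) {
  gm <- genotype_matrix(ss)
  incomplete <- apply(is.na(gm), 1L, any)
  kept <- ss
  kept$data <- ss$data[!incomplete, , drop = FALSE]
  rownames(kept$data) <- NULL
  list(sample_set = kept,
       dropped = ss$data$sample_id[incomplete],
       n_dropped = sum(incomplete),
       n_retained = sum(!incomplete))
}

#' Restrict a sample set to one quadrat
#'
#' @param ss A `sample_set`.
#' @param quadrat_id A quadrat identifier present in the layouts.
#' @return A `sample_set` containing only that quadrat's records.
#' @export
subset_quadrat <- function(ss, quadrat_id) {
  if (!quadrat_id %in% ss$layouts$quadrat_id)
    stop("unknown quadrat id: ", quadrat_id)
  out <- ss
  out$data <- ss$data[ss$data$quadrat_id == quadrat_id, , drop = FALSE]
  rownames(out$data) <- NULL
  out$layouts <- ss$layouts[ss$layouts$quadrat_id == quadrat_id, ,
                            drop = FALSE]
  out
}
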