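test_that("CSV round-trip preserves a toy table and canonicalizes alleles", {
  csv <- file.path(tempdir(), "toy.csv")
  writeLines(c(
    "sample_id,quadrat_id,row,col,stage,LA_1,LA_2,LB_1,LB_2",
    "s1,Q1,1,1,on_floor,102,100,200,200",
    "s2,Q1,1,2,on_floor,100,100,200,202",
    "s3,Q1,2,1,on_tree,104,102,202,202"), csv)
  ss <- read_genotype_table(csv)
  expect_s3_class(ss, "sample_set")
  expect_equal(nrow(ss$data), 3L)
  expect_equal(ss$panel$loci, c("LA", "LB"))
  # (102, 100) stored ascending
  expect_equal(unname(unlist(ss$data[1, c("LA_1", "LA_2")])), c(100L, 102L))

  out <- file.path(tempdir(), "toy_out.csv")
  write_genotype_table(ss, out)
  ss2 <- read_genotype_table(out)
  expect_equal(ss2$data, ss$data)
  # write(read(write(read(f)))) is byte-stable
  out2 <- file.path(tempdir(), "toy_out2.csv")
  write_genotype_table(ss2, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("validation rejects malformed records", {
  base <- data.frame(sample_id = c("a", "b"), quadrat_id = "Q1",
                     row = c(1L, 2L), col = 1L, stage = "on_floor",
                     LA_1 = c(100L, 102L), LA_2 = c(100L, 104L))
  panel <- marker_panel("LA")
  lay <- quadrat_layout("Q1")
  expect_s3_class(sample_set(panel, lay, base), "sample_set")

  half <- base; half$LA_2[1] <- 0L
  expect_error(sample_set(panel, lay, half), "half-missing")
  dup <- base; dup$sample_id <- "a"
  expect_error(sample_set(panel, lay, dup), "duplicate sample_id")
  out <- base; out$row[1] <- 11L
  expect_error(sample_set(panel, lay, out), "outside")
  st <- base; st$stage[1] <- "underground"
  expect_error(sample_set(panel, lay, st), "stage")
  clash <- base; clash$row <- 1L; clash$col <- 1L
  expect_error(sample_set(panel, lay, clash), "more than one record")
})

test_that("canonicalization is order-insensitive and idempotent", {
  g1 <- make_ss(list(c(102, 100, 200, 202)))
  g2 <- make_ss(list(c(100, 102, 202, 200)))
  expect_equal(genotype_matrix(g1), genotype_matrix(g2),
               ignore_attr = TRUE)
})

test_that("drop_incomplete_samples keeps exactly the fully genotyped", {
  # synthetic fixture mirroring the benchmark campaign: 592 collected,
  # 6 with at least one failed locus, 586 fully genotyped
  set.seed(42)
  n <- 592L
  L <- 11L
  loci <- sprintf("L%02d", seq_len(L))
  geno <- matrix(sample(seq(100L, 130L, 2L), n * 2L * L, replace = TRUE),
                 n, 2L * L)
  geno <- t(apply(geno, 1L, function(v) {
    m <- matrix(v, ncol = 2L, byrow = TRUE)
    as.vector(t(t(apply(m, 1L, sort))))
  }))
  miss <- sample(n, 6L)
  for (i in miss) geno[i, 1:2] <- NA_integer_
  i0 <- seq_len(n) - 1L
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                   quadrat_id = sprintf("Q%d", i0 %/% 100L + 1L),
                   row = (i0 %% 100L) %/% 10L + 1L,
                   col = i0 %% 10L + 1L,
                   stage = "on_floor")
  gdf <- as.data.frame(geno)
  names(gdf) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  ss <- sample_set(marker_panel(loci), quadrat_layout(sprintf("Q%d", 1:6)),
                   cbind(df, gdf))
  res <- drop_incomplete_samples(ss)
  expect_equal(res$n_retained, 586L)
  expect_equal(res$n_dropped, 6L)
  expect_setequal(res$dropped, sprintf("S%03d", sort(miss)))
  # retained genotypes untouched
  kept_ids <- res$sample_set$data$sample_id
  expect_equal(res$sample_set$data,
               ss$data[ss$data$sample_id %in% kept_ids, ],
               ignore_attr = TRUE)

  # no missing data -> identity
  res2 <- drop_incomplete_samples(res$sample_set)
  expect_equal(res2$n_dropped, 0L)
  expect_equal(res2$sample_set$data, res$sample_set$data)

  # everything missing -> empty set with full report
  allmiss <- ss
  allmiss$data$L01_1 <- NA_integer_
  allmiss$data$L01_2 <- NA_integer_
  res3 <- drop_incomplete_samples(allmiss)
  expect_equal(res3$n_retained, 0L)
  expect_equal(length(res3$dropped), n)
})

test_that("simulator output round-trips losslessly through CSV", {
  for (seed in c(1L, 7L)) {
    sim <- simulate_quadrat(sim_scenario(seed = seed, n_founders = 3L,
                                         ramets_per_founder = 60))
    f <- file.path(tempdir(), sprintf("sim%d.csv", seed))
    write_genotype_table(sim$sample_set, f)
    back <- read_genotype_table(f, layouts = sim$sample_set$layouts)
    expect_equal(back$data, sim$sample_set$data)
    expect_equal(back$panel$loci, sim$sample_set$panel$loci)
  }
})

test_that("layout sidecar JSON round-trips", {
  lay <- quadrat_layout(c("A", "B"), c("young", "old_growth"))
  f <- file.path(tempdir(), "lay.json")
  write_layouts(lay, f)
  expect_equal(read_layouts(f), lay)
})
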