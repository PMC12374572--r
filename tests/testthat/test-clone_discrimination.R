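test_that("collapse_mlgs groups identical genotypes, splits different ones", {
  g <- c(100, 102, 200, 200)
  ss <- make_ss(list(g, g, c(100, 104, 200, 200)))
  p <- collapse_mlgs(ss)
  expect_equal(p$n_mlgs, 2L)
  expect_equal(p$mlg_id, c(1L, 1L, 2L))
  empty <- ss
  empty$data <- ss$data[0, , drop = FALSE]
  expect_error(collapse_mlgs(empty), "empty")
  # ids are dense, assigned by first occurrence
  ss2 <- make_ss(list(c(100, 104, 200, 200), g, g))
  expect_equal(collapse_mlgs(ss2)$mlg_id, c(1L, 2L, 2L))
})

test_that("collapse_mlgs is a partition on random inputs", {
  ss <- random_ss(40, L = 3, seed = 11)
  p <- collapse_mlgs(ss)
  gm <- genotype_matrix(ss)
  for (i in seq_len(39)) {
    for (j in (i + 1L):40L) {
      same_geno <- all(gm[i, ] == gm[j, ])
      expect_equal(p$mlg_id[i] == p$mlg_id[j], same_geno)
    }
  }
  expect_equal(sort(unique(p$mlg_id)), seq_len(p$n_mlgs))
})

test_that("round-robin frequencies follow the leave-one-locus-out rule", {
  # A=(100/100, 200/200), B=(100/100, 200/202), C=(102/104, 200/200):
  # locus-1 representatives come from locus-2-only MLGs {A,C}->A, {B}->B,
  # so f1(100) = 1.0; locus-2 representatives from locus-1-only MLGs
  # {A,B}->A, {C}->C, so f2(200) = 1.0
  ss <- make_ss(list(c(100, 100, 200, 200),
                     c(100, 100, 200, 202),
                     c(102, 104, 200, 200)))
  fr <- round_robin_freqs(ss)
  expect_equal(fr$L01, c("100" = 1.0))
  expect_equal(fr$L02, c("200" = 1.0))
})

test_that("round-robin degenerates sensibly", {
  # all samples one clone: single representative per locus
  g <- c(100, 102, 200, 200)
  fr <- round_robin_freqs(make_ss(list(g, g, g)))
  expect_equal(fr$L01, c("100" = 0.5, "102" = 0.5))
  expect_equal(fr$L02, c("200" = 1.0))
  # single locus falls back to plain with a warning
  expect_warning(f1 <- allele_freqs(make_ss(list(c(100, 102))), "round_robin"),
                 "single locus")
  expect_equal(attr(f1, "estimation_mode"), "plain")
})

test_that("plain and round-robin agree when every projection is all-unique", {
  gs <- lapply(1:6, function(i) {
    a <- 100 + 2 * i
    matrix(rep(a, 6), ncol = 2, byrow = TRUE)  # homozygote a at 3 loci
  })
  ss <- make_ss(gs)
  expect_equal(unclass(allele_freqs(ss, "plain")),
               unclass(allele_freqs(ss, "round_robin")),
               ignore_attr = TRUE)
})

test_that("pgen implements the product-times-2^h formula", {
  # single locus, homozygote, f = 1 -> 1
  f1 <- structure(list(L01 = c("100" = 1.0)), class = "allele_freq_table")
  expect_equal(pgen(c(100, 100), f1), 1.0)
  # het (0.5, 0.5) and hom (0.2): 2 * 0.5 * 0.5 * 0.2 * 0.2 = 0.02
  f2 <- structure(list(L01 = c("100" = 0.5, "102" = 0.5),
                       L02 = c("200" = 0.2, "202" = 0.8)),
                  class = "allele_freq_table")
  expect_equal(pgen(c(100, 102, 200, 200), f2), 0.02)
  # unknown allele is a hard error
  expect_error(pgen(c(104, 104), f1), "absent")
})

test_that("log-space pgen equals the naive product on random inputs", {
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(3:12, 1)
    fr <- lapply(seq_len(L), function(i) {
      p <- stats::runif(4, 0.05, 1); p <- p / sum(p)
      stats::setNames(p, seq(100, 106, 2))
    })
    names(fr) <- sprintf("L%02d", seq_len(L))
    fr <- structure(fr, class = "allele_freq_table")
    g <- t(vapply(seq_len(L),
                  function(i) sort(sample(seq(100L, 106L, 2L), 2, TRUE)),
                  integer(2)))
    naive <- prod(vapply(seq_len(L), function(i) {
      fa <- fr[[i]][as.character(g[i, 1])]
      fb <- fr[[i]][as.character(g[i, 2])]
      unname(fa * fb * if (g[i, 1] != g[i, 2]) 2 else 1)
    }, numeric(1)))
    expect_equal(pgen(g, fr), naive, tolerance = 1e-12)
    # adding loci weakly decreases pgen
    expect_lte(pgen(g, fr), pgen(g[-L, , drop = FALSE], fr[-L]) + 1e-15)
  }
})

test_that("psex is the printed binomial upper tail", {
  expect_equal(psex(0, 1, 10), 0)
  # N = 2, n = 1, p = 0.5: 1 - (1 - 0.5)^2 = 0.75 (enumerate 4 outcomes)
  expect_equal(psex(0.5, 1, 2), 0.75)
  # closed form psex(p, 1, N) = 1 - (1 - p)^N
  for (p in c(0.01, 0.3, 0.9)) {
    for (N in c(2L, 17L, 100L)) {
      expect_equal(psex(p, 1, N), 1 - (1 - p)^N, tolerance = 1e-12)
    }
  }
  # n-1 convention is exposed
  expect_equal(psex(0.5, 1, 2, convention = "n_minus_1"), 1)
  expect_error(psex(0.5, 3, 2), "n <= N")
})

test_that("pairwise distances count allele mismatches optimally", {
  ss <- make_ss(list(c(100, 102, 200, 200),
                     c(100, 102, 200, 200),
                     c(100, 104, 200, 200),   # one allele off
                     c(102, 104, 200, 202)))  # shares 102 at locus 1
  p <- collapse_mlgs(ss)
  d <- pairwise_mlg_distances(ss, p)
  expect_equal(p$n_mlgs, 3L)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0L))
  expect_equal(d[1, 2], 1L)   # (100,102) vs (100,104)
  expect_equal(d[1, 3], 2L)   # (100,102)vs(102,104)=1 plus locus2 =1
  expect_equal(d[2, 3], 2L)   # (100,104)vs(102,104)=1 plus locus2 =1
})

test_that("cutoff predictor follows the retained-gap rule", {
  # ultrametric design with merge heights exactly {1, 2, 8, 9, 10}
  h <- matrix(10, 6, 6)
  h[1:5, 1:5] <- 9
  h[1:4, 1:4] <- 8
  h[1:3, 1:3] <- 2
  h[1:2, 1:2] <- 1
  diag(h) <- 0
  thr <- predict_mll_threshold(h, clonal_fraction = 0.5)
  expect_equal(as.numeric(thr), 5.0)
  expect_equal(attr(thr, "candidates"), c(1, 2, 8, 9, 10))
  expect_equal(attr(thr, "retained"), c(1, 2, 8))

  # all pairwise distances equal -> a single candidate -> 0
  eq <- matrix(3, 4, 4); diag(eq) <- 0
  expect_equal(as.numeric(predict_mll_threshold(eq)), 0)
  # fewer than 2 MLGs -> 0
  expect_equal(as.numeric(predict_mll_threshold(matrix(0, 1, 1))), 0)

  # mutant clouds: four well-separated clusters (within-cluster distances
  # <= 2 as from single/double somatic mutations, between-cluster >= 8):
  # the predicted threshold must fall strictly between the two scales
  pairs_at <- c(1, 2, 1, 2)            # within-cluster merge heights
  d2 <- matrix(0, 8, 8)
  cl <- rep(1:4, each = 2)
  between <- matrix(c(0, 8, 9, 10,
                      8, 0, 9, 10,
                      9, 9, 0, 10,
                      10, 10, 10, 0), 4, byrow = TRUE)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      d2[i, j] <- d2[j, i] <- if (cl[i] == cl[j]) pairs_at[cl[i]] else
        between[cl[i], cl[j]]
    }
  }
  t2 <- as.numeric(predict_mll_threshold(d2))
  expect_gt(t2, 2)
  expect_lt(t2, 8)
})

test_that("assign_mlls agglomerates per the documented merge-order rule", {
  ss <- make_ss(list(c(100, 100), c(100, 102), c(104, 106)))
  p <- collapse_mlgs(ss)
  d <- matrix(c(0, 1, 5,
                1, 0, 1,
                5, 1, 0), 3, byrow = TRUE)
  far <- assign_mlls(p, d, threshold = 1, linkage = "farthest")
  expect_equal(far$genet_of_mlg, c(1L, 1L, 2L))   # ties -> lowest ids first
  near <- assign_mlls(p, d, threshold = 1, linkage = "nearest")
  expect_equal(near$genet_of_mlg, c(1L, 1L, 1L))
  # threshold 0 is the identity
  id0 <- assign_mlls(p, d, threshold = 0)
  expect_equal(id0$genet_of_mlg, seq_len(3L))
  expect_equal(id0$n_genets, p$n_mlgs)
})

test_that("MLL count is monotone in threshold; nearest <= farthest", {
  set.seed(21)
  ss <- random_ss(25, L = 4, seed = 21)
  p <- collapse_mlgs(ss)
  d <- pairwise_mlg_distances(ss, p)
  prev_f <- Inf
  for (thr in c(0, 1, 2, 4, 8, 16)) {
    gf <- assign_mlls(p, d, thr, "farthest")$n_genets
    gn <- assign_mlls(p, d, thr, "nearest")$n_genets
    expect_lte(gf, prev_f)
    expect_lte(gn, gf)
    prev_f <- gf
  }
})

test_that("accumulation curve is exhaustive, monotone, plateau-correct", {
  # locus 1 alone separates all three samples; loci 2-3 are constant
  gs <- list(c(100, 100, 200, 200, 300, 300),
             c(102, 102, 200, 200, 300, 300),
             c(104, 104, 200, 200, 300, 300))
  ac <- accumulation_curve(make_ss(gs))
  expect_equal(attr(ac, "plateau_k"), 1L)
  expect_equal(ac$max[1], 3)
  expect_equal(ac$n_subsets, choose(3, 1:3))
  expect_true(all(diff(ac$max) >= 0))
  expect_equal(ac$max[3], attr(ac, "n_mlgs"))

  # L = 1: single point equal to n_mlgs
  ss1 <- make_ss(list(c(100, 100), c(100, 102), c(100, 102)))
  ac1 <- accumulation_curve(ss1)
  expect_equal(nrow(ac1), 1L)
  expect_equal(ac1$max, 2)
})
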