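test_that("genet hulls: degenerate cases and shoelace areas", {
  p1 <- genet_hull(cbind(2.5, 3.5))
  expect_equal(p1$kind, "point")
  expect_equal(p1$area, 0)

  tri <- genet_hull(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(tri$kind, "polygon")
  expect_equal(tri$area, 0.5)

  sq <- genet_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(sq$area, 1.0)
  # interior points do not change the hull
  sq2 <- genet_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.4)))
  expect_equal(sq2$area, 1.0)
  expect_equal(nrow(sq2$hull), 4L)

  seg <- genet_hull(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(seg$kind, "segment")
  expect_equal(seg$area, 0)
})

test_that("hull area is invariant under rigid motions", {
  set.seed(31)
  for (rep in 1:10) {
    pts <- matrix(runif(16, 0, 10), ncol = 2)
    a0 <- genet_hull(pts)$area
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- sweep(pts %*% R, 2, runif(2, -5, 5), "+")
    expect_equal(genet_hull(moved)$area, a0, tolerance = 1e-9)
  }
})

test_that("overlap rules: polygons, degenerates, touching", {
  sq <- function(x0, y0, s = 1) genet_hull(rbind(
    c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s)))
  expect_equal(count_overlaps(list(sq(0, 0))), 0)
  # offset by (0.5, 0.5): positive-area intersection
  expect_equal(count_overlaps(list(sq(0, 0), sq(0.5, 0.5))), 1)
  # edge-touching squares do NOT overlap (measure-zero contact)
  expect_equal(count_overlaps(list(sq(0, 0), sq(1, 0))), 0)
  # disjoint
  expect_equal(count_overlaps(list(sq(0, 0), sq(3, 3))), 0)
  # point inside polygon counts; point on the closure counts
  pt_in <- genet_hull(cbind(0.5, 0.5))
  pt_on <- genet_hull(cbind(1, 0.5))
  pt_out <- genet_hull(cbind(2, 2))
  expect_equal(count_overlaps(list(sq(0, 0), pt_in)), 1)
  expect_equal(count_overlaps(list(sq(0, 0), pt_on)), 1)
  expect_equal(count_overlaps(list(sq(0, 0), pt_out)), 0)
  # segment crossing a polygon counts
  seg <- genet_hull(rbind(c(-1, 0.5), c(2, 0.5)))
  expect_equal(count_overlaps(list(sq(0, 0), seg)), 1)
  # two degenerate hulls never count, even when they intersect
  seg2 <- genet_hull(rbind(c(0.5, -1), c(0.5, 2)))
  expect_equal(count_overlaps(list(seg, seg2)), 0)
  expect_equal(count_overlaps(list(pt_in, pt_on)), 0)
})

test_that("polygon overlap agrees with the rasterization oracle", {
  set.seed(77)
  n_checked <- 0L
  for (rep in 1:40) {
    geoms <- lapply(1:3, function(i) {
      cells <- unique(cbind(sample(1:8, 6, TRUE), sample(1:8, 6, TRUE)))
      genet_hull(cells - 0.5, genet_id = i)
    })
    polys <- Filter(function(g) g$kind == "polygon", geoms)
    if (length(polys) < 2L) next
    for (i in seq_len(length(polys) - 1L)) {
      for (j in (i + 1L):length(polys)) {
        got <- clonalarch:::.hulls_overlap(polys[[i]], polys[[j]])
        want <- oracle_overlap_raster(polys[[i]]$hull, polys[[j]]$hull)
        expect_equal(got, want)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("jackknife overlap statistics follow the estimator", {
  sq <- function(x0, y0, s = 2) genet_hull(rbind(
    c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s)))
  # 3 genets, all pairs overlapping: every leave-one-out value is 1
  all3 <- list(sq(0, 0), sq(1, 1), sq(0.5, 0.5))
  st <- jackknife_overlaps(all3)
  expect_equal(st$total_overlaps, 3)
  expect_equal(st$loo, rep(1, 3))
  expect_equal(st$jk_mean, 1)
  expect_equal(st$jk_se, 0)
  expect_equal(c(st$ci_low, st$ci_high), c(1, 1))

  # excluding a genet with zero overlaps leaves the total unchanged
  with_lone <- c(all3, list(sq(20, 20)))
  st2 <- jackknife_overlaps(with_lone)
  expect_equal(st2$total_overlaps, 3)
  expect_equal(st2$loo[4], 3)

  # no overlapping pairs -> all zeros, CI [0, 0]
  st3 <- jackknife_overlaps(list(sq(0, 0), sq(10, 0), sq(0, 10)))
  expect_equal(st3$total_overlaps, 0)
  expect_equal(c(st3$ci_low, st3$ci_high), c(0, 0))

  # CI non-overlap helper
  expect_true(ci_nonoverlap(st, st3))
  expect_false(ci_nonoverlap(st, st2))

  # G < 2 -> undefined CI
  expect_true(is.na(jackknife_overlaps(list(sq(0, 0)))$ci_low))
})

test_that("identity-by-distance bins all pairs and conserves counts", {
  gA <- c(100, 100); gB <- c(102, 102)
  # hand layout: A at (1,1),(1,2); B at (1,3),(5,1)   [cells, row fixed]
  ss <- make_ss(list(gA, gA, gB, gB),
                rows = c(1, 1, 1, 5), cols = c(1, 2, 3, 1))
  cl <- discriminate_clones(ss, threshold = 0)
  cu <- identity_by_distance(cl$mll, ss, "Q1", bin_width = 1)
  # cell centers: (0.5,0.5), (1.5,0.5), (2.5,0.5), (0.5,4.5); pairs:
  # (1,2) d=1 same; (2,3) d=1 diff; (1,3) d=2 diff;
  # (1,4) d=4 diff; (2,4) d=sqrt(17) diff; (3,4) d=sqrt(20) same
  expect_equal(sum(cu$n_pairs), choose(4, 2))
  b1 <- cu[cu$bin_low == 1, ]
  expect_equal(b1$n_pairs, 2L)
  expect_equal(b1$fraction, 0.5)
  expect_equal(cu[cu$bin_low == 2, ]$fraction, 0)
  expect_equal(cu[cu$bin_low == 4, ]$n_pairs, 3L)
  expect_equal(cu[cu$bin_low == 4, ]$fraction, 1 / 3)

  # all ramets one genet -> fraction 1 in every non-empty bin
  ss1 <- make_ss(list(gA, gA, gA), rows = c(1, 2, 7), cols = c(1, 5, 9))
  cl1 <- discriminate_clones(ss1, threshold = 0)
  cu1 <- identity_by_distance(cl1$mll, ss1, "Q1")
  expect_true(all(cu1$fraction == 1))

  # invariant under genet relabeling
  relab <- cl$mll
  relab$genet_of_sample <- c(2L, 2L, 1L, 1L)
  cu2 <- identity_by_distance(relab, ss, "Q1")
  expect_equal(cu2, cu)
})

test_that("aggregate_identity_curves averages per bin across quadrats", {
  c1 <- structure(data.frame(bin_low = c(0, 1), bin_high = c(1, 2),
                             n_pairs = c(2L, 2L), n_same = c(2L, 1L),
                             fraction = c(1, 0.5)),
                  class = c("distance_identity_curve", "data.frame"))
  c2 <- c1; c2$fraction <- c(0.5, 0.5)
  agg <- aggregate_identity_curves(list(A = c1, B = c2))
  expect_equal(agg$mean, c(0.75, 0.5))
  expect_equal(agg$sd[1], stats::sd(c(1, 0.5)))
})

test_that("stem density validates and averages sub-quadrat counts", {
  expect_equal(stem_density(rep(0L, 10))$mean_density, 0)
  expect_equal(stem_density(rep(1L, 10))$mean_density, 1.0)
  expect_equal(stem_density(c(3L, 5L, 7L), n_subquadrats = 3L)$mean_density,
               5)
  expect_error(stem_density(1:9), "expected 10")
  expect_error(stem_density(c(-1L, rep(1L, 9))), "non-negative")
})

test_that("overlap count is symmetric in genet order", {
  set.seed(12)
  geoms <- lapply(1:5, function(i)
    genet_hull(cbind(runif(5, 0, 10), runif(5, 0, 10)), genet_id = i))
  expect_equal(count_overlaps(geoms), count_overlaps(rev(geoms)))
  M <- overlap_matrix(geoms)
  expect_true(isSymmetric(unname(M)))
})
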