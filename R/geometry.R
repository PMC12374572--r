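# Small exact-enough 2D computational-geometry kernel for convex hulls of
# ramet positions. All polygons are convex, stored as 2-column matrices of
# vertices in counter-clockwise order without a repeated closing vertex.

.geom_eps <- 1e-9

# signed area (shoelace); positive for counter-clockwise vertex order
.signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1L]; y <- p[, 2L]
  i2 <- c(2:n, 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

.ccw <- function(p) if (.signed_area(p) < 0) p[rev(seq_len(nrow(p))), ,
                                              drop = FALSE] else p

# cross product of (b - a) x (c - a)
.cross3 <- function(a, b, c) {
  (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
}

# is point q inside the closed convex polygon p (CCW)?
.point_in_convex <- function(q, p, eps = .geom_eps) {
  n <- nrow(p)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (.cross3(p[i, ], p[j, ], q) < -eps) return(FALSE)
  }
  TRUE
}

# vectorized point-in-closed-convex-polygon over many points (used by the
# rasterization oracle in the tests as well)
.points_in_convex <- function(qx, qy, p, eps = .geom_eps) {
  n <- nrow(p)
  inside <- rep(TRUE, length(qx))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (p[j, 1L] - p[i, 1L]) * (qy - p[i, 2L]) -
      (p[j, 2L] - p[i, 2L]) * (qx - p[i, 1L])
    inside <- inside & (cr >= -eps)
  }
  inside
}

# Sutherland-Hodgman: clip convex subject polygon by convex clip polygon
# (both CCW); returns the intersection polygon (possibly with < 3 vertices)
.clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    inp <- out
    out <- matrix(numeric(0), ncol = 2L)
    np <- nrow(inp)
    for (k in seq_len(np)) {
      p1 <- inp[k, ]
      p2 <- inp[if (k == np) 1L else k + 1L, ]
      d1 <- .cross3(a, b, p1)
      d2 <- .cross3(a, b, p2)
      if (d1 >= -.geom_eps) out <- rbind(out, p1)
      if ((d1 > .geom_eps && d2 < -.geom_eps) ||
          (d1 < -.geom_eps && d2 > .geom_eps)) {
        t <- d1 / (d1 - d2)
        out <- rbind(out, p1 + t * (p2 - p1))
      }
    }
  }
  out
}

# do segments (a1,a2) and (b1,b2) intersect (touching counts)?
.segments_intersect <- function(a1, a2, b1, b2, eps = .geom_eps) {
  d1 <- .cross3(b1, b2, a1)
  d2 <- .cross3(b1, b2, a2)
  d3 <- .cross3(a1, a2, b1)
  d4 <- .cross3(a1, a2, b2)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on_seg <- function(p, q, r) {
    abs(.cross3(p, q, r)) <= eps &&
      min(p[1L], q[1L]) - eps <= r[1L] && r[1L] <= max(p[1L], q[1L]) + eps &&
      min(p[2L], q[2L]) - eps <= r[2L] && r[2L] <= max(p[2L], q[2L]) + eps
  }
  on_seg(b1, b2, a1) || on_seg(b1, b2, a2) ||
    on_seg(a1, a2, b1) || on_seg(a1, a2, b2)
}

#' Convex hull of a genet's ramet positions
#'
#' The genet's footprint is the minimum convex polygon enclosing its ramet
#' positions (cell centers); its area (shoelace formula) is the genet size
#' in square meters. One or two distinct positions, or a collinear set,
#' yield a degenerate hull (point or segment) with area 0.
#'
#' @param positions Numeric matrix / data.frame with columns x, y (meters).
#' @param genet_id Optional identifier carried through to reports.
#' @return An object of class `genet_geometry`: list with `genet_id`,
#'   `positions`, `hull` (vertex matrix, CCW; 1 or 2 rows when degenerate),
#'   `kind` (`"point"`, `"segment"`, `"polygon"`), `area` (m^2),
#'   `n_ramets`.
#' @export
genet_hull <- function(positions, genet_id = NA) {
  p <- as.matrix(positions)
  if (nrow(p) < 1L) stop("need at least one position")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  up <- unique(p)
  if (nrow(up) == 1L) {
    hull <- up; kind <- "point"; area <- 0
  } else {
    idx <- grDevices::chull(up)
    hull <- up[idx, , drop = FALSE]
    area <- abs(.signed_area(hull))
    if (nrow(hull) < 3L || area <= .geom_eps) {
      # collinear: keep the two extreme points
      d0 <- up[which.max(rowSums((up - matrix(up[1L, ], nrow(up), 2,
                                              byrow = TRUE))^2)), ]
      dists <- rowSums((up - matrix(d0, nrow(up), 2, byrow = TRUE))^2)
      hull <- rbind(d0, up[which.max(dists), ])
      kind <- "segment"; area <- 0
    } else {
      hull <- .ccw(hull); kind <- "polygon"
    }
  }
  structure(list(genet_id = genet_id, positions = p, hull = hull,
                 kind = kind, area = area, n_ramets = nrow(p)),
            class = "genet_geometry")
}

#' @export
print.genet_geometry <- function(x, ...) {
  cat("Genet", x$genet_id, "-", x$n_ramets, "ramets,", x$kind,
      sprintf("hull, area %.2f m^2\n", x$area))
  invisible(x)
}

# do two genet geometries overlap?  Polygon-polygon: positive-area
# intersection (boundary touching does NOT count).  Degenerate vs polygon:
# intersection with the polygon's closure.  Two degenerates: never.
.hulls_overlap <- function(g1, g2) {
  k1 <- g1$kind; k2 <- g2$kind
  if (k1 != "polygon" && k2 != "polygon") return(FALSE)
  if (k1 == "polygon" && k2 == "polygon") {
    inter <- .clip_convex(g1$hull, g2$hull)
    return(nrow(inter) >= 3L && abs(.signed_area(.ccw(inter))) > 1e-8)
  }
  poly <- if (k1 == "polygon") g1 else g2
  deg <- if (k1 == "polygon") g2 else g1
  if (deg$kind == "point")
    return(.point_in_convex(deg$hull[1L, ], poly$hull))
  a1 <- deg$hull[1L, ]; a2 <- deg$hull[2L, ]
  if (.point_in_convex(a1, poly$hull) || .point_in_convex(a2, poly$hull))
    return(TRUE)
  n <- nrow(poly$hull)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (.segments_intersect(a1, a2, poly$hull[i, ], poly$hull[j, ]))
      return(TRUE)
  }
  FALSE
}

#' Genet geometries for a quadrat
#'
#' @param mll An `mll_partition`.
#' @param ss The matching `sample_set`.
#' @param quadrat_id Quadrat to process.
#' @param stage Optional stage filter (`"on_floor"` / `"on_tree"`); both
#'   stages are pooled by default.
#' @return List of `genet_geometry`, one per genet present, ordered by
#'   genet id.
#' @export
genet_geometries <- function(mll, ss, quadrat_id, stage = NULL) {
  sel <- ss$data$quadrat_id == quadrat_id
  if (!is.null(stage)) sel <- sel & ss$data$stage == match.arg(stage, .stages)
  if (!any(sel)) stop("no ramets selected in quadrat ", quadrat_id)
  xy <- ramet_positions(ss)[sel, , drop = FALSE]
  genets <- mll$genet_of_sample[sel]
  lapply(sort(unique(genets)), function(g) {
    genet_hull(xy[genets == g, , drop = FALSE], genet_id = g)
  })
}
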