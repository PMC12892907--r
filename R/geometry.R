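#' Planar geometry primitives for cell-boundary processing
#'
#' Deterministic 2D geometry used by the resegmentation pipeline. A polygon
#' is a list with numeric vectors \code{x} and \code{y} giving the exterior
#' ring vertices in order, implicitly closed (the first vertex is not
#' repeated). Exterior rings are oriented counterclockwise. All coordinates
#' are planar micrometres.
#'
#' @name geometry
NULL

#' Polygon area (shoelace formula)
#'
#' Area of a polygon's exterior ring. For a multi-ring geometry (a list of
#' rings, as returned by \code{\link{polygonUnion}} with
#' \code{bridge = FALSE}) the signed areas are summed, so interior rings
#' (holes, traced clockwise) subtract.
#'
#' @param p polygon (list with \code{x}, \code{y}) or list of rings.
#' @return Non-negative area in square micrometres.
#' @export
#' @examples
#' polygonArea(list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
polygonArea <- function(p) {
  if (.isRing(p)) return(abs(.signedArea(p)))
  rings <- .asRingList(p)
  abs(sum(vapply(rings, .signedArea, numeric(1))))
}

#' Test points against a polygon (boundary-inclusive)
#'
#' Returns \code{TRUE} for points strictly inside the polygon or exactly on
#' its boundary (edges and vertices count as inside).
#'
#' @param x,y numeric vectors of point coordinates (recycled to common
#'   length).
#' @param p polygon.
#' @return Logical vector.
#' @export
pointInPolygon <- function(x, y, p) {
  stopifnot(.isRing(p))
  sp::point.in.polygon(x, y, p$x, p$y) > 0
}

# splice rings that share a vertex (within tol) into one pinched ring;
# returns a list of rings, merged where possible
.spliceTouching <- function(rings, tol = 1e-7) {
  changed <- TRUE
  while (changed && length(rings) > 1) {
    changed <- FALSE
    for (i in seq_len(length(rings) - 1)) {
      for (j in seq(i + 1, length(rings))) {
        a <- rings[[i]]; b <- rings[[j]]
        hit <- NULL
        for (ia in seq_along(a$x)) {
          d <- (b$x - a$x[ia])^2 + (b$y - a$y[ia])^2
          ib <- which.min(d)
          if (d[ib] <= tol^2) { hit <- c(ia, ib); break }
        }
        if (!is.null(hit)) {
          ia <- hit[1]; ib <- hit[2]
          # rotate each ring to start at the shared vertex, then concatenate
          rot <- function(v, k) if (k == 1) v else c(v[k:length(v)], v[seq_len(k - 1)])
          rings[[i]] <- list(
            x = c(rot(a$x, ia), rot(b$x, ib)),
            y = c(rot(a$y, ia), rot(b$y, ib)))
          rings[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  rings
}

#' Repair a polygon and fill interior holes
#'
#' Self-intersections are resolved and interior rings (holes) are removed,
#' so the output covers at least the input's exterior extent. An input that
#' is already a simple, hole-free ring is returned unchanged (exact
#' identity). If repair yields several parts that touch at a point (for
#' example the two lobes of a self-crossing "bowtie" ring) they are spliced
#' into a single pinched ring whose area is the sum of the parts; genuinely
#' disjoint parts trigger a warning and only the largest-area part is
#' returned.
#'
#' @param p polygon, or a list of rings where additional rings are holes.
#' @return A single polygon with no interior rings, counterclockwise.
#' @export
fillHoles <- function(p) {
  rings <- .asRingList(p)
  if (length(rings) == 1 && .isRing(rings[[1]])) {
    simp <- polyclip::polysimplify(rings[[1]], filltype = "evenodd", eps = .EPS)
    if (length(simp) == 1) {
      a0 <- abs(.signedArea(rings[[1]]))
      a1 <- abs(.signedArea(simp[[1]]))
      if (a0 > 0 && abs(a1 - a0) <= 1e-9 * max(a0, 1)) {
        return(.ensureCCW(rings[[1]]))
      }
    }
  } else {
    simp <- polyclip::polysimplify(rings, filltype = "evenodd", eps = .EPS)
  }
  outer <- Filter(function(r) .signedArea(r) > 0, simp)
  if (length(outer) == 0) .stopf("degenerate geometry: zero area after repair")
  if (length(outer) > 1) {
    outer <- .spliceTouching(outer)
    if (length(outer) > 1) {
      .warnf("repair produced %d disjoint parts; keeping the largest", length(outer))
      areas <- vapply(outer, function(r) abs(.signedArea(r)), numeric(1))
      outer <- outer[which.max(areas)]
    }
  }
  out <- .ensureCCW(outer[[1]])
  if (abs(.signedArea(out)) <= 0) .stopf("degenerate geometry: zero area after repair")
  out
}

#' Convex hull of a point set
#'
#' Smallest convex polygon containing all points. Degenerate inputs (all
#' points collinear or coincident) are handled by buffering each point with
#' a small regular 16-gon of radius \code{epsilon} before hulling, so the
#' result always has positive area and contains every input point.
#'
#' @param x,y numeric coordinate vectors, length >= 3.
#' @param epsilon buffer radius in micrometres applied only when the raw
#'   hull is degenerate (default 0.2).
#' @return Polygon (counterclockwise).
#' @export
#' @examples
#' convexHullPolygon(c(0, 4, 0), c(0, 0, 3))  # triangle, area 6
convexHullPolygon <- function(x, y, epsilon = 0.2) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) .stopf("convex hull requires at least 3 points, got %d", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y))) .stopf("non-finite coordinates in point set")
  hullOf <- function(px, py) {
    idx <- grDevices::chull(px, py)
    .ensureCCW(list(x = px[idx], y = py[idx]))
  }
  h <- hullOf(x, y)
  if (length(h$x) >= 3 && abs(.signedArea(h)) > 1e-12) return(h)
  if (epsilon <= 0) .stopf("degenerate (collinear) point set and epsilon <= 0")
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  bx <- as.vector(outer(epsilon * cos(th), x, "+"))
  by <- as.vector(outer(epsilon * sin(th), y, "+"))
  hullOf(bx, by)
}

#' Union of two polygons
#'
#' Boolean union. If the inputs are disjoint the result is bridged into a
#' single polygon by taking the convex hull of both (with a warning),
#' because each cell must end up with exactly one boundary; set
#' \code{bridge = FALSE} to instead return the disjoint parts as a list of
#' rings. Holes created by the union (two interlocking C-shapes) are
#' filled, consistent with the pipeline's hole-filling step.
#'
#' @param a,b polygons.
#' @param bridge logical; bridge disjoint results via their joint convex
#'   hull (default \code{TRUE}).
#' @return Polygon, or a list of rings when \code{bridge = FALSE} and the
#'   inputs are disjoint.
#' @export
polygonUnion <- function(a, b, bridge = TRUE) {
  stopifnot(.isRing(a), .isRing(b))
  u <- polyclip::polyclip(a, b, "union", closed = TRUE, eps = .EPS)
  outer <- Filter(function(r) .signedArea(r) > 0, u)
  if (length(outer) == 0) .stopf("union produced empty geometry")
  if (length(outer) > 1) outer <- .spliceTouching(outer)
  if (length(outer) > 1) {
    if (!bridge) return(lapply(outer, .ensureCCW))
    .warnf("disjoint union; bridging with joint convex hull")
    return(convexHullPolygon(c(a$x, b$x), c(a$y, b$y)))
  }
  .ensureCCW(outer[[1]])
}

#' Dilate a polygon by a disk (Minkowski sum)
#'
#' Uniform outward expansion by radius \code{r}, with round joins
#' discretized at 16 segments per quadrant. \code{r = 0} returns the input
#' unchanged.
#'
#' @param p polygon.
#' @param r dilation radius in micrometres, >= 0.
#' @return Polygon.
#' @export
dilatePolygon <- function(p, r) {
  stopifnot(.isRing(p))
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0)
    .stopf("dilation radius must be a single non-negative number")
  if (r == 0) return(p)
  # Clipper arc tolerance = max deviation from the true arc; 16 segments
  # per quadrant corresponds to deviation r * (1 - cos(pi / 64))
  tol <- r * (1 - cos(pi / 64))
  o <- polyclip::polyoffset(p, r, jointype = "round", arctol = tol, eps = .EPS)
  outer <- Filter(function(rr) .signedArea(rr) > 0, o)
  if (length(outer) == 0) .stopf("dilation produced empty geometry")
  areas <- vapply(outer, .signedArea, numeric(1))
  .ensureCCW(outer[[which.max(areas)]])
}
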