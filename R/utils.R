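# Internal helpers shared across modules. Polygons are represented as
# lists with numeric `x` and `y` vertex vectors describing one exterior
# ring, implicitly closed (first vertex is NOT repeated at the end).

.isRing <- function(p) {
  is.list(p) && !is.null(p$x) && !is.null(p$y) &&
    length(p$x) == length(p$y) && length(p$x) >= 3 &&
    all(is.finite(p$x)) && all(is.finite(p$y))
}

# list of rings (multi-ring geometry) vs single ring
.asRingList <- function(p) {
  if (.isRing(p)) list(p) else p
}

.signedArea <- function(ring) {
  x <- ring$x; y <- ring$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

.ensureCCW <- function(ring) {
  if (.signedArea(ring) < 0) list(x = rev(ring$x), y = rev(ring$y)) else ring
}

.ringCentroid <- function(ring) {
  x <- ring$x; y <- ring$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cross) / (6 * a), sum((y + yn) * cross) / (6 * a))
}

.bboxRing <- function(ring) c(min(ring$x), max(ring$x), min(ring$y), max(ring$y))

# minimum distance from points (px, py) to the boundary of `ring`;
# 0 for points inside or on the ring
.distToRing <- function(px, py, ring) {
  x1 <- ring$x; y1 <- ring$y
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  n <- length(px)
  out <- numeric(n)
  for (i in seq_len(n)) {
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- ((px[i] - x1) * dx + (py[i] - y1) * dy) / pmax(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    qx <- x1 + t * dx; qy <- y1 + t * dy
    out[i] <- sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }
  inside <- sp::point.in.polygon(px, py, ring$x, ring$y) > 0
  out[inside] <- 0
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

UNASSIGNED <- "UNASSIGNED"

# integer-grid resolution (um) for clipper operations: 1e-11 um keeps area
# agreement with closed forms below 1e-9 relative for coordinates up to ~1 mm
.EPS <- 1e-11
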