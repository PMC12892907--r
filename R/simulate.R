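#' Parameters for the synthetic sebaceous-gland generator
#'
#' The generator emulates the anatomy the refinement method targets: an
#' elliptical gland whose periphery is a thin monolayer of small KRT5-high
#' basal cells wrapped around large KRT79/AWAT2-high differentiated
#' sebocytes, plus a corrupted "default" segmentation whose basal
#' boundaries over-extend into the lipid-filled sebocyte territory.
#'
#' @param semiAxes gland ellipse semi-axes in micrometres
#'   (default \code{c(110, 95)}).
#' @param basalWidth radial width of the peripheral basal band in
#'   micrometres (default 4).
#' @param basalCellLength target arc length of one basal cell (default 6).
#' @param sebocyteDiameter target sebocyte diameter in micrometres
#'   (default 20).
#' @param rates genes-by-type (\code{basal}, \code{sebocyte}) matrix of
#'   per-cell Poisson expression rates; defaults to
#'   \code{defaultGlandRates()}.
#' @param jitterSD per-axis Gaussian placement jitter, micrometres
#'   (default 0.5); models optical/decoding noise.
#' @param qvLowFraction fraction of transcripts drawn from the low-quality
#'   mode (default 0.05).
#' @param qvHighMean,qvLowMean,qvSD means (35, 12) and common sd (3) of the
#'   two quality-value modes; values are truncated at 0.
#' @param overextension depth in micrometres by which the observed default
#'   segmentation extends basal boundaries inward into sebocyte territory
#'   (default 4).
#' @param nucleusScale linear shrink factor producing each nucleus from its
#'   cell (default 0.5).
#' @param seed integer PRNG seed (mandatory for reproducible fixtures).
#' @return Validated parameter list for \code{\link{simulateGland}}.
#' @export
glandParams <- function(semiAxes = c(110, 95), basalWidth = 4,
                        basalCellLength = 6, sebocyteDiameter = 20,
                        rates = defaultGlandRates(), jitterSD = 0.5,
                        qvLowFraction = 0.05, qvHighMean = 35,
                        qvLowMean = 12, qvSD = 3,
                        overextension = 4, nucleusScale = 0.5, seed = 1) {
  stopifnot(length(semiAxes) == 2, all(semiAxes > 0),
            basalWidth > 0, basalCellLength > 0, sebocyteDiameter > 0,
            jitterSD >= 0, qvLowFraction >= 0, qvLowFraction <= 1,
            overextension >= 0, nucleusScale > 0, nucleusScale < 1)
  if (!is.matrix(rates) || is.null(rownames(rates)) ||
      !all(c("basal", "sebocyte") %in% colnames(rates)))
    .stopf("rates must be a genes-by-type matrix with columns 'basal' and 'sebocyte'")
  if (any(rates < 0)) .stopf("expression rates must be non-negative")
  list(semiAxes = semiAxes, basalWidth = basalWidth,
       basalCellLength = basalCellLength, sebocyteDiameter = sebocyteDiameter,
       rates = rates, jitterSD = jitterSD, qvLowFraction = qvLowFraction,
       qvHighMean = qvHighMean, qvLowMean = qvLowMean, qvSD = qvSD,
       overextension = overextension, nucleusScale = nucleusScale,
       seed = as.integer(seed))
}

#' Default per-type Poisson expression rates
#'
#' Mean transcripts per cell per gene for the two simulated cell types.
#' Marker contrast follows the gland's biology: KRT5 high in basal cells
#' and low in differentiated sebocytes; KRT79 and AWAT2 essentially
#' sebocyte-exclusive; the five lipogenic sebogenesis genes about fivefold
#' elevated in sebocytes; FABP5/CRABP2 balanced at baseline (scenario
#' presets shift them); plus proliferation (MKI67), differentiation
#' (PPARG) and two abundant housekeeping genes.
#'
#' @return Genes-by-type numeric matrix.
#' @export
defaultGlandRates <- function() {
  genes <- c("KRT5", "KRT79", "AWAT2", "FASN", "AWAT1", "ACACA", "SREBF1",
             "FABP5", "CRABP2", "MKI67", "PPARG", "GAPDH", "ACTB")
  basal <- c(40, 0.2, 0.2, 4, 2, 4, 4, 5, 5, 3, 6, 18, 18)
  sebo <- c(0.5, 60, 45, 20, 10, 20, 20, 6, 6, 0.5, 10, 80, 80)
  matrix(c(basal, sebo), ncol = 2, dimnames = list(genes, c("basal", "sebocyte")))
}

# ellipse ring on a fine angular grid, scaled radially
.ellipseRing <- function(rx, ry, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = rx * cos(th), y = ry * sin(th))
}

.scaleAboutCentroid <- function(ring, f) {
  c0 <- .ringCentroid(ring)
  list(x = c0[1] + f * (ring$x - c0[1]), y = c0[2] + f * (ring$y - c0[2]))
}

# basal band cells: quadrilateral-ish cells between the outer ellipse and an
# inner ellipse offset radially inward, partitioned by arc length
.basalBand <- function(semiAxes, innerOffset, nCells, gridN = 720) {
  outer <- .ellipseRing(semiAxes[1], semiAxes[2], gridN)
  inner <- .ellipseRing(semiAxes[1] - innerOffset, semiAxes[2] - innerOffset, gridN)
  seg <- cumsum(sqrt(diff(c(outer$x, outer$x[1]))^2 + diff(c(outer$y, outer$y[1]))^2))
  per <- seg[gridN]
  arcpos <- c(0, seg[-gridN])  # arc position of each grid point
  cuts <- pmin(findInterval(arcpos, seq(0, per, length.out = nCells + 1),
                            rightmost.closed = TRUE), nCells)
  lapply(seq_len(nCells), function(k) {
    idx <- which(cuts == k)
    idx <- c(idx, (max(idx) %% gridN) + 1L)  # share the cut vertex with the neighbour
    .ensureCCW(list(x = c(outer$x[idx], rev(inner$x[idx])),
                    y = c(outer$y[idx], rev(inner$y[idx]))))
  })
}

# uniform points in a polygon by bounding-box rejection sampling
.samplePointsInRing <- function(ring, n) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  bb <- .bboxRing(ring)
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0
  while (length(xs) < n && guard < 1000) {
    m <- max(2L * (n - length(xs)), 16L)
    cx <- stats::runif(m, bb[1], bb[2])
    cy <- stats::runif(m, bb[3], bb[4])
    keep <- sp::point.in.polygon(cx, cy, ring$x, ring$y) == 1  # strict interior
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    guard <- guard + 1
  }
  if (length(xs) < n) .stopf("failed to sample points inside a degenerate cell polygon")
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Simulate a sebaceous gland with ground truth
#'
#' Builds the gland geometry (peripheral basal band partitioned into thin
#' cells by arc length; interior Voronoi-tessellated into sebocytes; nuclei
#' as shrunken cell copies), draws per-cell per-gene Poisson transcript
#' counts placed uniformly within the true cell and jittered by Gaussian
#' noise, samples two-mode quality values, and constructs the observed
#' "default" segmentation in which every basal boundary over-extends
#' \code{overextension} micrometres inward into sebocyte territory. The
#' observed transcript assignment is computed by containment against the
#' observed boundaries (with the package's deterministic tie rule). Fully
#' deterministic for a fixed seed.
#'
#' @param params a \code{\link{glandParams}} list.
#' @return A \code{\linkS4class{GlandSimulation}}.
#' @export
#' @examples
#' sim <- simulateGland(glandParams(semiAxes = c(40, 35), seed = 7))
#' sim
simulateGland <- function(params = glandParams()) {
  set.seed(params$seed)
  rx <- params$semiAxes[1]; ry <- params$semiAxes[2]
  wB <- params$basalWidth
  if (min(rx, ry) <= wB + params$sebocyteDiameter)
    .stopf("gland too small for the requested basal width and sebocyte diameter")

  gridN <- 720L
  outer <- .ellipseRing(rx, ry, gridN)
  seg <- cumsum(sqrt(diff(c(outer$x, outer$x[1]))^2 + diff(c(outer$y, outer$y[1]))^2))
  nBasal <- max(3L, round(seg[gridN] / params$basalCellLength))
  basalTrue <- .basalBand(params$semiAxes, wB, nBasal, gridN)
  innerRing <- .ellipseRing(rx - wB, ry - wB, gridN)

  # sebocyte seeds: jittered hexagonal grid inside the interior ellipse
  s <- params$sebocyteDiameter
  ys <- seq(-(ry - wB), ry - wB, by = s * sqrt(3) / 2)
  seedX <- numeric(0); seedY <- numeric(0)
  for (r in seq_along(ys)) {
    off <- if (r %% 2 == 0) s / 2 else 0
    xs <- seq(-(rx - wB) + off, rx - wB, by = s)
    seedX <- c(seedX, xs); seedY <- c(seedY, rep(ys[r], length(xs)))
  }
  seedX <- seedX + stats::runif(length(seedX), -s / 5, s / 5)
  seedY <- seedY + stats::runif(length(seedY), -s / 5, s / 5)
  inside <- (seedX / (rx - wB - s / 4))^2 + (seedY / (ry - wB - s / 4))^2 <= 1
  seedX <- seedX[inside]; seedY <- seedY[inside]
  if (length(seedX) < 2) .stopf("interior too small to place sebocytes")

  vor <- deldir::deldir(seedX, seedY, rw = c(-rx, rx, -ry, ry), suppressMsge = TRUE)
  tiles <- deldir::tile.list(vor)
  seboTrue <- list()
  for (tl in tiles) {
    clip <- polyclip::polyclip(list(x = tl$x, y = tl$y), innerRing, "intersection", eps = .EPS)
    pos <- Filter(function(rr) .signedArea(rr) > 1, clip)
    if (length(pos) == 0) next
    areas <- vapply(pos, .signedArea, numeric(1))
    seboTrue[[length(seboTrue) + 1]] <- .ensureCCW(pos[[which.max(areas)]])
  }
  nSebo <- length(seboTrue)
  if (nBasal + nSebo < 3) .stopf("parameters yield fewer than 3 cells")

  ids <- c(sprintf("b%03d", seq_len(nBasal)), sprintf("s%03d", seq_len(nSebo)))
  types <- c(rep("basal", nBasal), rep("sebocyte", nSebo))
  trueBnd <- c(basalTrue, seboTrue)
  nucleiL <- lapply(trueBnd, .scaleAboutCentroid, f = params$nucleusScale)
  truth <- CellSegmentation(ids, trueBnd, nucleiL, provenance = "default",
                            cellTypes = types)

  # transcripts: per cell, per gene Poisson counts, uniform placement + jitter
  rates <- params$rates
  genes <- rownames(rates)
  recX <- list(); recY <- list(); recG <- list(); recC <- list()
  for (i in seq_along(ids)) {
    lam <- rates[, types[i]]
    cnt <- stats::rpois(length(lam), lam)
    tot <- sum(cnt)
    if (tot == 0) next
    pts <- .samplePointsInRing(trueBnd[[i]], tot)
    recX[[i]] <- pts$x; recY[[i]] <- pts$y
    recG[[i]] <- rep(genes, cnt); recC[[i]] <- rep(ids[i], tot)
  }
  x0 <- unlist(recX); y0 <- unlist(recY)
  nT <- length(x0)
  if (params$jitterSD > 0) {
    x <- x0 + stats::rnorm(nT, 0, params$jitterSD)
    y <- y0 + stats::rnorm(nT, 0, params$jitterSD)
  } else {
    x <- x0; y <- y0
  }
  low <- stats::runif(nT) < params$qvLowFraction
  qv <- pmax(0, stats::rnorm(nT, ifelse(low, params$qvLowMean, params$qvHighMean),
                             params$qvSD))
  transcripts <- data.frame(
    transcript_id = sprintf("t%06d", seq_len(nT)),
    x = x, y = y, gene = unlist(recG), qv = qv,
    cell_id = UNASSIGNED, stringsAsFactors = FALSE)
  trueCell <- stats::setNames(unlist(recC), transcripts$transcript_id)

  # observed default segmentation: basal boundaries extended inward by delta
  obsBnd <- trueBnd
  if (params$overextension > 0) {
    basalObs <- .basalBand(params$semiAxes, wB + params$overextension, nBasal, gridN)
    obsBnd[seq_len(nBasal)] <- basalObs
  }
  observed <- CellSegmentation(ids, obsBnd, nucleiL, provenance = "default",
                               cellTypes = types)
  transcripts <- reassignTranscripts(observed, transcripts)

  new("GlandSimulation", transcripts = transcripts, observed = observed,
      truth = truth, trueAssignment = trueCell, params = params)
}

#' Disease-scenario parameter presets
#'
#' Named parameter sets shifting expression rates in the directions the
#' disease states show: \code{healthy} is the default gland;
#' \code{comedo_like} doubles the five lipogenic sebogenesis rates and
#' FABP5 (comedones upregulate sebogenesis); \code{pustule_like} halves the
#' lipogenic rates, triples FABP5 and halves CRABP2 (pustules downregulate
#' sebogenesis and skew the FABP5:CRABP2 balance upward). Magnitudes are
#' synthetic; only the directions are anchored in the biology.
#'
#' @param name one of \code{"healthy"}, \code{"comedo_like"},
#'   \code{"pustule_like"}.
#' @param seed PRNG seed passed through to \code{\link{glandParams}}.
#' @return A \code{\link{glandParams}} list.
#' @export
scenarioPresets <- function(name = c("healthy", "comedo_like", "pustule_like"),
                            seed = 1) {
  if (length(name) != 1 || !(name %in% c("healthy", "comedo_like", "pustule_like")))
    .stopf("unknown scenario preset: %s", paste(name, collapse = ", "))
  rates <- defaultGlandRates()
  lipo <- sebogenesisGenes()
  if (name == "comedo_like") {
    rates[lipo, ] <- rates[lipo, ] * 2
    rates["FABP5", ] <- rates["FABP5", ] * 2
  } else if (name == "pustule_like") {
    rates[lipo, ] <- rates[lipo, ] * 0.5
    rates["FABP5", ] <- rates["FABP5", ] * 3
    rates["CRABP2", ] <- rates["CRABP2", ] * 0.5
  }
  glandParams(rates = rates, seed = seed)
}
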