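# Independent oracles: deliberately naive implementations used only to
# cross-check the package's geometry and statistics.

# classic crossing-number ray cast (strict interior; boundary points are
# ambiguous and avoided by the random generators below)
rayCastInside <- function(px, py, poly) {
  n <- length(poly$x)
  out <- logical(length(px))
  for (k in seq_along(px)) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly$x[i]; yi <- poly$y[i]
      xj <- poly$x[j]; yj <- poly$y[j]
      if ((yi > py[k]) != (yj > py[k]) &&
          px[k] < (xj - xi) * (py[k] - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    out[k] <- inside
  }
  out
}

# fan triangulation area from the first vertex (signed triangle sum)
fanArea <- function(poly) {
  x0 <- poly$x[1]; y0 <- poly$y[1]
  n <- length(poly$x)
  s <- 0
  for (i in 2:(n - 1)) {
    s <- s + ((poly$x[i] - x0) * (poly$y[i + 1] - y0) -
              (poly$x[i + 1] - x0) * (poly$y[i] - y0)) / 2
  }
  abs(s)
}

# star-shaped (hence simple) random polygon around the origin
randomSimplePolygon <- function(nVerts, rMin = 0.5, rMax = 2) {
  th <- sort(stats::runif(nVerts, 0, 2 * pi))
  r <- stats::runif(nVerts, rMin, rMax)
  list(x = r * cos(th), y = r * sin(th))
}

# one-way ANOVA F and Tukey HSD adjusted p-values from first principles
tukeyOracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  means <- tapply(values, groups, mean)
  ni <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  mse <- ssw / df2
  Fstat <- (ssb / df1) / mse
  pF <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  combs <- utils::combn(levels(groups), 2)
  padj <- apply(combs, 2, function(pair) {
    se <- sqrt(mse / 2 * (1 / ni[pair[1]] + 1 / ni[pair[2]]))
    q <- abs(means[pair[1]] - means[pair[2]]) / se
    stats::ptukey(q, k, df2, lower.tail = FALSE)
  })
  list(F = Fstat, p = pF,
       pairs = paste(combs[2, ], combs[1, ], sep = "-"), p_adj = padj)
}

unitSquare <- function(dx = 0, dy = 0) {
  list(x = c(0, 1, 1, 0) + dx, y = c(0, 0, 1, 1) + dy)
}

regularPolygon <- function(n, r, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}
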