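test_that("cells are flagged at the marker-count threshold under the QV filter", {
  seg <- singleCellSeg()
  p <- ResegmentationParams()

  tr3 <- makeTranscripts(c(1, 2, 3), c(1, 2, 1), "KRT5", qv = 25)
  expect_true(flagCells(seg, tr3, p)[["c1"]])

  tr2 <- makeTranscripts(c(1, 2), c(1, 2), "KRT5", qv = 25)
  expect_false(flagCells(seg, tr2, p)[["c1"]])

  # one of three markers below QV 20 leaves only 2 countable
  trLow <- makeTranscripts(c(1, 2, 3), c(1, 2, 1), "KRT5", qv = c(25, 25, 10))
  expect_false(flagCells(seg, trLow, p)[["c1"]])
  expect_true(flagCells(seg, trLow, ResegmentationParams(countAllQV = TRUE))[["c1"]])

  trOther <- makeTranscripts(c(1, 2, 3), c(1, 2, 1), "KRT79", qv = 25)
  expect_warning(f <- flagCells(seg, trOther, p), "absent")
  expect_false(any(f))
})

test_that("marker-count threshold below the hull minimum is rejected", {
  expect_error(ResegmentationParams(minMarkerCount = 2), ">= 3")
})

test_that("boundary refinement is hull merged with nucleus, with documented fallbacks", {
  nuc <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))

  # marker points inside the nucleus: absorption, refined = nucleus
  r1 <- refineBoundary(NULL, nuc, c(0.2, 0.8, 0.5), c(0.2, 0.2, 0.8))
  expect_equal(polygonArea(r1$boundary), 1, tolerance = 1e-9)
  expect_equal(r1$action, "refined")

  # disjoint hull bridged with the nucleus: joint convex hull
  # hull vertices (0,0),(3,0),(2.5,1),(0,1) -> shoelace area 2.75
  r2 <- refineBoundary(NULL, nuc, c(2, 3, 2.5), c(0, 0, 1))
  expect_equal(polygonArea(r2$boundary), 2.75, tolerance = 1e-9)
  expect_match(r2$warning, "bridging")

  # no nucleus: the marker triangle alone
  r3 <- refineBoundary(NULL, NULL, c(0, 4, 0), c(0, 0, 3))
  expect_equal(polygonArea(r3$boundary), 6)
  expect_match(r3$warning, "no nucleus")

  # degenerate hull with no nucleus: original boundary retained
  orig <- list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  r4 <- refineBoundary(orig, NULL, c(1, 2, 3), c(0, 0, 0),
                       ResegmentationParams(epsilon = 0))
  expect_identical(r4$boundary, orig)
  expect_equal(r4$action, "retained")
})

test_that("transcript reassignment is conservative and resolves ties deterministically", {
  sq1 <- list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  sq2 <- list(x = c(5, 15, 15, 5), y = c(0, 0, 10, 10))  # overlaps sq1 on x in [5,10]
  nuc1 <- list(x = c(1, 2, 2, 1), y = c(4, 4, 6, 6))
  nuc2 <- list(x = c(13, 14, 14, 13), y = c(4, 4, 6, 6))

  tr <- makeTranscripts(x = c(2, 20, 6, 9), y = c(5, 5, 5, 5), gene = "KRT5",
                        cell_id = "UNASSIGNED")

  # equal priority: nearest nucleus centroid decides the overlap
  seg <- CellSegmentation(c("a", "b"), list(sq1, sq2), list(nuc1, nuc2))
  out <- reassignTranscripts(seg, tr)
  expect_equal(nrow(out), nrow(tr))
  expect_identical(out$cell_id, c("a", "UNASSIGNED", "a", "b"))

  # marker-refined provenance outranks default regardless of distance
  seg2 <- CellSegmentation(c("a", "b"), list(sq1, sq2), list(nuc1, nuc2),
                           provenance = c("default", "marker_refined"))
  out2 <- reassignTranscripts(seg2, tr)
  expect_identical(out2$cell_id, c("a", "UNASSIGNED", "b", "b"))

  # brute-force cross-check of the winner among candidates
  cands <- function(x, y) {
    inside <- c(a = pointInPolygon(x, y, sq1), b = pointInPolygon(x, y, sq2))
    names(inside)[inside]
  }
  expect_identical(cands(6, 5), c("a", "b"))
  expect_identical(cands(2, 5), "a")
})

test_that("resegmentation without marker transcripts is a no-op on boundaries", {
  seg <- singleCellSeg()
  tr <- makeTranscripts(c(1, 2), c(1, 2), "KRT79", qv = 30)
  res <- suppressWarnings(runMarkerResegmentation(seg, tr))
  expect_identical(boundaries(refinedSegmentation(res)), boundaries(seg))
  expect_identical(auditTable(res)$action, "retained")
  expect_identical(assignedTranscripts(res)$cell_id, c("c1", "c1"))
})

test_that("a hand-built flagged cell gets the hull-union-nucleus boundary", {
  seg <- singleCellSeg()
  # 5 marker points whose hull is the triangle (1,1),(9,1),(5,9), area 32;
  # the 2x2 nucleus at (4..6, 4..6) lies inside it, so union = hull
  tr <- makeTranscripts(x = c(1, 9, 5, 5, 2), y = c(1, 1, 9, 5, 2), "KRT5", qv = 30)
  res <- runMarkerResegmentation(seg, tr)
  ref <- boundaries(refinedSegmentation(res))[["c1"]]
  expect_equal(polygonArea(ref), 32, tolerance = 1e-9)
  expect_identical(auditTable(res)$action, "refined")
  expect_identical(unname(provenance(refinedSegmentation(res))), "marker_refined")
  # nucleus corners verified inside the hull (absorption precondition)
  expect_true(all(pointInPolygon(c(4, 6, 6, 4), c(4, 4, 6, 6), ref)))
})

test_that("resegmentation contracts hold on a small synthetic gland", {
  sim <- smallGland(seed = 3)
  tr <- glandTranscripts(sim)
  obs <- observedSegmentation(sim)
  res <- runMarkerResegmentation(obs, tr)
  out <- assignedTranscripts(res)
  refined <- refinedSegmentation(res)
  audit <- auditTable(res)

  # conservation: every transcript appears exactly once
  expect_identical(sort(out$transcript_id), sort(tr$transcript_id))
  expect_true(all(out$cell_id != "" & !is.na(out$cell_id)))
  # audit covers every cell exactly once
  expect_identical(sort(audit$cell_id), sort(cellIds(obs)))

  # retention: unflagged boundaries bit-identical to input
  keep <- !audit$flagged
  expect_identical(boundaries(refined)[keep], boundaries(obs)[keep])

  # containment: refined boundary holds nucleus and QV-passing markers
  p <- ResegmentationParams()
  for (cid in audit$cell_id[audit$action == "refined"][1:20]) {
    b <- boundaries(refined)[[cid]]
    sel <- tr$gene == "KRT5" & tr$qv >= 20 & tr$cell_id == cid
    near <- pointInPolygon(tr$x[sel], tr$y[sel], b) |
      markerseg:::.distToRing(tr$x[sel], tr$y[sel], b) < 1e-6
    expect_true(all(near))
    nuc <- nuclei(obs)[[cid]]
    expect_lte(polygonArea(polygonUnion(b, nuc)), polygonArea(b) * (1 + 1e-6) + 1e-6)
  }

  # locality: refined boundary within hull(original union nucleus)
  for (cid in audit$cell_id[audit$action == "refined"][1:20]) {
    orig <- boundaries(obs)[[cid]]
    nuc <- nuclei(obs)[[cid]]
    H <- convexHullPolygon(c(orig$x, nuc$x), c(orig$y, nuc$y))
    b <- boundaries(refined)[[cid]]
    expect_lte(polygonArea(polygonUnion(b, H)), polygonArea(H) * (1 + 1e-6) + 1e-6)
  }

  # monotone restriction: refined basal cells shrink relative to the
  # over-extended default boundaries
  types <- cellTypes(truthSegmentation(sim))
  basal <- names(types)[types == "basal"]
  refA <- vapply(boundaries(refined)[basal], polygonArea, numeric(1))
  defA <- vapply(boundaries(obs)[basal], polygonArea, numeric(1))
  expect_gte(mean(refA <= defA), 0.95)
})
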