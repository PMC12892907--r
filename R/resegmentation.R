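#' Flag cells for marker-directed resegmentation
#'
#' A cell is flagged when it carries at least \code{minMarkerCount}
#' marker-gene transcripts (under its current assignment) that pass the
#' quality threshold \code{minQV}. With the default parameters this flags
#' every cell containing at least 3 KRT5 transcripts of quality value 20 or
#' above.
#'
#' @param seg a \code{\linkS4class{CellSegmentation}}.
#' @param transcripts transcript table carrying input cell assignments.
#' @param params a \code{\link{ResegmentationParams}}.
#' @return Named logical vector over \code{cellIds(seg)}.
#' @export
flagCells <- function(seg, transcripts, params = ResegmentationParams()) {
  ids <- cellIds(seg)
  flags <- stats::setNames(rep(FALSE, length(ids)), ids)
  hit <- transcripts$gene == params@markerGene
  if (!any(hit)) {
    .warnf("marker gene '%s' absent from transcript table; no cells flagged",
           params@markerGene)
    return(flags)
  }
  if (!params@countAllQV) hit <- hit & transcripts$qv >= params@minQV
  counts <- table(factor(transcripts$cell_id[hit], levels = ids))
  flags[] <- as.vector(counts) >= params@minMarkerCount
  flags
}

#' Rebuild one cell boundary from its marker transcripts
#'
#' The refined boundary is the union of the convex hull of the cell's
#' quality-passing marker transcript coordinates with the (hole-filled)
#' nucleus polygon. When the nucleus is absent the hull alone is used, with
#' a warning. Collinear marker points are buffered by
#' \code{params@epsilon} so the hull has positive area.
#'
#' @param boundary the cell's current boundary polygon (used as fallback).
#' @param nucleus nucleus polygon or \code{NULL}.
#' @param markerX,markerY coordinates of the cell's quality-passing marker
#'   transcripts.
#' @param params a \code{\link{ResegmentationParams}}.
#' @return List with elements \code{boundary} (polygon), \code{action}
#'   (\code{"refined"} or \code{"retained"}) and \code{warning}
#'   (\code{NA} or a message).
#' @export
refineBoundary <- function(boundary, nucleus, markerX, markerY,
                           params = ResegmentationParams()) {
  warn <- NA_character_
  hull <- tryCatch(convexHullPolygon(markerX, markerY, epsilon = params@epsilon),
                   error = function(e) NULL)
  if (is.null(hull)) {
    if (is.null(nucleus)) {
      return(list(boundary = boundary, action = "retained",
                  warning = "degenerate marker hull and no nucleus; original boundary retained"))
    }
    return(list(boundary = fillHoles(nucleus), action = "refined",
                warning = "degenerate marker hull; nucleus polygon used alone"))
  }
  if (is.null(nucleus)) {
    return(list(boundary = hull, action = "refined",
                warning = "no nucleus polygon; marker hull used alone"))
  }
  refined <- withCallingHandlers(
    polygonUnion(hull, fillHoles(nucleus), bridge = TRUE),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  list(boundary = refined, action = "refined", warning = warn)
}

#' Reassign transcripts to cell boundaries by containment
#'
#' Every transcript (regardless of quality value) is tested against every
#' cell boundary. A transcript inside exactly one boundary is assigned to
#' that cell; inside none, to \code{"UNASSIGNED"}; inside several, the tie
#' is resolved deterministically: marker-refined boundaries outrank
#' default/expansion boundaries, then the candidate with the nearest
#' nucleus centroid wins (boundary centroid when the nucleus is absent),
#' and any remaining tie is broken lexicographically by cell id.
#'
#' @param seg a \code{\linkS4class{CellSegmentation}}.
#' @param transcripts transcript table.
#' @return The transcript table with \code{cell_id} replaced by the new
#'   assignment (row count and order preserved).
#' @export
reassignTranscripts <- function(seg, transcripts) {
  n <- nrow(transcripts)
  ids <- cellIds(seg)
  px <- transcripts$x; py <- transcripts$y
  # reference point per cell for distance tie-breaks
  refPts <- t(vapply(seq_along(ids), function(i) {
    src <- if (!is.null(seg@nuclei[[i]])) seg@nuclei[[i]] else seg@boundaries[[i]]
    .ringCentroid(src)
  }, numeric(2)))
  prio <- ifelse(seg@provenance == "marker_refined", 1L, 2L)

  hitT <- integer(0); hitC <- integer(0)
  for (i in seq_along(ids)) {
    b <- seg@boundaries[[i]]
    bb <- .bboxRing(b)
    cand <- which(px >= bb[1] & px <= bb[2] & py >= bb[3] & py <= bb[4])
    if (length(cand) == 0) next
    inside <- cand[sp::point.in.polygon(px[cand], py[cand], b$x, b$y) > 0]
    if (length(inside) > 0) {
      hitT <- c(hitT, inside)
      hitC <- c(hitC, rep(i, length(inside)))
    }
  }
  assigned <- rep(UNASSIGNED, n)
  if (length(hitT) > 0) {
    d2 <- (px[hitT] - refPts[hitC, 1])^2 + (py[hitT] - refPts[hitC, 2])^2
    ord <- order(hitT, prio[hitC], d2, ids[hitC])
    first <- ord[!duplicated(hitT[ord])]
    assigned[hitT[first]] <- ids[hitC[first]]
  }
  transcripts$cell_id <- assigned
  transcripts
}

#' Marker-directed resegmentation
#'
#' The full refinement pipeline: repair/fill all input polygons, flag cells
#' carrying at least \code{minMarkerCount} quality-passing marker
#' transcripts, rebuild each flagged cell's boundary as the convex hull of
#' its marker transcripts merged with its nucleus polygon, retain all other
#' boundaries unchanged, and reassign every transcript against the new
#' boundaries. Deterministic for fixed inputs.
#'
#' @param seg input \code{\linkS4class{CellSegmentation}} (the platform's
#'   default segmentation).
#' @param transcripts transcript table with input cell assignments.
#' @param params a \code{\link{ResegmentationParams}}.
#' @return A \code{\linkS4class{ResegmentationResult}}.
#' @export
#' @examples
#' sq <- list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
#' nuc <- list(x = c(4, 6, 6, 4), y = c(4, 4, 6, 6))
#' seg <- CellSegmentation("c1", list(sq), list(nuc))
#' tr <- data.frame(transcript_id = paste0("t", 1:4),
#'                  x = c(1, 2, 1.5, 8), y = c(1, 1, 2.5, 8),
#'                  gene = c("KRT5", "KRT5", "KRT5", "KRT79"),
#'                  qv = 30, cell_id = "c1")
#' res <- runMarkerResegmentation(seg, tr)
#' auditTable(res)
runMarkerResegmentation <- function(seg, transcripts,
                                    params = ResegmentationParams()) {
  transcripts <- validateTranscripts(transcripts)
  ids <- cellIds(seg)
  n <- length(ids)

  # repair pass: fill holes in every boundary and nucleus (exact identity
  # for already-simple rings, so retained boundaries stay bit-identical)
  bnd <- lapply(seg@boundaries, fillHoles)
  nuc <- lapply(seg@nuclei, function(p) if (is.null(p)) NULL else fillHoles(p))
  repaired <- CellSegmentation(ids, bnd, nuc, provenance = seg@provenance,
                               cellTypes = seg@cellTypes)

  flags <- flagCells(repaired, transcripts, params)

  markerHit <- transcripts$gene == params@markerGene
  if (!params@countAllQV) markerHit <- markerHit & transcripts$qv >= params@minQV
  nMarker <- table(factor(transcripts$cell_id[markerHit], levels = ids))

  action <- rep("retained", n)
  warnMsg <- rep(NA_character_, n)
  prov <- repaired@provenance
  newBnd <- repaired@boundaries
  qvPass <- transcripts$qv >= params@minQV
  for (i in which(flags)) {
    sel <- markerHit & qvPass & transcripts$cell_id == ids[i]
    r <- refineBoundary(repaired@boundaries[[i]], repaired@nuclei[[i]],
                        transcripts$x[sel], transcripts$y[sel], params)
    newBnd[[i]] <- r$boundary
    action[i] <- r$action
    warnMsg[i] <- r$warning
    if (r$action == "refined") prov[i] <- "marker_refined"
  }

  refined <- CellSegmentation(ids, newBnd, repaired@nuclei,
                              provenance = prov, cellTypes = seg@cellTypes)
  reassigned <- reassignTranscripts(refined, transcripts)

  audit <- data.frame(cell_id = ids, action = action, flagged = unname(flags),
                      n_marker = as.vector(nMarker), warning = warnMsg,
                      stringsAsFactors = FALSE)
  new("ResegmentationResult", refined = refined, transcripts = reassigned,
      flags = flags, audit = audit)
}
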