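#' @import methods
NULL

.PROVENANCE <- c("default", "marker_refined", "nuclear_expansion")

#' CellSegmentation: per-cell boundary and nucleus polygons
#'
#' Container for one segmentation of a tissue section: one boundary polygon
#' per cell, an optional nucleus polygon, the provenance of each boundary
#' (\code{default}, \code{marker_refined} or \code{nuclear_expansion}) and
#' an optional cell-type label (used by the synthetic-gland ground truth).
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot boundaries list of boundary polygons (one per cell).
#' @slot nuclei list of nucleus polygons; \code{NULL} entries mark cells
#'   without a detected nucleus.
#' @slot provenance character vector, one of \code{default},
#'   \code{marker_refined}, \code{nuclear_expansion} per cell.
#' @slot cellTypes character vector of cell-type labels (\code{NA} when
#'   unknown).
#'
#' @seealso \code{\link{readBoundaries}}, \code{\link{runMarkerResegmentation}}
#' @export
setClass("CellSegmentation",
  slots = c(cellIds = "character", boundaries = "list", nuclei = "list",
            provenance = "character", cellTypes = "character"))

setValidity("CellSegmentation", function(object) {
  n <- length(object@cellIds)
  if (length(object@boundaries) != n) return("boundaries length != cellIds length")
  if (length(object@nuclei) != n) return("nuclei length != cellIds length")
  if (length(object@provenance) != n) return("provenance length != cellIds length")
  if (length(object@cellTypes) != n) return("cellTypes length != cellIds length")
  if (anyDuplicated(object@cellIds)) return("duplicate cell ids")
  if (!all(object@provenance %in% .PROVENANCE))
    return(sprintf("provenance must be one of: %s", paste(.PROVENANCE, collapse = ", ")))
  for (i in seq_len(n)) {
    b <- object@boundaries[[i]]
    if (!.isRing(b)) return(sprintf("cell '%s': boundary is not a valid ring", object@cellIds[i]))
    if (abs(.signedArea(b)) <= 0) return(sprintf("cell '%s': zero-area boundary", object@cellIds[i]))
    nu <- object@nuclei[[i]]
    if (!is.null(nu) && !.isRing(nu))
      return(sprintf("cell '%s': nucleus is not a valid ring", object@cellIds[i]))
  }
  TRUE
})

#' Construct a CellSegmentation
#'
#' @param cellIds character vector of unique cell ids.
#' @param boundaries list of boundary polygons (lists with \code{x}, \code{y}).
#' @param nuclei optional list of nucleus polygons (\code{NULL} entries
#'   allowed); defaults to no nuclei.
#' @param provenance boundary provenance, recycled to one value per cell.
#' @param cellTypes optional cell-type labels.
#' @return A \code{\linkS4class{CellSegmentation}}.
#' @export
CellSegmentation <- function(cellIds, boundaries, nuclei = NULL,
                             provenance = "default", cellTypes = NA_character_) {
  n <- length(cellIds)
  if (is.null(nuclei)) nuclei <- vector("list", n)
  new("CellSegmentation",
      cellIds = as.character(cellIds),
      boundaries = boundaries,
      nuclei = nuclei,
      provenance = rep_len(as.character(provenance), n),
      cellTypes = rep_len(as.character(cellTypes), n))
}

#' @describeIn CellSegmentation number of cells
#' @param x a \code{CellSegmentation}.
#' @export
setMethod("length", "CellSegmentation", function(x) length(x@cellIds))

#' Accessors for CellSegmentation
#'
#' @param object a \code{\linkS4class{CellSegmentation}}.
#' @return \code{cellIds}: character vector; \code{boundaries},
#'   \code{nuclei}: named lists of polygons; \code{provenance},
#'   \code{cellTypes}: named character vectors.
#' @name segmentation-accessors
NULL

#' @rdname segmentation-accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @rdname segmentation-accessors
#' @export
setMethod("cellIds", "CellSegmentation", function(object) object@cellIds)

#' @rdname segmentation-accessors
#' @export
setGeneric("boundaries", function(object) standardGeneric("boundaries"))
#' @rdname segmentation-accessors
#' @export
setMethod("boundaries", "CellSegmentation",
          function(object) stats::setNames(object@boundaries, object@cellIds))

#' @rdname segmentation-accessors
#' @export
setGeneric("nuclei", function(object) standardGeneric("nuclei"))
#' @rdname segmentation-accessors
#' @export
setMethod("nuclei", "CellSegmentation",
          function(object) stats::setNames(object@nuclei, object@cellIds))

#' @rdname segmentation-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname segmentation-accessors
#' @export
setMethod("provenance", "CellSegmentation",
          function(object) stats::setNames(object@provenance, object@cellIds))

#' @rdname segmentation-accessors
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))
#' @rdname segmentation-accessors
#' @export
setMethod("cellTypes", "CellSegmentation",
          function(object) stats::setNames(object@cellTypes, object@cellIds))

#' @describeIn CellSegmentation subset by index, logical vector or cell id
#' @param i subscript.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CellSegmentation", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@cellIds)
    if (anyNA(idx)) .stopf("unknown cell id(s): %s", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  new("CellSegmentation",
      cellIds = x@cellIds[i], boundaries = x@boundaries[i],
      nuclei = x@nuclei[i], provenance = x@provenance[i],
      cellTypes = x@cellTypes[i])
})

setMethod("show", "CellSegmentation", function(object) {
  n <- length(object@cellIds)
  cat(sprintf("CellSegmentation with %d cell%s\n", n, if (n == 1) "" else "s"))
  cat(sprintf("  nuclei present: %d\n", sum(!vapply(object@nuclei, is.null, logical(1)))))
  cat(sprintf("  provenance: %s\n",
              paste(sprintf("%s (%d)", names(table(object@provenance)),
                            table(object@provenance)), collapse = ", ")))
  if (!all(is.na(object@cellTypes)))
    cat(sprintf("  cell types: %s\n",
                paste(sprintf("%s (%d)", names(table(object@cellTypes)),
                              table(object@cellTypes)), collapse = ", ")))
  invisible(NULL)
})

#' Parameters for marker-directed resegmentation
#'
#' @slot markerGene gene symbol whose transcripts direct the refinement
#'   (default \code{"KRT5"}).
#' @slot minMarkerCount minimum number of quality-passing marker
#'   transcripts for a cell to be flagged; at least 3, the convex-hull
#'   minimum (default 3).
#' @slot minQV minimum transcript quality value (Phred-like) for marker
#'   counting and downstream count matrices (default 20).
#' @slot epsilon buffer radius in micrometres used when a cell's marker
#'   transcripts are collinear (default 0.2).
#' @slot countAllQV logical; count marker transcripts regardless of quality
#'   value when flagging (default \code{FALSE}).
#' @export
setClass("ResegmentationParams",
  slots = c(markerGene = "character", minMarkerCount = "numeric",
            minQV = "numeric", epsilon = "numeric", countAllQV = "logical"))

setValidity("ResegmentationParams", function(object) {
  if (length(object@markerGene) != 1 || !nzchar(object@markerGene))
    return("markerGene must be a single non-empty gene symbol")
  if (object@minMarkerCount < 3)
    return("minMarkerCount must be >= 3 (convex-hull minimum)")
  if (object@minQV < 0) return("minQV must be >= 0")
  if (object@epsilon < 0) return("epsilon must be >= 0")
  TRUE
})

#' @rdname ResegmentationParams-class
#' @param markerGene,minMarkerCount,minQV,epsilon,countAllQV see slots.
#' @return A \code{ResegmentationParams} object.
#' @export
ResegmentationParams <- function(markerGene = "KRT5", minMarkerCount = 3,
                                 minQV = 20, epsilon = 0.2, countAllQV = FALSE) {
  new("ResegmentationParams", markerGene = markerGene,
      minMarkerCount = as.numeric(minMarkerCount), minQV = as.numeric(minQV),
      epsilon = as.numeric(epsilon), countAllQV = isTRUE(countAllQV))
}

setMethod("show", "ResegmentationParams", function(object) {
  cat(sprintf("ResegmentationParams: marker=%s, minMarkerCount=%g, minQV=%g, epsilon=%g um\n",
              object@markerGene, object@minMarkerCount, object@minQV, object@epsilon))
  invisible(NULL)
})

#' Result of marker-directed resegmentation
#'
#' @slot refined the refined \code{\linkS4class{CellSegmentation}} (flagged
#'   cells rebuilt, others retained).
#' @slot transcripts transcript table with reassigned \code{cell_id}.
#' @slot flags named logical: was each input cell flagged for refinement.
#' @slot audit per-cell record: \code{cell_id}, \code{action}
#'   (\code{refined}/\code{retained}), \code{flagged}, \code{n_marker},
#'   \code{warning}.
#' @export
setClass("ResegmentationResult",
  slots = c(refined = "CellSegmentation", transcripts = "data.frame",
            flags = "logical", audit = "data.frame"))

setMethod("show", "ResegmentationResult", function(object) {
  cat(sprintf("ResegmentationResult: %d cells (%d refined), %d transcripts (%d assigned)\n",
              length(object@refined), sum(object@audit$action == "refined"),
              nrow(object@transcripts),
              sum(object@transcripts$cell_id != UNASSIGNED)))
  invisible(NULL)
})

#' @rdname ResegmentationResult-class
#' @param object a \code{ResegmentationResult}.
#' @export
setGeneric("refinedSegmentation", function(object) standardGeneric("refinedSegmentation"))
#' @rdname ResegmentationResult-class
#' @export
setMethod("refinedSegmentation", "ResegmentationResult", function(object) object@refined)

#' @rdname ResegmentationResult-class
#' @export
setGeneric("assignedTranscripts", function(object) standardGeneric("assignedTranscripts"))
#' @rdname ResegmentationResult-class
#' @export
setMethod("assignedTranscripts", "ResegmentationResult", function(object) object@transcripts)

#' @rdname ResegmentationResult-class
#' @export
setGeneric("auditTable", function(object) standardGeneric("auditTable"))
#' @rdname ResegmentationResult-class
#' @export
setMethod("auditTable", "ResegmentationResult", function(object) object@audit)

#' Normalized expression matrix
#'
#' Cells-by-genes matrix of normalized expression: per-cell totals scaled to
#' a common target sum, then natural \code{log1p}.
#'
#' @slot matrix sparse cells-by-genes \code{Matrix} of normalized values.
#' @slot targetSum the per-cell total each cell was scaled to (the median
#'   total across cells with nonzero counts).
#' @slot logBase base of the log transform (\code{exp(1)}).
#' @export
setClass("NormalizedMatrix",
  slots = c(matrix = "ANY", targetSum = "numeric", logBase = "numeric"))

#' @rdname NormalizedMatrix-class
#' @param object a \code{NormalizedMatrix}.
#' @export
setGeneric("normValues", function(object) standardGeneric("normValues"))
#' @rdname NormalizedMatrix-class
#' @export
setMethod("normValues", "NormalizedMatrix", function(object) object@matrix)

#' @rdname NormalizedMatrix-class
#' @export
setGeneric("targetSum", function(object) standardGeneric("targetSum"))
#' @rdname NormalizedMatrix-class
#' @export
setMethod("targetSum", "NormalizedMatrix", function(object) object@targetSum)

setMethod("show", "NormalizedMatrix", function(object) {
  cat(sprintf("NormalizedMatrix: %d cells x %d genes (target sum %.6g, natural log1p)\n",
              nrow(object@matrix), ncol(object@matrix), object@targetSum))
  invisible(NULL)
})

#' Segmentation-method comparison
#'
#' Per-cell metric rows for each segmentation method together with the
#' group-comparison statistics: one-way ANOVA across methods and all
#' pairwise mean differences with Tukey-adjusted p-values and 95 percent
#' confidence intervals.
#'
#' @slot cells data.frame with columns \code{method}, \code{cell_id} and one
#'   column per metric.
#' @slot anova data.frame: \code{metric}, \code{F}, \code{p}, \code{df1},
#'   \code{df2}.
#' @slot tukey data.frame: \code{metric}, \code{comparison},
#'   \code{mean_diff}, \code{ci_lo}, \code{ci_hi}, \code{p_adj}.
#' @export
setClass("MethodComparison",
  slots = c(cells = "data.frame", anova = "data.frame", tukey = "data.frame"))

#' @rdname MethodComparison-class
#' @param object a \code{MethodComparison}.
#' @export
setGeneric("comparisonCells", function(object) standardGeneric("comparisonCells"))
#' @rdname MethodComparison-class
#' @export
setMethod("comparisonCells", "MethodComparison", function(object) object@cells)

#' @rdname MethodComparison-class
#' @export
setGeneric("anovaTable", function(object) standardGeneric("anovaTable"))
#' @rdname MethodComparison-class
#' @export
setMethod("anovaTable", "MethodComparison", function(object) object@anova)

#' @rdname MethodComparison-class
#' @export
setGeneric("tukeyTable", function(object) standardGeneric("tukeyTable"))
#' @rdname MethodComparison-class
#' @export
setMethod("tukeyTable", "MethodComparison", function(object) object@tukey)

setMethod("show", "MethodComparison", function(object) {
  cat(sprintf("MethodComparison: %d methods, %d metrics, %d cell rows\n",
              length(unique(object@cells$method)),
              nrow(object@anova), nrow(object@cells)))
  invisible(NULL)
})

#' Synthetic sebaceous gland with ground truth
#'
#' Output of \code{\link{simulateGland}}: the simulated transcript table
#' (with observed cell assignments), the observed (corrupted) default
#' segmentation, the ground-truth segmentation with cell-type labels, the
#' true per-transcript cell id, and the generating parameters.
#'
#' @slot transcripts transcript table; \code{cell_id} holds the observed
#'   (default-segmentation) assignment.
#' @slot observed observed \code{\linkS4class{CellSegmentation}} with basal
#'   boundaries over-extended into sebocyte territory.
#' @slot truth ground-truth \code{CellSegmentation} with \code{cellTypes}.
#' @slot trueAssignment character vector named by \code{transcript_id}: the
#'   cell each transcript was generated in.
#' @slot params the \code{\link{glandParams}} list used.
#' @export
setClass("GlandSimulation",
  slots = c(transcripts = "data.frame", observed = "CellSegmentation",
            truth = "CellSegmentation", trueAssignment = "character",
            params = "list"))

#' @rdname GlandSimulation-class
#' @param object a \code{GlandSimulation}.
#' @export
setGeneric("glandTranscripts", function(object) standardGeneric("glandTranscripts"))
#' @rdname GlandSimulation-class
#' @export
setMethod("glandTranscripts", "GlandSimulation", function(object) object@transcripts)

#' @rdname GlandSimulation-class
#' @export
setGeneric("observedSegmentation", function(object) standardGeneric("observedSegmentation"))
#' @rdname GlandSimulation-class
#' @export
setMethod("observedSegmentation", "GlandSimulation", function(object) object@observed)

#' @rdname GlandSimulation-class
#' @export
setGeneric("truthSegmentation", function(object) standardGeneric("truthSegmentation"))
#' @rdname GlandSimulation-class
#' @export
setMethod("truthSegmentation", "GlandSimulation", function(object) object@truth)

#' @rdname GlandSimulation-class
#' @export
setGeneric("trueAssignment", function(object) standardGeneric("trueAssignment"))
#' @rdname GlandSimulation-class
#' @export
setMethod("trueAssignment", "GlandSimulation", function(object) object@trueAssignment)

#' @rdname GlandSimulation-class
#' @export
setGeneric("glandParameters", function(object) standardGeneric("glandParameters"))
#' @rdname GlandSimulation-class
#' @export
setMethod("glandParameters", "GlandSimulation", function(object) object@params)

setMethod("show", "GlandSimulation", function(object) {
  tt <- table(object@truth@cellTypes)
  cat(sprintf("GlandSimulation (seed %s): %d cells (%s), %d transcripts\n",
              format(object@params$seed), length(object@truth),
              paste(sprintf("%d %s", tt, names(tt)), collapse = ", "),
              nrow(object@transcripts)))
  invisible(NULL)
})
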