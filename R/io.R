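#' Read a transcript table from CSV
#'
#' Reads and validates a per-transcript table with the fixed columns
#' \code{transcript_id,x,y,gene,qv,cell_id} (coordinates in micrometres,
#' \code{qv} a Phred-like quality value). Missing or empty cell assignments
#' are normalized to the sentinel \code{"UNASSIGNED"}. Malformed records are
#' rejected with the offending row index, never silently coerced.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{transcript_id}, \code{x}, \code{y},
#'   \code{gene}, \code{qv}, \code{cell_id}.
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) .stopf("transcript file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "x", "y", "gene", "qv", "cell_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    .stopf("transcript CSV missing required column(s): %s", paste(missing, collapse = ", "))
  df <- df[required]
  validateTranscripts(df)
}

#' Validate a transcript table
#'
#' Checks the invariants of the transcript table: finite coordinates,
#' non-negative quality values, unique transcript ids. Empty or \code{NA}
#' cell ids become \code{"UNASSIGNED"}.
#'
#' @param df data.frame with the six transcript columns.
#' @return The validated (normalized) data.frame.
#' @export
validateTranscripts <- function(df) {
  required <- c("transcript_id", "x", "y", "gene", "qv", "cell_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    .stopf("transcript table missing column(s): %s", paste(missing, collapse = ", "))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  df$qv <- suppressWarnings(as.numeric(df$qv))
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad) > 0)
    .stopf("non-finite coordinate in transcript row(s): %s", paste(bad, collapse = ", "))
  bad <- which(!is.finite(df$qv) | df$qv < 0)
  if (length(bad) > 0)
    .stopf("invalid quality value in transcript row(s): %s", paste(bad, collapse = ", "))
  df$transcript_id <- as.character(df$transcript_id)
  if (anyDuplicated(df$transcript_id))
    .stopf("duplicate transcript_id: %s",
           df$transcript_id[anyDuplicated(df$transcript_id)])
  df$gene <- as.character(df$gene)
  df$cell_id <- as.character(df$cell_id)
  df$cell_id[is.na(df$cell_id) | df$cell_id == ""] <- UNASSIGNED
  rownames(df) <- NULL
  df
}

#' Write a transcript table to CSV
#'
#' @param df transcript data.frame.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeTranscripts <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- boundary I/O -----------------------------------------------------------

.segFromFeatures <- function(ids, kinds, rings, provenance) {
  key <- paste(ids, kinds)
  if (anyDuplicated(key))
    .stopf("duplicate (cell_id, kind) feature: %s", key[anyDuplicated(key)])
  cellIdx <- which(kinds == "cell")
  nucIdx <- which(kinds == "nucleus")
  cellIds <- ids[cellIdx]
  orphan <- setdiff(ids[nucIdx], cellIds)
  if (length(orphan) > 0)
    .stopf("nucleus feature(s) without matching cell: %s", paste(orphan, collapse = ", "))
  bnd <- lapply(rings[cellIdx], fillHoles)
  nuc <- vector("list", length(cellIds))
  m <- match(ids[nucIdx], cellIds)
  for (k in seq_along(nucIdx)) nuc[[m[k]]] <- fillHoles(rings[[nucIdx[k]]])
  prov <- provenance[cellIdx]
  prov[is.na(prov) | !(prov %in% .PROVENANCE)] <- "default"
  CellSegmentation(cellIds, bnd, nuc, provenance = prov)
}

#' Read cell and nucleus boundaries
#'
#' Reads a segmentation from a GeoJSON FeatureCollection (features with
#' Polygon geometry and properties \code{cell_id} and \code{kind}, where
#' \code{kind} is \code{"cell"} or \code{"nucleus"}; an optional
#' \code{provenance} property is honoured) or, for files ending in
#' \code{.csv}, from a vertex-list dialect with columns
#' \code{cell_id,kind,vertex_index,x,y}. All polygons are repaired with
#' \code{\link{fillHoles}} on read. Duplicate \code{(cell_id, kind)}
#' features and nuclei without a matching cell are errors.
#'
#' @param path GeoJSON (\code{.geojson}/\code{.json}) or CSV vertex-list
#'   file.
#' @return A \code{\linkS4class{CellSegmentation}}.
#' @export
readBoundaries <- function(path) {
  if (!file.exists(path)) .stopf("boundary file not found: %s", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(.readBoundariesCSV(path))
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    .stopf("boundary GeoJSON must be a FeatureCollection")
  feats <- gj$features
  n <- length(feats)
  if (n == 0) .stopf("boundary GeoJSON contains no features")
  ids <- character(n); kinds <- character(n); prov <- rep(NA_character_, n)
  rings <- vector("list", n)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    if (is.null(f$properties$cell_id)) .stopf("feature %d lacks property cell_id", i)
    if (is.null(f$properties$kind) || !(f$properties$kind %in% c("cell", "nucleus")))
      .stopf("feature %d: property kind must be 'cell' or 'nucleus'", i)
    ids[i] <- as.character(f$properties$cell_id)
    kinds[i] <- f$properties$kind
    if (!is.null(f$properties$provenance)) prov[i] <- as.character(f$properties$provenance)
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon")
      .stopf("feature %d: geometry must be Polygon", i)
    rr <- lapply(f$geometry$coordinates, function(ring) {
      xy <- do.call(rbind, lapply(ring, function(pt) c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      # GeoJSON rings repeat the first vertex; our convention is implicit closure
      if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
      if (nrow(xy) < 3) .stopf("feature %d: ring with fewer than 3 vertices", i)
      if (!all(is.finite(xy))) .stopf("feature %d: non-finite coordinates", i)
      list(x = xy[, 1], y = xy[, 2])
    })
    rings[[i]] <- if (length(rr) == 1) rr[[1]] else rr
  }
  .segFromFeatures(ids, kinds, rings, prov)
}

.readBoundariesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "kind", "vertex_index", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    .stopf("boundary CSV missing column(s): %s", paste(missing, collapse = ", "))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    .stopf("boundary CSV contains non-finite coordinates")
  key <- paste(df$cell_id, df$kind)
  groups <- split(df[order(df$vertex_index), ], key[order(df$vertex_index)])
  # split() keys may reorder; recover ids/kinds from each group
  ids <- vapply(groups, function(g) as.character(g$cell_id[1]), character(1))
  kinds <- vapply(groups, function(g) as.character(g$kind[1]), character(1))
  bad <- which(!(kinds %in% c("cell", "nucleus")))
  if (length(bad) > 0) .stopf("boundary CSV: invalid kind '%s'", kinds[bad[1]])
  rings <- lapply(groups, function(g) list(x = g$x, y = g$y))
  .segFromFeatures(unname(ids), unname(kinds), unname(rings), rep(NA_character_, length(ids)))
}

#' Write a segmentation to GeoJSON
#'
#' Writes one \code{Polygon} feature per cell boundary (and per nucleus
#' where present), with properties \code{cell_id}, \code{kind},
#' \code{provenance} and, when known, \code{cell_type}. Rings are closed
#' explicitly per the GeoJSON convention. Coordinates keep full double
#' precision.
#'
#' @param seg a \code{\linkS4class{CellSegmentation}}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeBoundaries <- function(seg, path) {
  closeRing <- function(r) lapply(c(seq_along(r$x), 1L), function(i) c(r$x[i], r$y[i]))
  feats <- list()
  for (i in seq_len(length(seg))) {
    props <- list(cell_id = seg@cellIds[i], kind = "cell",
                  provenance = seg@provenance[i])
    if (!is.na(seg@cellTypes[i])) props$cell_type <- seg@cellTypes[i]
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = props,
      geometry = list(type = "Polygon",
                      coordinates = list(closeRing(seg@boundaries[[i]]))))
    if (!is.null(seg@nuclei[[i]])) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(cell_id = seg@cellIds[i], kind = "nucleus"),
        geometry = list(type = "Polygon",
                        coordinates = list(closeRing(seg@nuclei[[i]]))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- count-matrix I/O -------------------------------------------------------

#' Write a count matrix in MatrixMarket layout
#'
#' Writes \code{matrix.mtx}, \code{barcodes.tsv} (cell ids) and
#' \code{features.tsv} (gene symbols) under \code{dir}. The matrix is
#' stored genes-by-cells on disk, following the CellRanger convention;
#' \code{\link{readCounts}} transposes back to cells-by-genes.
#'
#' @param counts cells-by-genes sparse integer matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeCounts <- function(counts, dir) {
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    .stopf("count matrix must carry cell ids as rownames")
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    .stopf("count matrix must carry gene symbols as colnames")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(Matrix::t(methods::as(counts, "CsparseMatrix")), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  rn <- rownames(counts); cn <- colnames(counts)
  writeLines(if (is.null(rn)) character(0) else rn, file.path(dir, "barcodes.tsv"))
  writeLines(if (is.null(cn)) character(0) else cn, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket count matrix
#'
#' @param dir directory holding \code{matrix.mtx}, \code{barcodes.tsv},
#'   \code{features.tsv} as written by \code{\link{writeCounts}}.
#' @return Cells-by-genes sparse matrix (\code{dgCMatrix}) with dimnames.
#' @export
readCounts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) .stopf("matrix.mtx not found under %s", dir)
  # readMM may return a symmetric class when the values happen to be
  # symmetric; force a general matrix so dimnames can differ per margin
  m <- methods::as(Matrix::readMM(mtx), "generalMatrix")
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- readLines(file.path(dir, "features.tsv"))
  m <- Matrix::t(m)
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  m
}
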