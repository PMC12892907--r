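#' Quality-control filter for assigned transcripts
#'
#' Two-step filter, applied in this order: (1) transcripts with quality
#' value below \code{minQV} are dropped; (2) cells whose remaining assigned
#' transcript count is below \code{minTranscriptsPerCell} are excluded —
#' their surviving transcripts become \code{"UNASSIGNED"}. The operation is
#' idempotent.
#'
#' @param transcripts transcript table with cell assignments.
#' @param minQV minimum quality value (default 20).
#' @param minTranscriptsPerCell minimum kept transcripts per cell
#'   (default 10).
#' @return List with \code{transcripts} (the QV-passing rows, cell ids of
#'   excluded cells blanked to \code{"UNASSIGNED"}) and \code{keptCells}
#'   (character vector of surviving cell ids).
#' @export
qcFilter <- function(transcripts, minQV = 20, minTranscriptsPerCell = 10) {
  tr <- transcripts[transcripts$qv >= minQV, , drop = FALSE]
  assigned <- tr$cell_id[tr$cell_id != UNASSIGNED]
  counts <- table(assigned)
  keptCells <- names(counts)[counts >= minTranscriptsPerCell]
  drop <- tr$cell_id != UNASSIGNED & !(tr$cell_id %in% keptCells)
  tr$cell_id[drop] <- UNASSIGNED
  rownames(tr) <- NULL
  list(transcripts = tr, keptCells = keptCells)
}

#' Build a cell-by-gene count matrix from assigned transcripts
#'
#' Counts kept, assigned transcripts per (cell, gene). The matrix total
#' equals the number of assigned input transcripts.
#'
#' @param transcripts transcript table (QC already applied); unassigned
#'   rows are ignored.
#' @param cells,genes optional fixed row/column universes; defaults to the
#'   ids and genes present.
#' @return Sparse cells-by-genes integer matrix (\code{dgCMatrix}).
#' @export
buildCounts <- function(transcripts, cells = NULL, genes = NULL) {
  tr <- transcripts[transcripts$cell_id != UNASSIGNED, , drop = FALSE]
  if (is.null(cells)) cells <- sort(unique(tr$cell_id))
  if (is.null(genes)) genes <- sort(unique(tr$gene))
  i <- match(tr$cell_id, cells)
  j <- match(tr$gene, genes)
  ok <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(i = i[ok], j = j[ok], x = rep(1, sum(ok)),
                       dims = c(length(cells), length(genes)),
                       dimnames = list(cells, genes))
}

#' Normalize a count matrix
#'
#' Scales each cell's counts so its total equals a common target sum — by
#' default the median per-cell total (computed over cells with nonzero
#' counts) — then applies the natural \code{log1p} transform. A cell of
#' all-zero counts normalizes to all zeros. When normalized values are to
#' be compared across segmentation methods, pass the same \code{targetSum}
#' for every method so the values share a scale (in whole-tissue data the
#' median total is dominated by cells outside the compartment of interest
#' and is effectively method-invariant; a small simulated gland has no such
#' ballast, so the common target must be fixed explicitly).
#'
#' @param counts cells-by-genes count matrix.
#' @param targetSum optional fixed per-cell target total; default is the
#'   median per-cell total of \code{counts}.
#' @return A \code{\linkS4class{NormalizedMatrix}}.
#' @export
normalizeCounts <- function(counts, targetSum = NULL) {
  if (nrow(counts) == 0 || ncol(counts) == 0) .stopf("empty count matrix")
  totals <- Matrix::rowSums(counts)
  if (all(totals == 0)) .stopf("all-zero count matrix cannot be normalized")
  target <- if (is.null(targetSum)) stats::median(totals[totals > 0]) else targetSum
  if (!is.numeric(target) || length(target) != 1 || !is.finite(target) || target <= 0)
    .stopf("targetSum must be a single positive number")
  scale <- ifelse(totals > 0, target / totals, 0)
  m <- methods::as(Matrix::Diagonal(x = scale) %*% counts, "CsparseMatrix")
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(counts)
  new("NormalizedMatrix", matrix = m, targetSum = target, logBase = exp(1))
}

#' Composite gene-set score per cell
#'
#' The unweighted mean of normalized expression over the genes of a
#' signature that are present in the matrix. The default signature is the
#' five-gene sebogenesis set (FASN, AWAT1, AWAT2, ACACA, SREBF1). Signature
#' genes absent from the matrix are skipped with a warning, so the score is
#' invariant to padding the set with absent genes.
#'
#' @param norm a \code{\linkS4class{NormalizedMatrix}}.
#' @param genes character vector of signature genes (>= 1, unique).
#' @param name signature name (metadata only).
#' @return Named numeric vector of per-cell scores.
#' @export
geneSetScore <- function(norm, genes = sebogenesisGenes(), name = "score") {
  genes <- unique(genes)
  if (length(genes) < 1) .stopf("gene set must contain at least one gene")
  m <- normValues(norm)
  present <- intersect(genes, colnames(m))
  if (length(present) == 0)
    .stopf("none of the %d '%s' genes are present in the matrix", length(genes), name)
  if (length(present) < length(genes))
    .warnf("%d '%s' gene(s) absent from matrix: %s", length(genes) - length(present),
           name, paste(setdiff(genes, present), collapse = ", "))
  stats::setNames(Matrix::rowMeans(m[, present, drop = FALSE]), rownames(m))
}

#' The five-gene sebogenesis signature
#'
#' Lipogenic genes whose composite normalized expression scores sebaceous
#' gland function: FASN, AWAT1, AWAT2, ACACA, SREBF1.
#'
#' @return Character vector of five gene symbols.
#' @export
sebogenesisGenes <- function() c("FASN", "AWAT1", "AWAT2", "ACACA", "SREBF1")

#' Per-group expression ratio of two genes
#'
#' For each group of cells, computes \code{(mean(a) + delta) /
#' (mean(b) + delta)} on normalized expression, with a small pseudocount
#' \code{delta} guarding against zero denominators. Defaults compute the
#' FABP5:CRABP2 ratio, whose balance routes retinoic acid to PPAR-beta/delta
#' (high FABP5) versus RAR (high CRABP2) signaling. Empty groups are
#' skipped with a warning.
#'
#' @param norm a \code{\linkS4class{NormalizedMatrix}}.
#' @param groups character/factor of group labels, one per cell (named by
#'   cell id, or parallel to the matrix rows).
#' @param geneA,geneB gene symbols (defaults \code{"FABP5"},
#'   \code{"CRABP2"}).
#' @param delta pseudocount (default 0.01).
#' @return Named numeric vector: one ratio per group.
#' @export
expressionRatio <- function(norm, groups, geneA = "FABP5", geneB = "CRABP2",
                            delta = 0.01) {
  m <- normValues(norm)
  for (g in c(geneA, geneB))
    if (!(g %in% colnames(m))) .stopf("gene '%s' not present in the matrix", g)
  if (!is.null(names(groups))) groups <- groups[rownames(m)]
  if (length(groups) != nrow(m))
    .stopf("groups must provide one label per cell")
  # NA labels mark cells outside all groups; empty factor levels warn + skip
  lev <- if (is.factor(groups)) levels(groups) else setdiff(unique(as.character(groups)), NA)
  out <- numeric(0)
  for (g in lev) {
    idx <- which(as.character(groups) == g)
    if (length(idx) == 0) {
      .warnf("empty group '%s' skipped", g)
      next
    }
    ma <- mean(m[idx, geneA])
    mb <- mean(m[idx, geneB])
    out[g] <- (ma + delta) / (mb + delta)
  }
  out
}

#' Compare segmentation methods with ANOVA and Tukey post hoc tests
#'
#' For each metric column, fits a one-way ANOVA of the metric across
#' methods and derives all pairwise mean differences with Tukey-adjusted
#' p-values and 95 percent confidence intervals (via \code{stats::aov} and
#' \code{stats::TukeyHSD}). Each metric is tested independently.
#'
#' @param cells data.frame with columns \code{method}, \code{cell_id}, and
#'   one numeric column per metric.
#' @param metrics character vector of metric column names; defaults to all
#'   numeric columns other than \code{method}/\code{cell_id}.
#' @return A \code{\linkS4class{MethodComparison}}.
#' @export
compareMethods <- function(cells, metrics = NULL) {
  if (!all(c("method", "cell_id") %in% names(cells)))
    .stopf("cells table must have 'method' and 'cell_id' columns")
  if (anyDuplicated(paste(cells$method, cells$cell_id)))
    .stopf("duplicate (method, cell_id) rows")
  if (is.null(metrics))
    metrics <- setdiff(names(cells)[vapply(cells, is.numeric, logical(1))],
                       c("method", "cell_id"))
  methods_ <- unique(cells$method)
  if (length(methods_) < 2) .stopf("need at least 2 methods to compare")
  if (any(table(cells$method) < 2)) .stopf("need at least 2 cells per method")
  anovaRows <- list(); tukeyRows <- list()
  for (met in metrics) {
    d <- data.frame(y = cells[[met]], g = factor(cells$method))
    d <- d[is.finite(d$y), ]
    fit <- stats::aov(y ~ g, data = d)
    ss <- summary(fit)[[1]]
    ssw <- ss["Residuals", "Sum Sq"]; ssb <- ss["g", "Sum Sq"]
    # exact-zero within-group variance shows up as floating-point dust in the
    # residual sum of squares, so test it relative to the total sum of squares
    if (ssw <= 1e-12 * max(.Machine$double.xmin, ssb + ssw))
      .stopf("metric '%s': zero within-group variance in all groups; F undefined", met)
    anovaRows[[met]] <- data.frame(metric = met, F = ss["g", "F value"],
                                   p = ss["g", "Pr(>F)"],
                                   df1 = ss["g", "Df"], df2 = ss["Residuals", "Df"])
    th <- stats::TukeyHSD(fit, conf.level = 0.95)$g
    tukeyRows[[met]] <- data.frame(metric = met, comparison = rownames(th),
                                   mean_diff = th[, "diff"], ci_lo = th[, "lwr"],
                                   ci_hi = th[, "upr"], p_adj = th[, "p adj"],
                                   row.names = NULL)
  }
  new("MethodComparison", cells = cells,
      anova = do.call(rbind, c(anovaRows, list(make.row.names = FALSE))),
      tukey = do.call(rbind, c(tukeyRows, list(make.row.names = FALSE))))
}

#' Transcript misassignment rate against simulator ground truth
#'
#' Among the assigned transcripts of one gene, the fraction assigned to a
#' cell of \code{targetCellType} that is not the transcript's true cell —
#' for example, the rate at which sebocyte-marker (KRT79, AWAT2)
#' transcripts end up in basal cells under an over-extended segmentation.
#'
#' @param transcripts transcript table with assignments to evaluate.
#' @param trueCell character vector of true cell ids named by
#'   \code{transcript_id} (see \code{\link{trueAssignment}}).
#' @param types character vector of cell types named by cell id (see
#'   \code{\link{cellTypes}}).
#' @param gene gene symbol to evaluate.
#' @param targetCellType the cell type misassignment is counted into
#'   (default \code{"basal"}).
#' @return Fraction in [0, 1].
#' @export
misassignmentRate <- function(transcripts, trueCell, types, gene,
                              targetCellType = "basal") {
  sel <- transcripts$gene == gene
  if (!any(sel)) .stopf("gene '%s' absent from transcript table", gene)
  tr <- transcripts[sel & transcripts$cell_id != UNASSIGNED, , drop = FALSE]
  if (nrow(tr) == 0) return(0)
  truth <- trueCell[tr$transcript_id]
  if (anyNA(truth)) .stopf("ground truth does not cover all transcripts of '%s'", gene)
  assignedType <- types[tr$cell_id]
  mis <- assignedType == targetCellType & tr$cell_id != truth
  sum(mis, na.rm = TRUE) / nrow(tr)
}

#' Per-cell summary metrics for one segmentation run
#'
#' Convenience assembly of the per-cell rows used by
#' \code{\link{compareMethods}}: boundary area, transcripts per cell (after
#' QC), and normalized expression of selected genes.
#'
#' @param seg the segmentation the assignments came from.
#' @param transcripts assigned transcript table (pre-QC).
#' @param method method label for the rows.
#' @param normGenes genes whose normalized expression to report (default
#'   \code{c("KRT5", "KRT79")}).
#' @param minQV,minTranscriptsPerCell QC thresholds (see
#'   \code{\link{qcFilter}}).
#' @param targetSum optional common normalization target passed to
#'   \code{\link{normalizeCounts}}; fix it to one value when rows from
#'   several methods will be compared.
#' @return data.frame with columns \code{method}, \code{cell_id},
#'   \code{area}, \code{tpc} and \code{norm_<gene>} columns; only
#'   QC-passing cells appear.
#' @export
cellMetrics <- function(seg, transcripts, method,
                        normGenes = c("KRT5", "KRT79"),
                        minQV = 20, minTranscriptsPerCell = 10,
                        targetSum = NULL) {
  qc <- qcFilter(transcripts, minQV, minTranscriptsPerCell)
  counts <- buildCounts(qc$transcripts, cells = qc$keptCells)
  norm <- normalizeCounts(counts, targetSum = targetSum)
  m <- normValues(norm)
  ids <- rownames(counts)
  areas <- vapply(boundaries(seg)[ids], polygonArea, numeric(1))
  out <- data.frame(method = method, cell_id = ids,
                    area = unname(areas),
                    tpc = unname(Matrix::rowSums(counts)),
                    stringsAsFactors = FALSE)
  for (g in normGenes)
    out[[paste0("norm_", g)]] <-
      if (g %in% colnames(m)) as.numeric(m[, g]) else 0
  out
}
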