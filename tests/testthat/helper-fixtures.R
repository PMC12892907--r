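# Small in-code fixtures shared across test files.

makeTranscripts <- function(x, y, gene, qv = 30, cell_id = "c1",
                            id = sprintf("t%03d", seq_along(x))) {
  data.frame(transcript_id = id, x = x, y = y,
             gene = rep_len(gene, length(x)),
             qv = rep_len(qv, length(x)),
             cell_id = rep_len(cell_id, length(x)),
             stringsAsFactors = FALSE)
}

# one 10x10 cell at the origin with a central 2x2 nucleus
singleCellSeg <- function(provenance = "default") {
  CellSegmentation("c1",
                   list(list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))),
                   list(list(x = c(4, 6, 6, 4), y = c(4, 4, 6, 6))),
                   provenance = provenance)
}

# small, fast synthetic gland for unit tests (full-size glands are used in
# the end-to-end checks)
smallGland <- function(seed = 3, ...) {
  simulateGland(glandParams(semiAxes = c(45, 40), seed = seed, ...))
}
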