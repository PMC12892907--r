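test_that("QC keeps cells at the 10-transcript threshold, applying the QV filter first", {
  mk <- function(n, qv, cell = "c1", offset = 0) {
    makeTranscripts(seq_len(n) + offset, rep(1, n), "KRT5", qv = qv, cell_id = cell,
                    id = sprintf("%s_t%02d", cell, seq_len(n)))
  }
  # exactly 10 transcripts at QV 20: kept
  qc <- qcFilter(mk(10, 20))
  expect_identical(qc$keptCells, "c1")

  # 9 transcripts above QV: excluded, transcripts unassigned
  qc9 <- qcFilter(mk(9, 25))
  expect_length(qc9$keptCells, 0)
  expect_true(all(qc9$transcripts$cell_id == "UNASSIGNED"))

  # 12 transcripts, 3 below QV 20: only 9 countable -> excluded
  tr12 <- mk(12, c(rep(25, 9), rep(19, 3)))
  qc12 <- qcFilter(tr12)
  expect_length(qc12$keptCells, 0)

  # idempotence
  once <- qcFilter(mk(15, 25))
  twice <- qcFilter(once$transcripts)
  expect_identical(twice$transcripts, once$transcripts)
  expect_identical(twice$keptCells, once$keptCells)
})

test_that("count matrix totals equal the number of kept assigned transcripts", {
  empty <- buildCounts(makeTranscripts(numeric(0), numeric(0), character(0)))
  expect_equal(sum(empty), 0)

  five <- buildCounts(makeTranscripts(1:5, 1:5, "KRT5", cell_id = "c1"))
  expect_equal(as.numeric(five["c1", "KRT5"]), 5)

  set.seed(71)
  n <- 500
  tr <- makeTranscripts(runif(n), runif(n),
                        sample(c("A", "B", "C"), n, TRUE),
                        qv = runif(n, 10, 40),
                        cell_id = sample(c(paste0("c", 1:20), "UNASSIGNED"), n, TRUE))
  qc <- qcFilter(tr)
  m <- buildCounts(qc$transcripts)
  expect_equal(sum(m), sum(qc$transcripts$cell_id != "UNASSIGNED"))
})

test_that("normalization scales to the median total and log1p-transforms", {
  m <- Matrix::Matrix(matrix(c(4, 0), 1, 2,
                             dimnames = list("c1", c("g1", "g2"))), sparse = TRUE)
  norm <- normalizeCounts(m)
  expect_equal(as.numeric(normValues(norm)["c1", ]), c(log1p(4), 0))

  # identical cells normalize identically; zero gene column stays zero
  m2 <- Matrix::Matrix(matrix(c(3, 3, 2, 2, 0, 0), 2, 3,
                              dimnames = list(c("a", "b"), c("g1", "g2", "g3"))),
                       sparse = TRUE)
  n2 <- normValues(normalizeCounts(m2))
  expect_equal(as.numeric(n2["a", ]), as.numeric(n2["b", ]))
  expect_true(all(n2[, "g3"] == 0))

  # pre-log scaled totals all equal the median total
  set.seed(72)
  m3 <- Matrix::Matrix(matrix(rpois(60, 5), 10, 6), sparse = TRUE)
  dimnames(m3) <- list(paste0("c", 1:10), paste0("g", 1:6))
  n3 <- normalizeCounts(m3)
  preLog <- Matrix::rowSums(expm1(as.matrix(normValues(n3))))
  expect_equal(unname(preLog), rep(targetSum(n3), 10), tolerance = 1e-12)

  expect_error(normalizeCounts(m3 * 0), "all-zero")
})

test_that("gene-set scores are means over present genes, invariant to order and padding", {
  vals <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0), nrow = 2,
                 dimnames = list(c("hi", "lo"), sebogenesisGenes()))
  norm <- new("NormalizedMatrix", matrix = Matrix::Matrix(vals, sparse = TRUE),
              targetSum = 10, logBase = exp(1))
  sc <- geneSetScore(norm, sebogenesisGenes())
  expect_equal(unname(sc["hi"]), 1)
  expect_equal(unname(sc["lo"]), 0)
  expect_equal(geneSetScore(norm, rev(sebogenesisGenes())), sc)
  expect_warning(scPad <- geneSetScore(norm, c(sebogenesisGenes(), "NOTAGENE")),
                 "absent")
  expect_equal(scPad, sc)
  expect_error(geneSetScore(norm, c("NOPE1", "NOPE2")), "none of the")
})

test_that("sebocytes with elevated lipogenic rates score above basal cells", {
  sim <- smallGland(seed = 9)
  qc <- qcFilter(glandTranscripts(sim))
  counts <- buildCounts(qc$transcripts, cells = qc$keptCells)
  sc <- geneSetScore(normalizeCounts(counts), sebogenesisGenes())
  types <- cellTypes(truthSegmentation(sim))[names(sc)]
  expect_gt(mean(sc[types == "sebocyte"]), mean(sc[types == "basal"]))
})

test_that("expression ratios follow the group-mean-plus-pseudocount definition", {
  vals <- matrix(c(2, 2, 3, 0, 2, 2, 0, 0), nrow = 4,
                 dimnames = list(paste0("c", 1:4), c("FABP5", "CRABP2")))
  norm <- new("NormalizedMatrix", matrix = Matrix::Matrix(vals, sparse = TRUE),
              targetSum = 10, logBase = exp(1))
  # group g1 (c1,c2): equal means -> ratio 1
  # group g2 (c3,c4): CRABP2 zero -> (1.5 + 0.01) / 0.01
  r <- expressionRatio(norm, c("g1", "g1", "g2", "g2"))
  expect_equal(unname(r["g1"]), 1)
  expect_equal(unname(r["g2"]), (1.5 + 0.01) / 0.01)

  # groups holding identical data give identical ratios
  vals2 <- matrix(c(2, 3, 2, 3, 1, 0, 1, 0), nrow = 4,
                  dimnames = list(paste0("d", 1:4), c("FABP5", "CRABP2")))
  norm2 <- new("NormalizedMatrix", matrix = Matrix::Matrix(vals2, sparse = TRUE),
               targetSum = 10, logBase = exp(1))
  r2 <- expressionRatio(norm2, c("u", "u", "v", "v"))
  expect_equal(unname(r2["u"]), unname(r2["v"]))

  expect_warning(expressionRatio(norm, factor(c("a", "a", "a", "a"),
                                              levels = c("a", "b"))),
                 "empty group")
  expect_error(expressionRatio(norm, c("g", "g", "g", "g"), geneA = "NOPE"),
               "not present")
})

test_that("method comparison reproduces an independent ANOVA/Tukey computation", {
  # two identical groups: zero difference, adjusted p = 1
  same <- data.frame(method = rep(c("m1", "m2"), each = 4),
                     cell_id = paste0("c", 1:8),
                     val = rep(c(1, 2, 3, 4), 2))
  cmpSame <- compareMethods(same)
  expect_equal(tukeyTable(cmpSame)$mean_diff, 0)
  expect_equal(tukeyTable(cmpSame)$p_adj, 1, tolerance = 1e-9)

  # textbook 3-group fixture (n = 5 each, distinct means, common spread)
  fix <- data.frame(method = rep(c("A", "B", "C"), each = 5),
                    cell_id = paste0("c", 1:15),
                    val = c(51, 87, 50, 48, 79,
                            82, 91, 92, 80, 52,
                            79, 84, 74, 98, 63))
  cmp <- compareMethods(fix)
  ora <- tukeyOracle(fix$val, fix$method)
  expect_equal(anovaTable(cmp)$F, unname(ora$F), tolerance = 1e-6)
  expect_equal(anovaTable(cmp)$p, unname(ora$p), tolerance = 1e-6)
  tk <- tukeyTable(cmp)
  expect_equal(tk$p_adj[match(ora$pairs, tk$comparison)], unname(ora$p_adj),
               tolerance = 1e-6)

  # strongly separated groups: vanishingly small p-values. ptukey's lower
  # tail bottoms out near 2e-10, so assert 1e-9 on the adjusted p and use
  # the F-test p (computed via pf, accurate much deeper) for the tail bound.
  set.seed(73)
  big <- data.frame(method = rep(c("m1", "m2"), each = 50),
                    cell_id = paste0("c", 1:100),
                    val = c(rnorm(50, 0, 1), rnorm(50, 100, 1)))
  cmpBig <- compareMethods(big)
  expect_lt(tukeyTable(cmpBig)$p_adj, 1e-9)
  expect_lt(anovaTable(cmpBig)$p, 1e-50)

  # zero within-group variance everywhere: F undefined
  flat <- data.frame(method = rep(c("m1", "m2"), each = 3),
                     cell_id = paste0("c", 1:6),
                     val = rep(c(1, 2), each = 3))
  expect_error(compareMethods(flat), "zero within-group variance")
})

test_that("misassignment rate counts wrong-cell assignments into the target type", {
  types <- c(b1 = "basal", b2 = "basal", s1 = "sebocyte")
  # 10 KRT79 transcripts truly from s1
  tr <- makeTranscripts(1:10, 1:10, "KRT79",
                        cell_id = c(rep("s1", 7), "b1", "b2", "b1"),
                        id = sprintf("t%02d", 1:10))
  truth <- stats::setNames(rep("s1", 10), tr$transcript_id)
  expect_equal(misassignmentRate(tr, truth, types, "KRT79"), 0.3)

  perfect <- tr; perfect$cell_id <- "s1"
  expect_equal(misassignmentRate(perfect, truth, types, "KRT79"), 0)

  allWrong <- tr; allWrong$cell_id <- "b1"
  expect_equal(misassignmentRate(allWrong, truth, types, "KRT79"), 1)

  expect_error(misassignmentRate(tr, truth, types, "NOPE"), "absent")
})
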