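# markerseg

Marker-directed cell resegmentation for imaging-based spatial
transcriptomics.

## The problem

Imaging-based spatial transcriptomics assays (Xenium-style) report each
transcript at a sub-micron position and assign it to a cell using boundaries
derived from nuclear staining plus a fixed outward expansion. Thin cells
whose shape is poorly predicted by their nucleus — e.g. the basal
keratinocytes wrapping a sebaceous gland — get boundaries that over-extend
into neighboring transcript-dense cells. Downstream this inflates basal cell
area and transcripts-per-cell, contaminates the basal profile with sebocyte
markers (KRT79, AWAT2), and dilutes normalized expression of genuine basal
markers (KRT5).

## The method

Let a segmentation carry boundaries `B_c` and nuclei `N_c`, and let `T` be
the transcript table with positions, gene labels and quality values (QV).

1. **Flag** every cell containing ≥ 3 `KRT5` transcripts with QV ≥ 20
   (three points are the minimum for a convex hull; the threshold cannot be
   set lower).
2. **Refine** each flagged cell's boundary to
   `hull(marker transcripts) ∪ N_c`. Unflagged boundaries are kept
   bit-identically; degenerate hulls are buffered to a thin polygon; a hull
   disjoint from its nucleus is bridged by the joint hull, with a warning in
   the audit table.
3. **Reassign** all transcripts by boundary containment, breaking overlap
   ties by provenance (refined beats default), then distance to the nucleus
   centroid, then cell id — fully deterministic.

Baselines: nuclear expansion by a fixed radius (2/5 µm), with overlap
resolved by nearest nucleus edge. Quantification: QV ≥ 20 and ≥ 10
transcripts/cell QC, sparse cells-by-genes counts, median-total log1p
normalization, a five-gene sebogenesis score (FASN, AWAT1, AWAT2, ACACA,
SREBF1), the FABP5:CRABP2 group-mean ratio, and ANOVA + Tukey HSD across
segmentation methods. A synthetic sebaceous-gland generator with exact
ground truth (and a deliberately corrupted default segmentation,
δ = 4 µm basal over-extension) provides the validation substrate.

## Worked example

```r
library(markerseg)

# a small synthetic gland with corrupted default segmentation
sim <- simulateGland(glandParams(semiAxes = c(45, 40), seed = 1))
obs <- observedSegmentation(sim)
tr  <- glandTranscripts(sim)
obs
#> CellSegmentation with 54 cells
#>   nuclei present: 54
#>   provenance: default (54)
#>   cell types: basal (45), sebocyte (9)

res <- runMarkerResegmentation(obs, tr)
table(auditTable(res)$action)
#>  refined retained
#>       45        9

types <- cellTypes(truthSegmentation(sim))
misassignmentRate(tr, trueAssignment(sim), types, "KRT79")
#> [1] 0.208547
misassignmentRate(assignedTranscripts(res), trueAssignment(sim), types, "KRT79")
#> [1] 0.008605852

# per-cell metrics under a common normalization target, compared by
# ANOVA + Tukey over the basal cells
qc <- qcFilter(tr)
ts <- targetSum(normalizeCounts(buildCounts(qc$transcripts, cells = qc$keptCells)))
mDef <- cellMetrics(obs, tr, "default", targetSum = ts)
mRef <- cellMetrics(refinedSegmentation(res), assignedTranscripts(res),
                    "marker_refined", targetSum = ts)
basal <- names(types)[types == "basal"]
cmp <- compareMethods(rbind(mDef[mDef$cell_id %in% basal, ],
                            mRef[mRef$cell_id %in% basal, ]))
tukeyTable(cmp)[, c("metric", "comparison", "mean_diff", "p_adj")]
#>       metric             comparison   mean_diff        p_adj
#> 1       area marker_refined-default -25.1911432 3.561755e-10
#> 2        tpc marker_refined-default -37.4000000 3.561755e-10
#> 3  norm_KRT5 marker_refined-default   0.1036446 3.992754e-03
#> 4 norm_KRT79 marker_refined-default  -1.0767760 3.561780e-10
```

Refined basal cells are smaller, carry fewer transcripts, lose the KRT79
contamination and gain normalized KRT5 — the directions the method is built
to recover.

## Command line

A thin CLI wraps the same functions (`inst/cli/markerseg`, or call
`markersegCLI()` directly):

```sh
markerseg simulate  --seed 1 --preset healthy --out-dir sim/
markerseg resegment --transcripts sim/transcripts.csv \
                    --boundaries sim/boundaries.geojson --out-dir out/
markerseg baseline  --transcripts sim/transcripts.csv \
                    --boundaries sim/boundaries.geojson --radius 5 --out-dir exp5/
markerseg compare   --metrics metrics.csv --out comparison.tsv
markerseg score     --counts out/counts --genes FASN,AWAT1,AWAT2,ACACA,SREBF1 \
                    --out scores.tsv
```

Every run writes a `run_log.json` with the package version, parameters,
seed and input digests; exit status is 0 on success, 1 on data errors, 2 on
usage errors.

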