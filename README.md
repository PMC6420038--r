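# rupee: purely geometric protein structure search in R

`rupee` searches collections of protein structures by geometry alone — no
sequence clusters, no precomputed pairwise results, no classification
hierarchy. It is aimed at structural bioinformaticians who want fast,
unbiased "what folds like this?" queries over their own structure sets,
and at method developers who need a self-contained, fully tested
implementation of the underlying encoding and indexing machinery.

## The method

1. **Linear encoding.** Each residue's backbone torsions (φ, ψ) and DSSP
   secondary-structure code map to an integer descriptor 1–12 (helix
   torsion regions 1–4, strand 5–7, bend/coil 8–10, turn 11, bridge 12),
   giving a descriptor sequence per structure.
2. **Run-position-encoded shingle bags.** The sequence is shingled into
   overlapping triples, each hashed with the injective base-13 polynomial
   `shash = s1·13² + s2·13 + s3`, and offset by 10⁵ times a pyramidal
   *run position factor* — within a run of l identical descriptors,
   position i (zero-based) contributes `i` if `i < ⌊l/2⌋`, else
   `l − i − 1` — so long and short secondary-structure runs stop
   cross-matching while run boundaries still match. Bag similarity is the
   multiset Jaccard `J(a,b) = Σᵢ min(aᵢ,bᵢ) / Σᵢ max(aᵢ,bᵢ)`.
3. **Min-hash + LSH.** Each bag is summarized by 99 min-hashes split into
   33 bands of 3; one matching band nominates a candidate. At J = 0.60
   the nomination probability `1 − (1 − J³)³³` exceeds 99%.
4. **Two search modes.** *Fast*: rank the top 8000 candidates by the
   LCS-adjusted Jaccard (longest common subsequence of the ordered hash
   sequences over the exact multiset denominator) and return the top
   400. *Top-aligned*: re-rank the 8000 with a reduced-iteration
   TM-score alignment, realign the surviving 400 at full iterations, and
   sort by TM-score or RMSD. TM-scores are normalized by the average
   chain length by default (symmetric); query-length normalization is an
   option.

Everything is implemented in the package, including the iterative
TM-score aligner (threading + secondary-structure seeds, dynamic
programming over `1/(1+(d/d0)²)`, Kabsch superposition refreshes). See
the vignette `vignettes/run-position-encoding.Rmd` for the full model
description, parameter meanings and design choices.

## Worked example

The 16-residue β-turn-β motif encoding `[5,5,…,7,5,11,11,5,…,5]` runs
through every stage of the pipeline:

```r
library(rupee)
motif <- descriptorSequence(c(5,5,5,5,5,5,7,5,11,11,5,5,5,5,5,5), id = "motif")

shash(shinglesOf(motif))
#>  [1]  915  915  915  915  917  941 1259  999 2007 1929  915  915  915  915
runFactors(motif)
#>  [1] 0 1 2 2 1 0 0 0 0 0 0 1 2 2 1 0
formatEncodedHashes(bagOf(motif))
#>  [1] "00915" "10915" "20915" "20915" "10917" "00941" "01259" "00999"
#>  [9] "02007" "01929" "00915" "10915" "20915" "20915"
```

The 14 overlapping shingles hash to 915 (the dominant [5,5,5] strand
shingle), 917, 941, 1259, 999, 2007, 1929; the run factors rise and fall
pyramidally inside the two six-residue strand runs; and each encoded bag
element is `runfactor·10⁵ + shash` (rendered with the factor as leading
digit). A search over toy structures:

```r
plans <- c("H8-C3-E5", "H8-C4-E5", "E6-C3-E6", "H10-E4", "H6-C2-E4-C3-E4",
           "E5-C3-H9", "H12-C3", "E4-C2-E4-C2-E4", "H7-E7", "H9-C2-E6")
recs <- lapply(seq_along(plans), function(i)
  makeStructureRecord(buildToyBackbone(plans[i], seed = i),
                      id = sprintf("s%02d", i)))
idx <- buildIndex(recs)
fastSearch(recs[[1]], idx)[1:3, ]
#>   rank  id jaccardEst jaccardAdj nResidues
#> 1    1 s01  1.0000000  1.0000000        16
#> 2    2 s02  0.9797980  0.9230769        17
#> 3    3 s10  0.6767677  0.6666667        17
```

The query (a helix–coil–strand structure) retrieves itself with adjusted
Jaccard 1.0; the near-identical plan `H8-C4-E5` scores 0.92 — one extra
coil residue shifts a run boundary — and structures with different
architectures fall off quickly. `topAlignedSearch` re-ranks the same
shortlist by alignment:

```r
topAlignedSearch(recs[[1]], idx)[1:3, c("rank","id","jaccardAdj","tmScore","rmsd")]
#>   rank  id jaccardAdj   tmScore         rmsd
#> 1    1 s01  1.0000000 1.0000000 2.722695e-15
#> 2    2 s02  0.9230769 0.6073544 3.558947e+00
#> 3    3 s04  0.3750000 0.6007801 4.159302e+00
```

The self-match aligns at TM-score 1.0 and RMSD 0; note the re-ranking —
`s04` (`H10-E4`) aligns better in space than its bag similarity 0.375
suggests, which is exactly the gap between shingle matching and
structural alignment that top-aligned mode closes.

A thin command-line front end over the same functions lives at
`inst/cli/rupee.R` (`encode`, `index build/add/info`, `search`,
`fixtures make`):

```sh
Rscript inst/cli/rupee.R encode --descriptors 5,5,5,5,5,5,7,5,11,11,5,5,5,5,5,5 --print bag
# {00915,10915,20915,20915,10917,00941,01259,00999,02007,01929,00915,10915,20915,20915}
```

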