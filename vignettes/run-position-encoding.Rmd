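---
title: "Purely geometric protein structure search with run position encoding"
author: "rupee package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purely geometric protein structure search with run position encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rupee)
```

## The problem

Protein structure searches answer the question: given one structure, which
structures in a collection fold the same way? Classical answers either run
pairwise structure alignments against everything (accurate, hours per
query) or lean on precomputed sequence clusters (fast, but biased toward a
classification hierarchy). `rupee` implements a purely geometric middle
road borrowed from near-duplicate document detection: protein backbones
become bags of hashed "shingles" over a torsion-angle alphabet, bags are
compared with multiset Jaccard similarity, and min-hashing with
locality-sensitive hashing (LSH) banding prunes the collection to
candidates before any expensive scoring happens.

## From backbone to descriptor sequence

Every residue contributes a backbone torsion pair (phi, psi) and a DSSP
secondary-structure code. Six of the eight DSSP codes are pooled into
three torsion groups - helices (G/H/I), strands (E), bends and coils
(S/C) - and each group's torsion plane is partitioned into regions. A
residue's descriptor is the region containing its (phi, psi): helix
regions map to descriptors 1-4, strand regions to 5-7, bend/coil regions
to 8-10. Turns (T) and bridges (B) map directly to 11 and 12 regardless
of torsions. Reading descriptors along the chain gives the linear
encoding, e.g. a beta-turn-beta motif:

```{r}
motif <- descriptorSequence(c(5,5,5,5,5,5,7,5,11,11,5,5,5,5,5,5),
                            id = "beta-turn-beta")
descriptors(motif)
```

The region boundaries shipped in `inst/extdata/region_map.json` are a
qualitative default: axis-aligned (phi, psi) boxes around the canonical
right-handed helical, left-handed helical, extended-beta and alpha-like
basins, tried in priority order, with the last box of each group absorbing
everything else. Published numerical boundaries for the torsion-region
partition do not exist, so the default is deliberately a *configuration*
(users can refine the JSON), not a calibration, and the "regions are
disjoint and cover the torus" contract is realized by first-match
priority: the effective regions are disjoint by construction and the
absorbing default guarantees coverage. The one angular subtlety is the
convention: angles live in the half-open interval (-180, 180], with -180
normalized to +180, so the torsion torus has a single seam at phi = 0 and
wrapped boxes (`min > max`) are legal in the configuration.

Residues with undefined torsions - chain termini, and residues adjacent
to a chain break (C-N distance above 2.5 angstroms; the peptide bond is
about 1.33) - are excluded from the encoding. This keeps the descriptor
sequence well defined without inventing angles at gaps.

When no DSSP output file is available, `assignSSHeuristic()` fills codes
from torsion windows alone (runs of at least 4 helical-window residues
become H, runs of at least 2 strand-window residues become E, all else
C). It is documented as an approximation: it never emits G/I/S/T/B and
knows nothing about hydrogen bonds. Supplying real DSSP output via
`readDssp()`/`applyDssp()` is always preferable.

## Shingle bags and run position encoding

The descriptor sequence is shingled into overlapping windows of 3
consecutive descriptors (a length-n sequence yields n-2 shingles), and
each shingle is hashed with the base-13 polynomial

    shash = s1 * 13^2 + s2 * 13 + s3

which is injective over descriptor triples (range 183..2196), so no
information is lost:

```{r}
shash(shinglesOf(motif))
```

Because regular secondary structure dominates real chains, plain shingle
bags let many short strands match a few long strands. Run position
encoding (RPE) restores specificity: within each maximal run of identical
descriptors of length l, the residue at zero-based position i receives the
pyramidal factor `i` if `i < floor(l/2)` and `l - i - 1` otherwise, and a
shingle inherits the factor of its first residue, scaled by 1e5:

```{r}
runFactors(motif)
formatEncodedHashes(bagOf(motif))
```

The factors rise toward the middle of a run and fall symmetrically, so
run *boundaries* still match across structures whose runs differ in
length by one or two, while the interiors of long runs stop matching
short runs wholesale. The encoded value is normatively the integer
`runfactor * 1e5 + shash`; the five-digit rendering above (factor digit
followed by the zero-padded hash) is presentation only, and for runs of
40 or more residues the factor simply occupies more leading digits. An
alternative scheme that computes run factors over runs of identical
*shingle hashes* instead of descriptors is available as
`bagOf(..., shingleRuns = TRUE)`; it is off by default and its exact
semantics are this package's inference, as no reference description of
that variant was available.

Similarity between two bags a and b is the multiset Jaccard similarity

    J(a, b) = sum_i min(a_i, b_i) / sum_i max(a_i, b_i)

over encoded hash counts.

## Min-hashing and LSH banding

Each bag is summarized by 99 min-hashes. The classical result - that two
sets agree at any signature position with probability J - holds for
multisets once duplicates are expanded into (value, occurrence-ordinal)
tokens, which is what `minhashSignature()` does; whether the original
method respected counts is not documented, so the set-semantics variant
is kept available (`multiset = FALSE`) for comparison. The hash family is
99 seeded 64-bit mixing functions (splitmix64 finalizer) with a fixed
integer base seed recorded in every signature and index header;
signatures are only comparable within one seed set, and the index loader
enforces that.

Signatures are cut into 33 bands of 3 min-hashes; each band is mixed
(order-sensitively, band index included) into a single band hash, and a
single matching band anywhere nominates a candidate pair. The probability
of nominating a pair with similarity j is

    1 - (1 - j^3)^33

which exceeds 0.99 at j = 0.60 - the operating threshold the banding is
tuned for - while pairs near j = 0.2 are nominated at about a quarter of
that rate and j = 0.1 pairs almost never. The 33 band probes are
independent, so they can run concurrently; the implementation guarantees
the result equals the sequential union.

## Operating modes

**Fast mode** (`fastSearch`) ranks LSH candidates by estimated Jaccard
(fraction of matching signature positions), keeps the best 8000, then
rescores each retained candidate with the *LCS-adjusted* Jaccard: the
denominator is the exact multiset denominator recomputed from the stored
hash sequences, and the numerator is replaced by the length of the
longest common subsequence of the two ordered encoded hash sequences.
Out-of-order matches therefore stop counting, and the adjusted score
never exceeds the plain multiset Jaccard. The top 400 hits are returned,
sorted by adjusted Jaccard, ties broken by ascending structure id
(everywhere in the package, so output order is deterministic). The LCS
runs over run-position-encoded hashes - the same tokens the bag matching
used.

**Top-aligned mode** (`topAlignedSearch`) re-ranks fast mode's
8000-candidate shortlist by structure alignment: every candidate is
aligned with a reduced number of dynamic-programming rounds, sorted by
the requested criterion (TM-score descending or RMSD ascending), the top
400 are realigned with the full number of rounds, and the 400 results are
returned sorted by the criterion. The caps (8000/400) are configuration
defaults chosen to balance result quality against the cost of pairwise
alignment, not algorithmic constants; both are arguments.

## The built-in TM-score aligner

No TM-score alignment engine exists in the R ecosystem, so the package
implements one. Given two CA traces, seed pairings come from gapless
threading at multiple offsets plus a secondary-structure
string alignment; each seed is refined by alternating (a) a
superposition search that maximizes the TM-score of the current pairing
(Kabsch fits iteratively reseeded on close residue pairs) and (b)
Needleman-Wunsch dynamic programming over the TM-score distance kernel
`1 / (1 + (d_ij/d0)^2)` with gap penalty -0.6 and free end gaps, until
the pairing reaches a fixpoint or the round cap. "Reduced" iterations
mean 2 DP rounds and "full" means 30 (both configurable); in practice
alignments converge in a handful of rounds, and a full realignment never
substantially worsens a reduced-round score - the test suite asserts a
0.02 TM-score tolerance on that.

The TM-score is `(1/L_norm) * sum 1/(1+(d_i/d0)^2)` with
`d0 = max(0.5, 1.24 (L_norm - 15)^(1/3) - 1.8)` (the 0.5 floor covers
short chains). `L_norm` is the **average** of the two chain lengths by
default - a symmetric score, matching the symmetric Jaccard filtering in
front of it - with query-length normalization available as an option
(`normalization = "query"`) since that is what some other searches
report. Under average normalization the implementation aligns the pair
in a canonical, rotation-invariant argument order (longer chain first,
ties broken on the sorted centroid-distance profile), so the score is
symmetric by construction. Reported RMSD is the least-squares RMSD over
the final aligned pairs; a self-alignment scores TM = 1.0, RMSD = 0.0
exactly.

`kabschSuperpose()` exposes the underlying superposition: SVD of the
cross-covariance with a determinant guard, so the rotation is always
proper (mirror images are never "aligned" by reflection), and collinear
configurations are rejected as rank-deficient rather than silently
returning an arbitrary axis.

## Synthetic data: what it emulates and what it does not

The workbench generates two kinds of fixtures, chosen so that every
module is testable without downloading any structure database.

*Descriptor sequences* (`generateDescriptorSet`) are concatenations of
maximal runs: run lengths follow a truncated geometric distribution
(default success probability 0.25, truncation 15 - mean run length about
4, matching the short-run-dominated look of real secondary structure),
and run descriptors follow a frequency profile dominated by the canonical
helix (1) and dominant strand (5) descriptors. Families of related
structures come from `perturbFamily`, which resamples a fixed fraction of
positions uniformly - a crude but monotone model of structural
divergence. These fixtures exercise the exactly-specified part of the
pipeline (shingling, hashing, RPE, Jaccard, min-hash, LSH, search) while
deliberately bypassing the region map, whose boundaries are the one
under-specified ingredient.

*Toy backbones* (`buildToyBackbone`) are ideal-geometry chains built by
natural-extension-reference-frame placement from canonical torsions
(helix -57/-47, strand -120/+135, coil drawn from windows the heuristic
classifies as coil), with `perturbBackbone` adding Gaussian coordinate
noise. They exercise the geometric half: torsion computation round-trips
construction to within 0.5 degrees, and the aligner sees structures with
real helical/strand geometry.

Neither fixture reproduces real proteins: there are no side chains, no
hydrogen-bond-defined secondary structure, no loops with native torsion
statistics, and descriptor frequencies are stylized. Passing tests
therefore demonstrate the correctness of the machinery - encodings,
hashes, probabilistic guarantees, ranking logic, alignment optimization -
not retrieval quality on PDB-scale corpora, which would require the
curated classification databases and third-party services that are out
of scope here.

Generator defaults and RNG: all generators take explicit integer seeds,
use R's `sample()`-based integer path, and restore the caller's RNG
state, so fixtures are bit-reproducible across platforms.

## Numerical and design choices

- **Chain-break cutoff** 2.5 angstroms on the C(i)-N(i+1) distance; no
  published value exists, and anything between the bond length (1.33)
  and twice it behaves identically on real coordinates.
- **Angle convention**: degrees, IUPAC sign, (-180, 180] with -180
  mapped to +180 (one seam at phi = 0). Collinear atom quadruples yield
  an undefined torsion with a warning rather than an arbitrary angle.
- **Alternate locations** resolve by highest occupancy, ties by label
  order, making parsing deterministic.
- **Worked-example reading**: the printed bag listing of the reference
  encoding concatenates two adjacent hashes ("1259999"); evaluating the
  polynomial on the seventh and eighth shingles gives 1259 and 999, so
  the listing is read as those adjacent values. The acceptance tests pin
  the full 14-element listing.
- **Degenerate inputs**: sequences shorter than 3 cannot be shingled
  (error); empty bags have undefined similarity (error); empty-vs-nonempty
  is 0. Queries too short to shingle fail before touching the index.
- **Index persistence** is a single versioned archive (R serialization
  with an explicit header: format tag, version, LSH parameters, seed).
  Loading a truncated file, a foreign format, an unsupported version, or
  - when expectations are supplied - a foreign seed set fails with a
  clear error instead of producing a partial index.
- **Problem sizes in the test suite** were chosen as the package's own
  desk-scale study conditions: a 100-structure coordinate-bearing index
  for self-retrieval/determinism, a 200-structure collection (20 families
  of 10 at 5% mutation) for the brute-force ranking oracle, 10,000
  signature pairs for the banding guarantee and 1,000 for estimator
  calibration.

## Limitations

- The region map is qualitative; descriptor assignments near region
  boundaries will differ from any particular reference deployment, which
  is why all exactness tests enter the pipeline at the descriptor level.
- The heuristic secondary-structure assigner is not DSSP; for faithful
  encodings supply DSSP output files.
- The internal aligner targets the same objective as the standard
  TM-score alignment programs but is an independent implementation;
  absolute TM-scores on arbitrary real proteins may differ in the third
  decimal from other implementations, and only its internal consistency
  (self-alignment, symmetry, noise monotonicity, rigid-motion
  invariance) is asserted.
- mmCIF input, NMR multi-model handling beyond the first model,
  flexible/circular-permutation alignment and containment search are out
  of scope.
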