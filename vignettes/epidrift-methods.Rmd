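---
title: "Methods: histone-state drift calling and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone-state drift calling and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the methods it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the design decisions
taken where the problem was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. From peak calls to modification codes

The pipeline consumes MACS-style peak lists (per condition, mark and
replicate) and a refGene-like gene table, and produces a gene × sample
matrix of two-bit modification codes, written in mark order
H3K4me3–H3K27me3: `(00)` unmodified, `(10)` active, `(01)` repressed,
`(11)` bivalent.

**Consensus.** Per condition and mark, a peak is retained when it is
detected in both replicates, or as a singleton with fold enrichment
strictly above `fe_threshold` (default 5.0). "Detected in both" is not
precisely defined upstream of this package; we adopt the most permissive
reading — ≥ 1 bp overlap between replicate peaks, matched one-to-one by a
greedy maximum-overlap rule (ties: leftmost replicate-1 start, then
leftmost replicate-2 start). For a matched pair, the coordinates of the
*broader* replicate peak are taken (a selection, not a union: the
"maximum breadth taken" convention implies choosing an existing peak;
ties go to the denser peak, then replicate 1), and tag density and fold
enrichment are the pairwise maxima. The rescue inequality is strict
(`> 5.0`, not `≥`), which the tests pin with a boundary case at exactly
5.0. Peaks are never merged across marks or conditions.

**Coding.** A gene's promoter is TSS ± `flank` (default 1000 b,
strand-aware, clipped at the origin); its body is `[start, end)`. Because
the promoter always touches the body at the TSS, their union is one
contiguous interval, and the overlap fraction of a peak is computed
against that union so a peak straddling both is not double counted. The
bit is 1 iff some consensus peak overlaps the union by at least
`min_overlap_frac` of the *peak's* breadth (default 0.05, boundary
inclusive). The 5% could also be read against the gene region; the
grammatical subject of the source convention is the peak, so peak-relative
is the default and `mode = "region"` is offered. Presence is binary — no
dosage. Genes and peaks on chrX/chrY (matched case-insensitively against
chrX/chrY/X/Y) are excluded to avoid sex-specific artifacts. All
coordinates are 0-based half-open throughout.

The upstream description mentions a "three-digit" code while defining only
two marks and elsewhere a 0/1-doublet; the two-mark doublet is what this
package implements (the third digit plausibly refers to the H3pan control,
which is out of scope).

## 2. Drift calling

A transition rule `L: (xy) → (x'y')` over groups A and B labels a gene iff
it shows `(xy)` in **every** A sample and `(x'y')` in **every** B sample —
strict all-sample consistency, no majority voting. Genes matching no rule
are `unclassified`, never force-assigned; a gene matching two rules is a
configuration error and is reported rather than silently resolved. The
standard rule set is: constant a `(10)` and b `(01)` (rules with identical
from/to state over all samples); tissue→organoid c `(10)→(00)`,
d `(00)→(01)`, e `(11)→(01)`, f `(11)→(10)`; long-term-only g `(11)→(10)`
and h `(00)→(10)`. For g/h it is not fully specified upstream whether the
from-state is required in tissue samples as well as short-term organoids;
the default includes tissue (`include_tissue_in_longterm = TRUE`),
toggleable. This combinatorial caller is authoritative for all tests; the
SOM below is the discovery/visualisation route, mirroring the dual use of
explicit state descriptions alongside map clusters.

## 3. Self-organizing map

`train_som()` is a standard batch SOM: per epoch each gene is assigned its
best-matching unit (BMU; Euclidean distance, ties to the lowest unit
index) and each unit's weight becomes the Gaussian-neighborhood-weighted
mean of the data. The radius decays linearly from half the grid diagonal
to 0.5; at radius 0 the update is exactly Lloyd's k-means, which the tests
exploit as a reference limit (against `stats::kmeans`, same initial
centers). Binary code matrices are expanded to two numeric columns per
sample (`.K4`, `.K27`) before training, so a metagene value reads directly
as an average modification level.

Declared defaults (the upstream analysis defers to a package's "default
parametrization", so these are this artifact's own): 30 × 30 grid (tests
use 8 × 8 for speed; grid size is a knob), 20 epochs, initialisation from
sampled data rows (alternatives: uniform-in-range, or deterministic
"linear" init on the first two principal components), 8-neighborhood for
all spot connectivity.

**Quantization error.** `qe[t]` is the mean gene-to-BMU distance *achieved
after* epoch *t*'s update. Measured this way it was non-increasing in every
configuration we tested (all three inits, Gaussian and binary data,
multiple seeds), and the acceptance suite asserts it. The error relative
to the *initial* weights can rise in the first epoch — a wide initial
neighborhood necessarily contracts the map toward the data mean, which can
be a worse quantizer than a well-spread initialisation — so the initial
fit is deliberately not part of the monotonicity claim.

**Spots.** Correlation clusters are connected components of grid-adjacent
units whose metagene profiles correlate at ≥ `threshold` (default 0.9;
identical profiles count as 1 even when constant, otherwise a zero-variance
unit correlates with nothing). Under-expression spots take units whose
mean value over a "low" column group is ≤ the `quantile` quantile across
units while their value over a contrast group is above a *fixed*
`contrast_quantile` (default 0.5); fixing the contrast side makes the spot
monotone in `quantile` (lowering it can only shrink spots). K-means
landscapes use Lloyd's algorithm on metagene weights with seeded center
sampling (centers get ±1e-9 jitter to tolerate duplicate metagenes). The
sample spanning tree is Prim's MST on 1 − Pearson correlation of the
portrait columns; cutting the longest edges yields the unsupervised sample
groups.

## 4. Transcription statistics

RPM divides counts by the column total × 10⁶ (columns conserve 10⁶
exactly); RPKM further divides by gene length/1000. All log transforms use
log₁₀ with a pseudocount of 0.1 RPKM — the upstream analysis logs values
without stating its offset or base, so both are declared package defaults
and are knobs. `Δlog(T)` is the log₁₀ difference of group mean RPKM
(positive = activation in group B). The cluster expression test pools one
observation per gene per group (the gene's mean log expression over the
group's samples) and applies a two-sided Welch t-test; Welch because the
synthetic groups have unequal variances by construction, pooled-per-gene
because box plots of "all genes of the cluster" imply gene-level
observations. Constant input is flagged `degenerate` (statistic 0, p NA)
rather than crashing. The GSZ-score has no printed formula upstream; this
package *defines* it as the standardized mean of per-gene across-sample
z-scores, `GSZ(s) = mean(z_g(s)) · √|set|` — zero-variance genes
contribute z = 0, and the score scales with √|set| by construction.
Over-representation is a one-sided upper-tail hypergeometric test with
Benjamini–Hochberg correction across sets (the correction is not stated
upstream; BH is the field default). "Measured with sufficient reliability"
is operationalized as mean RPKM ≥ 1 across samples (`reliable_genes()`),
configurable.

## 5. The synthetic world

The generator's job is to make every downstream stage testable with
planted ground truth; it emulates the *outputs* of a mapping/peak-calling
workflow, not the reads.

* **Genome.** Non-overlapping genes (lengths U[2, 20] kb) laid along
  autosomes with U[10, 30] kb gaps — wide enough that a promoter-centred
  peak can never touch a neighbouring gene, which is what makes zero-noise
  encoding provably exact. Optionally a fraction (default 0.1) of genes on
  chrX/chrY to exercise the exclusion rule.
* **Conditions.** Three tissue, two short-term and two long-term organoid
  conditions by default, matching the tissue / 3-week / 20-week design
  with paired genotypes.
* **States.** Planted cluster genes follow their canonical trajectories
  exactly. Background genes draw states at random per condition,
  rejection-sampled so that no background gene realises one of the eight
  cluster patterns: planted labels are then *exactly* the rule matches,
  making precision/recall 1.0 a meaningful zero-noise assertion rather
  than a statistical accident.
* **Peaks.** One peak per carrying gene, centred on the promoter (a 10%
  minority on the gene body — promoter and body count identically for
  coding, so promoter-centric emission suffices), breadth U[600, 1600] b,
  fold enrichment log-normal with median 8 and σ = 0.6 — deliberately
  straddling the rescue threshold 5 so singleton peaks exercise the rescue
  rule in both directions. Peak attributes are drawn once per gene and
  shared between replicates; dropout (one uniform draw per gene/replicate
  compared to the probability, hence monotone in it) and edge jitter
  (±50 b) are per replicate. With zero dropout and jitter the replicate
  lists are identical. The breadth and FE distributions are placeholders,
  not estimates of any real dataset.
* **Counts.** Negative-binomial with mean proportional to the planted
  per-condition expression mean, scaled to a 10⁶ library; dispersion 0.1.
  State coupling: mean 100 for `(10)`, 30 for `(11)`, 3 for `(01)` and
  `(00)` — the direction (active high, bivalent intermediate,
  repressed/unmodified low) matches the repression/activation
  observations the state transitions predict, without asserting
  magnitudes.
* **Seeding.** All randomness flows from one root seed through named
  substreams (a small polynomial hash per emitter), so changing one
  emitter's parameters never perturbs another's draws, and every emitter
  is byte-reproducible.

What a green test therefore establishes: the deterministic machinery
(consensus, coding, calling, statistics) is exact, and the stochastic
stages behave correctly *under this noise model* — pure dropout, no false
peaks, no signal-level variation. It does not establish robustness to
mappability artifacts, GC bias, broad-domain K27 topology, replicate
batch effects or peak-caller idiosyncrasies, none of which are simulated.
In particular precision 1.0 under dropout noise is a property of the
noise model (dropout can only destroy evidence), not a general claim.

## 6. Numerical choices and degenerate inputs

* Overlap pairing ties: largest overlap, then leftmost start — verified
  against a brute-force per-base oracle on random instances.
* BMU ties: lowest unit index; k-means landscape `k = #units` returns the
  identity partition directly (duplicate metagenes would otherwise break
  center initialisation).
* Empty inputs: empty peak lists code to 0; an empty cluster average
  returns `NA` with a warning; a gene set fully absent from the matrix is
  an error, partial absence a warning.
* RPM refuses zero-total columns; RPKM refuses missing or non-positive
  lengths.
* The acceptance scenario sizes the planted transition clusters as the
  published clusters (c = 401, d = 102, e = 342, f = 147, g = 86,
  h = 233); the published headline numbers themselves (total cluster
  sizes including a/b at genome scale, overlap percentages, specific
  Δlog(T) values) derive from the deposited mouse data and are not
  reproducible at desk scale, which is why all acceptance checks are
  property-based.

## 7. Known limitations

Single-interval gene models (no per-isoform promoters), binary coding (no
signal strength), strict all-sample transition rules (sensitive to a
single noisy sample — by design, as in the source convention), planar SOM
(no toroidal topology), and a synthetic noise model without false-positive
peaks. The hypergeometric enrichment is a generic stand-in for curated GO
tooling: it tests user-supplied sets only.
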