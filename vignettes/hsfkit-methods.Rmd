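---
title: "hsfkit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hsfkit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsfkit)
```

`hsfkit` analyses plant heat shock transcription factor (Hsf) families:
candidate discovery in a proteome, domain-based classification into classes
A/B/C and phylogeny-anchored subclasses, homeolog-triad detection in
allopolyploid genomes, intron–exon structure, and treatment-response
profiling. This vignette records the models behind each stage, the defaults
and why they were chosen, and what the synthetic-data validation does and
does not demonstrate.

## Candidate screen: an ungapped log-odds profile

The discovery stage scores a proteome against a position-specific scoring
model built from a seed alignment of the Hsf DNA-binding domain (DBD).
Column emissions are smoothed counts,

$$e_j(a) = \frac{c_j(a) + w\,b(a)}{n_j + w},$$

with pseudocount weight $w$ (default 1), uniform background $b$ (overridable
by observed proteome frequencies), and $n_j$ the non-gap residues in
column $j$. Alignment columns at or above 50% gaps are dropped; the
threshold includes the boundary so that a two-row alignment with one gapped
row loses that column, which matches how a majority-rule seed should treat
half-gapped columns. Every ungapped target window is scored
$S = \sum_j \log_2 (e_j(x_j)/b(x_j))$; unknown residues (`X`) contribute 0.

A full profile HMM with insert/delete states is deliberately **not**
implemented. The screen is only a recall filter ahead of strict domain
validation, and the Hsf DBD is compact and well conserved, so an ungapped
scan with calibrated E-values is sufficient and fully deterministic.

Window scores are converted to E-values against a null built from
residue-shuffled decoys drawn from the proteome's own length distribution
(default 200 decoy sequences, seedable). Two tail estimators are available:

* `empirical` — the add-one tail $P = (1 + \#\{S_0 \ge s\})/(n_0 + 1)$,
  exactly as exposed by `estimate_evalue()`. Its resolution is bounded below
  by $1/(n_0+1)$, so at genome scale it cannot certify very small E-values
  without an impractically large null.
* `gumbel` (default in `screen_proteome()`) — a Gumbel (extreme-value)
  right tail fitted to the null scores by the method of moments, the
  standard model for optimal ungapped alignment scores. This extrapolates
  smoothly into the far tail where true Hsf hits live (hundreds of bits
  above the null) while leaving decoys at $E \gg 1$.

The default threshold is $E < 0.001$. On synthetic proteomes the separation
is enormous (planted genes at $E \approx 10^{-16}$, decoys at $E > 10$), so
the choice of threshold is not delicate.

## Domain annotation and the class rule

`detect_dbd()` reports the best window above a score floor expressed as a
fraction of the profile's maximum attainable bitscore (default 0.3 — far
above random-window scores, far below any real DBD). Each
secondary-structure element (α1, β1, β2, α2, α3, β3, β4) is called `full`
when ≥ 80% of its columns score positively, `partial` when some do, and
`absent` when none do; both thresholds are arguments.

`detect_hrab()` finds the oligomerization region C-terminal of the DBD — the
only side of the DBD where the HR-A/B region occurs in the Hsf
architecture. A heptad is accepted when its `a`/`d` positions are
hydrophobic; the hydrophobic set includes alanine (`LIVFMA`) and the
per-heptad acceptance fraction is 0.75 (with two scored positions this
means both), both configurable because no published heptad-calling rule
exists for this family. An array is a maximal run of frame-aligned heptads
(≥ 2); HR-A is the first array, HR-B the next, and the insert is the
residue count strictly between them. A single contiguous array of ≥ 4
heptads is interpreted as the fused class-B arrangement (insert 0), with
the final two heptads reported as HR-B.

Classes follow the canonical insert lengths 21/0/7 (A/B/C), interpolated
into exhaustive bands — B: 0–2, C: 3–13, A: ≥ 14 — so the classifier is
total on the nonnegative integers. Real families vary around the canonical
values, so out-of-band inserts (outside canonical ± 2) are flagged
(`in_band = FALSE`) but never rejected. The retention filter then drops
candidates missing either domain and resolves same-chromosome, same-strand
overlapping gene models by keeping the longest protein (ties broken
lexicographically by ID), reporting every exclusion with its reason.

## Motif scanners and physico-chemical calculators

The C-terminal scanners are *consensus approximations*, not
re-implementations of the scoring-matrix or neural-network predictors used
in the original wheat survey, whose internals are not published:

* **AHA** — core `F W x x [F/L]`; a trailing `[F/I/L]` within three
  residues is reported (`extended`) but not required, because published
  class-A activator peptides (e.g. the A9-type `MHLWF...` entries) violate
  the strict two-part reading.
* **NLS** — monopartite: any 4-residue window with ≥ 3 K/R, overlapping
  windows merged and trimmed to their K/R core; bipartite: a 3-window with
  ≥ 2 K/R, a 6–14 residue spacer, then a 5-window with ≥ 3 K/R.
* **NES** — the leucine-rich consensus Φ-x(1,4)-Φ-x(1,4)-Φ-x(0,2)-Φ with
  Φ ∈ {L,I,V,F,M}; at each start the longest match is taken and matches are
  reported greedily without overlap. One published wheat NES string does
  not fit this consensus (its first inter-Φ gap is 5); the grammar is kept
  as the normative rule rather than widened to fit one string.
* **ER retention** — the C-terminal tetrapeptide is looked up in an
  editable lexicon shipped as plain text (`er_retention_lexicon()`), seeded
  from published wheat entries. No mechanistic rule for these signals is
  published; the lexicon is data, not code.
* **LFGV** — exact search restricted to the C-terminal half, where the
  class-B repressor element resides.

Because these are approximations, genome-wide NES/NLS *counts* are not
meaningful validation targets; the scanners are instead verified
exhaustively against brute-force oracles on random sequences.

Molecular weight uses ExPASy-standard average residue masses plus one
water, reported to two decimals in kDa; `X` residues are excluded with a
warning. The isoelectric point solves the Henderson–Hasselbalch net-charge
equation (termini plus D, E, C, Y, K, R, H; Lehninger pKa table, documented
in the source) by bisection to |charge| < 1e-4 — valid because the charge
function is strictly decreasing in pH.

## Phylogeny and subclass assignment

Distances are computed on the N-terminal region (DBD through HR-B).
Sequences are placed onto the profile columns by their best-scoring window
(`profile_align()`) rather than by de-novo multiple alignment: the region
is strongly conserved, and this keeps the stage deterministic. The distance
is the Poisson-corrected p-distance with pairwise deletion,
$d = -\ln(1-p)$, which errors (rather than guessing) at $p \ge 1$;
saturated pairs indicate the inputs are outside the conserved-region regime
this stage is designed for.

Neighbor joining is implemented directly: the Saitou–Nei Q-criterion with
ties broken by the lowest-index pair (deterministic), negative branch
estimates clamped to zero and counted in an attribute. On additive matrices
the generating tree is recovered exactly (verified against an independent
NJ implementation and by path-length identity). Bootstrap support resamples
alignment columns with replacement (default 1000 replicates, seedable) and
reports, per internal edge, the percentage of replicate trees containing
the same bipartition; taxa are sorted internally so input order cannot
affect results.

Subclass assignment follows three anchored rules: a query adopts the
subclass of its best-identity reference within the smallest enclosing clade
with bootstrap support above 50, provided that identity exceeds a
threshold; queries whose smallest supported clade holds no reference found
a novel subclass (class letter + next unused integer — how a
reference-free class-C clade becomes "C3"); queries with no supported
enclosing clade are flagged `unresolved`. The identity threshold defaults
to 90% but is applied to the N-terminal region and is configurable: across
distant species, > 90% full-length identity is implausible, so the
threshold is best interpreted against the conserved region.

## Genome context

`chromosome_counts()` tallies the 21 wheat chromosomes (1A–7D), reports
unanchored (`U`) genes separately, and sums A+B+D per homeologous group.
Two triad detectors are provided because two kinds of input exist:

* `find_homeolog_groups()` — sequence-based: candidate triples are one gene
  per subgenome on the same group number and subclass, accepted when all
  three pairwise global identities (Needleman–Wunsch, via Biostrings) reach
  the threshold (default 0.90); conflicts resolve greedily by mean
  identity, ties by ID, each gene joining at most one group.
* `triad_tally()` — naming-convention based, for published tables without
  sequences: within a subclass, a window of three consecutive-index genes
  covering subgenomes A, B and D is a triad. Group numbers are deliberately
  ignored here because wheat's ancestral translocations (4A/5A/7B) place
  genuine homeologs on different group numbers.

Gene structure is derived by ordered exact anchoring of cDNA blocks in the
genomic sequence, accepting only GT..AG junctions, with backtracking over
candidate boundaries. This is an exact-match spliced placement matching the
synthetic-data contract, not a Smith–Waterman spliced aligner; inputs that
cannot be reconstructed exactly raise an error rather than producing a
guessed alignment. `intron_in_dbd()` projects the protein DBD span onto the
cDNA (optionally shifted by a 5' UTR offset) and reports junctions strictly
inside it.

## Expression profiling

Display values are `log2(TPM + 1)`. Response calls compare each
organ × treatment cell against that organ's control (replicates averaged
first) using fold change $(t+\varepsilon)/(c+\varepsilon)$ with
$\varepsilon = 0.01$: `up` at FC ≥ 2 with the treated level at or above the
1-TPM expression floor, `down` symmetric, `not_expressed` when both sides
sit below the floor, otherwise `insensitive`. None of the three constants
(fold threshold, floor, ε) are published for this design; 2-fold and 1 TPM
are conventional descriptive choices and all are arguments. Differential
testing with replicates (DESeq2-style) is out of scope — calls are
descriptive categories matching the narrative vocabulary of family surveys.
The 2^−ΔΔCt calculator normalises a target gene to a reference gene and a
calibrator sample; the calibrator evaluates to exactly 1.

## The synthetic generator and what passing means

`generate_family()` assembles each gene as: random N-tail, subclass-flavoured
DBD consensus (six loop-column substitutions keyed to the subclass name, so
subclasses separate in trees without touching element columns), polar
linker, three ideal HR-A heptads, a class-specific polar insert (21/0/7),
two HR-B heptads, and a C-terminal region carrying the planted motifs (NLS
for all; NES for all; AHA only in class A; LFGV only in class B; an ER
tetrapeptide on a configurable fraction, default 0.25). Background
substitutions at the spec rate (default 0.02) avoid motif and heptad-anchor
positions unless `hard_mode` is set; polar segments stay polar so planted
coiled-coil boundaries remain sharp. Decoys are shuffled-composition
sequences with the family's length distribution. The default composition is
the published wheat family: 13 subclasses, 40/16/26 members per class.
`generate_allohexaploid()` triples ancestral genes onto the A/B/D
chromosomes of one homeologous group at a target pairwise identity (default
0.97, divergence rate per copy $(1-\mathrm{id})/2$), leaving a configurable
number of singletons. `generate_gene_models()` back-translates proteins,
plants one GT..AG intron inside the DBD codons for class A/B genes
(C3-designated genes stay intronless) with lengths uniform on 80–5836 bp —
the observed extremes of the wheat family. `generate_expression()` draws
TPM around a class × organ × treatment design (class A induced by
H2O2/heat in leaf, class C by ABA, class B by H2O2/heat/ABA) with
multiplicative log-normal noise; σ = 0 reproduces the design exactly.

The generator emulates the *logical structure* of real data — domain
architecture, insert-based classes, triads, motif placement, splice
junctions, design-driven expression — but not its hard parts: real linkers
contain hydrophobic residues that can blur heptad boundaries, real DBDs
diverge with indels an ungapped profile cannot absorb, real splice sites
need a scoring aligner, and real expression has overdispersion and batch
structure. Passing tests therefore demonstrates correctness of the
algorithms under their stated contracts, not field performance on arbitrary
proteomes.

## Validation, problem sizes and limitations

The test suite checks each operation against an independent oracle:
brute-force window summation for the scanner, anchored-regex enumeration
for the motif scanners (1000 random sequences), construction parameters for
heptad inserts (k = 0–40), additive matrices and an independent NJ
implementation for the tree builder, and the generator's truth tables for
the end-to-end pipeline (an 82-gene family with 100 decoys — recovery must
be exact). Those sizes keep the whole suite under a minute on one CPU while
exercising every code path; `scripts/acceptance.R` re-runs the same
measurements from scratch and also re-derives the published wheat family
statistics (class tallies 40/16/26, length extremes 209–701 aa, chromosome
maxima of 8 on 3B and 5A, group totals 19 and 18, 18 A2 members, 21
complete triads) from the annotation table shipped under `inst/extdata/`.

Known limitations, stated plainly:

* The shipped annotation table carries the *published* per-gene lengths and
  molecular weights; the full 82 protein sequences are not distributed with
  the package, so per-gene MW recomputation from sequence is validated
  against independently derived reference peptides instead.
* The MW/pI values depend on the chosen mass and pKa tables; alternatives
  shift pI by up to ~0.5 units.
* The DBD seed alignment is a synthetic consensus construct (labelled as
  such in its filename); swapping in a curated seed changes absolute
  bitscores but not the pipeline's logic.
* Subclass labels are only as good as the reference set: shipping different
  references renames subclasses.
* Bootstrap replicates error out if a resample saturates the Poisson
  correction (p ≥ 1); this is by design, as it signals input outside the
  conserved-region regime.
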