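---
title: "Deriving a PUF-domain RNA recognition code from selection sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a PUF-domain RNA recognition code from selection sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufcode)
```

## The problem

A PUF (Pumilio homology) domain binds an 8-base RNA site as eight tandem
repeats in antiparallel register: repeat *i* reads base 9 − *i*. Within
each repeat, three residues — positions 12, 13 and 16, the tripartite
recognition motif (TRM) — determine which base is recognized: positions
12 and 16 hydrogen-bond to the Watson–Crick edge while position 13
stacks against the base. Because recognition is modular, substituting
TRMs should reprogram the domain toward arbitrary 8-mers, which makes a
complete per-repeat, per-base TRM code a design resource.

`pufcode` implements the computational side of measuring such a code by
deep mutational scanning: NNK-saturated TRM libraries (one per repeat)
are selected by yeast three-hybrid growth against RNA sites whose
cognate base is varied, sequencing of input and post-selection pools
yields per-variant enrichments, and base-specific variants are distilled
into a code table that drives domain design, oligo-array construction
and binding analysis. Because the raw selection data are not shipped
with the package, a synthetic-data generator reproduces the structure of
the experiment end to end; every downstream stage is exercised against
planted ground truth.

## The selection model

Each (repeat, cognate base) library is one selection culture. The
generator models one round of exponential growth: a variant with
activity $a$ (log2 units) is sampled into the post-selection pool with
weight $f \cdot 2^{a}$, where $f$ is its input frequency. Input and
selected pools are independent multinomial draws of the configured
depth. Writing $Z = \sum_v f_v 2^{a_v}$ for the library normalizer, the
expected interaction score of variant $v$,

$$S_v = \log_2 \frac{f^{sel}_v}{f^{in}_v},$$

equals $a_v - \log_2 Z$, so *differences* in score estimate differences
in activity exactly. A noise-free mode (`sampling = "expected"`) returns
the fractional expected counts; on such pools the within-library spread
of $S_v - a_v$ is zero to machine precision, the property the
parameter-recovery tests assert at depth $10^6$.

Scores follow the standard enrichment definition: frequencies are
computed within each (repeat, base) library per pool; a variant present
in the input but absent from the selected pool receives a pseudocount of
1 in the selected pool (library totals unchanged); variants absent from
the input are dropped and logged. The specificity score is the gap
between a variant's highest and second-highest per-base scores. A hit
has maximal score strictly above 5 and specificity strictly above 4, the
field's operating point for "highly base-specific". An optional
re-centering subtracts the score of a spiked-in wild-type TRM per
library, putting separate cultures on a common scale.

## What the generator emulates — and what it does not

Ground-truth activities are drawn per missense TRM from three classes:

* **dead** (95%): no binding to any base; activity $N(-5, 1)$ clamped
  at 0. Nonsense TRMs (any stop at 12/13/16) are always dead.
* **broad** (4.5%): comparable binding to all four bases; level
  $N(4, 0.75)$ with per-base jitter (sd 0.3).
* **specific** (0.5%): one preferred base at $N(6.5, 0.75)$, clamped to
  [5, 8]; other bases dead-like.

These proportions were fixed once from two published anchors: hit
counts of order tens per repeat out of 8000 missense TRMs, and a
bimodal missense score distribution with deleterious nonsense variants.
They also keep the normalizer $\log_2 Z$ near zero, so simulated scores
sit approximately on the activity scale and the >5/>4 thresholds bite
where intended. `truth_config()` exposes every knob.

For code-recovery tests, `build_truth_model(planted = ...)` places a
designated TRM in chosen (repeat, base) cells at activity 9 with all
off-base activities fixed at −8. Planted entries therefore *are* the
true per-cell optimum by construction — ground truth must be
well-defined before recovery can be scored — while the cap at 8 on
ordinary specific variants keeps them strictly second.

The simulated reads mirror the published read layout: a 10-nt common
prefix (exact-match filter), an 8-nt repeat tag (exact match at a fixed
offset), then a 16-nt variable region — one RNA-identifier base plus
five codons for residues 12–16. The real libraries encoded the RNA
identity through synonymous codon changes flanking the TRM; that code
was never published, so the layout collapses it to a single identifier
base with a configurable decode map (default A→A, C→C, G→G, T→U).
Emission uses one canonical (lexicographically first) NNK codon per
residue; decoding accepts any codon under the standard genetic code, so
synonymous spellings collapse into one variant at the tally step.
Qualities are a constant Phred "I" and no sequencing-error model is
applied by default (an optional uniform substitution rate exists to
exercise the filters).

The generator does **not** model 3-AT stringency, colony growth
dynamics, plasmid copy number, transformation bottlenecks, PCR jackpots
or position-dependent sequencing error. Passing tests therefore
demonstrate that the analysis recovers what this selection model plants,
not that the model captures every noise source of the real assay.

A note on replicate concordance: the package's replicate-correlation
property is measured on targeted-screen-sized libraries (a few hundred
variants at depth $10^6$, matching the assay's per-variant coverage of
roughly 0.1% frequency). On a full 9261-variant library at the same
depth, dead variants draw only a handful of selected reads and the
correlation becomes depth-limited (≈0.89) — an honest property of
counting noise, not of the scoring.

## Clustering, logos and the code table

Hits are row-normalized by their maximal score (so profiles, not
magnitudes, are compared) and clustered by average-linkage agglomerative
clustering on Euclidean distances; the linkage and metric are not
dictated by the underlying method and are configurable. The tree is cut
at the smallest cluster count at which every cluster is pure in
preferred base, and rows are canonically sorted first so the output is
invariant to input order. Clusters larger than ten members are
subgrouped by the physico-chemical class signature of the
base-contacting residues 12 and 16 (classes: positive {K,R,H}, negative
{D,E}, aromatic {F,W,Y}, polar-neutral {S,T,N,Q,C,G}, hydrophobic
{A,V,L,I,M,P}).

Logos report per-position residue frequencies and information content
$\log_2 20 - H$ bits. No small-sample correction or pseudocount is
applied: hit sets are selections, not samples from a population, so the
frequencies describe the set itself.

The code table assigns each (repeat, base) cell the hit with the highest
specificity score, ties broken by higher maximal interaction score, then
lexicographically — a stated operationalization of "best represents the
pattern", a choice that in practice involves curator judgment. Empty cells
render as `"---"`; entries equal to the repeat's wild-type TRM carry a
marker. The packaged `default_code_table()` is explicitly partial: it
contains the base-specific TRMs reported for this domain (QFR, VFQ, THE, TFR, NPG,
SNE, SWD, SGD, PHQ, SRQ, NYQ, NWP, RAN, CFP, IFV) placed at their
reported cells, wild-type motifs elsewhere, and `"---"` where nothing
was reported.

## Design, the oligo array and register shifts

`design_puf()` substitutes, for every position where the target differs
from UGUAAAUA, the code-table TRM of the cognate repeat (9 − position);
uncovered positions are returned as gaps rather than errors. The
1,900-element array comprises 20 wild-type copies, 55 copies of each of
16 targets, and 1,000 sequences drawn position-independently from the
published per-position base probabilities (sampled in the DNA alphabet,
emitted as RNA). The default 16-target panel carries the published
Hamming-distance spectrum (1, 2×2, 3×8, 4×3, 5, 6); only four of its
sequences have reported assignments, so the remainder are labelled
synthetic stand-ins and any 16 targets may be supplied.

Register-shift diagnostics enumerate the 3 (one-base shift) or 9
(two-base shift) frame-neighbour 8-mers at either end. The two-base set
requires a mismatch at *both* of the last two positions — the only
reading consistent with the published count of nine (3 × 3).
`evaluate_selection()` removes flagged artifact sequences (default
UCCGACUA, a sequence enriched independently of the TRMs substituted),
ranks the rest by mean replicate score, and flags rank-discordant
replicates without changing the mean-based ranking.

## Binding isotherms

`fit_kd()` fits the single-site hyperbola $\theta(P) = P/(P + K_d)$ by
nonlinear least squares. Titrations must span the half-maximal point,
or $K_d$ is unidentifiable and the fit refuses with advice to extend
the range. The 95% interval is a seeded case-resampling bootstrap
formed on $\log K_d$ (the parameter is positive and multiplicative;
working on the log scale also makes the interval equivariant under
concentration rescaling). The default interval is the *symmetric
studentized* (bootstrap-t) one: in calibration simulations at the
package's reference conditions (8-point two-fold titration from 1 µM,
true $K_d$ 80 nM, Gaussian noise sd 0.05, 500–1000 replications),
percentile, basic and normal intervals covered at 89–91% — the usual
small-sample shortfall of unstudentized resampling — while the
symmetric bootstrap-t held 94–95%. Percentile, basic and normal
intervals remain available; with 8 or more points the asymptotic Wald
interval is reported alongside. No Hill coefficient is fitted: the
underlying assay was analyzed with the plain half-maximal model.

## Numerical choices and degenerate inputs

* Ties in specificity are exact score ties and yield 0; ties in
  code-table ranking fall through max score to lexicographic order, so
  derivations are deterministic.
* Row normalization is undefined for all-zero rows and errors; negative
  entries pass through the division verbatim.
* Reads with ambiguity codes (N) are discarded (`invalid_char`), never
  imputed; all filters are exact-match with no mismatch tolerance.
* Every stochastic step takes an explicit integer seed and restores the
  caller's RNG state; reruns of `run_pipeline()` with one config are
  bit-identical.
* Duplicate repeat tags or a non-bijective base code fail at layout
  construction, not at decode time.

## Problem sizes

The shipped tests and scripts run the full 8-repeat screen at depth
$10^6$ per pool (multinomial or expected counts), route $10^4$–$10^5$
reads through FASTQ emission/decoding, and use 500 simulations × 400
resamples for the coverage study — sizes chosen so the whole suite
completes in a few minutes on one CPU while leaving every statistical
check well-powered.

## Known limitations

* The identifier-base layout is a stand-in for the unpublished
  synonymous-change code; decoding reads from a real screen
  would need the true map and tag sequences supplied via
  `read_layout()`.
* The packaged code table and target panel are partial reconstructions
  from reported motifs and targets, not a complete reference set.
* Scores carry no variance model or shrinkage; low-coverage variants
  are flagged (`low_input`), not corrected.
* The wild-type TRM table is assembled from natural recognition codes
  and is configurable rather than authoritative.
```{r}
sessionInfo()
```
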