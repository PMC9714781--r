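---
title: "Identifying small plasma-cell clones from single-cell transcriptomes"
author: "clonetracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying small plasma-cell clones from single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetracer)
```

## The problem

POEMS syndrome is a rare monoclonal plasma-cell disorder. Unlike multiple
myeloma (MM), where the malignant clone dominates the marrow plasma-cell
compartment, the pathogenic clone in POEMS is small — often a few percent of
plasma cells — which makes it invisible to bulk sequencing and hard to sort.
Full-length single-cell RNA-seq offers a way in: plasma cells transcribe
their immunoglobulin genes at enormous levels, so each cell's rearranged
heavy- and light-chain sequences can be reconstructed directly from its
transcriptome. Cells sharing the same V-J rearrangement and the same
CDR3/junction sequence are, by definition, one clone.

`clonetracer` implements that analysis as a tested pipeline:

1. **Repertoire reconstruction** — per-cell local alignment of transcripts
   against gapped germline V and J references, CDR3/junction extraction
   between the conserved anchors, and projection onto IMGT unique numbering.
2. **Clonotype calling** — exact-key grouping on
   `(V call, J call, junction nucleotide sequence)`, clone flags, clone
   fractions, and concordance between single-cell clone fractions and bulk
   repertoire read frequencies.
3. **Signature analysis** — germline amino-acid substitution calling on IMGT
   coordinates, and a disease-specific lambda light-chain rule (below).
4. **Expression profiling** — median-of-ratios normalisation, a
   negative-binomial Wald test, top-k DE pooling with K-means, pre-ranked
   GSEA, marker phenotyping, and an in-silico analog of the
   CD138+CD19-HLA-DR-/lo sorting gate.
5. **Synthetic cohorts** — a fully seeded generator that plants a clone at a
   configurable fraction, with known substitutions, sequencing error, bulk
   reads and marker-gene expression shifts, so every stage can be scored
   against ground truth.

## The light-chain signature

POEMS clones are strongly restricted in their light-chain repertoire: the
clonal lambda V genes come from the IGLV1-36/-40/-44/-47 families, always
rearranged to IGLJ3\*02, and carry recurrent amino-acid replacements at IMGT
positions 38 (CDR1) and 40 (FR2). The replacement at position 40 is
invariably asparagine; position 38 changes to varying residues that are
always nonpolar (observed G, P, A). `classify_poems_signature()` encodes
this as four evidence flags:

* `v_family_ok` — V gene in {IGLV1-36, IGLV1-40, IGLV1-44, IGLV1-47}
  (allele-agnostic, since the restriction is reported at gene level);
* `j_ok` — J allele exactly IGLJ3\*02;
* `pos40_asn` — position 40 substituted to N;
* `pos38_nonpolar` — position 38 substituted to one of
  {G, A, V, L, I, P, F, M, W}.

The default `strict` mode requires all four. Because the minimal rule is not
settled — every reported clone shows both changes, but one could imagine a
clone presenting only one — an `either` mode accepts either position change
together with the V/J restriction. The nonpolar set is the standard
hydrophobic nine; all observed position-38 mutants belong to it.

The signature matters beyond classification: a *single* cell carrying the
full signature is strong evidence of a clone even though it fails any count
threshold. `rescue_singletons()` promotes signature-positive singleton
clonotypes to putative clones at fraction `1/n`, mirroring the situation
where one signature-bearing cell among 59 plasma cells (~1.7%) flags a
clone later confirmed at ~2% by bulk sequencing.

## Reconstruction details and numerical choices

**Alignment.** Transcripts are aligned to every ungapped germline segment
with a Smith–Waterman–Gotoh local aligner (Rcpp): match +2, mismatch −2, and
a gap of length L costs 6 + L (open −6, extend −1 per base). Ties in the
traceback prefer the diagonal, keeping mismatches as substitutions rather
than paired indels. Hits are ranked by score with lexicographic tie-break on
allele name; a call requires 80% identity (configurable) — below that the
transcript is *unassigned*, a value, not an error. V search needs ≥ 50 nt,
J search ≥ 15 nt. The test suite holds the aligner to exact score equality
with an independent plain-R dynamic-programming oracle.

**IMGT numbering.** Germline V references are stored gapped; the IMGT
position of any codon is recovered by counting codons along the gapped
sequence. Each transcript codon inherits the position of the germline codon
it aligns to. Insertions relative to germline are excluded; deletions and
uncovered codons leave positions absent; codons broken by an indel are
skipped. Self-alignment of a germline sequence reproduces its own template
exactly, and the operation is idempotent.

**CDR3/junction.** The CDR3 spans the codons strictly between the conserved
V Cys-104 and J Phe-118 (IMGT 105–117); the *junction* includes both
anchors. Clonotype identity uses the junction *nucleotide* string — the
strictest equality, immune to convergent amino-acid collisions. A chain is
productive when the CDR3 is in frame, position 104 is Cys, and the junction
translation carries no stop. Adjacent anchors (empty CDR3) are legal but
flagged for review; a frameshift flags the chain non-productive.

**Multi-transcript cells and doublets.** Per locus the transcript with the
highest V score wins (ties: longer transcript, then id). A cell showing two
distinct productive light-chain junctions is flagged a suspected doublet and
excluded from clone-fraction denominators — the conservative choice.

**Coordinates.** 0-based half-open internally (alignment intervals); IMGT
positions are 1-based by definition.

## Clonotype grouping choices

Grouping defaults to light-chain-only keys (`require_both_chains = FALSE`):
the clone definition names both IGL and IGH, but the light chain carries the
disease signature and the bulk validation is light-chain based, so requiring
IGH would discard usable cells. In strict mode the heavy-chain triple must
match too and cells lacking IGH are excluded. `min_cells = 2` is the default
clone threshold; a count of 1 is degenerate (every cell a "clone") and
warns. Fractions are computed over non-doublet annotated cells.

## Expression model choices

**Normalisation** is median-of-ratios: size factor = median over reference
genes of count/geometric-mean, reference genes being those nonzero in every
cell. Sparse single-cell matrices often have *no* such gene, so the
estimator falls back to genes nonzero in ≥ 90% of cells, with geometric
means and medians over positive counts only. Factors are rescaled to
geometric mean 1; scaling one sample by c scales its factor relative to
every other sample exactly by c.

**Differential expression** is a deliberately simple, fully specified
negative-binomial Wald test, not a reimplementation of shrinkage-based
estimators: per gene, group means of normalised counts are compared on the
log2 scale with a method-of-moments variance (sample variance floored at the
mean, i.e. dispersion `max(0, (var − mu)/mu²)`), a t reference with
`n1 + n2 − 2` degrees of freedom, and Benjamini–Hochberg adjustment. Genes
with zero counts in both groups are excluded. On 2000-gene null simulations
the raw p < 0.05 rate sits within Monte-Carlo error of 5% and BH at 0.05
yields no rejections in the vast majority of seeds. The cutoff conventions
follow the analysis the package reproduces: DE genes at raw p < 0.01, the
top 30 up- and downregulated genes per contrast pooled across contrasts
(duplicates collapse, so the pool is smaller than 6k), K-means on
gene-standardised log2 values of the pooled panel. A stricter pass (e.g.
q < 10⁻⁴) is the same test with a different cutoff.

**GSEA** is pre-ranked with the weighted Kolmogorov–Smirnov running sum
(weight exponent 1 on |score|). The null is *gene-set permutation* — random
sets of equal size — rather than phenotype permutation, matching pre-ranked
usage and the small group sizes of single-cell contrasts. NES divides the ES
by the mean |permuted ES| of matching sign; the FDR q compares each NES with
the pooled sign-matched permuted NES distribution relative to the observed
NES distribution. Genes with no reads in both groups are excluded before
ranking (`make_ranking()`). A set equal to the whole ranking carries no
information and is defined to ES 0.

**Marker phenotype and gating.** Displayed values are `log2(normalized + 1)`
throughout. Group flags (CD19-negative, HLA-DR-low, CD38-low, MYC-low,
CCND1-low) compare group means with the control mean minus a margin
(default 1 log2). The in-silico gate is the expression-space analog of
sorting CD138+ plasma cells that are CD19- and HLA-DR-/lo: cells below
thresholds on both CD19 and HLA-DRA are gated, thresholds defaulting to the
reference-group mean − 2 SD in log2 space (flow gates do not translate into
expression cutoffs, so the reference distribution defines them). The gate is
scored by purity and recall against truth or clonotype labels.

## What the synthetic cohorts emulate — and what they do not

The generator's defaults describe the regime the pipeline targets: clones
planted at fractions spanning roughly 2–33% of plasma cells (the small-clone
disease range; MM-like cohorts use 96–100%), the position 38/40 signature on
an IGLV1-44/IGLJ3\*02 rearrangement, CDR3s of 12 residues, per-base
substitution error 0.001, negative-binomial counts (dispersion 0.3,
log-normal library sizes with sdlog 0.3 — enough spread to exercise the
size-factor estimator), and clone marker shifts of CD19 −5, HLA-DRA/B1 −4,
CD38 −1.5, MYC/CCND1 −1 log2 — the CD19-negative, MHC-II-low, low-to-normal
MYC/CCND1 clone phenotype. Bulk repertoire libraries draw reads uniformly
across cells (3'-anchored 200 nt windows covering the junction), so the
expected clonal read fraction equals the planted fraction. Per-cell read
depth and error characteristics of full-length single-cell libraries are not
published for this setting; the error rate and read length are free
parameters chosen once at realistic values.

Germline references are *synthetic scaffolds*: random sequences wearing real
allele names, a shared IMGT gap layout, conserved Cys-23/Trp-41/Cys-104 and
the family-specific position 38/40 residues. Only names and anchor structure
follow the IMGT convention — no licensed database entries ship with the
package, and none are needed by the algorithms.

Deliberate non-realisms: no somatic hypermutation model (nonclone cells are
unmutated germline recombinants), no D segment or N-region model for heavy
chains beyond a random insert, no UMI/droplet chemistry, doublets only as a
config flag that merges two cells' chains, and independent NB genes with no
correlation structure. Passing tests therefore demonstrate correctness of
the algorithms under a clean generative model, not robustness to every
artifact of real libraries; in particular, real hypermutated repertoires
would stress the 80% identity floor and the exact-key clonotype definition
in ways the simulation does not.

CDR3 collisions between independent nonclone cells are possible in principle
but vanishingly rare at 12 residues; ground truth is defined by planted
labels, not sequence identity, so a collision would surface as a (correct)
merged clonotype scored against labels.

## Problem sizes used by the test suite

The shipped checks run at desk scale, chosen to give stable statistics:
clonotype grouping versus a brute-force transitive-closure oracle on 50
random cohorts of up to 50 cells; clone-fraction recovery on 100 seeded
cohorts over fractions {0.02, 0.1, 0.2, 0.33} × sizes {60, 100, 200}, scored
against the exact binomial 95% CI of the planted count; single-cell/bulk
concordance over 8 cohorts at bulk depth 10⁴; signature sensitivity on all
four families at zero error and specificity on 20 null cohorts of 500 cells;
junction recovery on 200-cell cohorts at 0 and 0.5% error (the oracle being
the junction of the transcript *as sequenced* — substitution errors do not
move coordinates); DE calibration on 2000-gene nulls over 20 seeds; gating
at the default marker shifts plus a monotonicity sweep over effect sizes
{0, −1, −2, −4} with a widened (1 SD) gate for stable purity estimates.
Light-chain-only simulation is used where heavy chains play no role in the
quantity under test.

## Known limitations

* The aligner is exact (no banding or seeding); it is fast enough for
  cohorts of hundreds of cells and deduplicated bulk libraries, but a
  million-read repertoire would want a seeded aligner in front.
* The DE test is asymptotic; with fewer than ~10 cells per group its
  calibration degrades and a count-based exact test would serve better.
* Signature calling requires coverage of positions 38–40; chains truncated
  before FR2 return a coverage warning, never a silent negative-by-absence
  (the flags are false, the warning says why).
* The FDR q of the GSEA follows the classic pooled-permutation recipe and
  is meaningful only across a collection of sets, not for a single set.
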