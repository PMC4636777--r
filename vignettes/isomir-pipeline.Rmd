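---
title: "Methods: small RNA-seq preprocessing, isomiR classification and differential expression"
author: "isomiRpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA-seq preprocessing, isomiR classification and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRpipe)
```

# Scope and model

Deep sequencing of small RNA libraries shows that most miRNA loci express
not one mature sequence but a population of length variants — isomiRs.
This package implements a complete, testable pipeline for *template*
isomiRs: variants whose sequence is still an exact substring of the
precursor hairpin, so that every 5' or 3' difference from the canonical
mature can be described as an addition (ADD) of flanking hairpin bases or
a deletion (DEL) of terminal mature bases. Non-template events
(untemplated 3' tailing, editing) are deliberately out of scope: they
require a different evidence model and cannot be read off the precursor.

The pipeline covers:

1. read cleaning (per-base Phred gate, 3' adapter trimming,
   length/ambiguity filter) and collapsing to unique tags;
2. exact-match annotation against a miRBase-style mature + hairpin
   reference and offset-based isomiR classification;
3. seed extraction (positions 2–8) and seed-family aggregation of
   normalized counts;
4. expression filtering, TMM normalization, two-group negative-binomial
   exact tests with Benjamini–Hochberg correction, and Venn set
   comparisons of DE lists;
5. Pearson-distance hierarchical clustering and a from-scratch
   Self-Organizing Tree Algorithm (SOTA) for expression profiles;
6. canonical seed-match scanning of 3'UTRs (6mer / 7mer-A1 / 7mer-m8 /
   8mer) to compare the target repertoires of a canonical miRNA and its
   5' isomiR;
7. a ground-truthed synthetic-data generator used by the test suite to
   validate every stage end to end.

Sequences are held internally in the DNA alphabet (U → T on input,
because FASTQ is DNA-alphabet); RNA rendering (T → U) happens only in
user-facing strings such as display names, modification bases and seeds.
All coordinates are 0-based, half-open, which keeps the offset arithmetic
of the classifier free of fence-post cases.

# Read cleaning

`preprocess_params()` bundles the thresholds:

* **Quality gate** — a read is kept only if *every* base quality is
  strictly greater than `min_phred = 20`. The strict inequality is the
  documented contract; `strict = FALSE` switches to `>=` for users who
  prefer the more common convention. An empty read is discarded.
* **Adapter trimming** — the trimmer scans alignment offsets left to
  right and accepts the leftmost position where an adapter prefix of at
  least `min_adapter_overlap = 8` bases aligns with a mismatch rate of at
  most `max_adapter_mismatch_rate = 0.1`; near the 3' end the prefix may
  be shortened down to the minimum overlap. Reads with no qualifying
  match are discarded: for a 3'-ligated small RNA library a missing
  adapter means the insert boundary is unknown. These are conventional
  small-RNA trimming defaults; no published algorithm is prescribed for
  this step, so the policy is fully parameterized and checked in the test
  suite against a brute-force scan over all offsets.
* **Length/ambiguity filter** — inserts shorter than `min_len = 17` nt or
  containing anything outside A/C/G/T are removed. No *upper* length cap
  is imposed: the 17–31 nt range seen in real libraries is an
  observation, not a rule.
* **Collapsing** — identical inserts across all samples become one unique
  tag with per-sample counts, ordered by decreasing total count (ties by
  sequence) and labelled `tag1`, `tag2`, .... Collapsing conserves
  per-sample read counts exactly, and the chain's tallies (raw ≥
  pass_quality ≥ adapter_found ≥ valid) are monotone by construction;
  both properties are asserted as invariants in the tests.

5' adapter handling is not implemented: with the assumed chemistry reads
are insert-first. Other chemistries should be trimmed upstream.

# Annotation cascade and isomiR classification

`annotate_tag()` applies a strict exact-match cascade — there is no
alignment, mismatch tolerance or partial identity anywhere:

1. exact equality with a primary-species mature ⇒ **canonical**;
2. exact full-length occurrence inside a primary-species hairpin at an
   interval overlapping a recorded mature locus ⇒ **template isomiR** of
   that mature;
3. exact equality with an other-species mature ⇒ **mammalian_canonical**
   (identified, but excluded from isomiR statistics, which require
   precursor context in the study species);
4. otherwise **unannotated**.

If step 2 finds qualifying loci of more than one *distinct* mature name
the tag is **ambiguous** and excluded from isomiR statistics; multiple
loci of the *same* mature (multi-copy miRNAs) are not ambiguous, and the
locus with the smallest total end offset is used. An optional *rescue
pass* (`rescue_mature_fasta`) re-tests unannotated tags against a newer
mature catalogue, mirroring the common situation where isomiRs lack a
canonical partner until the reference is updated.

`classify_offsets()` turns interval differences into end calls: with
`d5 = tag_start − mature_start`, a positive `d5` is a 5' DEL and a
negative one a 5' ADD; with `d3 = tag_end − mature_end`, positive is a 3'
ADD and negative a 3' DEL. The affected bases are read off the hairpin,
so the template property — re-extracting the hairpin at the tag interval
reproduces the tag — holds by construction and is verified exhaustively
on toy hairpins in the tests. Display names follow the field convention:
`miR-191-5p DEL G` for a 3' deletion, `miR-140-3p 5' DEL U` for a 5'
one, the 5' clause first when both ends are modified.

Modification sizes are reported in the 1–6 nt range; larger offsets are
still classified but tallied in a `">6"` bin. The summary percentages by
site (3'-only / 5'-only / both) are computed over the isomiR set with
canonical sequences excluded; ADD/DEL percentages are per end, over the
modifications present at that end.

The **seed** is fixed at the 7-mer in positions 2–8 of the tag. The
target-recognition literature allows 6–8 nt definitions; the 7-mer is
what seed-family aggregation and the Fig-style family tables need, and
making it configurable would silently change family membership, so it is
not a parameter. `build_seed_families()` groups tags by identical seed
and sums normalized counts per sample; mass conservation over families is
a tested invariant.

# Expression filtering and differential expression

`expression_filter()` keeps a tag iff in at least one group the number of
samples with ≥ `min_reads = 10` reads reaches the group requirement —
`min_samples = 4` by default, overridable per group (e.g. `c(CD12 = 3)`
when one library of a group failed QC). A requirement exceeding the group
size is a configuration error, not a silent pass.

**TMM normalization** is implemented in-package: tag-wise log2 ratios (M)
against a reference sample are trimmed two-sided (30% on M, 5% on average
log intensity A), averaged with inverse delta-method variance weights,
and exponentiated; factors are rescaled to geometric mean 1; the
reference is the sample whose upper-quartile count fraction is closest to
the mean. Normalized counts are CPM after factor adjustment. The test
suite cross-checks the factors against edgeR's implementation on
negative-binomial data (agreement to ~1e-6) — the cross-check is a test,
not the implementation.

**Dispersion** is a pooled method-of-moments estimate: within each group
with ≥ 2 replicates, per-tag `max(0, (s² − m)/m²)` on normalized counts,
averaged over tags and groups. This is simpler than conditional
maximum likelihood, easy to validate by simulation (recovering planted
dispersions within 25% at realistic depth), and adequate for a common
dispersion; the `phi` argument of the test functions is the pluggable
interface for anything better.

**The exact test** conditions on the per-tag total after equalizing
library sizes (counts scaled to the geometric mean of the effective
library sizes and rounded). Under the null the total splits between the
groups in proportion to their sample numbers; each group sum is a sum of
independent NB variables with the common dispersion, which is again NB,
and with `phi = 0` the conditional law is exactly binomial. The
two-sided p-value sums the probabilities of all splits at most as
probable as the observed one (the "small-p" convention). A zero-count
tag gets `p = 1` and `log2fc = 0`. The fold change is
`log2((meanB + ε)/(meanA + ε))` on the CPM scale with ε equal to half a
count at that scale, keeping fold changes finite on zeros.

**Multiple testing** uses an in-package Benjamini–Hochberg step-up,
checked against both the textbook definition and `stats::p.adjust`.
Significance uses the standard operating point |log2FC| ≥ 1 and
FDR < 0.05; "p < 0.05 BH-corrected" is read as a threshold on the
*adjusted* values. Day-course ("ANOVA-like") comparisons are implemented
as all pairwise exact tests within a status with BH over the union of
p-values — the exact multi-group behaviour of the original analysis
software is version-dependent and not reproducible from its description,
so the package owns this simpler, fully specified design. `venn_sets()`
partitions 2–3 DE lists into disjoint regions for the usual overlap
diagrams.

# Clustering

Profiles for clustering are group-mean `log2(CPM + 1)` values,
row-mean-centered (`profile_matrix()`), so that patterns rather than
absolute levels are compared. `pearson_distance()` is `1 − r` (range
0–2); constant rows have no defined correlation and are dropped with a
warning. `hcl_cluster()` wraps average-linkage `stats::hclust` — a
standard step, deliberately not re-invented — and returns the merge list
plus an optional k-cut.

`sota()` is a from-scratch Self-Organizing Tree Algorithm: a binary tree
of cells starting from a root with two leaves; each growth cycle trains
leaf centroids over up to `max_epochs = 1000` epochs (winner moves toward
the profile at rate 0.01, and when the winner's sibling is a leaf the
parent and sibling follow at 0.005 and 0.001), then the leaf with the
highest *resource* — mean correlation distance of its members to the
centroid — is split into two children seeded at the parent centroid with
a tiny seeded perturbation to break symmetry. Growth stops at the target
leaf count, or earlier when every resource falls below the optional
`variability_threshold`. Whether the original analyses grew to a fixed
cluster count or used a variability cutoff is not documented; the target
count is the default here because it makes results directly comparable
(e.g. "7 clusters"), and the threshold remains available. Distances,
updates and splits are deterministic under `rng_seed`.

# Seed-match target scanning

`scan_sites()` uses the canonical site definitions: the Watson–Crick
match to miRNA positions 2–7 is the 6mer core; a match to position 8
immediately 5' of the site upgrades to 7mer-m8; an A opposite position 1
(immediately 3' of the site) upgrades to 7mer-A1; both give an 8mer —
the efficacy hierarchy 8mer > 7mer-m8 > 7mer-A1 > 6mer. Every core
occurrence (including overlapping ones) is reported once, at its highest
type. Note that a 2–8 seed string equals core6 plus the position-8 base,
so 7mer-m8 and 8mer calls under the two conventions coincide.
`target_set()` thresholds on site type (default 7mer-A1, the weakest type
with reproducible efficacy); `compare_canonical_vs_isomir()` deletes
`shift5` leading bases and reports the Venn regions of the two target
sets. Conservation filtering, context scores and ortholog mapping — the
machinery of database-backed target predictors — are out of scope: target
sets here are pure sequence-match sets on user-provided UTRs.

# The synthetic-data generator

`sim_config()` fixes the study conditions for validation:

* 50 miRNAs by default, one ~22-nt mature per ~80-nt hairpin with ≥ 6 nt
  flanks (so template ADDs up to 6 nt exist), pairwise-distinct seeds;
* modification mix `none 0.30, 3'-only 0.48, 5'-only 0.07, both 0.15` —
  chosen so that among *modified* reads the 3'-only share is ≈ 69%, the
  figure reported for real endometrial libraries; deletion probabilities
  0.66 (3') and 0.71 (5') and a decreasing size distribution with 1-nt
  changes dominant (0.50) mirror the reported ADD/DEL and size spectra.
  These defaults are data-informed choices, not prescribed constants;
* every insert is built from the hairpin, so the template property holds
  by construction; sizes that would leave the hairpin or drop the insert
  below 17 nt are resampled (bounded retries, falling back to the
  unmodified mature);
* the 3' adapter defaults to the common TruSeq-style small-RNA adapter
  sequence as a documented placeholder — real kits vary and the adapter
  is always a required input for real data;
* qualities are truncated-Gaussian per base (mean 36, sd 3, min 2), with
  2% of reads planted with one base ≤ Q20 to exercise the strict gate;
* counts are NB with log-uniform baseline means (20–2000), common
  dispersion, and planted signed log2 fold changes in a designated group.

What the generator does **not** emulate: sequencing substitution errors,
PCR duplication bias, non-template tailing, expression-dependent isomiR
preferences, and multi-mature hairpins. Passing the round-trip tests
therefore shows that the pipeline's logic is correct on clean template
variants — not that it is robust to base-calling errors (which the
exact-match cascade would classify as unannotated, by design).

A point worth noting when interpreting summaries: the generator's
modification mix applies per *read*; at the unique-*tag* level the
both-end category is relatively enriched simply because it has many more
distinct sequences per parent. Recovery tests therefore compare
read-level shares against the configured distribution, and tag-level
labels against per-tag truth.

# Validation scale and limitations

The test suite and the acceptance script validate at desk scale: 10,000
reads from 50 miRNAs for the preprocessing/annotation round trip (the
recovered 3'-only share is compared within three binomial standard
errors); 2,000 tags with 5 samples per group, dispersion 0.05 and
|log2FC| = 2 planted on 10% of tags for DE recovery (sensitivity ≥ 0.8 at
empirical FDR ≤ 0.10 under the |log2FC| ≥ 1, FDR < 0.05 operating
point); exhaustive enumeration oracles for the binomial limit of the
exact test (totals ≤ 50) and for BH; 30 profiles in 3 planted orthogonal
groups for SOTA (adjusted Rand index 1). These sizes are the package's
validation choices and are deliberately small enough to re-run routinely.

Full-scale results from the motivating real-data study — per-library
read-count chains in the millions, the 873 annotated sequences, 223 DE
sequences, fold-change ranges, 7 SOTA clusters on real profiles, or
database-backed target counts — depend on the deposited sequencing
libraries and on external annotation databases, and are not reproducible
from synthetic data; the pipeline exposes every operation needed to
recompute them once those inputs are supplied.

# Numerical choices

* Ties in collapsing break by sequence; ties in SOTA winner selection by
  lowest cell index; HCL inherits `stats::hclust` conventions.
* The exact test compares outcome probabilities with a relative guard of
  1e-12 when summing "as or more extreme" splits, so equal-probability
  outcomes are included regardless of floating-point noise.
* Pearson distances clamp tiny negative values (from `1 − r` round-off)
  to 0.
* TMM returns factor 1 for degenerate pairs (no co-expressed tags, or
  all M-values ≈ 0) rather than NaN.
* `count_table()` validates non-negative integer counts and a complete
  sample-to-group mapping at construction, so downstream code never
  re-checks.
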