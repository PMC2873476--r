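---
title: "Haplotyping and copy-number estimation from deep amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotyping and copy-number estimation from deep amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplihap)
```

## The problem

Some loci of the human genome — the beta-defensin (DEFB) cluster at
chromosome 8p23.1 is the canonical example — exist as a variable number of
near-identical repeat units per genome, commonly 2 to 12 per diploid
genome. A polymorphic position inside such a repeat is a *multisite
variation* (MSV): a sample does not have a diploid genotype there but a
ratio of alleles over all of its repeat copies. Two quantities are of
interest and are usually measured by separate experiments:

* the **haplotypes** present — which allele combinations occur across the
  MSVs of a region; and
* the **copy number** (CN) — how many repeat units the sample carries.

Deep amplicon sequencing gives access to both at once. Every read is a
faithful copy of one physical repeat unit, so the allele combination read
off a single read — its *haplotype call* (HC) — identifies one haplotype,
and the ratios of HC counts estimate the ratios of copy counts. From a few
thousand reads per amplicon both the haplotype inventory and a minimal
copy number can be derived.

`amplihap` implements this workflow: panel definition, read assignment and
HC extraction, artifact filtering, integer-ratio CN fitting with
cross-amplicon harmonization, parsimony merging of direction-limited
partial haplotypes, and a ground-truth read simulator that makes every
stage testable without sequencing data.

## Read assignment and haplotype calls

Reads are assigned by semi-global alignment (`align_read()`): the read
aligns end-to-end against the best window of each amplicon reference, on
both strands, with free end gaps on the reference side. The scoring is
match +1, mismatch −1, gap −2 for the first base and −1 per extension; the
best-scoring combination wins, ties resolved by higher identity, then
lexicographic amplicon id, then the plus strand. Assignments below a
minimum identity (default 0.90) or from reads shorter than 40 b are
rejected. The thresholds are deliberately permissive: pyrosequencing
substitution error rates are well below 1%, so a 10% divergence allowance
rejects only genuinely foreign or junk reads.

At each MSV position of the assigned amplicon the aligned read base is
taken as the allele (`extract_haplotype()`). A read that covers every MSV
of its amplicon yields a *full* call. Amplicons longer than the read
length are covered asymmetrically — forward reads reach one subset of
MSVs, reverse reads another — so the panel declares a forward and a
reverse MSV set, and a read covering exactly (or more than) one of them,
in the matching orientation, yields a *forward-partial* or
*reverse-partial* call. Reads spanning neither declared set are omitted
rather than tabulated: a call over an arbitrary MSV subset would not be
comparable across reads. Alleles are always reported on the plus strand of
the reference, in panel MSV order, which makes the call invariant under
reverse complementation of the read.

One platform artifact gets special handling. Pyrosequencing misjudges
homopolymer run lengths, producing single-base indels inside runs. A read
gap that falls on an MSV inside a reference homopolymer of length ≥ 3 is
treated as a flow undercall when the read carries all but one base of the
run: the gap is realigned away from the MSV and the run base is reported.
Without this rule such reads would either fabricate indel alleles or be
discarded.

## Artifact filtering

PCR on a multicopy template produces chimeric molecules: a partially
extended strand anneals to a different copy and is completed there,
yielding a false recombinant haplotype. Together with polymerase errors
and cross-contamination this creates low-frequency spurious HCs.
`filter_fractions()` removes, within each (sample, amplicon, direction
class) group, every haplotype whose fraction of the group's calls is
*strictly* below a threshold (default 0.10). The logic of the threshold: a
sample with at most `n` copies cannot have a true haplotype below `1/n` of
calls (up to sampling noise), so `0.10` is safe for loci that rarely
exceed 10 copies, and pooling several independent PCRs — which dilutes any
chimera that arose early in one reaction — justifies lowering it (0.06
with `pooled_replicates = TRUE`). Filtering is single-pass on pre-filter
totals and is *not* re-applied iteratively; a second pass on renormalized
fractions could cascade and is not what a fixed `1/n` argument licenses.

## Minimal copy number from call ratios

Observed haplotype frequencies `f` constrain the per-haplotype copy counts
`a` only up to an integer multiple, so the estimable quantity is the
*minimal* CN: the smallest total `n` such that some composition of
positive integers summing to `n` matches `f` within a tolerance
(`minimal_cn()`). Candidate totals are examined in increasing order; for
each, every `a_i` can only take the few integer values inside
`f_i·n ± tol·n`, so an exact bounded search decides feasibility and
returns the smallest-deviation composition. We deliberately implement the
exact search rather than a rounding heuristic: rounding with a
largest-remainder repair almost always agrees but can reject a total near
`max_cn` whose only consistent composition gives a small frequency one
copy, and an exact method costs nothing at these sizes.

Two tolerances are exposed. For count-backed data the default `tol = 0.05`
absorbs sampling noise at realistic depths (at 2,000 calls the standard
error of a frequency is under 0.012). For illustrative ratios quoted
without counts `ratio_minimal_cn()` uses `tol = 0.005`, tight enough that
a ratio of 1.2 resolves to 6:5 (total 11) rather than some looser fit.
`max_cn` defaults to 16 — one more than the reciprocal of the loosest
filter threshold in use (1/16 at 6%), beyond which the filter itself would
have removed the evidence.

Different amplicons of one sample can return different minimal CNs,
because an amplicon whose haplotype classes happen to be equally frequent
reports only the reduced total (a 2:2 sample looks like 1:1).
`harmonize()` reconciles them: a consensus is taken as the median of the
base CNs of estimates with ≥ 3 haplotypes when any exist — three-class
ratios pin the total far more tightly than two-class ones — otherwise of
all estimates, and each estimate is scaled by the integer `k ≥ 1` that
brings `k·base` closest to the consensus (ties prefer the smaller,
more parsimonious `k`). The sample CN is the arithmetic mean of the
harmonized values, rounded half-up (`sample_cn()`); the mean rather than a
least-common-multiple combination because per-amplicon estimates are
noisy measurements of one quantity, not exact constraints.
`compare_external()` sets the result against absolute measurements (MLPA,
paralog-ratio tests), flagging differences of two or more copies as
concordance violations worth individual scrutiny — minimal-CN estimation
can sit at an integer fraction of the truth, and one published sample
genuinely violates cross-method concordance.

All polymorphic amplicon groups are reported, always. The source tables
this package reproduces leave a few polymorphic cells blank without
stating a rule; we prefer an unconditional report over an undocumented
exclusion, and the affected cells are exactly the ones flagged by large
fit deviations.

## Merging directional partial haplotypes

For a split-coverage amplicon the forward and reverse HC frequency vectors
are two marginal views of the same copy composition, linked by the overlap
MSVs both directions cover. `merge_directional()` reconstructs complete
haplotypes as a transportation problem: forward frequencies supply,
reverse frequencies demand, arcs only between pairs whose overlap alleles
agree. The parsimony assumption — no more complete haplotypes than the
data force — is operationalized as **minimum support**: the smallest arc
set in which every directional haplotype has a partner, and among sets of
that size the one transporting the most mass. Each chosen arc becomes a
complete haplotype with its transported mass as frequency.

Frequencies, not raw counts, are matched, because sequencing efficiency
differs systematically between directions (reverse:forward call ratios
around 1.7 are observed on real data); count-based matching would mistake
that skew for compositional information. The residual L1 mismatch between
the margins is reported, and results exceeding a `slack` (default 0.10)
are flagged with a warning rather than rejected. This is a deliberate
choice: treating the slack as a hard feasibility constraint would force
extra arcs into noisy samples — shallow groups can easily show mismatches
of 0.11–0.14 from sampling alone — and every extra arc fabricates a novel
complete haplotype. Strict parsimony with a soft QC flag reproduces the
known haplotype inventory of the locus; the flag still directs attention
to the noisy merges. An orphan directional haplotype (no compatible
partner) is an error, since it indicates inconsistent calling or
over-filtering rather than noise.

The minimum-support search enumerates arc subsets by increasing size with
coverage pruning, computing each subset's maximum flow by deterministic
augmenting paths; it is exact and fast for the handful of haplotypes per
direction that real panels produce, and refuses instances beyond its
enumeration cap rather than approximating silently. Ties are broken by
ranking arcs on descending `min(supply, demand)`, then lexicographic
haplotype strings.

`long_range_join()` extends haplotypes across amplicons: per sample, the
modal (most abundant) haplotype of each amplicon — for split amplicons the
complete haplotype with the highest merge flow — is concatenated in panel
order with `|` separators. This is a deliberately simple construction: it
assumes the most abundant haplotype per amplicon sits on the most abundant
repeat unit, which held for the samples motivating it but is not
guaranteed; ties are reported and flagged rather than resolved.

## The read simulator

`simulate_reads()` generates pyrosequencing-style amplicon reads from a
known copy composition, emulating the study conditions of a flow-based
amplicon run:

* **read length** normal around 225 b (sd 15), clipped to
  `[40, amplicon length]` — the average read length reported for the
  platform; a `truncation_rate` (default 0.05) draws occasional short
  reads uniformly from `[40, 225]`, producing the partial-span reads that
  exercise the omission rule and the split coverage of long amplicons;
* **direction skew**: reads are reverse with probability
  `skew/(1+skew)`; 1.0 by default, 1.7 reproduces the observed skew;
* **substitution errors** per base (default 0.004, the platform's
  approximate accuracy) and **homopolymer indels**: each reference run of
  length ≥ 3 gains or loses one base with a small probability (default
  0.002 per run);
* **chimeras**: with probability `chimera_rate` (default 0.01) the read
  derives from a template switch between its source copy and a *different*
  physical copy, at a breakpoint uniform over the gaps between consecutive
  MSVs — switches between identical bases are invisible, so only
  inter-MSV breakpoints are modelled. With two equal copies differing at
  both MSVs of a two-MSV amplicon and `chimera_rate = 0.02`, each
  recombinant is therefore expected at fraction 0.01 of calls, safely
  below the 0.10 filter;
* constant Q30-equivalent qualities — the caller is quality-agnostic, as
  flowgram qualities are not informative at the per-base level this
  pipeline uses.

Identical configuration and seed give byte-identical output, and a truth
table records each read's source copy, chimera breakpoint, direction and
length.

What the simulator does **not** model: flowgram-level noise, emulsion-PCR
amplification bias between copies, primer artifacts, or
cross-contamination. Passing the round-trip tests therefore demonstrates
the pipeline's correctness under the stated error model, not robustness
to every failure mode of real libraries; the fraction filter is the
defence against the unmodelled ones.

## The bundled panel and tables

The package ships a six-amplicon beta-defensin panel (F2, F4–F8; 26 MSVs
over 1,498 bp, ≈ 17 MSV/kb) whose MSV structure — amplicon membership,
allele sets, and the split forward (MSVs 6–8) / reverse (MSVs 7–10a)
coverage of the 340-bp F5 amplicon — follows the published haplotype
tables, together with the published per-sample HC count tables of eleven
lymphoblastoid cell lines and their external CN measurements. The
reference sequences and MSV offsets are synthetic, deterministically
generated stand-ins (the original primer and coordinate tables are not
redistributed); genomic coordinates are included only for the two MSVs
whose positions are published. Counts are normalized to plain integers
and haplotype strings to uppercase (mixed-case reverse strings in the
sources are display conventions).

## Numerical and testing choices

* Fractions exactly at the filter threshold are retained (strict `<`);
  the boundary case occurs in the bundled data (21/210 = 0.10).
* Averages and external comparisons round half-up.
* Floating-point comparisons in the CN fit use an epsilon of 1e-9 on
  tolerance boundaries.
* Merge flows use an epsilon re-allocation when a support arc ends with
  zero mass in the maximum flow, so every reported haplotype has positive
  frequency.
* The test suite runs at desk scale: oracle-equivalence checks use
  exhaustive dynamic programming on reads ≤ 60 b, exhaustive composition
  enumeration up to totals of 12, and exhaustive arc-subset search on
  instances up to roughly 4×5; simulation-based checks use 250–5,000
  reads per amplicon and the round-trip CN recovery uses 20 random
  compositions at 2,000 noiseless reads each, restricted to compositions
  that are *strongly* minimal (no smaller total fits the exact
  frequencies even at twice the tolerance) so that sampling noise cannot
  legitimately flip the recovered total.

## Known limitations

* Minimal CN is a lower bound by construction; integer multiples of the
  truth are only caught by harmonization or external comparison.
* Samples with a single haplotype everywhere carry no ratio information
  and are reported as indeterminate.
* The merge is exact only at small instance sizes (it errors beyond its
  enumeration cap) and assumes the overlap MSVs discriminate haplotypes;
  directionally invisible distinctions cannot be recovered.
* Long-range joins are modal-haplotype concatenations, not phased
  reconstructions.
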