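---
title: "Detecting differential A-to-I RNA editing with editscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential A-to-I RNA editing with editscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis and its assumptions

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA, and
sequencers read inosine as guanosine. In RNA-seq variant tables an editing
event therefore looks like an A>G mismatch when the edited transcript comes
from the plus strand, and like a T>C mismatch on the reference strand when it
comes from the minus strand. editscan starts from per-library variant tables
(VCF with `DP`/`AD` depths, one library per sequencing run) and works through
five stages:

1. **Candidate selection.** A variant is a candidate editing site only if it
   is strand-consistent with a gene: A>G within (or within a flank of) a
   plus-strand gene, T>C for a minus-strand gene. This single predicate
   removes three quarters of random mismatches and fixes the inferred
   transcript strand of every site. Variants farther than the flank from
   every gene carry no strand information and are discarded.
2. **Confident-site filtering.** A candidate becomes a confident
   ("for-sure") editing site when total depth ≥ 5 reads, edited reads ≥ 3,
   and the editing rate (edited / total reads, an exact quotient) lies in
   [0.05, 0.95], both bounds inclusive. The lower bounds remove isolated
   sequencing errors; the 0.95 cap removes homozygous-variant signals whose
   alternate fraction is ~1 regardless of condition.
3. **Annotation.** Each site gets exactly one gene-region category —
   5' distal (≤ 50 kb upstream, strand-oriented), promoter (≤ 1 kb
   upstream), 5' UTR, exon, intron, 3' UTR, downstream (≤ 1 kb) or 3' distal
   (≤ 50 kb) — and one repeat status: the innermost RepeatMasker element
   containing it (class SINE/LTR/LINE/... and, for SINEs, subfamily
   B1/B2/B4/Other), or non-repeat.
4. **Paired differential calling.** Control (CON) and treated (TM)
   libraries of the *same animal* are compared site by site, which cancels
   germline SNPs by design: a SNP has the same true allele fraction on both
   sides of the pair. A site is `CON_GT_TM` when the rate difference
   Δ = rate(CON) − rate(TM) ≥ 0.05 and the CON side has confident support
   (depth ≥ 5, edited reads ≥ 3, rate ≤ 0.95); `CON_LT_TM` by the mirrored
   TM-focal rule; otherwise `NOT_DIFF`. The partner side is deliberately
   unconstrained so that complete loss of editing (site absent from the TM
   variant table) remains callable; a missing side contributes
   (0 reads, 0 edited, rate 0).
5. **Repeat-region aggregation and consensus.** Confident sites in the same
   repeat element are grouped; an element is a high-editing repeat region
   (`HIGH`) when the CON side has strictly more confident sites *and* a
   strictly higher unweighted mean rate than the TM side, `LOW` for the
   mirror, `NEITHER` otherwise (all ties included). Finally, per-animal site
   and repeat-region calls are intersected across replicate animals; a
   "shared" call requires the same direction in both.

The model is purely threshold-based — no binomial or beta-binomial test, no
multiple-testing correction — because the classification it reimplements is
defined by fixed read-support criteria, not by p-values.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_total_reads` | 5 | reads | minimum evidence that a position is expressed |
| `min_alt_reads` | 3 | reads | ≥ 3 edited reads makes a recurrent-error explanation unlikely |
| `min_rate`, `max_rate` | 0.05, 0.95 | fraction | inclusive rate window; the cap excludes homozygous variants |
| `min_delta` | 0.05 | fraction | smallest rate change called directional |
| `flank_bp` / `distal_bp` | 50 000 | bp | widest annotation window; also bounds candidate search |
| `promoter_bp` | 1 000 | bp | promoter / downstream window |

`flank_bp` is exposed because the candidate universe need not extend beyond
gene bodies in every design; the default keeps the distal annotation
categories reachable. Whether the candidate universe for pairing should use
candidates or confident sites was an open design choice; editscan pairs
*candidates* so that a site confidently edited in CON but weakly covered in
TM is still compared — the focal-support criteria then gate the call.

## What the synthetic generator emulates

`sim_params()` / `simulate_study()` generate, from one seed, a toy genome
(default 4 × 2.5 Mb), ~300 non-overlapping genes with UTR/CDS/intron
structure, ~4 300 repeat elements placed mostly in introns and 3' UTRs
(SINE subfamilies B1/B2/B4/Other at weights 0.45/0.30/0.15/0.10), and per
animal ~16 000 true editing sites (half inside repeats), 800 homozygous and
1 600 heterozygous SNP confounders, and labelled error-prone positions.
Control editing rates are Beta(2, 2); treated rates are `ko_scale` (default
0.2) times the control rate, emulating near-complete enzyme loss. Read
counts are Binomial at truncated-Poisson depths (mean 50), with a symmetric
per-base error rate of 0.001 that also seeds background error records at
non-truth positions, so the filters face realistic contamination. All
randomness flows from the master seed through named substreams
(annotation / per-animal truth / per-library counts), so any stage can be
regenerated independently and identical seeds give byte-identical files.

What it does **not** model: read-level artifacts (mapping bias, splice-aware
coverage, hyper-edited read loss), allele-specific or variable expression,
strand-biased errors, and truly shared polymorphisms between animals.
Passing tests on this generator therefore demonstrate that the *decision
rules* are implemented correctly and recover a knockout-shaped signal under
binomial noise — not that the thresholds are optimal for any particular real
library. Replicate animals share the annotation but redraw site positions,
so cross-animal overlap arises by chance collision within the repeat-rich
gene space, qualitatively emulating partial replicate agreement rather than
reproducing any particular overlap fraction.

## Numerical choices

* **Inclusive boundaries, tolerantly compared.** Rates are exact quotients
  and compare exactly against the printed bounds (19/20 passes ≤ 0.95). The
  rate *difference*, however, is a difference of two rounded quotients, so
  the Δ ≥ 0.05 test uses a tolerance of 1e-9 — far below the smallest
  non-zero |Δ − 0.05| attainable at realistic depths (1/(20·d₁·d₂)), far
  above double rounding error. The test suite checks the classifier against
  an exact integer-arithmetic oracle.
* **Tie-breaks.** Gene assignment prefers a gene whose span contains the
  site, then smallest distance to the span, then lexicographic `gene_id`;
  overlapping repeats resolve to the shortest (innermost) element, then
  lexicographic id. Both make output order-independent and deterministic.
* **Degenerate inputs.** A zero-depth record has no defined rate and is
  never a candidate; an empty side of a repeat-region comparison contributes
  count 0 and mean 0 (complete loss of editing stays representable); empty
  libraries produce header-only tables rather than errors.
* **Genic precedence.** UTR5/UTR3 outrank EXON (UTRs are exonic and would
  otherwise be unreachable); EXON is thereby reserved for CDS-bearing exon
  positions, and any other genic position is INTRON. Upstream/downstream are
  strand-oriented, so the 5' side of a minus-strand gene lies at higher
  genomic coordinates.

## Problem sizes in the checks

The test suite validates the selection + filtering path record-for-record
against a brute-force scan of 10⁴ random variants over a 50-gene model, the
differential classifier on 10⁴ random pairs, repeat-region calls on 10³
random pairs, and consensus counts on repeated random tables. Parameter
recovery runs the full default study (two animals, ~2 × 10⁴ truth sites per
animal, mean depth 50, seed 42): rate estimates at analytically detectable
editing sites must be unbiased within 3 binomial standard errors, recall in
that stratum ≥ 0.95, and the mean SINE editing rate must drop after
knockout in both animals. These sizes give stable proportions while keeping
a full run in the low minutes on one core.

## Known limitations

* **Heterozygous SNPs at moderate depth.** For a het SNP (allele fraction
  0.5 both sides) the paired rate difference has standard deviation
  √(0.5/d); at d = 200 that is exactly the 0.05 calling threshold, so about
  a third of het SNPs receive a spurious directional call, and depths above
  ~1 300 are needed before the threshold dominates the noise at the 1%
  level. Threshold-based calling cannot fix this; the design mitigates it
  through within-animal pairing (hom SNPs are removed by the 0.95 cap) and
  through cross-replicate consensus, which squares the per-animal error
  probability.
* Sites in unannotated territory are unreachable: strand inference is
  gene-anchored.
* The repeat-region mean is unweighted by depth, so a single deep site and a
  single shallow site count equally.
* Annotation is relative to the single assigned gene; a site that is genic
  for one gene and promoter-proximal for a neighbour is reported only under
  its assigned gene.
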