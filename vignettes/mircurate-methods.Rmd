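---
title: "Curation of plant miRNA candidates: methods and design notes"
author: "mircurate developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation of plant miRNA candidates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircurate)
```

## The problem

Small-RNA sequencing of plant tissue yields thousands of read stacks over
candidate hairpin precursors, but only a minority of those stacks reflect
genuine Dicer-processed miRNAs. Community annotation standards (the
Meyers-style criteria and their stricter extensions) turn this into a
rule-based decision: a genuine miRNA leaves a structural signature (a
mature/star duplex with 2-nt 3' overhangs, few mismatches, at most a tiny
asymmetric bulge) and an expression signature (reads concentrated at the
excised duplex ends, consistent 5' termini, support on both arms). This
package implements that decision procedure end to end, from dot-bracket
structures and aligned read stacks to confidence calls, conserved/novel
assignment, isomiR typing, TPM expression tables and
differential-expression flags — with a synthetic-data generator so the whole
chain is testable without any sequencing data.

## The seven rules

High confidence (HC) requires the structural core:

1. the mature and star form a duplex with 2-nt 3' overhangs — or, when no
   star read is observed, the mature is detected in multiple (default >= 2)
   independent libraries;
2. at most 4 mismatches between the mature and the opposite arm;
3. at most one asymmetric bulge, smaller than 2 nt;
4. *precise excision*: more than 75% of all reads on the precursor fall
   inside the (windowed) mature or star intervals. Rule 4 acts as a rescue:
   a candidate violating exactly one of rules 1–3 is still accepted when
   excision is precise. Candidates passing rules 1–3 but not rule 4 remain
   HC with a `low_excision` warning flag (set `require_r4 = TRUE` to make
   rule 4 mandatory); which behaviour matches a given historical dataset is
   not decidable from the criteria alone, so both are supported.

Very high confidence (VHC) additionally requires:

5. at least 10 reads mapping with no mismatches to each arm, anchored at
   the arm's 5' end;
6. at least 50% of each arm's reads sharing the modal 5' end;
7. folding energy below −0.2 kcal/mol/nt.

Boundary semantics follow the printed wording exactly: "at least" is `>=`,
"more than"/"less than" and "<−0.2" are strict. Two ancillary checks are
carried in every report: the 60%-paired-nucleotides criterion (informative
by default, because it belongs to the upstream candidate-discovery stage)
and the <=15-genome-hits filter (a hard candidate filter).

Because a rescued candidate can also satisfy rules 5–7, a rescued candidate
with strong read support is classified VHC; that follows directly from
"VHC = HC and rules 5–7".

### Thresholds and monotonicity

All eleven thresholds live in `mirna_thresholds()` and are echoed into every
report sidecar. The classifier is monotone: relaxing any threshold can never
demote a candidate and tightening can never promote one (this is enforced by
the acceptance suite over all eleven). One consequence worth noting: the
rule-1 overhang check is implemented as `overhang >= min_overhang` rather
than exact equality, because an equality test cannot be monotone in its
threshold; canonical 2-nt-overhang duplexes are unaffected.

## Duplex geometry conventions

Coordinates are 1-based and closed throughout, the R/Bioconductor
convention. The paper-style counting convention for internal loops is: for
each gap between consecutive duplex base pairs with `a` unpaired mature
bases and `b` unpaired opposing bases, `min(a, b)` mismatches are counted
and an asymmetry `|a − b| > 0` is one bulge on the longer arm. The unpaired
terminal overhang bases are excluded from this accounting (they are rule
1's subject). Star coordinates are read off the pair table with the
textbook 2-nt-overhang construction; when the anchor base is unpaired the
nearest paired base toward the duplex interior is used — stepping outward
would walk into the overhang/loop, where no paired base exists.

Both the dot-bracket parser and the duplex walk are verified against
independent reference implementations (an O(n²) partner search, and an
explicit column-wise alignment of the two arms) exhaustively for all
balanced strings up to length 14 and on 1,000 random hairpins.

## Read-stack evidence

A read belongs to an arm when its full span lies in the arm interval
extended 2 nt upstream and 5 nt downstream (the miRDeep2-quantifier
window); reads fitting both arms go to the mature arm. Modal-5' ties break
to the 5'-most start. A library "detects" the miRNA when it contributes at
least one windowed mature read (detection deliberately does not require an
exact read). Rule 6 on an arm with no reads evaluates false rather than
erroring: absence of evidence fails an evidence rule. Rule 4's 75%
denominator pools all libraries (configurable in principle; per-library
evaluation is not implemented).

## Conserved/novel and families

A mature sequence within 2 mismatches of any known mature (miRBase-style
FASTA) is conserved, inheriting the match's family (`ath-miR156a` →
`Jcu-MIR156`). Comparison is ungapped; sequences differing in length by at
most 2 nt slide against each other with overhanging bases counted as
mismatches, equal-length pairs are plain Hamming comparisons. Novel matures
are single-linkage clustered at distance <= 2 and families are numbered
`Jcu-nMIR001…` by decreasing total abundance (ties by lexicographically
smallest member sequence, for determinism).

## isomiRs

Variants are pooled by (start, sequence) across libraries. A candidate
isomiR must not be the mature/star read itself, be 18–26 nt, carry at most
one *internal* mismatch, start within 4 nt of its reference's 5' end, and
have pooled count >= 100. It is retained when it reaches 50% of its
reference's read count or exceeds 10,000 reads outright. A terminal run of
3' mismatches is treated as a nontemplated tail rather than internal
mismatches — "perfectly mapped (allowing one mismatch in the middle)" is
self-contradictory otherwise, and this reading is what makes the observed
3'-nontemplated class expressible. Typing gives 5' shifts precedence
(`5p_deletion`/`5p_extension`), with the 3' difference kept as a secondary
tag; that is why type-count totals can exceed isomiR totals in published
summaries. `seed_polymorphic` flags internal mismatches in read positions
2–9. A star-referenced variant whose star reference has zero exact reads
can only be retained through the 10,000-read route, since its reference
fraction is undefined.

## Expression

Quantification sums windowed reads with at most one mismatch, per library.
TPM follows the published definition — counts × 10⁶ / *genome-mapped* reads
of the sample. That denominator is unconventional (it is not the
miRNA-mapped total), so TPM columns do not sum to 10⁶; the conservation
property actually guaranteed (and tested) is
`colSums(tpm) = 1e6 * colSums(counts) / genome_mapped`.

The differential-expression test is a simplified negative-binomial Wald
test, **not** a DESeq2 re-implementation and with no claim of numerical
equivalence: median-of-ratios size factors (total-count fallback when no
row is all-positive), a per-miRNA method-of-moments dispersion pooled
across the two groups and floored at 1e-8, and a Wald statistic on the log
ratio of normalized group means. The statistic is referred to a *t*
distribution with `nA + nB − 2` degrees of freedom rather than a normal:
with 3 replicates per stage the dispersion is estimated from 6
observations, and a normal reference is anti-conservative at that sample
size. Null simulations (1,000 miRNAs, 3v3, dispersion 0.1) put the raw
p < 0.05 fraction near 0.045–0.05, and power for a planted 4-fold change at
mean 200 exceeds 0.95. Zero-mean groups get a 0.5 pseudo-count for the
reported fold change only; all-zero rows report p = 1, log2FC = 0. A miRNA
is differentially expressed when |log2FC| > 1 and BH-adjusted p < 0.05 in
at least one of the three stage contrasts (I/Y, M/I, M/Y). The BH step-up
is implemented directly and verified both against the literal definition
(exhaustively for up to 6 p-values) and against `stats::p.adjust`.

`ddct()` provides the 2^−ΔΔCt relative-quantification formula used for
RT-qPCR validation against a reference gene and control condition.

## The synthetic generator: what it emulates, what it does not

`make_hairpin()` constructs stem-loops whose duplex geometry round-trips
exactly: requested mismatches, bulges and overhangs are what
`duplex_profile()` reports on the product. The synthetic MFE is a
deterministic function of structure, `−energy_scale × paired_fraction ×
length` (default `energy_scale = 0.5` gives ≈ −0.33 kcal/mol/nt for a
typical stem, comfortably past rule 7; 0.2 lands ≈ −0.17, failing it) —
rule 7 needs only a controllable number, not thermodynamics.

`simulate_stack()` draws multinomial read counts over a small template set:
modal arm reads, two 5'-shifted variants (so that low homogeneity settings
genuinely dethrone the modal start), loop-spanning off-duplex reads
(controlling the excision fraction), and planted isomiRs pinned to a
fraction of the sampled modal count. `simulate_experiment()` draws NB
counts over a 3-stage × 3-replicate design with planted monotone fold
changes (half effect at the intermediate stage), a 21-nt-modal /
24-nt-secondary length mixture and a U-biased (C at 24 nt) first-base
distribution — qualitative echoes of real small-RNA libraries, kept as
configuration, not assertions about any real dataset.

Defaults represent one stated world: per-library depth in the hundreds to
thousands, excision 0.92, 5' homogeneity 0.9, star fraction 0.3, NB
dispersion 0.1, baseline mean 200, planted |log2FC| = 2. What a green test
establishes is that the implementation recovers planted truth under these
conditions with margins well clear of every threshold; it does not
establish performance on real libraries with sequencing error, cross-mapping
paralogs, or degradation products, none of which are modelled (no
quality-error model, no rRNA/tRNA contamination, no multi-locus mapping
ambiguity).

## Pipeline determinism and degenerate inputs

`run_pipeline()` is a pure function of its inputs and configuration: no
RNG, fixed column orders, no timestamps — reruns are byte-identical (tested
on the shipped fixture and across 20 regenerated fixtures). The mature
interval of each candidate is inferred from its stack (the most abundant
exact-matching 18–30 nt read; ties to the 5'-most then shorter read), since
candidate lists of this kind carry their mature definition in the read
evidence. Candidates whose structure cannot yield a duplex (loop-spanning
mature, truncated star) are rejected with all structural rules failed
rather than aborting the run; missing inputs are reported as configuration
errors before any stage runs.

## Known limitations

* No thermodynamic folding, pseudoknots, or multi-loop (polycistronic)
  precursors.
* No dispersion shrinkage across miRNAs; the NB test is calibrated by
  simulation, not validated against DESeq2 outputs.
* Rule interpretation points that the criteria leave open (the exact bulge
  boundary, pooled vs per-library denominators, the definition of
  "multiple" libraries, whether rule 4 is mandatory for non-rescued
  candidates) are configurable, with the defaults documented above.
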