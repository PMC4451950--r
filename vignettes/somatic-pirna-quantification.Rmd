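---
title: "Quantifying somatic piRNA populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic piRNA populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somapiR)
```

## The analysis in one paragraph

In *Drosophila* ovarian follicle cells, transposable elements (TEs) are
silenced by Piwi loaded with primary piRNAs, most of which derive from the
somatic *flamenco* cluster; a second, Piwi-bound class comes from the 3'UTRs
of genes such as *traffic jam*. somapiR implements the computational side of
asking whether a perturbation (for the motivating case, loss of miRNA
biogenesis through a trans-dominant negative Drosha) removes TE-targeting
piRNAs specifically, sparing the 3'UTR class: annotate a small-RNA library
by a fixed cascade, anchor all libraries to a normalizer piRNA cluster that
the somatic perturbation cannot touch, count piRNAs per TE family with a
mismatch-tolerant consensus scan, profile 5' ends along features, form fold
changes and correlations between conditions, and gate every two-sample claim
through a normality-aware decision procedure. Because the real libraries are
sequencing deposits, the package carries a synthetic-data generator that
reproduces the *structure* of those libraries, so the whole chain is
testable end to end at desk scale.

## The annotation cascade

Reads of 18-29 nt are classified in a fixed order; each read gets exactly
one category:

1. exact substring of an abundant ncRNA (rRNA/tRNA/snRNA stand-ins) ->
   `abundant_ncRNA`;
2. exact, full-length identity with a mature miRNA -> `miRNA`;
3. no perfect genome alignment (either strand) -> `nonmapper`;
4. length 21 -> `siRNA`; length 23-29 -> `piRNA`;
5. everything else (mappers of length 18-20 or 22) -> `unclassified`.

Choices worth making explicit: ncRNA subtraction is exact substring
matching on the stored strand only, and miRNA identity is exact full-length
identity without isomiR tolerance — both rules are stated without a
mismatch policy in the protocols this follows, and the exact reading is the
reproducible one. "Mapper" means a perfect (0-mismatch) genome match;
genome-unique means exactly one such match, and only genome-unique piRNAs
are attributed to clusters and 3'UTRs, by full containment of the alignment
in the interval. T stands in for U throughout.

## Mapping semantics

Two distinct semantics coexist, and both are specified as *all-hit* scans:

- `map_perfect()`: every exact occurrence of the read or its reverse
  complement on the genome. Implemented over Biostrings dictionary
  matching; a read shorter than 15 nt is refused as a guard against
  spurious hits.
- `map_consensus()`: every ungapped alignment of the read, in both
  orientations, against each TE consensus with Hamming distance <= 4 (the
  budget used for RepBase-style consensus counting). Implemented as a small
  C++ scan; there are no indels, matching the substitution-only convention
  of piRNA/TE analyses.

Coordinates are 1-based inclusive internally (the R/Bioconductor
convention; BED exports are 0-based half-open). The 5' end of a minus-strand
hit is the *rightmost* aligned base on the reference forward strand, so
antisense profile peaks sit at biological piRNA 5' ends. The test suite
keeps an independent brute-force scanner and requires exact hit-set
equality on seeded read sets.

## Normalization and quantification

Libraries are scaled so that the genome-unique piRNA mass of the germline
normalizer cluster (42AB-like) equals 1,000,000. The factor is
`1e6 / n`, with `n` the count of piRNA-category, genome-unique reads whose
alignment lies in the cluster; `n = 0` is an explicit error (the library is
unusable), and after scaling the identity holds exactly — this is asserted,
not approximated, in the tests. The normalizer is germline-specific, so
follicle-cell-restricted perturbations leave it untouched; that is what
makes cross-condition fold changes interpretable.

Per-TE-family counting gives each piRNA read one count per family it hits
within the budget, however many positions it matches — the quantity of
interest is piRNA abundance per TE, not hit abundance. Positional
multiplicity is retained only in 5'-end profiles, where every qualifying
hit adds the scale factor at its 5' coordinate (TE consensi: all hits,
<= 4 mismatches; clusters/3'UTRs: genome-unique perfect hits only, reported
5'->3' on the feature strand). Profile TSVs negate antisense values
(sense-up/antisense-down plotting convention) while objects store
non-negative vectors.

Fold changes are `(condition + pc) / (control + pc)` on normalized totals
with pseudocount `pc = 1` by default; profiles use no pseudocount (they
stay faithful to the data, while ratios must stay finite). Pearson r for
scatter comparisons is computed on raw normalized counts by default with an
optional `log10(x + 1)` mode, since the plotted scale is not part of the
statistic's definition; with fewer than two features or zero variance the
correlation is flagged undefined rather than silently dropped. RNA-IP
enrichment scales both fractions to one million genome-unique reads of any
category (IP material is not piRNA-restricted) before forming ratios.

## qPCR and ChIP formulas

Relative RNA levels use 2^(-ddCt), with replicate Ct values aggregated by
arithmetic mean before exponentiation; the small-RNA variant is the same
arithmetic against a reference piRNA species and exists as a separately
named operation so reports label the assay. The ChIP relative DNA level is
implemented character-for-character as printed in the source protocol:

E_t^Ct_IP(t) * E_r^Ct_input(r) / ( E_r^Ct_IP(r) * E_t^Ct_input(t) )

with both right-hand factors in the denominator. This orientation is the
*reciprocal* of the common Pfaffl-style efficiency-corrected ratio — an
enriched target (lower Ct in the IP) gives a *smaller* value. The printed
form remains the default truth; `pfaffl_orientation = TRUE` returns the
reciprocal for users who want the conventional direction. Replicate SDs are
propagated by recomputing the statistic over every combination of one Ct
per replicate set and reporting the SD of those values. Efficiencies
default to 2 when a Ct table omits them and must lie in (1, 2].

## The statistical gate

`compare_two_samples()` encodes the decision procedure: Shapiro-Wilk on
each series at `gate_alpha = 0.05`; if both pass, Levene's test (classic,
mean-centered) chooses between the pooled two-tailed Student's t-test and
Welch's t-test; any normality failure routes to the two-tailed Mann-Whitney
test (midranks, normal approximation with continuity correction; the exact
distribution for tie-free samples of at most 8). Two completions were
genuinely open and are our choices: the gate alpha is fixed at 0.05 and
recorded in every result for audit, and Welch is used when Levene rejects —
the source procedure tests homogeneity without stating the consequence, and
Welch is the conservative completion. Series too short or constant for
Shapiro-Wilk fall through to Mann-Whitney with a recorded warning rather
than erroring. `bh_adjust()` wraps the standard Benjamini-Hochberg step-up
adjustment with input validation.

Monte-Carlo calibration (1,000 seeded replicate pairs, n = 10) keeps the
empirical size within 3 binomial SDs of 0.05 and the power above 0.8 at a
2-SD shift; both checks run in the suite and in `scripts/acceptance.R`.

## What the generator emulates — and what it does not

`build_reference()` creates one random chromosome (default 60 kb, base
composition 1/4 each) and places without overlap: a 4 kb germline
normalizer cluster, a somatic cluster built from one antisense copy of each
soma-dominant TE consensus (three families, 0.9-1.5 kb) separated by 150 bp
of backbone, three 3'UTR source intervals (0.7-0.9 kb, mixed strands), and
two exact genomic copies of each germline-dominant consensus. Placement of
the TE sequence space is the one genuinely open design point, and it is
resolved by the annotation contract: soma-dominant consensi occur in the
genome *only* inside the somatic cluster (their piRNAs are genome-unique
cluster mappers, as for real flamenco, whose TE fragments are diverged
enough to be unique), while germline consensi are genomic multi-mappers.
Cluster 23-mer genome-uniqueness — the property that makes "genome-unique"
semantics exactly testable — is enforced by rejection sampling at build
time and checked by `cluster_kmers_unique()`.

`simulate_library()` draws reads with class probability proportional to
`weight x depletion` over seven sources (germline cluster, somatic cluster,
soma TE, germline TE, 3'UTR, miRNA, ncRNA fragment). Default weights
(0.25/0.20/0.15/0.10/0.10/0.12/0.08) depict a total-ovary library with a
strong somatic compartment; no per-class abundances are published for
follicle cells, so these are stated once here and not tuned. piRNA-class
lengths sit on 23-29 nt with a mode at 26; the 1U bias (default 0.75) is
implemented by sampling the 5' origin from T-start versus non-T-start
positions so that the *expected* 5'-U fraction equals the parameter
exactly. TE-derived reads are drawn mostly antisense to the consensus (0.9
for soma-dominant, 0.6 for germline families) and carry, with probability
`mismatch_rate = 0.1`, one to four substitutions uniform over positions and
alternative bases — no empirical error model is published, so the uniform
model is used. Named scenarios encode the study's perturbations:
TN-Drosha-like depletes the somatic cluster and soma-TE classes fourfold
(the reported flamenco loss) and miRNAs about threefold, leaving germline
and 3'UTR classes at factor 1; Yb-like and piwi-KD-like deplete all
somatic piRNA classes including the 3'UTR class.

Known departures from real data, hence the limits of what green tests
show: no sequencing-error or adapter model; no ping-pong signature (absent
from this soma-focused system anyway); TE reads carrying simulated
substitutions are non-mappers on the toy genome, whereas real divergent
reads map to genomic TE copies — this removes a constant fraction from
both sides of every comparison and cancels in all ratio-based statistics,
but per-family absolute counts undercount by about `mismatch_rate`; one
chromosome only; truth labels live in a sidecar TSV that the pipeline never
reads. Passing tests demonstrate that the *computations* are correct and
that injected signals of realistic size are recovered — not that the
defaults match any particular real library.

## Numerical and reproducibility choices

Everything downstream of a seed is deterministic: bundles are
byte-identical for a fixed seed, and `run_pipeline()` writes result
directories whose files are byte-identical across reruns of the same
configuration (fixed-format TSV writing, no timestamps in outputs). Ties in
TE-family strand assignment (a read hitting one family on both strands)
resolve to the hit with fewer mismatches, sense on a tie. Degenerate inputs
error early and explicitly: infeasible feature packing, empty genome, zero
normalizer counts, empty base-composition selections, out-of-domain
configuration keys or values.

Problem sizes used by the shipped analyses: 20 kb reference with 20,000-
read libraries for unit-level work; the study-condition checks (depletion
recovery at factors 2, 4 and 8; replicate concordance) use the default
60 kb reference with 200,000 reads per library, where recovered factors sit
within 10% of the injected value and 3'UTR fold changes within [0.9, 1.1].

## Limitations

The package quantifies; it does not render figures (tables are
plot-ready). It does not estimate primer efficiencies from standard curves,
call differential expression with shrinkage models, or predict miRNA
targets; and re-analysis of the real deposited libraries would additionally
require the fly genome, RepBase consensi and cluster annotations, which are
deliberately outside the desk-scale scope.
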