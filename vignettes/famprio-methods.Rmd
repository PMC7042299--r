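---
title: "Prioritizing germline variants in familial MDS/AML: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing germline variants in familial MDS/AML: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famprio)
```

## The problem

Families in which two or more members develop myeloid malignancy — with at
least one member diagnosed with MDS or AML — fall into two situations. In
some, a germline variant at an established predisposition locus (RUNX1,
GATA2, DDX41, CEBPA, telomerase genes, and a growing tier of emerging loci)
explains the disease. In the rest, the lesion is unknown and exome-wide
discovery is required. famprio implements both arms: triage against the
known loci, and a discovery cascade that prioritizes candidate genes by
cross-family recurrence of rare, germline-range, predicted-damaging
variants.

The central difficulty is signal-to-noise: every exome carries hundreds of
rare coding variants (the cascade's operating point is roughly 300 per
patient at an external allele frequency below 0.005), while a causal
germline lesion is a single variant shared by affected relatives. The
cascade's levers are (a) hard per-variant evidence (VAF, consequence class,
population frequency, in-silico predictors), (b) pedigree segregation, and
(c) recurrence of the same *gene* across independent families.

## The per-variant criteria

A variant survives the cascade when all of the following hold:

1. **Germline-range VAF.** `vaf > 0.30`, strictly: a heterozygous germline
   variant in blood DNA is binomially distributed around 0.5, so 0.30 is a
   generous lower envelope; a value of exactly 0.30 fails. Somatic clones
   usually sit lower — but not always (see CHIP, below).
2. **Consequence class.** Missense, indels, nonsense, start-lost, or
   splice-region changes within ±3 bases of the exon boundary, on the
   canonical transcript. The intronic offset is parsed from the HGVS
   coding notation (`c.N+k`, `c.N-k`); a `+5` splice variant does not
   qualify. Start-loss (`p.Met1?`) is treated as loss-of-function.
3. **Segregation not refuted.** See below.
4. **Rarity.** ExAC frequency below 1e-4 or absent. Absence from the
   reference database is evidence of rarity, so missing frequencies pass.
   (The upstream pre-filter uses the looser 0.005 against both ExAC and
   gnomAD, plus depth ≥ 20 and exclusion of segmental duplications; the
   known-locus rule uses the stricter 1e-5. The three thresholds are
   deliberately distinct stages, not one reconciled constant.)
5. **Predictor consensus.** At least 2 of the 4 substitution-oriented
   tools (PolyPhen2, MutationTaster, SIFT, Provean) call a missense
   variant damaging; a missing call never counts as damaging.
   Truncating-class variants and in-frame indels pass unconditionally,
   because these tools only score amino-acid substitutions; retained
   truncating variants routinely lack scores. `strict_predictors = TRUE`
   withdraws the exemption for sensitivity analyses.

## Segregation with reduced penetrance

Reduced penetrance and late onset are documented features of the
established loci (GATA2, DDX41, C-terminal CEBPA), so an **unaffected
carrier never refutes** a variant by default; it is recorded as context.
Only a genotyped *affected* non-carrier refutes. "Segregates" requires at
least two genotyped affected members, all carriers; with fewer than two
genotyped affected members the variant is *untestable* and is retained —
the cohort deliberately keeps index-only families rather than discarding
them. A strict mode that counts unaffected carriers against the variant is
available but off by default. Whether one additional affected carrier
should suffice for "segregates" is genuinely open; requiring two genotyped
affected members is this package's reading of "where testing was
possible", and the threshold only separates "segregates" from "untestable"
— both pass the cascade, so the choice does not move the final list.

## Gene-level recurrence

Recurrence counts **families, not variants**: two qualifying variants in
one family count once. A gene is included when

* loss-of-function-class variants occur in ≥ 2 families
  (`lof_recurrence`),
* LoF and missense support together span ≥ 2 families with at least one
  LoF family (`mixed_recurrence`), or
* missense variants occur in ≥ 3 families (`missense_recurrence`) —
  the stricter rule that offsets missense dominance (86.3% of rare coding
  variants).

For the family-counting split, in-frame indels sit on the non-missense
side: the criteria group "indels" with truncating classes, and
substitution predictors cannot score them. A gene that fails recurrence
but carries at least one criteria-passing variant and appears in an
external candidate list (prior familial MDS/AML or inherited
bone-marrow-failure series) is **rescued** (`cross_reference_rescue`);
the rescued variant must still pass criteria (1)–(5) — the wording of the
published rescue does not state which criteria were relaxed, and requiring
all of them is the conservative reading. Listed genes with no passing
variant are never rescued.

Synonymous variants are excluded from the cascade but scanned separately:
novel (absent from ExAC and gnomAD) synonymous variants whose upstream
splice-impact annotation exceeds a threshold are reported as a disjoint
list, since a synonymous change can disrupt splicing.

## CHIP contamination

Age-related clonal hematopoiesis (TET2, DNMT3A, ASXL1) produces somatic
clones in blood-derived DNA whose VAF can reach the germline range —
contaminants at VAF 0.46–0.49 pass the VAF criterion and can only be
excluded by recurrence and segregation (they are private to one
individual). Final-list variants in these genes therefore carry a caution
flag rather than being silently trusted or removed.

## Known-locus triage

A variant previously described in familial MDS/AML is pathogenic outright.
A novel variant at a known locus is likely pathogenic when it is rare
(< 1e-5), germline-range, predictor-supported, carries no ACMG benign
assertion, is not refuted by segregation, and is consistent with the
gene's inheritance model (heterozygous for the dominant loci; biallelic —
compound heterozygous with trans phase flagged unverified, or
homozygous-range VAF — for ERCC6L2/FANC/SBDS; hemizygous-range VAF in
males for WAS). A dominant-model variant with VAF above 0.7 is flagged as
a possible loss-of-heterozygosity anomaly without changing its category.

The ACMG judgement is a **curator input** (`not_benign` / `uncertain` /
`benign`), not an implemented engine: full ACMG classification draws on
literature and database evidence outside this package's scope. An
`uncertain` judgement caps the category at VUS — this is how an otherwise
criteria-passing index-only variant (the classic single-proband missense)
stays a VUS, matching practice. Families whose best finding is a VUS are
*held out* of both groups: they are not molecularly explained, and
including them in discovery would contaminate gene hunting with families
that may already carry their lesion.

## Interval analysis of constitutional deletions

Deletion breakpoints are stored 1-based inclusive so printed coordinates
reproduce bit-exactly; BED I/O converts to the 0-based half-open
convention. The common deleted segment across families is the coordinate
intersection `[max(starts), min(ends)]`. Two published coordinate pairs
exist for the third RUNX1-deletion family; both are packaged, the array
set is the default, and the intersection is identical under either because
that family attains neither the maximal start nor the minimal end. Lengths
are reported as computed (`end − start + 1`), never as prose
approximations; the kb form rounds to the nearest integer to match printed
sizes.

## Telomere length (T/S)

Telomere (T) and single-copy-gene (S) quantities are interpolated from
per-channel standard curves `Cq = slope·log10(q) + intercept`
(least-squares; efficiency `10^(−1/slope) − 1`; a non-negative slope is
rejected as failed amplification). Quadruplicates are averaged on the
**quantity** scale, not the Cq scale, because quantities are additive.
T/S is invariant to a common intercept shift with equal slopes (plate
shift), which the tests assert. Flagging is rank-based and
distribution-free: the reported percentile is the proportion of controls
strictly below the sample, and the short flag fires when the ratio falls
strictly below the type-1 (inverse-ECDF) empirical centile of the control
set — an observed control value, so a ratio exactly at the centile is not
flagged. At least 20 controls are required; with fewer the flag is `NA`.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the cascade
assumes, with defaults fixed once as the study conditions:

* **Burden**: negative-binomial per-patient rare-variant counts, mean 311,
  size 8, truncated to 161–781 (the published mean and range; no
  dispersion is reported, and size 8 puts the truncation bounds at
  plausible tail positions).
* **VAF**: alt reads ~ Binomial(depth, 0.5); depth ~ Poisson(80) with a
  3% low-depth fraction (mean 12) and a 2% segmental-duplication rate to
  exercise the pre-filter.
* **Consequence mix**: 86.3 / 6.2 / 2.4 / 5.1 percent missense / indel /
  nonsense / splice; indels split 60/40 frameshift/in-frame.
* **Population frequency**: 5% of background variants absent from the
  reference databases; present variants log-uniform on [1e-5, 5e-3].
* **Predictors**: per-tool damaging probability 0.15 for background, 0.9
  for causal missense (with two tools forced damaging so injected signal
  satisfies the consensus by construction).
* **Pedigree shapes**: 38% index-only, 20% duo, 22% trio, 20% extended —
  mirroring a cohort where roughly a third of families have material on
  the index case only and the rest support segregation.
* **Background pool**: 15,000 neutral symbols (`BG#####`), disjoint from
  known-gene, rescue-list and CHIP symbols, so collisions with fixtures
  cannot occur.
* **Injected signal**: three causal genes by default (LoF in 2 families,
  missense in 3, mixed in 2), shared identically by all affected sampled
  members of their families; CHIP contaminants private to one individual.

What it does **not** model: within-family sharing of background rare
alleles (relatives share ~50% of rare variants; here background variants
are private, which makes segregation *more* discriminating than in real
data), linkage and haplotype structure, annotation error, and relatedness
between families. Passing recovery tests therefore demonstrates the
correctness of the cascade's logic under its stated assumptions, not its
operating characteristics on real exomes.

A consequence of realistic background rates is that background genes can
*legitimately* recur across families by chance — exactly as in real
cohorts, where the published candidate list is itself a mixture of causal
and coincidental recurrence. Recovery evaluation therefore distinguishes
**wrongly included** genes (included despite failing an independent
recount of the recurrence thresholds — a logic defect; always zero) from
**background-recurrent** genes (chance recurrence that genuinely meets
the published rule; reported separately).

## Problem sizes and numerical choices

The test suite runs simulations at the study scale (37 families, ~300
background variants per patient) for the recovery and containment
properties — 20 replicate cohorts for parameter recovery — and smaller
6-family cohorts for I/O round trips; the per-base interval oracle runs on
1000 random triples with coordinates scaled to a few hundred bases.
Boundary behavior is strict where the published thresholds are strict
(`vaf > 0.30`, `af < 0.005`, `depth >= 20`); ties in interval feature
ordering are broken by start coordinate; degenerate inputs (zero depth,
empty cohorts, constant dilution series, < 3 standard-curve points, fewer
than 20 telomere controls) error or flag explicitly rather than silently
propagating.

## Known limitations

* The ACMG dimension is curator-supplied; two curators can disagree and
  the package will faithfully reproduce either decision.
* The rescue step depends entirely on the supplied external lists; the
  packaged lists are small illustrative subsets.
* The cohort-scale published headline (144 variants in 65 genes across 34
  families) depends on the original sequencing data and annotation
  database versions and is not recomputable from packaged data; the test
  suite substitutes property-based checks at simulation scale and an
  (optional) summary check against the externally distributed variant
  table.
* The RUNX1 feature model shipped with the package is synthetic — laid
  out to match the qualitative description of the deleted segment — and
  is labelled as such.
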