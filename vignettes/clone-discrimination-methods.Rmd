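---
title: "Discriminating vegetatively propagated clones with amplicon marker panels"
author: "ampliClone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating vegetatively propagated clones with amplicon marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliClone)
```

## The problem

Grapevine cultivars are propagated vegetatively, so the "clones" (clonal
selections) of a cultivar are genetically near-identical: they differ only
by the somatic mutations each lineage accumulated during decades to
centuries of asexual propagation. Those few hundred to few thousand
lineage-private variants sit on top of millions of heterozygous sites that
every clone shares with its cultivar's reference assembly. A marker that
identifies a clone must therefore be (i) present in every biological
replicate of that clone (to exclude per-sample calling noise), (ii) absent
from every sample of every other clone, and (iii) assayable by a cheap,
reproducible readout — here, deep sequencing of a short PCR amplicon
spanning the variant, where the per-allele read counts reveal the
genotype.

`ampliClone` implements this whole chain as composable, seeded,
file-interchangeable stages: genotype-matrix construction from VCF-level
calls, replicate-concordance and exclusivity filtering, summary statistics
and PCA, amplicon marker selection, allele counting and genotype calling,
and the final identification rule. A synthetic clonal-cohort generator
with an attached ground truth drives all testing.

## The discrimination model

Let the cohort contain clones $c = 1..K$, clone $c$ having $r_c \ge 1$
biological replicates, and let $d_{vs} \in \{0, 1, 2, \mathrm{NA}\}$ be
the alternate-allele dosage of sample $s$ at variant site $v$ (NA =
missing call). Sites are identified by the full tuple (contig, position,
REF, ALT) after multi-allelic splitting and left-alignment, so
representation differences cannot masquerade as clonal differences.

* **Replicate-consistent set** of clone $c$:
  $C_c = \{v : d_{vs} \ge 1 \ \forall s \in c\}$. A missing call counts as
  not-present. A single-replicate clone (legal; real surveys contain them)
  contributes its own presence set.
* **Clone-exclusive set**:
  $E_c = C_c \setminus \{v : \exists s \notin c,\ d_{vs} \ge 1\}$.
  Exclusive sets are pairwise disjoint by construction. Under the default
  (joint-genotyping) reading a missing call outside the focal clone counts
  as absent; `strict = TRUE` instead treats it as potentially-present and
  drops the site. The choice is exposed because per-sample calling and
  joint calling produce different missingness semantics.
* **Site-quality filter**: only calls with QUAL strictly greater than 100
  survive (the conventional stringency for clonal variant calls; the
  threshold is a parameter). QUAL is interpreted as the site-level score,
  not the per-genotype GQ.
* **Presence vs genotype**: concordance across replicates is defined on
  *presence* (dosage ≥ 1), not on an exact het/hom match. This is the more
  permissive of the two readings; the marker-selection stage separately
  demands heterozygosity, which restores stringency where it matters.

PCA of the samples uses dosage encoding {0, 1, 2}, missing imputed to the
site mean, centred but not variance-scaled, restricted by default to the
union of replicate-consistent sets, and decomposed by SVD. Coordinates are
sign-canonicalised per axis, so repeated runs are identical.

Summary statistics follow the field's conventions: transitions are A↔G
and C↔T; Ts/Tv is reported as missing when no transversions exist; the
heterozygous fraction is het calls over called variant sites; densities
are per kbp and per 100-kbp windows (BED-style 0-based half-open at the
interfaces, 1-based VCF coordinates internally at I/O boundaries).

## Marker selection and the identification rule

Only **heterozygous** exclusive variants become marker candidates: in a
highly heterozygous, clonally propagated crop, somatic mutations arise on
one haplotype, and a validated clonal marker behaves as REF/ALT
heterozygote in its clone and REF-homozygote elsewhere. Each candidate
receives an amplicon window of `targetLen` (default 200 bp) centred on
the variant; both allele lengths must lie within [141, 487] bp (the
practical size range for a two-step PCR amplicon panel, defaults
configurable), the window must sit fully on its contig, and — as an
automatable proxy for visual read-mapping inspection — no other variant
may fall inside the window. Candidates are ranked by site QUAL. Primer
thermodynamics is deliberately out of scope: windows are exported as BED
for external primer design.

Genotype calling from allele counts uses an explicit ambiguous zone:
depth < 20 → `no_call`; minor-allele fraction ≥ 0.20 → `het`; ≤ 0.05 →
homozygous for the major allele; in between → `no_call`. The published
validation work shows read-coverage bars but prints no numeric cutoffs,
so these three thresholds are this package's own, chosen to be
conservative for a diagnostic assay, and all are configurable. The caller
is symmetric in its two counts, and increasing depth at a fixed allele
fraction never converts a correct call into a wrong one.

Identification then follows the single-marker sufficiency rule: a marker
is *positive* when the sample's call at it is heterozygous; positives for
exactly one clone assign that clone; no positives leave the sample
`unassigned` (clones without validated markers can never be positively
identified); positives for two or more clones yield `ambiguous` with all
conflicts listed. A diagnostic tool must not guess, so ambiguity is
reported, never tie-broken.

## The synthetic cohort generator

Real clonal resequencing data (tens of 20× genomes) cannot ship with a
package, so the generator emulates the *output* of the calling stage —
never raw reads or mapping:

* a reference of i.i.d. bases at GC 0.345 (grapevine assemblies run
  34.1–34.8% GC);
* background heterozygous variants shared by every sample at 0.005/bp,
  matching the ~4.4–5.5 SNV/kbp observed when clone genomes are compared
  with their cultivar assembly;
* per-clone exclusive variants (counts per clone configurable; real
  surveys show ~100–2,000 SNVs plus ~25–750 InDels per clone), planted
  heterozygous with probability 0.94 — the observed heterozygous fraction
  of clone-specific SNVs — and homozygous-alternate otherwise;
* SNV substitutions drawn to a Ts/Tv of 2.1; a 0.26 InDel proportion;
  InDel sizes 1–10 bp, planted left-aligned with VCF anchor bases and a
  minimum spacing so footprints never overlap;
* call noise: each truly present genotype is dropped (set to `./.`)
  independently per replicate with probability 0.05; spurious singleton
  het calls arise at 10⁻⁵ per site per replicate; QUAL is drawn from
  N(800, 150) for true calls and N(60, 30) for false ones, so the Q > 100
  filter removes ~91% of false positives and essentially no true calls.
  The real noise structure of a caller is unobservable from the published
  tables; these two-component defaults are free parameters chosen so that
  every filter in the pipeline does measurable work;
* amplicon reads as full-length copies of the two allele sequences
  (allele A with probability `alleleBias` per read for a heterozygote)
  with independent per-base substitution errors. Real amplicon data are
  150-bp paired-end reads that must first be merged; that read-level step
  is out of scope, so passing tests say nothing about merge artefacts,
  PCR chimeras, or index hopping.

All randomness flows from one integer seed through `withr::with_seed`
(the call simulator uses seed + 1 so truth and noise draws stay
decoupled); no global RNG state is touched. What the generator does *not*
model — deliberately, because no parameter for it is published — includes
reference redundancy (the cause of anomalously low InDel heterozygosity
in some cultivars), mappability structure, linked variants sharing
haplotypes, and coverage heterogeneity. Results on synthetic cohorts
therefore validate the *logic* of the pipeline, not caller behaviour on
real genomes.

## Numerical and design choices

* Coordinates are 1-based inclusive at every VCF boundary; window
  arithmetic is 0-based half-open internally and converts at I/O.
* "Q > 100" is a strict inequality, as conventionally printed.
* Multi-allelic rows are split before normalisation; each ALT becomes its
  own record and site identity is the full (contig, pos, REF, ALT) tuple.
* Equal-length multi-base substitutions classify as "other" and are
  excluded from SNV/InDel tallies, which partition the remainder.
* Normalisation trims the shared suffix (left-extending from the
  reference when an allele would empty), then the shared prefix, which
  left-aligns InDels; the operation is idempotent and is tested against
  an independent global-diff oracle.
* Clone-coverage percentage truncates (does not round) to one decimal:
  14 covered clones of 18 evaluated is reported as 77.7%.
* The outlier-replicate problem (a mislabelled vine in the source
  records, say) is handled by an explicit `exclude` column in the design
  table — exclusion is never automatic.
* PCA imputation to the site mean is the simplest reproducible choice; no
  published encoding exists to follow.

## Test problem sizes

The acceptance-level checks run at desk scale by design: a 1-Mbp,
4-clone × 3-replicate noiseless cohort recovers planted exclusives with
precision = recall = 1; ten seeded 1-Mbp cohorts of four two-replicate
clones at 1,500 exclusive variants each, with dropout 0.05 and false
positives at 10⁻⁵, are required to average recall ≥ 0.90 and precision
≥ 0.95 after Q > 100 filtering. Two-replicate clones are the right shape
for that bound: a variant is recovered only if called in *every*
replicate, so expected recall is $(1-0.05)^r$ — 0.9025 at $r = 2$ but
0.857 at $r = 3$, i.e. the 0.90 bound mathematically characterises
cohorts with at most two replicates per clone, and more replicates trade
recall for precision. The exclusivity operator is also checked against an
exhaustive per-site scan on 200 random matrices, the Ts/Tv and
heterozygosity estimators must recover their generating parameters within
three standard errors, and identification must assign 250/250 simulated
samples (5 clones × 50 seeded trials, depth 200, 0.5% read error)
correctly. Whole-genome-scale figures (millions of SNVs per cultivar)
require the original resequencing reads and are out of scope.

## A worked example

```{r example, eval = FALSE}
design <- CohortDesign(c("A", "B", "C"), replicates = 2,
                       genomeLength = 1e5, cloneSpecific = 50, seed = 42)
ref <- generateReference(1e5, seed = 42)
truth <- plantCohort(design, ref)
calls <- simulateCalls(truth, design, ref)
cohort <- buildMatrix(qualityFilter(calls, 100), designSamples(design))
sets <- cloneExclusive(cohort)
panel <- selectCandidates(cohort, sets, ref)
summarizePanel(panel, data.frame(cultivar = "NN",
                                 clone_id = c("A", "B", "C")))
```

## Known limitations

* The generator's i.i.d. reference has no repeats, so the flank-variant
  window check is exercised only by chance variant proximity, not by the
  repeat-induced ambiguity that motivates it on real genomes.
* Allele counting matches reads to full amplicon sequences in a fixed
  orientation; real pipelines must merge read pairs and orient them
  first.
* The identification rule assumes the panel's expected positive genotype
  is heterozygous for every marker; a future homozygous marker type would
  need a per-marker expected genotype column.
* Sensitivity to the genotype-caller thresholds is not explored beyond
  the symmetry and monotonicity properties; users with unbalanced PCR
  (allele bias far from 0.5) should widen the het acceptance band.
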