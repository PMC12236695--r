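---
title: "Scanning hybrid genomes for mitonuclear incompatibilities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning hybrid genomes for mitonuclear incompatibilities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Mitochondrial genomes evolve quickly and encode only a handful of proteins, all
of which work in intimate contact with nuclear-encoded, mitochondrially
targeted ("n-mt") partners. When two diverged lineages hybridize, a
mitochondrial haplotype can find itself in a nuclear background it never
coevolved with, and mismatched mitonuclear genotype combinations may be
selected against — a Dobzhansky–Muller incompatibility with the mitogenome on
one side. If such selection acts broadly across n-mt genes, hybrid genomes
should retain an excess of *matched* ancestry: nuclear alleles at n-mt loci
should co-occur with the mitochondrial haplotype from the same parent species
more often than expected.

`mitoscan` implements the genome-wide version of this test for admixed
populations characterized by local-ancestry inference. Its genetic input is a
matrix of ancestry posteriors at ancestry-informative markers (AIMs): one
value per marker and individual on the dosage scale (the expected fraction of
the individual's two alleles derived from the designated "major" parent
species, in [0, 1]). The mitogenome does not recombine, so a single
mitochondrial AIM represents it. Nuclear genes are partitioned *a priori*
into three classes: interacting n-mt (the encoded protein physically contacts
mitochondrially encoded gene products — OXPHOS subunits, mitoribosomal
proteins, aminoacyl-tRNA synthetases, organellar polymerases),
non-interacting n-mt (mitochondrially targeted but not in contact), and
non-n-mt (everything else).

# Statistics

## Mitonuclear linkage disequilibrium

For a population whose mitochondrial haplotype still segregates, the
association between a nuclear AIM (locus A) and the mitochondrial haplotype
(locus B) is measured with classical two-locus disequilibrium, both alleles
labelled by the same parent so that positive values mean parental (matched)
combinations in excess:

$$D = p_{AB} - p_A p_B, \qquad D' = D / D_{max}, \qquad
r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}$$

with the usual sign-dependent bound
$D_{max} = \min(p_A(1-p_B),\,(1-p_A)p_B)$ for $D > 0$ and
$\min(p_A p_B,\,(1-p_A)(1-p_B))$ for $D < 0$, and $D' \equiv 0$ when
$D = 0$ (the piecewise bound is undefined there).

Estimation from posteriors: over individuals with both a nuclear dosage and a
mitochondrial call (pairwise-complete deletion per AIM), $p_A$ is the mean
dosage, $p_B$ the fraction of major-parent mitogenomes, and $p_{AB}$ the mean
of dosage × indicator(mito = major). This estimator was chosen because it
keeps the marginals consistent (summing $p_{AB}$ over the two mitochondrial
states returns $p_A$) and reduces exactly to haplotype counting when dosages
are hard 0/1 calls — the property the test suite verifies against a counting
oracle. When a marginal frequency is 0 or 1 the statistics are reported as
missing, never as 0, so monomorphic sites cannot drag class means toward
zero. A `hard_calls` switch recomputes LD from thresholded calls instead of
raw dosages; the default is raw dosages.

## Filtering, per-gene averaging, and the class tests

Posteriors strictly between 0.2 and 0.8 carry little information and are set
to missing before any analysis; values exactly at the thresholds are
retained. The filter is idempotent and only ever removes data.

Per-AIM statistics are averaged (unweighted) within each annotated gene to
limit pseudo-replication from the many AIMs a gene contains. Gene-level
values then enter:

* a one-way fixed-effects ANOVA (`lm` + `anova`) of value on gene class;
* a permutation test of the directional contrast (interacting n-mt minus
  non-n-mt by default): values are reassigned across all gene labels, class
  sizes fixed, and the one-sided upper p-value uses the add-one estimator
  $(b+1)/(n_{perm}+1)$, which is valid (never zero) for any number of
  permutations; ties are counted as "at least as extreme" up to float
  round-off, keeping the estimator conservative when many permutations tie.
  A two-sided option scores $|T|$;
* an exact upper-tail hypergeometric test for overrepresentation of each
  class in the top fraction (default 1%) of genes, with all ties at the
  cutoff included in the top set;
* Z-score standardisation per gene against the genome-wide mean and sample
  standard deviation ($n-1$ denominator), flagging genes with $z > 2$
  (one-sided, strict) as outliers.

For populations *fixed* for one mitochondrial haplotype, LD is undefined;
the analysis instead compares per-gene matched (major-parent) allele
frequencies across classes, with the same ANOVA/permutation machinery. The
pipeline switches modes automatically when the mitochondrial AIM is
monomorphic among called individuals and refuses an explicit LD request in
that case.

# The synthetic-data generator

The forward-in-time simulator exists so that every stage of the analysis can
be exercised, calibrated and power-tested against known ground truth, without
any external download.

**Demography.** Founders are pure parental individuals; individual genomes
are drawn from the major parent with probability given by the admixture
proportion. Each subsequent non-overlapping generation is formed by random
mating (mother from the females, father from the males, with replacement),
with the census size constant and sexes assigned in equal numbers.
Presets encode the three study populations (CALL, CHAF, HUEX-STAC):
admixture proportions 0.522 / 0.682 / 0.846, generations since admixture
46 / 46 / 263, founding maternal major-mitogenome frequencies
0.637 / 0.936 / 1.0, and census sizes 281 / 250 / 255. The HUEX-STAC preset
idealizes its mitogenome as fixed (the observed 99.6% is a post-filter call
frequency; the preset parameter is the founding maternal frequency).

**Founding mitonuclear coupling.** A pure parental founder carries the
mitogenome of its own species, which is what seeds admixture LD between the
mitogenome and all nuclear loci. Because the founding maternal mitogenome
frequency and the genome-wide admixture proportion are separate parameters,
the female pure-major fraction is set to the mitogenome frequency and the
male fraction to (2 × admixture − mito frequency), clamped to [0, 1] with a
warning, so both summaries hold simultaneously at founding.

**Recombination.** Haplotypes are ancestry-tract lists on a genetic map;
meiosis draws Poisson(chromosome length in Morgans) crossovers at uniform
positions and alternates between the parental haplotypes from a random
start. The tract merge runs in compiled code. Output files use physical
coordinates through a fixed linear map, 1 Morgan = 25 Mb; only monotonicity
of this map matters to the analysis.

**Mitochondrial inheritance** is strictly maternal: each offspring copies
its mother's haplotype, so the transmitting population is roughly half the
census and the haplotype drifts accordingly (this matters below).

**Selection.** Incompatibility loci are configured per gene as
(s, h, matched parent). An offspring whose mitogenome comes from the
locus's matched parent survives with probability $1 - s\,g(d)$ per locus,
multiplicatively across loci, where $d$ is the fraction of its two alleles
at the locus *not* derived from that parent and $g(0)=0$, $g(1/2)=h$,
$g(1)=1$. Individuals carrying the other mitogenome are unaffected by that
locus; listing a gene once per parent makes the incompatibility symmetric.
Selection is viability selection before census (the motivating phenotype is
death during embryonic development), and the census is refilled by
resampling surviving offspring, with an explicit extinction error if no
offspring survive.

**Posterior emission.** A true dosage $t \in \{0, 1/2, 1\}$ is emitted as a
draw from $\mathrm{Beta}(1+\kappa t,\, 1+\kappa(1-t))$ — a perturbation with
mode $t$ that lives in [0, 1] without truncation and sharpens as the
concentration $\kappa$ grows; $\kappa = \infty$ emits $t$ exactly. A
configurable fraction of entries is resampled uniformly from (0.2, 0.8) to
emulate the low-confidence calls the standard filter removes. Note that a
confident heterozygote ($t = 1/2$) is *itself* removed by the 0.2/0.8 filter
on the dosage scale; at intermediate allele frequencies this discards real
information, but it biases no class comparison because it applies equally
everywhere, and at an allele frequency of one half the retained-homozygote
mean remains an unbiased ancestry estimator.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: dosage-scale
posteriors with noise and missingness, admixture LD decaying at an
unlinked-locus rate of one half per generation, maternal mitochondrial drift,
viability selection at annotated loci, and gene-class structure in
configurable proportions (defaults scaled from the genome-wide counts
148 : 883 : 19,312, with an optional clustering knob that places a fraction
of interacting genes in consecutive intervals). It does **not** simulate
population structure or migration — the real hybrid populations are
structured, and that structure is the plausible source of their strong
genome-wide mitonuclear LD — nor mutation, overlapping generations, or
sequence-level reads. Passing calibration tests on simulated data therefore
says nothing about robustness to population structure in real data.

# Study designs and their rationale

The package ships four seeded study runners; the acceptance script and test
suite run them at the sizes below (chosen to complete in minutes on one CPU;
all sizes are arguments).

**Permutation calibration** (`study_permutation_calibration`): 500
exchangeable-null replicates (60 i.i.d. gene values, random class labels),
999 permutations each. Type-I error at α = 0.05 and a KS uniformity check.

**Neutral ANOVA calibration** (`study_neutral_type1`): 200 neutral CALL-like
replicates (n = 100, 46 generations, two 1-Morgan chromosomes, 2,000 AIMs,
407 genes in preset proportions). With ~50 transmitting mothers, drift fixes
the mitochondrial haplotype in roughly half the replicates; D′ and the class
ANOVA are defined only where it still segregates, and the rejection rate is
computed over those replicates — the same rule the pipeline applies.

**Sensitivity under strong selection** (`study_sensitivity`): CALL-like
demography (n = 281, 46 generations) with embryonic-lethal recessive
incompatibilities (s = 1, h = 0, both mitonuclear directions) at 7%, 25% and
50% of 30 interacting genes. These parameters mirror the known biology of
the motivating system (homozygous mismatched genotypes die during
development) and were fixed from that biology. An important dynamical
consequence, documented here because it shapes the results: in a panmictic
population, strong viability selection tied to the mitochondrial background
purges the mitochondrial polymorphism well before 46 generations — symmetric
incompatibilities fix the majority coadapted pair through positive feedback,
and one-sided incompatibilities impose a persistent load on one haplotype
class. Replicates that lose the polymorphism have no defined mitonuclear LD,
so the study reports, per replicate, whether the haplotype still segregates
alongside the ANOVA p-value and the Z > 2 recovery of truly selected genes.
Under panmixia the segregating share at s = 1 is near zero; maintaining both
haplotypes under such selection requires the population structure that this
simulator deliberately does not model.

**Fixed-mitogenome selection response** (`study_fixed_mito`): HUEX-STAC-like
regime (mitogenome fixed, 263 generations, n = 100, six 1-Morgan
chromosomes, 300 genes) with a *weak polygenic* incompatibility
(s = 0.12, h = 0.5) at every interacting gene, paired with neutral runs.
Weak per-locus selection is essential at this genome scale for the class
contrast to exist at all: strong selection at many loci simultaneously (i)
collapses the effective population size through viability load and (ii)
sweeps whole chromosomes by hitchhiking, dragging the non-n-mt background to
fixation along with the selected genes and erasing the class difference.
With weak selection the selected class reaches the posterior-noise ceiling
(a per-gene mean near 0.98 rather than 1.0, set by the Beta emission and the
0.2/0.8 filter) while the background stays below it.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; the gene table is BED-like
  but declares `#coords=1-based-inclusive`.
* The missing sentinel in files is `NA`; `#` lines are metadata.
* Thresholds: filter and call bounds default to 0.2/0.8; values exactly at a
  bound are kept (filter) and called (haplotype calls, `>= hi` / `<= lo`).
* Fewer than 2 pairwise-complete individuals at an AIM, or a monomorphic
  marginal, yields missing statistics; genes whose AIMs are all missing are
  dropped from gene-level tables; a gene class with fewer than 2 genes is a
  hard error for the ANOVA; zero spread across genes is a hard error for
  Z-scores ("degenerate distribution").
* The Z threshold (2) is strict and one-sided; the top-fraction cutoff
  includes ties; sample sd uses n − 1.
* Determinism: every stochastic stage (simulation, emission, permutations)
  derives its stream from the configured seed; identical configurations give
  byte-identical outputs, which the suite verifies on disk.

# Known limitations

* No population structure or migration, as discussed above: the simulator
  cannot reproduce the mechanism that most plausibly sustains genome-wide
  mitonuclear LD in real hybrid zones, and calibration results are
  conditional on panmixia.
* Dosage-scale posteriors: upstream tools that emit genotype-state
  posteriors must be collapsed to a single dosage per marker before
  ingestion; how the original study collapsed states is not specified, and
  the dosage convention here is a documented choice.
* The 0.2/0.8 filter on the dosage scale removes confident heterozygotes;
  this matches the stated filtering rule but discards information at
  intermediate frequencies.
* Small simulated genomes exaggerate linkage: hitchhiking halos around
  selected loci cover a larger fraction of a 4–6 Morgan genome than of a
  real ~25-chromosome genome, which is why the fixed-mitogenome study uses
  weak selection and several chromosomes.
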