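---
title: "Temporal F_ST selection scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal F_ST selection scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A recurring question in invasion genomics is whether the genetic changes
seen in an introduced population reflect adaptation to the new range, or
changes that the native range has been undergoing at the same time.
Comparing only contemporary native and invasive samples cannot separate
the two: both lineages have evolved since they split. Adding a
*temporal anchor* — genotypes from museum specimens collected near the
time and place of the introduction — turns the comparison into a
three-way design in which the direction of change becomes identifiable:

* a SNP strongly differentiated between the two contemporary ranges
  *and* between at least one contemporary range and the historical
  sample has changed in one lineage only (**divergent selection**);
* a SNP differentiated between *both* contemporary ranges and the
  historical sample, but *not* between the contemporary ranges, has made
  the same change on both continents (**parallel selection**).

`temporalfst` implements this design end to end for biallelic SNP
panels (DArTseq/RADseq-style reduced-representation data): input
handling and filtering, per-site and windowed Weir–Cockerham F_ST,
outlier-window selection, outlier classification, chromosome-class
enrichment statistics, and a forward Wright–Fisher simulator of the
whole study so every stage can be validated without access to the
original sequencing data.

# The differentiation statistic

Per site, differentiation between two pools is the Weir–Cockerham
(1984) moment estimator for `r = 2` populations. From per-pool sample
sizes $n_i$ (called individuals), alternate-allele frequencies $p_i$,
and observed heterozygote fractions $h_i$, three variance components
are computed: $a$ (among populations), $b$ (among individuals within
populations), and $c$ (within individuals, $c=\bar h/2$ from *observed*
heterozygosity — no Hardy–Weinberg assumption), giving
$\hat\theta = a/(a+b+c)$. A site is defined only when both pools have at
least two called individuals; sites monomorphic across both pools carry
an undefined $\hat\theta$. Negative estimates are retained, never
clamped: clamping would bias window sums upward.

Windowed values use the conventional **ratio-of-sums**
$\sum a / \sum(a+b+c)$ over the sites in a window, not the mean of
per-site ratios; the two differ whenever site denominators differ, and
the ratio-of-sums is much less sensitive to low-information sites.
Windows are 900,000 bp advanced in 10,000-bp steps (the vcftools
`--weir-fst-pop` windowed layout), so an interior site contributes to 90
overlapping windows. With a few variants per window — the density a
reduced-representation panel gives on a ~1 Gb genome — this smooths
single-site noise while small steps keep breakpoints sharp.

# From windows to outlier SNPs

Per pairwise comparison, windows at or above the 99th percentile
(linear-interpolation quantile, `>=` comparison) of weighted values are
flagged. All SNPs inside flagged windows (deduplicated across
overlapping windows) form the candidate set, whose per-site
$\hat\theta$ values are ranked in decreasing order and cut at a knee.

The knee replaces a by-eye "plateau" judgement and is deliberately
simple and reproducible: rank and value are min–max normalized to
$[0,1]$ and the break point is the point at maximum perpendicular
distance from the chord joining the first and last points. The
threshold is the value at the break's *upper edge*: the break point
itself when it lies above the chord (the end of an initial plateau),
and the preceding rank when it lies below (the first point past a
cliff). Candidates with $\hat\theta$ at or above the threshold become
outliers. Degenerate inputs (fewer than three values, or all equal)
retain everything. A manual threshold can override the knee for
parity with analyst-chosen cuts. Like any elbow heuristic this is a
convention, not an estimator; when the ranked curve has no clear break
the cut is arbitrary within the tail, which is why the neutral
false-positive rate — not the knee itself — is what the validation
battery constrains.

External outlier calls (e.g. a BayeScan run, retained at q-value
$\le$ 0.05) can be imported and pooled with the scan per comparison;
pooled SNPs carry method tags so downstream reports preserve
provenance. The package never recomputes BayeScan's posterior model
comparison.

# Classification

Five comparisons are built from six sampling groups: pooled
contemporary native vs. historical (UK–HS), each invasive
subpopulation vs. historical (AUe–HS, AUs–HS), and pooled native vs.
each invasive subpopulation (UK–AUe, UK–AUs). Classification runs
separately per invasive subpopulation on its triple
(UK–HS, AUx–HS, UK–AUx), assigning each flagged SNP exactly one
category; the full membership-pattern table, in order
(UK–HS, AU–HS, UK–AU), is

| pattern | category |
|---|---|
| 100 | uk_only |
| 010 | au_only |
| 001 | ukau_only |
| 110 | parallel |
| 101, 011, 111 | divergent |

The triple pattern (111) satisfies the divergent rule's conditions and
is excluded from parallel by the "but not divergent between the
ranges" clause, so it is classified divergent. The two subpopulation
maps are then pooled by union, so one SNP can legitimately carry both
a divergent and a parallel pooled label (each from a different
subpopulation). Where a single grouping per SNP is required (the
enrichment test), precedence is divergent > parallel > other selected.

# Chromosome-class statistics

Scaffolds are classed as macrochromosome (autosomal, strictly longer
than 20 Mb), microchromosome, or Z (by designation, overriding
length). Enrichment of SNP groupings (divergent / parallel / other
selected / not selected) across classes uses the plain Pearson
chi-square test of independence on the 4×3 table (df = 6), reporting
Pearson residuals $(O-E)/\sqrt E$ and per-cell shares of the statistic
for mosaic-style display. Expected counts below 5 produce a warning
rather than a switch to an exact test, keeping the test the standard
one.

Two artefact checks accompany the test. Bioinformatic sexing exploits
female hemizygosity on Z: per individual, $F = 1 - H_{obs}/H_{exp}$ is
computed on autosomal and Z polymorphic sites separately, and an
individual is called female when $F_Z - F_{auto} > \delta$. The
threshold $\delta = 0.3$ is a package choice (the quantity compared is
standard; the cutoff is not), sitting far from both modes of the
simulated separation: diploid callers give $F_Z \approx 1$ for females
and $\approx 0$ for males, and with at least 50 called Z sites the
simulator-based check classifies essentially every individual
correctly (fewer than 10 called Z sites yields "unknown"). Second, an
interaction ANOVA asks whether major-allele frequency depends on the
SNP location × selection-status interaction — a signature of
frequency-based artefacts such as hemizygous calling bias. The
interaction is tested by model comparison (additive vs. full linear
model), the unambiguous reading for unbalanced designs, with
$F = ((RSS_{add}-RSS_{full})/1)/(RSS_{full}/(N-4))$.

# The simulator: what it emulates

`simulate_invasion()` is a forward Wright–Fisher simulator of the
study design, not of any particular genome. Defaults encode the study
conditions:

* **Demography.** One ancestral deme (Ne 10,000) sampled at generation
  0 (the museum sample), then three independent lineages for 50
  generations (~150 years at a ~3-year generation time): a native deme
  (Ne 10,000) and two invasive demes founded *independently* from the
  ancestral pool — introductions at different sites drew different
  founders — each by a binomial draw of 2×200 allele copies
  (several hundred introduced individuals) and expanding at Ne 5,000,
  reflecting the rapid post-introduction growth that makes loss of
  common variants by drift unlikely.
* **Sampling.** Six groups: HS = 10 historical; MW, NC, AW = 15 each
  contemporary native; OR = 13 and MV = 15 contemporary invasive. Two
  native labels sample the native deme directly; the third samples a
  5-generation drift replicate, emulating the very weak native-range
  substructure (pairwise F_ST of order 0.001–0.008) without modelling
  migration.
* **Selection.** Genic selection, $p' = p(1+s)/(1+ps)$, with no
  dominance — the simplest model consistent with an
  allele-frequency-shift narrative. Parallel loci feel $s$ in the
  native and both invasive demes; divergent loci in the invasive (or,
  optionally, native) demes only. At selected loci the favoured
  alternate allele founds at the *minor* frequency: selection on
  standing variation favours an allele that then rises, and a
  sustained shift of ≥ 0.4 over 50 generations (the calibration the
  validation battery uses, satisfied by the default $s = 0.1$ for all
  founding frequencies ≤ 0.5) is impossible for an allele founding
  near fixation. This matches the observed pattern of intermediate
  historical frequencies sweeping toward fixation in both contemporary
  ranges.
* **Genome.** An avian-style karyotype of ~1.08 Gb: ten
  macrochromosomes, twelve microchromosomes, one Z (75 Mb). Loci are
  placed uniformly, proportional to scaffold length; 5,040 loci give a
  few variants per 900-kb window, the density the window size was
  designed for.
* **Data artefacts.** Per-call missingness at 0.5 for historical
  individuals (degraded museum DNA) vs. 0.05 for contemporary ones;
  per-call allele-flip error 0.001; females are hemizygous at Z loci —
  drawn haploid and recorded as the corresponding homozygote, exactly
  as a diploid caller would emit them (error flips preserve
  homozygosity).
* **Founding frequencies.** Beta(0.8, 0.8) truncated to [0.05, 0.95]:
  a realistic U-shaped folded spectrum with guaranteed polymorphism.

The random stream is partitioned per stage (demography / genotype
sampling / missingness), so switching missingness off does not perturb
the genotypes, and identical configurations reproduce identical VCF
fixtures byte for byte (modulo the file-date header).

What the simulator deliberately does **not** emulate: linkage (loci are
independent — there are no multi-SNP sweep regions), mutation during
the simulated period, read-level artefacts (no FASTQ), reference bias,
and the RAD-tag structure of real reduced-representation data (no
"one SNP per tag" semantics). Passing recovery tests therefore show
that the pipeline detects *isolated* strongly selected SNPs under
museum-grade missingness; on real data, hitchhiking makes selected
regions multi-SNP targets that windowed scans find more easily, so the
simulation is conservative in that one respect.

# Filtering and numerical choices

* Coordinates are 1-based inclusive (VCF convention) everywhere,
  including window arithmetic.
* Site filters: call rate ≥ 0.9, pooled minor-allele frequency
  ≥ 0.025, and a Hardy–Weinberg exact-test p ≥ 0.001 computed by full
  conditional enumeration. MAF and HWE are computed on pooled samples
  (the combined file is filtered before splitting). The HWE rule is a
  switch: on for the population-structure path, where non-neutral loci
  distort structure estimates, and off for the selection path, which
  would otherwise discard its own signal.
* Comparison files keep sites called in ≥ 5 individuals per pool (half
  of a ten-specimen museum series, and the matching contemporary
  floor) with pooled MAF ≥ 0.025 after restriction. Missing calls
  never enter allele counts.
* Multi-locus pairwise F_ST significance: the bootstrap resamples
  *loci* with replacement and reports the fraction of replicates with
  estimate ≤ 0 — a one-sided test that differentiation exceeds zero.
  The number of replicates trades precision for time (default 200 in
  the pipeline; the floor of the attainable p-value is 1/n_boot).
* Nei's (1972) standard distance at identity $I = 0$ returns `+Inf`
  rather than erroring, so distance matrices remain constructible;
  the neighbour-joining builder rejects non-finite matrices.
  Neighbour joining clamps negative branch lengths to zero, moving the
  excess to the sister branch so path lengths through the parent node
  are preserved.
* PCA standardizes each site by $\sqrt{\hat p(1-\hat p)}$ and imputes
  missing calls with the site mean (zero after centring) — the
  standard genotype-PCA construction; monomorphic sites are dropped.

# Validation battery and its outcome

The test suite validates every stage against independent oracles
(brute-force transcriptions of the F_ST and HWE formulas, closed-form
NJ and ANOVA cases, exhaustive classification patterns) and runs an
end-to-end recovery experiment: 5,000 neutral + 20 parallel + 20
invasive-divergent loci, historical missingness 0.5, five replicate
invasions (seeds 1–5), full pipeline, then comparison of pooled labels
against the simulator's truth table.

Under these conditions the false-positive bound is comfortable (well
under 1% of neutral loci flagged, against a 2.5% bound) and parallel
recovery averages just above one half. Divergent recovery averages
just *below* one half (0.48 on seeds 1–5; ≈0.49 over 20 seeds), and
the corresponding assertion in the acceptance tests fails by that
margin. This is a structural property of the design, not a bug: a
divergent label requires a locus to (i) survive the selection-file
floor of ≥ 5 called historical individuals — under 50% per-call
missingness over 10 specimens this retains only ~62% of loci — and
(ii) clear the top-1%-of-windows scan in two comparisons whose window
values are diluted by the same neutral neighbours, capping conditional
capture near 80%. The product sits at ≈0.5. With real, linked sweep
signals (or more museum specimens) capture rises; with independent
single-SNP signals this is the honest power of the method at these
settings, and we report it rather than recalibrate around it.

# Known limitations

* Independent loci only; no LD-aware deduplication of nearby outliers.
* The knee threshold is a convention standing in for expert judgement;
  per-comparison manual thresholds are supported for that reason.
* BayeScan-style imports are trusted at face value (q-values are not
  recomputed).
* Relatedness filtering and ancestry modelling (ADMIXTURE-style) are
  out of scope; remove related individuals upstream.
* The sexing rule assumes a ZW system with diploid-coded hemizygous
  calls; it will misbehave on XY systems or haploid-aware callers.
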