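---
title: "Dosage-quotient CNV calling for MLPA pharmacogene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-quotient CNV calling for MLPA pharmacogene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpacnv)
```

## The measurement model

MLPA quantifies relative DNA copy number at ~40–60 targeted loci. Each probe
ligates only on its intact target and is then amplified with universal
primers, so the fluorescence peak height of probe $p$ in sample $s$ is, to
first order,

$$h(s,p) \;=\; c_s \cdot \beta_p \cdot \frac{n(s,p)}{2} \cdot \varepsilon,$$

where $c_s$ is a sample-wide intensity factor (DNA input, injection
efficiency), $\beta_p$ a probe-specific amplification factor, $n(s,p)$ the
copy number of the target region, and $\varepsilon$ multiplicative noise.
Neither $c_s$ nor $\beta_p$ is of interest; two normalizations cancel them.

**Intra-sample** (`intra_sample_normalize()`): divide every height by the
median height of the sample's reference probes — probes on regions assumed
copy-number stable. This cancels $c_s$ exactly, which is why the pipeline is
invariant to rescaling a sample's entire peak vector (a tested property).
The median rather than the mean is used so that a single aberrant reference
probe cannot shift the scale; the mean is available via `stat = "mean"`.

**Inter-sample** (`inter_sample_normalize()`): divide each relative signal by
the arithmetic mean of the relative signals of designated *reference samples*
at the same probe. Reference samples are assumed diploid at every target, so
this cancels $\beta_p$ and leaves the **dosage quotient**
$\mathrm{DQ}(s,p)$ with $E[\mathrm{DQ}] = n(s,p)/2$. When no reference
samples are designated the package falls back to normalizing against the
median of the whole cohort, with a loud warning: that is only valid when most
samples are diploid at most probes, which fails badly for genes like *GSTM1*
where homozygous deletion can be the modal genotype.

## Classification and gene-level calls

`classify_dq()` applies the canonical DQ bands for a diploid locus
(homozygous deletion at DQ below 0.10; heterozygous deletion in (0.40, 0.65);
normal in (0.80, 1.20); heterozygous duplication in (1.30, 1.65); homozygous
duplication in (1.75, 2.15); everything else ambiguous). Three numerical
choices matter:

* **Endpoints are ambiguous.** The defining inequalities are strict, so the
  eight interval endpoints classify as AMBIGUOUS. This is pinned by tests.
* **The homozygous-deletion tolerance.** The nominal rule is DQ = 0, which no
  noisy measurement attains; `hom_del_eps = 0.10` accepts DQ below 0.10 as
  zero copies. Values in [0.10, 0.40] stay ambiguous. The tolerance is a
  configurable argument of `dq_thresholds()`.
* **Zero stays zero.** A zero peak height propagates to DQ 0, never NaN;
  division is guarded only at the reference aggregate, where a zero aggregate
  marks the probe uncallable (`NA`) for the batch.

`call_gene()` aggregates exon probes: any deleted/duplicated exon marks the
whole gene, consistent with whole-gene CNV mechanisms in these loci. Two cases
the rule itself does not settle are resolved as follows: probes of one
direction but mixed zygosity take the more extreme class (a HOM_DEL exon
beside a HET_DEL exon reads as homozygous deletion), and probes in opposite
directions make the gene discordant with genotype `Unknown` rather than
forcing a call. Ambiguous probes are ignored whenever a sibling probe is
called; a gene with only ambiguous probes is ambiguous and drops out of
frequency denominators (exclusion counts are reported by
`genotype_frequencies()`).

## Cohort statistics

Allele frequencies use gene counting on called diplotypes:
$p_{del} = f(\mathrm{Del/Del}) + f(\mathrm{Del/Wt})/2$ and symmetrically for
duplications. The 14-category mutational-status taxonomy is a pure function of
the *set* of non-normal gene-level classes in a sample; two of its printed
definitions ("homo and heterozygous deletions", categories 4 and 7) are
textually indistinguishable, so the classifier emits 4 and documents 7 as
unreachable, and the three class sets with no printed definition (e.g.
{heterozygous deletion, heterozygous duplication} alone) return category 0
with the set recorded. The four carrier groups (deletions only, duplications
only, both, none) partition the cohort, and "none" coincides with category 1
by construction — both facts are property-tested.

`sample_size()` implements Cochran's formula with optional finite population
correction; at the conventional 95% confidence with anticipated proportion 3%
and margin 3% it returns 125, the design size of the reference cohort.

## The bundled reference cohort

The package embeds the per-gene CNV genotype percentages observed by this
panel in 123 healthy individuals of Colombian origin — the cohort whose
printed tables are the only available record (no per-sample data were
deposited). `reference_genotype_counts()` recovers integer counts by
largest-remainder apportionment at $n = 123$: every column then sums to 123
and every count sits within half a rounding unit of its printed percentage.
All published per-gene quantities (allele frequencies, carrier percentages,
the 13/14-gene census) follow from these counts and are recomputed, not
stored, by `scripts/acceptance.R`. Joint per-individual quantities (category
percentages, carrier-group fractions, the *GSTM1*×*GSTT1* double-deletion
rate) are **not** reproducible from printed marginals — they depend on the
unpublished joint genotypes — so tests cover their structural invariants
(partition, sum to one) instead of their values.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws each gene's two alleles i.i.d. from
$(p_{del}, p_{wt}, p_{dup})$ — random mating, genes independent. The defaults
are the reference cohort's allele frequencies, i.e. the study conditions the
package is validated under. `simulate_from_genotype_table()` instead draws
diplotype labels directly from a genotype table (multinomially, or exactly by
largest remainder), which preserves departures from Hardy–Weinberg such as the
strong homozygote excess at *GSTM1*.

`peaks_from_truth()` applies the linear dosage law with log-normal
multiplicative noise per probe (`noise_cv`, default 0.05) and per sample
(`sample_scale_cv`, default 0.10), both unit-mean; fluorescence is positive
and heteroscedastic, and no error model was published, so log-normal CVs are
the generator's parameterization, not estimates. `base_height` (default 1000
fluorescence units) is the two-copy expectation. Zero-copy targets emit
exactly zero — no additive background — so the homozygous-deletion class is
reachable. Q-fragments are emitted at 15% of the reference level scaled
inversely with `dna_quantity`; D-fragments and the X-fragment at the reference
level; the Y-fragment at the reference level for XY samples and zero for XX
(sex simulated with `p_female = 0.58`, the reference cohort's composition).
QC thresholds (`q_max = 0.33`, `d_min = 0.40`, `y_min = 0.30` of the
reference-probe level) are package defaults, configurable; the control
fragments' roles are standard but no cutoffs were published.

Not emulated: electropherogram traces, stutter/pull-up artifacts, GC- or
length-dependent amplification bias, batch effects, SNVs under ligation
sites, and between-gene correlation of CNVs. Passing tests therefore
demonstrate correctness of the arithmetic and robustness to multiplicative
noise — not robustness to every artifact of real capillary data.

## Validation design and problem sizes

The suite checks, among others: exact equality $\mathrm{DQ} = n/2$ on
noise-free simulations end to end; scale, permutation and
reference-duplication invariance; exhaustiveness and monotonicity of the
classifier over a fine DQ grid; recovery of generating allele frequencies
within three binomial standard errors at 5% noise ($n = 500$, deletion allele
frequencies 0.05, 0.30, 0.476) with genotype concordance ≥ 99%; and exact
reproduction of the reference cohort's allele-frequency table from its
genotype table at one decimal. Simulation sizes (200 noise-free samples, 500
noisy samples, 10,000 for the binomial-oracle check of the allele sampler)
keep the full suite around ten seconds while leaving the stochastic assertions
far from their tolerance boundaries.

## Known limitations

* **Del/Dup blindness.** A 0 + 2 diplotype has total dosage 2 and is called
  Wt/Wt. This is a property of total-dosage assays, asserted in tests as the
  expected outcome. Consequently allele-frequency estimates are biased toward
  wild type at genes where deletions and duplications both segregate.
* Duplications of inactive alleles cannot be distinguished from duplications
  of active ones, so `predict()`'s metabolizer phenotypes are
  copy-number-only predictions and are flagged as such.
* CNVs outside the probed exons are invisible; hybrid-gene rearrangements
  (e.g. *CYP2D6/2D7* fusions) are out of scope.
* Hardy–Weinberg equilibrium testing is not implemented (an extension point).
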