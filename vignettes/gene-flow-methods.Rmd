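---
title: "Detecting gene flow in a four-taxon quartet: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene flow in a four-taxon quartet: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetflow)
```

## The problem and the model

Given one genome each for three ingroup taxa H1, H2, H3 and an
outgroup, incomplete lineage sorting (ILS) makes some genomic regions
of H1 or H2 group with H3 even when the species tree is
((H1, H2), H3). ILS alone is symmetric: derived alleles shared by H2
and H3 ("ABBA" sites) and by H1 and H3 ("BABA" sites) are equally
frequent in expectation. Post-divergence gene flow between H3 and one
ingroup taxon breaks that symmetry. `quartetflow` tests for the
asymmetry with Patterson's D,

$$D = \frac{\sum \text{ABBA} - \sum \text{BABA}}
           {\sum \text{ABBA} + \sum \text{BABA}},$$

and localizes and sizes it with the windowed admixture statistic
f_dM. Sites are polarized by the outgroup allele (taken as ancestral);
each site contributes frequency weights
$w_\text{ABBA} = (1-p_1)p_2p_3$, $w_\text{BABA} = p_1(1-p_2)p_3$,
$w_\text{BBAA} = p_1p_2(1-p_3)$, where $p_i$ is the fraction of taxon
$i$'s alleles that are derived (0/0.5/1 for one diploid individual,
0/1 for a haploid call).

Assumptions worth keeping in mind: the outgroup allele is ancestral
(violated at sites where the outgroup lineage itself mutated —
partially diagnosed by the tri-allelic test below); no recurrent
mutation at biallelic sites; a single individual per taxon represents
its lineage (population structure can mimic gene flow); and windows
are long enough (5 Mb) that the block jackknife sees approximately
independent blocks.

### f_dM and its haploid-mode behaviour

For a window, the frequency-mode f_dM is $S/S_D$, where
$S = \sum_i [(1-p_1)p_2p_3 - p_1(1-p_2)p_3]$ and the denominator
re-evaluates the same sum with the dynamic donor frequency
$p_D = \max(p_2, p_3)$ substituted into both donor slots; when $S < 0$
the roles of H1 and H2 are exchanged and the sign flipped. This keeps
f_dM on $[-1, 1]$, antisymmetric under the H1/H2 swap, positive for
H2–H3 sharing.

When every individual contributes exactly one nucleotide per site
(haploidized X data, or homozygous-only autosomal calls), the counts
are integers and the package reports f_dM = window D (`"haploid"`
mode). The literature frequency formula does not reduce to D in this
case, but the single-nucleotide-per-site convention is the one under
which the genome-wide statistics of this kind are conventionally
reported, and it is what our worked examples anchor to; `mode =
"auto"` (the default) selects haploid mode exactly when all
frequencies are 0/1, and both modes are available explicitly.

### Weighted block jackknife

Genome-wide significance uses delete-one-block resampling over the 5
Mb windows, weighted by each window's ABBA + BABA sum (its
informativeness), with the weighted delete-$m_j$ variance of Busing et
al. (1999). Two design choices were genuinely open:

* **What is jackknifed.** We jackknife the ratio of sums (the pooled
  numerator and denominator re-summed after each block deletion)
  rather than a weighted mean of per-window values. This is the
  standard construction for ratio statistics, keeps the genome-wide
  estimate identical to the one computed from pooled totals, and
  avoids instability from low-weight windows' noisy ratios. For
  frequency-mode f_dM the sign branch of the denominator is fixed by
  the full-data numerator, so block deletion cannot flip it.
* **Interval scale.** CIs are normal ($\pm 1.96$ SE), matching the
  symmetric intervals conventionally reported. With ~20 blocks the
  Z statistic is slightly heavy-tailed (t-like with n−1 df), which is
  visible in our null calibration: 95% CI coverage in 200 null
  replicates is ~94%, and |D| < 3·SE holds in ~98–99% of seeds rather
  than the normal-theory 99.7%.

### The tri-allelic rate test

A derived allele shared by all three ingroup taxa (BBBA) can mutate
again: in H1 (CBBA), in H2 (BCBA), or before the H1/H2 split (CCBA,
three segregating alleles). If H1 and H2 evolve at equal rates, CBBA
and BCBA counts have equal expectation, so an exact two-sided binomial
test (BCBA successes out of CBBA + BCBA at p = 0.5) tests for a
lineage rate difference — relevant because roughly one in three
"C" mutations reverts to the ancestral base and would inflate D
without any gene flow. Classification uses the majority allele per
taxon; a 50/50 heterozygote in any taxon is a tie and the site is
classified `other`.

## Filters and X-chromosome handling

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_depth` | 5 | reads | calls below 5X are unreliable; set to missing |
| `indel_buffer` | 3 | bp | alignment artefacts cluster around indels |
| `het_buffer` | 3 | bp | same logic around male pseudo-het sites |
| `par_boundary` | 403,495 | bp (X pos) | pseudoautosomal boundary of the rhesus X assembly used as mapping reference |
| `window_bp` | 5,000,000 | bp | long enough to decorrelate blocks, short enough for ≥20 blocks |

Males are hemizygous on the non-pseudoautosomal X, so an apparent male
heterozygote there is an artefact (mismapped Y reads or genotyping
error). The package (i) tabulates het sharing across samples on the
non-PAR X — artefactual male hets tend to be shared between males,
real female hets tend to be private — and (ii) haploidizes X calls by
depth: the allele with the higher allele depth (AD) is kept, exact
ties are broken by a seeded uniform draw. The tie RNG runs in its own
seeded stream so unrelated randomness never perturbs haploid calls.
Two X modes exist because both are analytically defensible:
`haploid-all` (default; both sexes haploidized, giving strictly
one-nucleotide-per-site X data) and `haploid-males-diploid-female`
(keeps real female heterozygosity at the cost of mixed ploidy). The
optional female-het exclusion mirrors the male one as a conservative
variant. The PAR boundary site itself is placed in the PAR (the
boundary is approximate; it is exposed as configuration), and PAR
sites are excluded from X gene-flow statistics.

Coordinates: genotype tables use 1-based VCF positions; interval masks
use 0-based half-open BED intervals, normalized through IRanges, with
the conversion localized and tested once.

## Divergence

Pairwise divergence is the average per-site percent nucleotide
difference over all ordered allele pairs of the two individuals (4
pairs for diploid–diploid, 2 for diploid–haploid, 1 for
haploid–haploid), over sites where both are called after filtering —
that denominator choice is logged explicitly in the result. It is
uncorrected by default; Jukes–Cantor correction
($d = -\tfrac34\ln(1-\tfrac43\hat p)$) is a flag, never a default.
"Conditional" divergence attaches, per window, d(H2,H3) when f_dM > 0
and d(H1,H3) when f_dM < 0: introgressed windows should sit closer to
the donor.

## The synthetic generator

The generator is a categorical site-pattern model, not a coalescent:
each site independently draws a topology class — with probability
$\gamma$ the introgressed history (H2 with H3), otherwise the species
history, and within each history ILS randomizes the grouping over the
three topologies with probability $\rho$ (species) or $\rho_I$
(introgressed). This gives the closed form

$$E[D] = \frac{\gamma(1-\rho_I)}
             {\gamma(1-\rho_I) + \tfrac23[(1-\gamma)\rho + \gamma\rho_I]},$$

so recovery tests compare realized statistics against an exact
expectation instead of a second simulation. Defaults describe a
deep-coverage three-genome study: mean depth 40X (negative binomial,
size 10), 5X filter threshold, male pseudo-het rate 0.0005 on the
non-PAR X (matching the ~0.05% observed in male macaque X data),
female het rate 0.001 (hets are about twice as frequent in the female
as pseudo-hets in the males), 0.2% missing calls, ILS fractions
$\rho = \rho_I = 0.3$, tri-allelic rate 0.01 (tri-allelic sites are
roughly 1% of informative sites in the macaque data) and BBBA rate
0.05. An optional block mode (`intro_window_frac`) confines $\gamma$
to a random subset of windows, producing the window-level
heterogeneity that the conditional-divergence display and the
jackknife-under-autocorrelation behaviour need; a full coalescent
backend could be slotted in by any generator that fills the same
genotype-table contract.

What the generator does **not** emulate: linkage within windows
(sites are i.i.d. except in block mode), recombination-rate and
mutation-rate variation, real base composition, indels and repeats
(filter tests build those fixtures directly), reference bias, and
autosomal heterozygosity (autosomal calls are homozygous, so
frequency-mode weights are only exercised by X female hets and by
hand-built fixtures). Passing tests therefore validate the
statistical machinery, not the robustness of D/f_dM to those real-data
complications.

## Numerical and degenerate-input choices

* Window tiling is anchored at position 1 of each chromosome; the last
  window may be short. Empty windows are omitted from output.
* D and f_dM with a zero denominator are `NA` and flagged, never 0;
  zero-weight windows are dropped from the jackknife with a message;
  fewer than two usable blocks is an error.
* f_dM values outside $[-1, 1]$ (possible only through floating-point
  pathology) are clamped with a warning.
* Haploidization refuses to run without allele depths rather than
  silently guessing, and never emits an allele absent from the diploid
  call.
* A heterozygous outgroup call makes a site unpolarizable (counted in
  a skip log) rather than half-weighted: the ancestral state is simply
  unknown there.
* Sites with more than three segregating alleles are unusable; sites
  where the outgroup carries a third allele relative to an ingroup
  biallelic pair are excluded from biallelic weights but remain
  eligible for CCBA classification.
* Because one diploid individual yields integer autosomal counts only
  under a counting convention, both a frequency-weighted mode (the
  default) and a hard-call majority mode (skipping 50/50 ties) are
  provided for the window tallies.

## Problem sizes used by the test suite

The suite validates the stack at sizes chosen to give tight
statistical checks while staying quick on one core: 200 null
replicates of 10^5 sites in 20 blocks for CI calibration (the
block-level fast path through the same categorical model), 10^5 sites
per point for the $\gamma$ response curve, 2×10^5 X sites for
error-rate recovery, and a few thousand fully rendered genotype sites
for end-to-end pipeline runs. Each check states its tolerance in
statistical terms (binomial bounds, 3 Monte-Carlo SEs, or exact
equality for deterministic quantities).

## Known limitations

* One individual per taxon: no population allele frequencies, no
  D extensions to more taxa (D_FOIL, f-branch), no dating of the
  gene-flow event.
* The divergence denominator (jointly called, filter-surviving sites)
  makes divergences comparable within an analysis but not across
  different filter settings.
* The generator's closed-form expectation applies to the categorical
  model; data with linkage will show wider jackknife scatter than the
  i.i.d. theory suggests — which is precisely why the block jackknife,
  not a binomial SE, is used on real data.
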