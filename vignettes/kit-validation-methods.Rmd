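---
title: "Validation metrics and kinship statistics for supplementary STR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation metrics and kinship statistics for supplementary STR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinstr)
```

## Scope

`kinstr` implements the analysis side of an internal validation study for a
multiplex autosomal STR genotyping kit used as a *supplement* to standard
CODIS/ESS panels in complex kinship casework, together with the
population-genetic and kinship statistics such studies report. Because raw
validation data (per-sample electropherograms and population genotype
tables) are essentially never deposited, the package pairs every analysis
stage with a seeded synthetic-data generator that reproduces the
statistical structure those analyses assume. The generator is first-class,
tested code: it is what makes every downstream stage verifiable end to end.

The pipeline covers six areas: the panel/locus data model and table I/O;
synthetic populations and peak tables; kit performance metrics
(completeness, peak balance, stutter, sizing, ladder coverage,
concordance); forensic identity and paternity statistics; the exact
Hardy-Weinberg test; and linkage analysis of syntenic locus pairs.

## Panel model and bundled fixtures

A `kit_panel` is an ordered set of `locus_def` objects: chromosome, dye
channel, fragment-size window, allelic-ladder alleles with nominal
("actual") sizes, an optional cumulative genetic-map position, and aliases.
Allele labels are strings (`"11.3"`), compared only after parsing into
(repeat count, partial nucleotides) pairs — floating-point comparison of
labels is deliberately impossible. The loader corrects the superseded
D5S2500 locus name to D5S2800, recording the old name as an alias, and
alias resolution is idempotent, so re-loading a written panel is identity.

The bundled 23-marker panel fixture (22 autosomal STRs plus amelogenin)
carries the published chromosome assignments and cumulative map positions.
Its ladder "actual sizes" are **synthetic placeholders**: the manufacturer
values are not published, so sizes sit on a consistent grid (window minimum
plus 6 nt anchor, 4 nt per repeat, 1 nt per partial-repeat step). Every
metric that consumes sizes (precision, accuracy, binning) is exact relative
to this grid, which is all the analyses require. Two locus-map fixtures
(the 21 reference-kit autosomal STRs, and Penta D/E) support the combined
38-locus linkage work. Amelogenin is carried in the panel but excluded from
every statistic; population work uses autosomal loci only.

## The synthetic electropherogram model

The generator's defaults are the study conditions; they are not tuning
knobs. Its signal model is copy-number driven:

* **Template.** At template mass $m$ pg, each allele of a heterozygote
  contributes $c = m / 6.6$ effective genome copies (3.3 pg per haploid
  copy); a homozygote contributes $2c$.
* **Degradation.** Copies are attenuated by $\exp(-k\,(s - 80))$ for
  amplicon size $s$ nt, with $k = \log(\mathrm{DI})/140$ so that the
  degradation index equals the 80 nt / 220 nt signal ratio — mirroring the
  small/large autosomal quantitation targets used to measure DI in
  casework. An `efficiency` multiplier stands in for PCR inhibition; no
  inhibitor chemistry is modelled.
* **Peak height.** A peak is Gamma-distributed with shape equal to its
  effective copy number and a fixed scale of `rfu_per_copy` (default 12
  RFU). Shape proportional to copies is the key design choice: the
  coefficient of variation grows as template falls, which is what produces
  stochastic dropout at low template while leaving high-template peaks
  tight. A fixed-shape model cannot be calibrated to show both complete
  profiles at 125 pg and substantial dropout at 31 pg, because its mean
  scales linearly while its relative noise stays constant. A fixed or
  infinite `height_dispersion` override restores the fixed-shape (or
  noise-free) limit for exact tests.
* **Heterozygote imbalance.** The expected ratio of the longer to the
  shorter allele's peak is $\exp(-\lambda \Delta)$ for allele size
  difference $\Delta$ nt, the shorter amplicon taking the larger share
  (degradation-consistent). Default $\lambda$ is set per locus so the
  expected peak-height ratio is ~45% at $\Delta = 50$ nt for D21S2055 —
  the longest, most imbalance-prone marker, with the widest allele range —
  and ~90% at a typical two-repeat difference elsewhere.
* **Stutter.** One back-stutter peak per true allele, one repeat unit
  below its parent, with per-peak ratio drawn from a normal truncated at
  zero around the locus's expected ratio. Locus defaults span 3.8%
  (D2S441) to 16.15% (D12S391) with a grand mean near 9.2%, the range
  reported for tetranucleotide multiplexes. Only the $n-1$ stutter class
  is modelled. A stutter product landing on a true allele is added to that
  allele's peak rather than listed separately.
* **Sizing.** Observed size = nominal size + Gaussian noise (default s.d.
  0.05 nt, the mid-range of per-allele sizing s.d. values seen on
  capillary instruments; reported maxima are near 0.10 nt).

With these defaults and 50/150 RFU heterozygote/homozygote thresholds, the
dilution series 500/250/125/62/31 pg gives mean completeness of 100% down
to 125 pg, ~98% at 62 pg and ~55% at 31 pg: complete profiles well below
the recommended input, with a stochastic dropout zone at the bottom —
the qualitative sensitivity pattern such validations report. Per-allele
dropout probabilities under the default model are ~1e-7 at 125 pg and
~2e-66 at 500 pg.

Allele frequencies come from symmetric Dirichlet draws over each locus's
ladder alleles (spiky, realistic spectra at small concentration; exactly
uniform at `Inf`), genotypes from Hardy-Weinberg proportions with optional
inbreeding $F$, and an optional forced linkage-disequilibrium pair draws
two-locus genotypes from haplotype frequencies deviating by $D$ on the
most-frequent-allele pair (the deficit spread proportionally so both
margins are preserved; infeasible $D$ errors out). All randomness flows
from a single integer seed; derived per-replicate seeds keep dilution
series reproducible element-wise.

What the generator does **not** emulate: mixtures, pull-up/spike
artefacts, baseline noise, forward stutter, Y/X markers beyond a static
amelogenin entry, and inhibitor chemistry beyond a scalar efficiency.
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to every artefact class of real
casework data.

## Kit performance metrics

Calling re-implements the genotyping-software contract: peaks are binned
to the nearest ladder allele within ±0.5 nt (off-ladder otherwise),
stutter-filtered (a peak one repeat below a neighbour and below 20% of its
height is removed — the maximum locus stutter ratio plus margin), then
thresholded. A single peak between 50 and 150 RFU is left uncalled with a
`possible_dropout` flag rather than forced homozygous: the conservative
validation-practice reading, since the sister allele may have dropped.
More than two surviving peaks flags the locus and leaves it uncalled;
mixture interpretation is out of scope. Peaks outside their locus window
are flagged, and flagged again as collisions when they land inside another
same-dye locus's window — the misassignment risk that motivates
re-running undesignated alleles.

Completeness is reported under both homozygote conventions — one distinct
allele (the merged-cell convention of dilution figures) and two allele
copies — because published "profile percentage" denominators are
ambiguous. Peak balance uses $\mathrm{PHR} = 100\,\min(h_1,h_2) /
\max(h_1,h_2)$; the balance-versus-size-difference curve averages PHR over
genotypes sharing a size difference and smooths with a centred moving
average (window 5 grid points — published smoothers for such curves are
typically unnamed, and nothing downstream depends on the choice). Dye
balance uses mean total locus heights (lowest/highest within a dye,
and across dye means), the estimator being unstated in guidelines that
only give thresholds. Stutter ratios exclude positions shared with a true
allele to avoid inflation. Sizing precision is the per-allele sample s.d.
($n-1$ denominator) excluding single-observation alleles; accuracy is the
deviation of mean observed size from nominal size, flagged at ±0.5 nt
(outside the bin).

## Identity and kinship statistics

Per locus, with observed genotype proportions $f_g$, allele frequencies
$p_i$, heterozygosity $h$ and homozygosity $H = 1-h$:

* match probability $\mathrm{MP} = \sum_g f_g^2$ (observed proportions,
  matching the behaviour of the forensic summary software these studies
  use; an HWE-expected mode is available),
* power of discrimination $\mathrm{PD} = 1 - \mathrm{MP}$,
* power of exclusion $\mathrm{PE} = h^2(1 - 2hH^2)$,
* typical paternity index $\mathrm{TPI} = 1/(2H)$ (infinite with a warning
  when no homozygotes are observed),
* $\mathrm{PIC} = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$.

Combined indices multiply across loci in log10 space (combined match
probabilities reach 1e-27 scale; naive products underflow), and reports
carry both log10 and "1 in X" forms. The theoretical most common profile
assumes heterozygosity: per locus $2 p_{(1)} p_{(2)}$ over the two highest
frequencies, ties broken by allele order. The posterior probability of
paternity is $W = \mathrm{CPI}\cdot\mathrm{Pr} /
(\mathrm{CPI}\cdot\mathrm{Pr} + 1 - \mathrm{Pr})$, formatted as a
percentage to 8 decimals with half-up rounding, the convention of
paternity reports. Pairwise matching counts, for every sample pair, loci
with identical unordered genotypes and loci sharing at least one allele.

## The exact Hardy-Weinberg test

Conditioning on allele counts $m_i$, a genotype table $\{n_{ij}\}$ has
probability

$$P(T) = \frac{N!}{\prod_{i \le j} n_{ij}!}\; 2^{n_{het}}\;
\frac{\prod_i m_i!}{(2N)!}$$

and the exact p-value sums $P(T)$ over tables no more probable than the
observed one. Two routes are implemented. The exhaustive route enumerates
all tables with the given margins (feasible for small $k$, $N$; the
enumeration checks that probabilities sum to 1 as a built-in self-test)
and is the oracle. The Markov-chain route targets $P(T)$ with degree-2
switch proposals: an ordered allele quadruple $(i_1, j_1, i_2, j_2)$ drawn
uniformly on $\{1..k\}^4$ proposes $n_{i_1 j_1}{-}{-},\; n_{i_2
j_2}{-}{-},\; n_{i_1 j_2}{+}{+},\; n_{i_2 j_1}{+}{+}$, which preserves
every allele count; each forward quadruple has a unique equal-probability
reverse, so the proposal is symmetric and Metropolis acceptance
$\min(1, P'/P)$ suffices, with reverse moves giving irreducibility for
$k \ge 3$. Defaults are 1,000,000 chain steps after 100,000
dememorization steps — the conventional settings for this test in
population-genetics software — and both are overridable.

Numerical choices: log-factorials are precomputed (no bignum arithmetic);
the chain tracks only log-probability differences and re-derives the exact
value every 10,000 steps so float drift cannot swamp the tie rule; ties
$P(T) \le P(\mathrm{obs})$ are accepted within 1e-9 on the log scale
(befitting the 1e-12-relative spirit of the tie tolerance while staying
above accumulated drift); the Monte-Carlo standard error comes from 100
batch means, which absorbs chain autocorrelation. A chain that never
visits a table at or below the observed probability would report $p = 0$;
since the estimator's resolution is $1/\mathrm{steps}$, the result is
floored there and flagged instead — an exact zero is not a statement the
chain can make.

## Linkage: map distances, haplotype frequencies, disequilibrium

Kosambi's map function converts genetic distance to recombination
fraction, $r = \tfrac12\tanh(2d)$ with $d$ in Morgans, and back via
$d = \tfrac14\ln\frac{1+2r}{1-2r}$; syntenic pairs ~50 cM or more apart
are effectively unlinked ($r \to 0.5$). Pair distances are absolute
differences of cumulative map positions; reported fractions are rounded
half-up to 4 decimals, matching reference-table formatting. Syntenic
enumeration lists all unordered same-chromosome pairs: 18 for the combined
38-locus set (21 reference + 17 non-CODIS supplementary loci). Adding
Penta D/E creates three more same-chromosome pairs; published tables of
this combination list only the two involving the supplementary panel
(PentaE-D15S659, PentaD-D21S2055), omitting D21S11-PentaD, whose
recombination fraction was already established by family studies. The
`exclude_pairs` argument reproduces that 20-row table view; the
enumeration itself stays complete. Chromosome-arm assignments are
annotation only and are not modelled.

Haplotype frequencies for unphased two-locus genotypes come from EM: only
double heterozygotes are phase-ambiguous, and the E-step splits them by
current haplotype-frequency odds. The number of EM starting conditions
defaults to 2 — the widely used setting in population-genetics software
(interpreted here as starting conditions: the first start is the
linkage-equilibrium point, further starts are random) — and the
log-likelihood is asserted non-decreasing at every iteration. The LD test
statistic is $G = 2(\log L_{EM} - \log L_0)$, with $L_0$ evaluated at
products of observed allele frequencies ($G \ge 0$ by construction since
EM starts there). Because phase is unknown, the null is a permutation
distribution: locus-B genotypes are shuffled across individuals 1000 times
(default) and the p-value is $(1 + \#\{G_{perm} \ge G_{obs}\})/(1 + B)$
— the validity-preserving estimator, never exactly zero, a deliberate
divergence from software that reports $p = 0$. Individuals uncalled at
either locus are dropped pairwise. Bonferroni thresholds are $\alpha/k$,
reported also at 3 decimals (0.05/18 = 0.00278, reported 0.003).

## Problem sizes and tolerances in the test suite

The suite verifies: exact worked examples (hand-enumerated HWE tables,
closed-form statistics on 4-sample genotype tables, reference-table
Kosambi fractions to 4 dp, paternity posteriors to 8 dp); chain-vs-
enumeration agreement within 3 Monte-Carlo standard errors on randomized
margins with $k \le 4$, $N \le 20$; type-I error within [0.02, 0.08] at
$\alpha = 0.05$ for the HWE chain (400 null datasets, 500 individuals, 8
alleles, 12,000-step chains) and the LD permutation test (300 null
datasets, 200 individuals, 199 permutations); generator parameter recovery
on a 500-sample population (stutter ratios ±0.01 absolute, sizing s.d.
±15% relative, imbalance decay ±20% relative, disequilibrium coefficient
±0.02 at n = 1000); combined-index identities to 1e-12; and
dilution-series monotonicity with full profiles at 125 pg over 100
replicates per level. These sizes were chosen to keep each Monte-Carlo
bound several standard errors away from its pass boundary while the whole
suite stays comfortably inside a few minutes on one core.

## Known limitations

The statistics assume unrelated individuals and no population
substructure: no theta/F_ST correction enters the match probability, and
paternity indices are mutation-model-free — both standard extensions this
package deliberately leaves out. Kinship likelihoods for arbitrary
pedigrees, and the incorporation of recombination fractions into kinship
likelihood ratios, are out of scope (syntenic-pair reporting supplies the
inputs those methods need). The exact test is two-sided by table
probability only; heterozygote-excess one-sided variants are not provided.
Allelic ladders and bins are taken from the panel definition; no
chromatogram-level (.fsa/.hid) parsing is attempted.
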