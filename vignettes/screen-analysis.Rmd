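---
title: "Modelling pooled shRNA dropout screens at GWAS loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pooled shRNA dropout screens at GWAS loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrnascreen)
```

## The problem

A pooled loss-of-function screen for GWAS follow-up has two statistical
halves. Upstream, each trait-associated sentinel SNP must be turned into
a set of candidate genes: association signals live in linkage
disequilibrium (LD) blocks, blocks are bounded by recombination hotspots,
and regulatory variants can act on genes some distance away. Downstream,
pooled shRNA counts measured along a differentiation time course must be
turned into per-gene effect estimates that are robust to the modality's
two notorious confounders: hairpin-to-hairpin differences in knockdown
efficiency and off-target activity. `shrnascreen` implements both
halves, and a simulator with known ground truth to validate them.

## Locus-to-gene nomination

For each sentinel SNP the package computes the LD block — the interval
spanning every panel SNP whose squared Pearson dosage correlation with
the sentinel reaches `r2_threshold` (default 0.8; composite LD from
unphased dosages, so no phasing is needed) — then extends it to the
inner edges of the nearest flanking recombination hotspots, and
nominates every gene whose *wingspan* overlaps the extended window. The
wingspan reaches 110 kb beyond the transcription start and 40 kb beyond
the transcription end.

Choices worth making explicit, since the conventions differ across
tools:

* **Coordinates** are 0-based half-open throughout (BED-compatible), and
  overlap means a nonempty intersection of half-open intervals. A gene
  whose wingspan *starts exactly at* the window end is therefore not
  nominated; one base closer and it is. The test suite pins these edge
  cases down at exactly 110 kb and 40 kb.
* **Hotspot extension stops at the hotspot's inner edge.** A hotspot is
  where the association signal decays, so it delimits the window rather
  than belonging to it. With no hotspot on one side the window runs to
  the chromosome boundary.
* **Upstream/downstream are strand-aware by default**, because
  "transcription start" is a stranded notion. The strand-agnostic
  variant (upstream always to the left) is available via
  `strand_aware = FALSE` for comparison with annotations that ignore
  strand; on toy panels the two differ for roughly half the borderline
  genes, which is why the choice is a flag rather than a constant.
* **A monomorphic SNP has no defined r²** and is reported as `NA`, never
  silently 0 — silently-zero correlations would shrink LD blocks without
  a trace.
* **Manual window overrides** (e.g. gene deserts expanded by hand) are
  supported as an explicit per-sentinel table, never heuristically.

For the comparison with eQTL-based nomination, LD windows are resized
symmetrically about their midpoints to a fixed 100 kb before
intersecting with eQTL genes; small windows are thereby made comparable
with large ones, which is the only reading of a "fixed padding" that
does not leave tiny windows unusable. The 2×2 table of hit status
against eQTL nomination over the eQTL universe is tested with a
two-sided Fisher exact test.

## From counts to the response

Counts are normalised per sample as
$v_{hs} = \log_2\!\big((c_{hs} + 1)\,/\,\textstyle\sum_h (c_{hs} + 1) \times 10^6\big)$,
i.e. a pseudocount of 1 added to every hairpin *before* the library size
is computed, so that $\sum_h 2^{v_{hs}} = 10^6$ holds exactly. The
model's response is the within-replicate contrast
$y_{hrt} = v_{hrt} - v_{hr,\mathrm{baseline}}$; baseline rows are
identically zero and are not emitted. No hairpin filtering is applied
beyond requiring the baseline sample (a replicate missing its baseline
is a named error): an optional minimum-representation filter exists but
defaults to off, since dropping low-abundance hairpins silently biases
dropout estimates downward. Representation QC reports the fraction of
hairpins at or above 5 log₂ CPM at the baseline day, the standard
"was the library delivered intact" check; a uniform library of up to
$10^6/2^5 = 31{,}250$ hairpins passes it by construction.

## The per-gene mixed model

Each gene is fitted separately (the hit definition is per gene, and with
5–7 hairpins per gene nothing is shared across genes):

$$ y = \beta_{\mathrm{day}} + b_h \cdot \mathrm{elapsed} + \varepsilon,
\qquad b_h \sim N(0, \sigma_h^2), \quad
\varepsilon \sim N(0, \sigma^2) $$

* `day` is categorical with no intercept: one coefficient per
  post-baseline day, so $\beta_k$ is the gene's cumulative log₂ fold
  change at day $k$ with no shape assumption across days. (A gene may
  drop out early and recover, or act only late.)
* $b_h$ is a single random *slope* per hairpin on elapsed days, not a
  per-day random vector: an inefficient or off-target hairpin deviates
  in a way that accumulates with time, and a 5×5 hairpin covariance is
  unidentifiable from 5–7 hairpins. The per-day-diagonal alternative is
  available via `random = "day"` for sensitivity analysis.
* Variance components are estimated by REML (`lme4`); each coefficient
  gets a Wald statistic $W_k = (\hat\beta_k / SE_k)^2$ referred to
  $\chi^2_1$. With few hairpins the Wald SE carries no small-sample
  correction and is mildly anti-conservative; per-coefficient ±3 SE
  coverage in simulation is ≈ 98 %, joint five-day coverage ≈ 94 %.

Degenerate inputs are handled explicitly rather than left to the
optimizer: a response that the per-day means fit exactly (zero residual
variance) is returned as the closed-form OLS solution with status
`"degenerate"`; $\hat\sigma_h^2 = 0$ is a legitimate boundary fit
(status `"singular"`) at which the coefficients equal the per-day OLS
means — the equivalence the test suite asserts at 10⁻⁶. Non-converging
fits are retried up to three times from jittered starts and otherwise
flagged `"failed"`, excluded from hit calling but never dropped from the
output.

## Hit calling

Coefficients are converted to per-day slopes, by default *cumulative*:
$\beta_k / (t_k - t_0)$ — the coefficient is a cumulative fold change,
and the headline threshold is phrased per day. The *incremental* mode
$(\beta_k - \beta_{k-1})/(t_k - t_{k-1})$ is selectable; the two agree
exactly for linear trajectories and differ for saturating ones (a
trajectory flat after day 6 has cumulative slope 1/12 at day 16 but
incremental slope 0).

BH adjustment is applied jointly across all gene × day tests, control
genes included, matching day-specific FDR reporting. A gene is a hit
when *some* day passes both gates: per-day slope magnitude > 0.1
log₂FC/day and q < 0.1. Direction (depleted/enriched) is taken at the
qualifying day with the smallest q. Both thresholds, the slope mode and
the BH pool are arguments, not constants.

## The simulator

`simulate_screen()` draws, for hairpin $h$ of gene $g$:

$$ \log_2 a_h(t) = \log_2 a_{h0} + (\gamma_g + \delta_h)(t - t_0) +
\epsilon, $$

with baseline abundances $a_{h0}$ log-normal (sdlog 0.8, reproducing the
right-skewed baseline representation of a real pooled library),
$\delta_h \sim N(0, \sigma_\mathrm{hairpin})$ a *slope* deviation
constant in time (the random-effect structure the model fits), and
$\epsilon$ residual log₂ noise per observation. Counts are
negative-binomial around `depth × proportion` via a gamma–Poisson
mixture with overdispersion $\phi$ (variance $\mu + \phi\mu^2$;
$\phi = 0$ is Poisson). Defaults describe the study conditions the
package is tested under: 200 genes × 6 hairpins × 3 replicates at days
4, 6, 9, 12, 14, 16, depth 10⁷, $\phi = 0.05$,
$\sigma_\mathrm{hairpin} = 0.05$, $\sigma_\mathrm{resid} = 0.1$, 10 % of
genes carrying $|\gamma| \in [0.15, 0.3]$ log₂/day.

Effect signs default to depletion (`enriched_fraction = 0`). This is
deliberate: counts are compositional, and a simulated gene *gaining*
0.3 log₂/day grows 12-fold by day 16, diluting every other hairpin by
~0.04 log₂/day — enough to push null genes over the hit threshold. Real
enrichment in a differentiation screen is modest and bounded; unbounded
exponential enrichment is an artifact of the log-linear generative
model, so it is off by default and available by parameter for
robustness studies.

What the simulator does *not* emulate: PCR amplification bias,
multiplicity of infection, hairpin-level dropout of entire barcodes,
donor-specific biology (replicates are exchangeable), and
time-correlated noise beyond the shared baseline draw. Passing recovery
tests on these simulations therefore demonstrates that the estimator
recovers the generative model it assumes, not that the model is correct
for any particular real screen.

`simulate_genome_toy()` builds LD blocks *by construction* — each
block's SNPs are noisy copies of a latent diploid haplotype, blocks are
independent, hotspots sit in the gaps — so nomination can be checked
against a brute-force oracle. `simulate_annotations()` ties
essentiality scores, a stage-expression matrix, coding-variant flags
and a five-gene gold-standard list to the simulated truth so that
enrichment statistics have real signal to find, and none when all
$\gamma = 0$.

## Permutation inference

All four enrichment statistics share one null: gene sets of the hit
set's size drawn uniformly without replacement from a stated universe
(the screened library by default; the same code serves genome-wide or
alternative-GWAS universes by swapping the `universe` argument).
Empirical p values use the add-one estimator
$(n_\mathrm{extreme} + 1)/(n_\mathrm{perm} + 1)$ — never exactly zero —
with ties counted as extreme, the conservative convention. Seeds are
recorded in every result and reruns reproduce $n_\mathrm{extreme}$
exactly. For the overlap statistic the exact hypergeometric upper tail
is reported alongside the Monte-Carlo p, and the test suite holds the
two within three Monte-Carlo standard deviations of each other across
random configurations, as well as holding score-sum and rank-sum p
values to exhaustive enumeration on small universes. Genes missing an
annotation are dropped from universe and hit set alike (logged), the
only consistent reading of "all genes in the library" when coverage is
partial.

Expression matrices are z-scored within gene across stages (sample SD;
a constant gene contributes 0 everywhere), so each gene carries only
its relative stage preference and the per-stage sums over any gene set
total zero across stages.

## Numerical and scale choices

* Test-suite problem sizes: recovery at 200 genes (one seed), null
  calibration at 50 seeds × 200 genes, enrichment oracles at ≤ C(12, k)
  enumerable universes with 4,000 Monte-Carlo draws, uniformity of each
  permutation p via Kolmogorov–Smirnov over 200 null replicates. The
  discrete overlap statistic is calibrated on a wide hypergeometric
  support (universe 2,000) because a near-continuous p distribution is
  what makes a KS test against the uniform meaningful.
* The pipeline (`run_pipeline()`) derives all stage seeds from one
  master seed by fixed offsets, writes every table with a run-id header
  comment, and reruns are byte-identical per table; the JSON manifest
  additionally records row counts, wall times and file checksums (and
  is written even when a stage fails, naming the stage).

## Known limitations

* **Fixed effect vs mean hairpin deviation.** With $m$ hairpins the
  gene effect is confounded with the mean of the hairpin slope
  deviations, which has SD $\sigma_\mathrm{hairpin}/\sqrt{m} \approx
  0.02$ log₂/day at the defaults; a ~3σ gene shows sustained
  pseudo-dropout no model can attribute correctly. More hairpins, not
  more modelling, is the remedy.
* **Early-interval noise amplification.** The cumulative slope at the
  first post-baseline day divides by the shortest elapsed time, while
  NB dispersion puts a depth-independent noise floor
  ($\mathrm{SD} \approx \sqrt{\phi}$ in natural log) on every sample.
  At $\phi = 0.05$ a gene-level day-6 slope has SD ≈ 0.05 log₂/day, so
  the 0.1 magnitude gate is only ~2σ there and most false hits in
  simulation qualify at day 6. Under the default study conditions the
  realised false-discovery proportion of the dual gate is ~0.2 — the
  gate bounds neither FDR nor FDP by itself, and downstream users
  should treat early-day-only hits with corresponding scepticism.
* The Wald χ² test has no small-sample correction (see above), and the
  response's shared baseline induces a within-replicate correlation
  across days that the model ignores; both are inherited from the
  analysis idiom the package implements rather than defects of the
  implementation.
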