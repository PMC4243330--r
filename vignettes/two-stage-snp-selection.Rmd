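---
title: "Two-stage SNP selection with epsilon-SVR and a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SNP selection with epsilon-SVR and a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpselga)
```

## The problem

Genome-wide association studies of continuous traits (milk yield breeding
values, growth traits, metabolite levels) usually rank markers one at a time
by the p-value of a per-SNP regression and keep the top of the list. Two
things go wrong. First, a marker whose effect is confined to one genotype
class — a heterozygote advantage, or an effect masked by a second locus — has
a weak *monotone* association with the trait, so rank-based single-marker
statistics can miss it even when it carries most of the signal. Second, the
markers that survive the cut are often mutually redundant (in linkage
disequilibrium), so the selected panel is larger than the information it
carries.

`snpselga` implements a two-stage wrapper strategy around epsilon support
vector regression (SVR) that addresses both:

1. **Stage one (filter + model evaluation).** Every SNP is scored by the
   Spearman correlation of its allele dosage with the phenotype. The
   p-values define an increasing ladder of thresholds, and each threshold
   defines a *nested group* of markers (every group contains all smaller
   ones). Each group is then evaluated as a whole by the cross-validated
   accuracy of an SVR trained on its dosage columns, so interactions among
   markers — invisible to the per-SNP score — can still express themselves.
   The chosen group is the smallest one whose mean cross-validated Pearson
   correlation is within a tie tolerance of the best.
2. **Stage two (wrapper).** A binary genetic algorithm (GA) searches subsets
   of the chosen group. Each chromosome switches markers on or off; its
   fitness is the cross-validated mean squared error of the SVR restricted
   to the active markers. Elitism keeps the best subset monotone across
   generations. The result is a smaller panel with equal or better
   cross-validated accuracy.

## The regression model

For training pairs $(x_i, y_i)$ the epsilon-SVR estimates
$f(x) = \sum_i (\alpha_i - \alpha_i^*) K(x_i, x) + b$ by maximizing the
standard dual

$$
-\tfrac12 \sum_{i,j} (\alpha_i-\alpha_i^*)(\alpha_j-\alpha_j^*) K(x_i,x_j)
- \varepsilon \sum_i (\alpha_i+\alpha_i^*) + \sum_i y_i(\alpha_i-\alpha_i^*)
$$

subject to $\sum_i(\alpha_i-\alpha_i^*) = 0$ and
$0 \le \alpha_i, \alpha_i^* \le C$. Residuals smaller than $\varepsilon$ are
free; $C$ prices the rest. The dual is solved by the sequential minimal
optimization routine of **kernlab** on kernel matrices computed by this
package; the test suite verifies the returned solution against an
independent interior-point solve of the same dual (box and equality
constraints written out explicitly), to $10^{-4}$ in predictions.

Three kernels are available:

* linear, $K(x,z) = \langle x, z\rangle$;
* Gaussian RBF, $K(x,z) = \exp(-\gamma\lVert x-z\rVert^2)$;
* the Pearson VII universal kernel (PUK)

$$
K(x,z) = \Big[1 + \big(2\lVert x-z\rVert\sqrt{2^{1/\omega}-1}/\sigma\big)^2\Big]^{-\omega},
$$

whose shape parameter $\omega$ interpolates between a Lorentzian
($\omega = 1$) and, as $\omega \to \infty$, a Gaussian of width set by
$\sigma$. This adaptability is why the pipeline tunes a single kernel family
instead of switching kernels: with matched parameters the PUK Gram matrix
correlates with an RBF Gram matrix at $r > 0.99$ (asserted in the tests), so
one family covers the usual spectrum. Dosage columns are standardized to
zero mean and unit variance *using training-fold statistics only* before any
kernel evaluation; distance-based kernels on raw 0/1/2 dosages would
otherwise conflate scale with signal.

### Cross-validation protocol

Accuracy is reported as repeated k-fold cross-validation (default
$10\times$10-fold): for each repeat the samples are reshuffled, out-of-fold
predictions for *all* samples are pooled, and **one** Pearson correlation per
repeat is computed, giving 10 estimates whose mean and standard deviation
are reported. Pooling before correlating is deliberate: per-fold
correlations on 25-60 samples are noisy and their average is biased low for
small folds; a per-fold mode is retained as an option (`per_fold = TRUE`)
for comparability. A repeat with constant predictions (a degenerate model)
is recorded as correlation 0 and flagged rather than dropped.

Hyperparameters are tuned by grid search on the same repeated-CV criterion
that is reported (non-nested). This matches common practice for this kind
of pipeline but means the reported correlation of the *tuned* model is
mildly optimistic; an honest generalization estimate would nest the tuning
inside an outer CV, at k times the cost.

### Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `C` | price of residuals outside the tube | grid `{0.1, 1, 10, 100, 1000}` |
| `epsilon` | insensitive-tube half-width, phenotype units | grid `{0.001, 0.01, 0.1, 1}` x sd(y) |
| `gamma` | RBF inverse squared width | grid `10^-4..10` |
| `omega`, `sigma` | PUK shape and width | grids `{0.5..16}`, `{0.25..8}` |
| `k`, `r` | CV folds and repeats | 10, 10 |
| `tie_tolerance` | group-selection tie margin | 0.005 (two printed decimals) |
| `min_ga_size` | skip the GA at or below this group size | 10 |

The epsilon grid is expressed in units of the phenotype standard deviation
because the tube is a residual scale, not an absolute one. For
high-dimensional groups (hundreds of standardized columns) pairwise
distances concentrate around $\sqrt{2d}$, so the evaluation scripts extend
the PUK `sigma` grid to 32; with `sigma` far below the typical distance the
kernel is effectively local and underfits. The same scripts drop the
weakest `C` values (below 10) from the search: they are never selected on
these designs, and small-`C` solves dominate SMO time on the larger
cohorts.

## The genetic algorithm

Chromosomes are bit vectors over the candidate group; the initial population
is i.i.d. Bernoulli(0.5). Each generation: the best `elitism_count`
individuals are copied unchanged; parents are chosen by size-2 tournaments
(roulette on inverse MSE is available); selected pairs undergo one-point
crossover with probability 0.6; every bit then mutates with probability
0.033. These operator rates are the package defaults for this workflow;
population and generation counts default to 20 each and should be raised
(100 x 500 is a reasonable target) when the candidate group is small enough
to afford it.

Two design choices matter for reproducibility:

* The fold partition used inside the fitness is drawn **once per run** from
  the GA seed, so fitness is a deterministic function of the chromosome.
  This removes noise-driven churn between generations and lets fitness
  values be memoized — revisiting a subset costs no new SVR fits.
* The SVR hyperparameters inside the GA are frozen at the values tuned for
  the full candidate group. Re-tuning per chromosome would multiply the
  cost by the grid size, and the frozen values are the right scale for all
  subsets of the same group.

An all-zero chromosome (no marker selected) is assigned infinite fitness
rather than repaired, so it can occur transiently but never wins. With at
least one elite the per-generation best fitness is non-increasing; this is
asserted on every GA run in the test suite. On 10-marker instances, where
all $2^{10}$ subsets can be enumerated, a 40 x 60 GA reaches within 5% of
the exhaustive optimum in at least 9 of 10 seeds (asserted in the
acceptance tests).

## Quality control and diagnostics

Marker-level QC implements three filters — call rate, minor allele
frequency, and a 1-df Pearson chi-square test of Hardy-Weinberg equilibrium
whose significance level is Bonferroni-divided by the pre-QC marker count.
The chi-square (rather than exact) test matches the threshold style
`alpha / m` this workflow inherits; it is isolated behind `hwe_pvalue()` and
trivially swappable. All statistics are computed on the raw matrix *before*
heterozygote imputation: imputing missing calls as heterozygotes first would
bias the HWE statistic toward excess heterozygosity. In simultaneous mode
every filter is evaluated on the input matrix, so the retained set is
invariant to filter order and QC is a fixed point (both asserted in tests);
sequential mode only changes how removals are attributed per filter.

Linkage disequilibrium is reported as composite $r^2$: the squared Pearson
correlation of dosage columns. Phase is never available here and dosage
correlation is the estimator that needs no haplotype model. For a set of
mutually independent markers the off-diagonal mean sits at the sampling
background $\approx 1/(n-1)$, which is the yardstick to read the
before/after-GA diagnostic against.

## The simulated reference designs

Two fully specified generative designs make every stage testable without
external data. Genotypes are drawn per SNP from Hardy-Weinberg proportions
with minor allele frequency uniform on (0.10, 0.40); markers are mutually
independent, so LD arises only through finite sampling. Classes are labeled
1/2/3 (homozygous reference / heterozygous / homozygous variant) and stored
as allele dosages 0/1/2.

**Additive design** (1,000 SNPs x 250 subjects): seven indicator effects

$$
Y = 200\,[S_1{=}2] + 200\,[S_{10}{=}1] + 200\,[S_{20}{=}3] + 900\,[S_{30}{=}3]
  + 200\,[S_{40}{=}3] + 200\,[S_{50}{=}2] + 200\,[S_{60}{=}2] + \epsilon,
$$

$\epsilon \sim N(0, 5^2)$. Effects sit on specific genotype classes, not on
dosage, so some are nearly invisible to rank statistics in some
realizations: a rare-homozygote effect ($[S{=}3]$ with small MAF) may fire
for a handful of subjects, and a heterozygote effect is non-monotone in
dosage whenever the variant homozygote class is sizeable. This is the
design's point — stage one alone cannot be trusted to keep every causal
marker.

**Epistatic design** (10,000 SNPs x 600 subjects):

$$
Y = 150\,L_1 + 150\,L_2 + 40\,L_3 + \epsilon,\qquad \epsilon \sim N(0,1),
$$

with $L_1 = [S_4 \ne 3]\wedge[S_3{=}2]$, $L_2 = [S_5{=}3]$,
$L_3 = [S_{12}\ne 1]\wedge[S_9{=}3]$. The load-bearing term is $L_1$: a
heterozygote-specific effect at $S_3$, masked when $S_4$ is the variant
homozygote. Conditional on $S_3$ the phenotype mean is non-monotone in
dosage (baseline, high, baseline-plus-mask), which is exactly the situation
where a linear kernel on the single best marker fails while a flexible
kernel recovers nearly the full explainable signal — the non-linearity
signature the acceptance checks quantify. The masking condition was chosen
over a heterozygote mask ($[S_4\ne 2]$) because the latter caps the
single-marker explainable variance well below what the design is meant to
exhibit: $P(S_4 \ne 2)$ can never exceed $1 - 2q(1-q) \le 0.82$ on this MAF
range, while $P(S_4 \ne 3) = 1 - q^2 \ge 0.84$ keeps the masked effect
nearly always on.

Because the per-SNP minor allele frequencies are redrawn each run, the
*explainable* single-marker variance varies across realizations (through
$q_3$, $q_4$ and the nuisance term frequency $q_5^2$); quantities conditioned
on one realization reproduce only in distribution. The generator exposes the
genotype and noise streams under separate seeds so one genotype matrix can
be reused across phenotype redraws.

What these designs deliberately do **not** emulate: LD blocks and physical
maps, allele-frequency spectra from real chips, missingness and genotyping
error (QC is exercised on constructed fixtures instead), population
structure, and polygenic backgrounds. Passing tests on these designs shows
the machinery is correct and that the method behaves as intended under
class-specific and epistatic architectures; it does not certify performance
on real panels with correlated markers.

## Numerical choices

* Spearman statistics use mean ranks (tie-corrected) and the two-sided
  t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; dosage columns always
  have heavy ties, so the tie-robust form is the only correct one. A column
  constant after ranking gets $\rho = 0$, $p = 1$. Agreement with
  `cor.test(..., method = "spearman", exact = FALSE)` and with a
  brute-force rank-then-correlate oracle is asserted to $10^{-12}$.
* Group membership uses strict inequality ($p < \tau$); boundary p-values
  are possible and must fall outside the group for the printed "< threshold"
  semantics to hold.
* Group-evaluation tables are produced with `tune_r = 1` (a single CV repeat
  during grid search) and the selected point is then re-evaluated with the
  full repeated CV. Tuning noise affects only which grid point wins ties;
  the reported accuracy always comes from the full protocol.
* The degenerate no-support-vector case (target inside the tube everywhere,
  e.g. a constant phenotype) returns the flat function at the median, with
  all dual coefficients zero.
* A training fold containing a constant dosage column leaves that column
  centred at zero rather than dividing by a zero standard deviation.
* Problem sizes: 5 replicates per simulated design in the test suite and 8
  in the reproduction script (the single-marker linear-kernel accuracy has a
  per-replicate spread of ~0.13, so the mean needs the extra replicates); GA checks use 10 seeds with population 24 x 25 generations over
  the p < 0.20 group (about 200 candidates) and 40 x 60 on 10-marker
  enumeration instances; fitness CV uses 2-3 folds there. These sizes are
  the package's accuracy/runtime compromise for a single-CPU run.

## Known limitations

* The reported accuracy of tuned models is selection-biased (non-nested
  tuning); use nested CV for publication-grade generalization estimates.
* Stage one is blind to markers whose marginal rank association is null in
  a given realization; stage two can only recover what stage one lets
  through. Under strong epistasis the method collapses to the single best
  marker — by design it never enlarges the chosen group.
* On panels without genuine redundancy the GA cannot reduce mean pairwise
  $r^2$ below the $1/(n-1)$ sampling background; redundancy reduction is
  only observable when real LD structure exists.
* The GA with the default 20 x 20 budget under-searches groups of hundreds
  of markers; scale population and generations with the group size.
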