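---
title: "Detecting daily rhythms in qPCR expression time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting daily rhythms in qPCR expression time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmoscope)
```

## The problem

Peripheral tissues such as fish skeletal muscle express the core circadian
clock genes (*clock*, *arntl/bmal*, *per*, *cry*, *nr1d/rev-erb*, *rorα*,
*npas2*, *tim*) with daily oscillations, and many muscle growth and
maintenance genes (the myogenic regulatory factors *myoD*, *myf5*, *mrf4*,
*myoG*, plus *mstn*, *pcna* and others) follow them. A typical study design
samples n = 6 individuals every 3 h across one light–dark cycle
(Zeitgeber times ZT0, 3, ..., 24; ZT0 = lights on), measures transcript
levels by qRT-PCR, and asks three questions per tissue:

1. Which genes are *rhythmic*, and with what amplitude and peak time?
2. At which timepoints do expression levels differ (letter annotations on
   the time-course plots)?
3. Which gene pairs co-vary across the day (candidate regulatory links)?

`rhythmoscope` implements this whole chain — relative quantification,
rhythmometry, group statistics, correlation screening — plus a seeded
synthetic-data generator shaped like the study design, so that every stage
can be validated against known generating truth.

## The cosinor model and the noise/signal rhythmicity rule

Expression of gene *g* at time *t* (hours) is modelled by a single cosinor
with fixed 24-h period:

$$ f(t) = M + A \cos\!\left(\frac{\pi t}{12} - \varphi\right), $$

with mesor $M$ (rhythm-adjusted mean, expression units), amplitude $A \ge 0$
(half the peak-to-trough extent, same units) and acrophase $\varphi$
(radians; the curve peaks at ZT $12\varphi/\pi$). `fit_cosinor()` rewrites
the model as a linear regression on
$\{1, \cos(\pi t/12), \sin(\pi t/12)\}$ with coefficients
$(M, \beta, \gamma)$, so that $A = \sqrt{\beta^2 + \gamma^2}$ and
$\varphi = \operatorname{atan2}(\gamma, \beta)$ wrapped to $[0, 2\pi)$.
The atan2 construction forces $A \ge 0$, removing the sign ambiguity of the
phase.

Rhythmicity is judged by the amplitude noise/signal statistic
$P = SE(A)/A$, with the conventional strict rule: rhythmic iff $P < 0.3$.
$SE(A)$ is obtained by the delta method from the OLS coefficient
covariance,

$$ \operatorname{Var}(A) = \frac{\beta^2\operatorname{Var}(\beta) +
   \gamma^2\operatorname{Var}(\gamma) +
   2\beta\gamma\operatorname{Cov}(\beta,\gamma)}{A^2}. $$

This is standard single-cosinor practice; the package's tests verify it
against the Monte-Carlo scatter of refitted amplitudes (agreement within
15%). When $A$ is numerically zero ($< 10^{-12}$) the ratio is undefined
and $P$ is set to $+\infty$: a flat gene is arrhythmic, never 0/0.

Design choices worth stating explicitly:

* **Period is fixed at 24 h.** No period estimation, no multi-component
  cosinor, no zero-amplitude F-test and no multiple-testing correction:
  the screening statistic is $SE(A)/A$ alone.
* **Replicate-level vs mean fitting.** `rhythm_table(fit_on =)` offers
  both. With `"replicates"` (default) all 54 observations enter the fit,
  so $SE(A)$ reflects between-individual scatter directly; with
  `"timepoint_means"` the nine per-ZT means are fitted, which weights each
  timepoint equally and matches how such time courses are usually plotted.
  Point estimates coincide on balanced designs; $P$ differs. Both are
  legitimate; neither is privileged by convention, so both are exposed.
* **ZT0 and ZT24 are distinct samples** taken one cycle apart. Their
  phases coincide in the 24-h model; both are kept in the fit as genuine
  replication rather than dropping or merging one.

```{r}
zt <- rep(seq(0, 24, by = 3), each = 6)
set.seed(1)
y <- cosinor_signal(zt, mesor = 1, amplitude = 0.4, acrophase = 2) *
  2^rnorm(length(zt), 0, 0.1)
fit_cosinor(zt, y, gene = "example")
```

## Relative quantification: 2^-ddCt and geNorm

Raw qPCR output is a cycle threshold Ct per sample and gene; one fewer
cycle means twice the template. `delta_delta_ct()` computes, per sample,
$\Delta Ct = Ct_{target} - Ct_{ref}$ (arithmetic mean Ct over the reference
set, i.e. geometric mean of reference quantities), subtracts a calibrator
$\Delta Ct$, and reports $R = 2^{-\Delta\Delta Ct}$.

The calibrator — the "control" sample of the classic formula — is a free
choice that only rescales $R$ by a constant per gene; cosinor $P$,
acrophase and every correlation are invariant to it. The default
(`global_mean`) centres each gene on its mean $\Delta Ct$ so no single
timepoint is privileged; `zt0_mean` and `min` are available for
conventional presentations (expression relative to ZT0, or to the
least-expressed sample).

Reference-gene stability uses the geNorm measure: for candidates $j,k$ the
pairwise variation $V_{jk}$ is the standard deviation over samples of
$\log_2(q_j/q_k)$, and $M_j$ is the mean of $V_{jk}$ over all $k \ne j$ —
a gene that tracks the others has low $M$. `genorm_m()` also records the
iterative exclusion of the least stable gene and the pairwise variations
$V(n/n{+}1)$ between normalisation factors of top-$n$ sets;
`select_reference()` applies the conventional $V < 0.15$ rule, or returns
the single most stable gene for single-reference normalisation. Base-2
logarithms are used throughout, following the original method. No
amplification-efficiency correction (Pfaffl) or absolute quantification is
attempted.

## Group statistics: ANOVA and Duncan letters

Per gene, `group_stats_table()` runs a one-way fixed-effects ANOVA across
the nine timepoints and annotates them with Duncan's multiple range test at
$\alpha = 0.05$. Duncan's procedure compares ranked means with
span-dependent least significant ranges
$R_p = q\!\left(p, df_e;\ (1-\alpha)^{p-1}\right)\sqrt{MSE/n_h}$,
where $q$ is the studentized-range quantile at Duncan's protection level
and $n_h$ the harmonic mean group size (groups are usually balanced at
n = 6, but the harmonic mean covers dropped samples). The containment rule
applies: a pair inside a span already declared homogeneous is never
declared different. The resulting relation is rendered as a compact letter
display by the insert-and-absorb algorithm with letters ordered by
descending mean, the usual lower-case annotation style of time-course
figures. Degenerate inputs (zero within-group variance with unequal means)
report $F = \infty$ and separate every distinct mean.

## Correlation screening

Replicates at one timepoint are different individuals, so there is no
within-sample pairing between genes; the only well-defined correlated
quantity is the per-timepoint mean profile (9 values per gene), computed by
`mean_profile()`. `correlation_table()` evaluates Pearson's $r$ for every
unordered gene pair and applies the screening gate used for reporting:
keep a pair iff $|r| > 0.5$ *and* at least one member is rhythmic.
Strength categories follow the published convention — strong when
$|r| \ge 0.80$, moderate when $0.5 < |r| < 0.80$ — applied to the
magnitude with the direction tracked separately (the convention's
published wording leaves $[0.79, 0.80)$ unassigned; it is resolved as
moderate, making the bands exhaustive). No correlation p-values are
computed: screening is by magnitude and rhythm gate only, with 9 profile
points there is little power for more.

## The synthetic-data generator

`generate_expression_dataset()` draws, for each gene, timepoint and
replicate,

$$ y = \left[M + A\cos(\pi t/12 - \varphi)\right] \cdot 2^{\varepsilon},
   \qquad \varepsilon \sim N(0, \sigma^2), $$

i.e. multiplicative log-normal noise, the error structure of relative
qPCR quantities (additive on the Ct scale). `generate_ct_dataset()` maps
expression to cycle thresholds via $Ct = Ct_0 - \log_2(y)$ with
$Ct_0 = 22$ by default; a stable reference candidate is a flat gene, and
an unstable candidate drifts linearly in $\log_2$ expression across the
day (total span set by its `amplitude` field, in log2 cycles — ribosomal
RNA is the classic drifting normaliser). The default candidate panel has
six members, five stable and one drifting, mirroring common practice of
screening about half a dozen housekeeping genes.

Defaults reproduce the study design this package targets: 9 Zeitgeber
times, 6 replicates, and per tissue the 26-gene panel (15 clock + 11
myogenic genes) with published mesor/amplitude/acrophase values as
generating truth (`default_gene_panel()`). Three printed parameter rows
have amplitude slightly above mesor; since a transcript level cannot be
negative, the generator caps amplitude at the mesor for those genes while
the packaged table keeps the printed values. The noise scale is not known
from published mean ± SEM summaries alone; the default
$\sigma = 0.1$ log2 units (about 7% CV) is a representative low-noise
qPCR setting chosen once, not calibrated to reproduce printed $P$ values —
simulated data are cleaner than the real measurements, and simulated $P$
values are correspondingly smaller.

Randomness is organised as one root seed with a child stream per gene in
declaration order, so extending a panel never perturbs the draws of
earlier genes, and identical configurations are byte-identical.

What the generator does *not* emulate: amplification-efficiency
differences between primer pairs, plate and batch effects, censoring at
high Ct, non-sinusoidal waveforms, and between-individual phase
dispersion. Passing tests therefore demonstrate correctness of the
computations under the stated model, not robustness of the statistics to
real-data pathologies.

## Numerical choices and degenerate inputs

* Cosinor fits require $\ge 4$ observations over $\ge 3$ distinct phases
  (mod 24); anything less is a hard error, which `rhythm_table()` converts
  into a flagged `note` row so one bad gene never aborts a batch.
* Acrophase is wrapped to $[0, 2\pi)$ and its ZT form to $[0, 24)$;
  classification at the $P$ threshold and at the $|r|$ gate is strict.
* geNorm ties for the least stable gene are broken by column order;
  stability values are invariant to per-sample rescaling, which the tests
  assert exactly.
* Problem sizes in the test-suite simulations (200 geNorm replicates, 500
  cosinor recovery draws, 1000 ANOVA type-I draws, 2000 Monte-Carlo refits)
  were chosen to bound the Monte-Carlo error of each asserted proportion
  well below its acceptance margin while keeping the suite quick to run.

## Known limitations

* The $P = SE(A)/A < 0.3$ rule is a screening heuristic, not a calibrated
  test; its false-positive rate under flat truth is measured by simulation
  (a few percent at the default design) rather than controlled analytically.
* With nine profile points, correlation estimates are noisy and the
  moderate/strong bands should be read as descriptive categories.
* Duncan's multiple range test does not control the family-wise error
  rate; it is implemented because it is the convention in this literature,
  not because it is the best available post-hoc procedure.
* The pipeline analyses relative expression; analyses on the
  $\Delta Ct$ scale would weight noise differently and are not provided.
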