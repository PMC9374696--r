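---
title: "Detecting circadian cycling genes in short TPM time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circadian cycling genes in short TPM time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

cyclescan implements a rhythmicity screen tailored to a very common but
statistically awkward experimental design: a bulk RNA-seq time course with
only six samples per replicate, taken under continuous light (LL) from
cultures grown under two conditions (here: low-salt, 0.5 M NaCl, and
high-salt, 2.5 M NaCl, as used for the extremely halotolerant cyanobacterium
*Halothece*). Six points spanning 30 h is far too short for
periodogram-style methods, so the screen asks a narrower question: *how
closely does each gene's course follow a 24-h cosine, relative to what
random courses achieve on the same grid?*

```{r}
library(cyclescan)
library(dplyr)
```

## The statistic

For each gene, condition and replicate, the TPM course
$y = (y_1, \dots, y_6)$ at times $t = (4, 10, 16, 22, 28, 34)$ h in LL is
scored by two indices:

**Amplitude.** The course is divided by its mean and the population
standard deviation (divide by $n$, not $n-1$) of the result is taken:

$$ \mathrm{amp}(y) = \mathrm{SD}_{pop}\!\left(\frac{y}{\bar y}\right)
   = \mathrm{CV}(y). $$

Using the coefficient of variation rather than the raw SD makes a single
threshold (0.1) meaningful across five orders of magnitude of expression;
z-scoring instead would force every amplitude to 1 and make the index
useless. This is the one place where the convention is genuinely open, and
the CV reading is the only scale-free one compatible with a fixed cut.

**Correlation p-value.** A bank of $K = 60$ reference cosines
$s_k(t) = \cos\!\big(2\pi (t - \phi_k)/T\big)$, $\phi_k = kT/K$, $T = 24$ h,
is evaluated on the grid, and the gene's score is the maximum Pearson
correlation $r_{\max} = \max_k r(y, s_k)$, with the maximizing $\phi_k$
reported as the gene's phase (smallest $k$ on ties). Because $r_{\max}$ is
a maximum over many regressors its null distribution is far from any
textbook form, so it is calibrated by Monte Carlo: `build_null()` draws
$10^6$ i.i.d. standard-normal courses on the same grid, scores each the
same way, and the empirical p-value of a gene is

$$ p = \frac{1 + \#\{r^{null} \ge r_{\max}\}}{n_{null} + 1}. $$

The add-one form is never exactly zero and is a strictly valid p-value;
it converges to the plain exceedance fraction as $n_{null}$ grows. Since
Pearson correlation is location- and scale-free, only the i.i.d. shape of
the null draws matters; Gaussian is the neutral choice, and the
calibration property below confirms it transfers to log-normal expression
noise.

A gene is called **cycling** when *every* replicate passes both cuts:
amplitude $> 0.1$ and $p < 0.1$. No multiple-testing correction is
applied — the rule is deliberately a per-gene screen, and with ~3800
genes it admits roughly $0.01 \times 3800 \times
P(\mathrm{amp\ filter\ passes})$ false calls, which the replicate-AND
rule is the only guard against. The per-gene **peak time** is the best
phase of the replicate-averaged course, reported modulo 24 h.

```{r}
params <- rhythm_params(n_null = 2e4, seed = 7)  # 1e6 for production runs
sim <- simulate_expression(sim_params(n_genes = 500, seed = 7))
null <- build_null(c(4, 10, 16, 22, 28, 34), params)
scan_low <- detect_cycling(sim$expression, "low_salt", params, null = null)
scan_low
glance(scan_low)
tidy(scan_low) |> filter(is_cycling) |> head(3)
```

### Numerical choices and degenerate inputs

* One null is built per time grid and reused for every gene and both
  conditions; it depends only on the grid, the period and the bank size.
* Ties in the maximum correlation resolve to the smallest phase index, in
  both the vectorized implementation and the naive oracle the tests
  compare against, so equality can be asserted exactly.
* A constant or all-zero course has undefined Pearson correlation; such
  genes get amplitude 0 and p-value 1, are flagged `degenerate`, and can
  never be called cycling.
* With samples at 4–34 h and a 24-h period, the 28 h and 34 h columns
  repeat the circadian phases of 4 h and 10 h, so the six samples probe
  only four distinct phases. This aliasing is a property of the design,
  not of the implementation; it limits phase resolution (see the ±2 h
  recovery figure below) and is asserted as an invariant rather than
  "fixed".
* The grid of 60 phases at period 24 gives 0.4 h phase spacing — far finer
  than the data can resolve, so the phase grid contributes no meaningful
  discretization error.

## Differential expression

Between-condition calls are purely fold-change based (no dispersion
estimation — with two replicates per condition, a fold-change screen is
what the design supports). TPM values at LL 16, 22, 28 and 34 — a window
covering a full circadian cycle, so endogenous oscillation averages out —
are pooled over replicates (8 values per condition), and genes are tiered
by $\log_2 \mathrm{FC}$ of high over low: `up`/`down` at $|\log_2FC| \ge
1$, `up_high`/`down_high` at $\ge 2$, boundaries inclusive. The default
pseudocount is 0, with explicit `Inf`/`-Inf`/`undefined_zero` flags so
zero-expression genes stay visible instead of being shifted by an
arbitrary constant. Whether the replicate average is taken before or
after the time average is immaterial here because the mean is flat over
all 8 values; with missing data the flat mean is what is computed.

```{r}
deg <- deg_table(sim$expression)
deg_summary(deg)
```

## Term enrichment

`enrich_terms()` runs a one-sided (over-representation) Fisher exact test
per annotation term — the hypergeometric tail probability of observing at
least the seen number of DEGs in the term — followed by a two-branch
selection rule: a term is reported if $p \le 0.1$, or if $0.1 < p < 0.5$
*and* more than half of the term's genes are DEGs. The borderline branch
exists to surface small terms that can never reach a small p-value but are
almost entirely differentially expressed. The background universe defaults
to the annotated genes, with `background = "all"` for the whole matrix;
both readings of the denominator are defensible and the toggle keeps each
reproducible. The test direction (one-sided) is itself a documented
choice: enrichment reporting is about over-representation.

## The synthetic-data generator

`simulate_expression()` exists so that every stage can be validated
against known truth without any download. It generates

$$ y_{g,c,r,t} = B_g \cdot F_{g,c} \cdot
   \big(1 + A_{g,c}\cos(2\pi (t - \phi_{g,c})/24)\big) \cdot \varepsilon, $$

with log-normal baseline $B_g$ (default: $\log_{10}$ TPM $\sim N(2,
0.8^2)$, i.e. a median of 100 TPM), condition factor $F = 2^{\pm 2}$ for
planted up/down genes, planted relative amplitudes $A$ drawn from
$[0.15, 0.6]$, and i.i.d. log-normal noise $\varepsilon$ with mean 1 and
CV 0.2 — a typical biological-replicate CV for bulk RNA-seq TPM. The
default design mirrors the target study: 3843 genes, 2 conditions ×
2 replicates × 6 times, cycling prevalences 51/3843 (low salt, phases
uniform over the cycle) and 218/3843 (high salt, phases concentrated at
LL16, emulating the observed LL16–20 peak band), exactly one shared
cycling gene, and up/down prevalences 1368/3843 and 446/3843 at
$|\log_2FC| = 2$.

What it deliberately does **not** emulate: read-level sampling noise,
library-size/TPM renormalization coupling between genes, batch effects,
non-sinusoidal or damped waveforms, and condition-dependent noise. Tests
passing on this generator therefore demonstrate correctness of the
statistics and calibration of the p-value under a clean multiplicative
noise model — not robustness to waveform mismatch, which is out of scope.

Two generator facts the tests rely on:

* At `noise_cv = 0` the amplitude statistic recovers not $A/\sqrt 2$ but
  the exact finite-sample CV of the cosine on the six-point grid — the
  two differ by up to ~0.07 depending on where the grid hits the
  waveform, so tests compare against the exact finite-sample value.
* The mean measured amplitude of arrhythmic genes sits a few percent
  *below* $\mathrm{cv}\sqrt{1 - 1/6}$ (Jensen: $E[\sqrt X] <
  \sqrt{E[X]}$), so the corresponding test compares against a direct
  simulation of six-point log-normal draws, not the closed form.

## Reporting

`replicate_summary()` reduces per-replicate indices to the conservative
pair (min amplitude, max p) — thresholding that pair is provably identical
to the per-replicate AND rule, which is also property-tested.
`heatmap_order()` z-normalizes each gene's replicate-mean course to mean 0
and population SD 1 and sorts rows by ascending peak time (ties:
lexicographic gene id); `plot_heatmap()`, `plot_rhythm_indices()`,
`plot_peak_amplitude()` and `plot_time_course()` render the standard
figures, and tests assert only on the underlying tables, never on pixels.
The replicate-mean (rather than single-experiment) course feeds the
heatmap; with only two replicates this is the stablest single row per
gene.

```{r, fig.width = 5, fig.height = 3.5}
autoplot(scan_low)
```

## Validation strategy and problem sizes

The test suite checks, among others: exact equality of the vectorized
maximum-correlation search with a naive double-loop oracle; exact equality
of the Fisher p with exhaustive hypergeometric enumeration on universes up
to 50 genes; calibration of the empirical p-value (fraction of arrhythmic
genes at $p < 0.1$ equals $0.10 \pm 0.01$ over 10,000 genes with a
$10^5$-draw null, and $0.01 \pm 0.003$ for the two-replicate AND);
recovery of planted rhythms (200 genes at $A = 0.4$, noise CV 0.05:
$\ge 95\%$ sensitivity, zero false calls among 1800 arrhythmic genes, and
$\ge 90\%$ of peaks within ±2 h of truth — the ±2 h tolerance is a design
constant reflecting the 6-h sampling grid); and byte-identical pipeline
output under a fixed seed. Production-scale defaults ($10^6$ null draws,
3843 genes) run in seconds; test-scale sizes ($10^3$–$10^5$ draws) were
chosen as the smallest sizes at which the Monte Carlo tolerances above are
comfortably resolvable.

## Known limitations

* The period is fixed (default 24 h), never estimated; this is a
  detection screen, not a period-finding method (no Lomb–Scargle, JTK or
  RAIN equivalents).
* Six time points spanning 1.25 cycles cannot distinguish a damped
  oscillation from a sustained one, and phase resolution is limited to
  roughly the 6-h sampling interval.
* The raw $p < 0.1$ rule is intentionally uncorrected; an FDR column can
  be added downstream but is never used for the cycling call, so cycling
  counts at genome scale include an expected ~1% × amplitude-pass-rate
  false-positive contribution.
* Fold-change DEG calls carry no error control at all; they are a
  screening criterion, not inference.
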