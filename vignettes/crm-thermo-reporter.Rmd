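---
title: "Decoding cis-regulatory logic: the thermodynamic model and the robust reporter statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding cis-regulatory logic: the thermodynamic model and the robust reporter statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmkit)
```

# Scope

`crmkit` implements the computational loop used to dissect enhancers and
silencers of a developmentally regulated gene (the motivating system is
*Cebpa* in myeloid and red-blood-cell progenitor lines) at binding-site
resolution:

1. annotate transcription-factor (TF) binding sites on cis-regulatory
   module (CRM) sequences from alignment (count) matrices;
2. predict construct activity with a sequence-based thermodynamic model
   of transcription;
3. design site-killing mutations in silico and verify them by re-scanning;
4. infer TF roles (activator vs repressor) by fitting an ensemble of
   role assignments to reporter activity;
5. normalize dual-luciferase reporter measurements with robust
   errors-in-variables (EIV) regression and attach bootstrap confidence
   intervals;
6. generate synthetic data with known ground truth so that every stage is
   testable without external downloads.

This vignette documents the model forms, the estimator, the numerical
choices, and the limits of what the test suite demonstrates.

# Site annotation

A TF's binding preference is a position count matrix.  With pseudocount
$p$ (default 0.5) added to every cell, the frequency of base $b$ at
position $i$ is $f_i(b)$, and the **relative affinity** of a site $s$ is

$$ q(s) = \prod_i \frac{f_i(s_i)}{f_i(c_i)} \in (0, 1], $$

where $c$ is the consensus (per-position argmax, ties broken
alphabetically).  Both strands are scanned; windows containing `N` are
skipped; sites with $q \ge q_{\min}$ are reported.  The default
$q_{\min} = 0.01$ is deliberately permissive: thermodynamic models draw
real signal from weak sites, and the threshold only gates annotation —
occupancy arithmetic downweights weak sites by $q$ anyway.  Coordinates
are 0-based half-open throughout.

# The thermodynamic model

Bound TF configurations on a set of annotated sites are weighted by

$$ W(\sigma) = \prod_{i \in \sigma} K_{t(i)}\, q_i\, \nu_{t(i)}
   \prod_{\text{adjacent pairs}} \omega, $$

where $K$ is a per-TF binding scale, $\nu$ the condition-specific TF
concentration, and $\omega$ an optional cooperativity factor for declared
partner pairs bound within a gap limit (default 50 bp; the default model
declares none).  Overlapping sites are never co-bound.  Site occupancy is
the Boltzmann fraction

$$ O_i = \frac{\sum_{\sigma \ni i} W(\sigma)}{\sum_\sigma W(\sigma)}, $$

computed by a partition-function dynamic programme over sites sorted by
start (linear chain over the rightmost bound site), which
`enumerate_configurations()` cross-checks by explicit enumeration on
small instances.

Repression acts twice, as the data demand different reaches:

* **Quenching (short range).**  A repressor site $j$ within $d_q$ bp
  (edge-to-edge, default 150) of an activator site multiplies that
  activator's occupancy by $(1 - \gamma_j O_j)$, giving effective
  occupancies $O_i^{\mathrm{eff}}$.
* **Long-range (dominant) repression.**  The interaction strength
  $E = \sum_i \alpha_i O_i^{\mathrm{eff}}$ (activation efficiencies
  $\alpha$ as weights) is scaled by $\prod_j (1 - \beta_{R,j} O_j)$ over
  all repressor sites regardless of distance, giving $E'$.  This is the
  mechanism that lets a distal silencer pull a construct *below* the
  promoter-alone baseline.

Transcription initiation is an enzymatic barrier-crossing step:

$$ r = R_{\max} \exp\big(-\max(0,\, \theta - E')\big), $$

so basal activity is $R_{\max} e^{-\theta}$, activators lower the barrier
$\theta$, and the rate saturates at $R_{\max}$.  The published account of
the model describes quenching, a weighted-sum interaction strength,
long-range repression, and enzymatic initiation qualitatively; the
specific multiplicative $(1-\gamma O)$ and $(1-\beta_R O)$ factors and the
exponential law above are this package's declared forms, chosen for
boundedness, monotonicity, and dominance of full repression.  They are
isolated behind `site_occupancies()`, `interaction_strength()`, and
`transcription_rate()` so alternative forms can be swapped without
touching the rest of the pipeline.

Reporter constructs place the promoter and the distal CRM in one
coordinate frame separated by a site-free spacer (default 2000 bp of `N`,
standing in for vector backbone).  Since the model is distance-symmetric
beyond $d_q$, the orientation of the distal CRM is not modelled.  Folds
are always normalized to the promoter-only construct in the same
condition, which makes $R_{\max}$ cancel; the ensemble fitter therefore
fixes $R_{\max} = 1$ and does not attempt to recover it.

# In-silico mutagenesis

A site is killed by replacing every position with the base of *lowest*
pseudocounted frequency in the cognate matrix (alphabetical tie-break;
when the wildtype base is itself the rarest, the rarest *other* base is
used so that every edit is a real substitution).  The mutant sequence is
then re-scanned with all matrices; the design is accepted only if the
target scores $q < q_{\min}$ and no site absent from the wildtype scan has
appeared for any matrix.  Where the all-lowest choice fails these checks,
second-lowest bases are substituted at the implicated positions only,
searching combinations with the fewest fallbacks first, and the designer
fails loudly (listing the violating sites) if no combination works.
Sites that do not overlap the target cannot change, because every edit
lies inside the target; weak sites that *overlap* the target may be lost
collaterally, which the re-scan reports honestly.

# Role-ensemble fitting

With $n$ candidate TFs there are $2^n$ assignments of activator/repressor
roles.  `fit_ensemble()` fits each assignment's free parameters — per-TF
$\log_{10} K \in [-2, 2]$, $\alpha \in [0, 10]$ for activators,
$\gamma, \beta_R \in [0, 1]$ for repressors, and
$\theta \in [0.05, 10]$ — to an observed fold table by weighted least
squares on log folds (folds are ratio-scaled, so residuals belong on the
log scale), using L-BFGS-B from Latin-hypercube multi-starts.  The
assignment ranking by score is the inference; $\theta$ is only weakly
identified when no construct saturates, which is expected and harmless
for ranking.  Site locations do not depend on the parameters, so each
construct is scanned once and the per-evaluation work is a small C++
kernel.  Hierarchical clustering of low-scoring models is out of scope;
only the ranked list is produced.

# Robust EIV normalization of dual-luciferase data

Transfection efficiency varies multiplicatively from well to well (a 2-4
fold spread is typical), so Firefly luminescence $y$ is regressed on
Renilla luminescence $x$ through the origin, $y = \beta x$, and the slope
is the normalized activity.  Because both channels are noisy, the
residual is the *orthogonal* distance
$d_i(\beta) = (1+\beta^2)^{-1/2}(y_i - \beta x_i)$, and because outliers
are common, the loss is Tukey's biweight $\rho_c$ with $c = 4.7$, paired
with an M-estimate of scale $S$ solving
$\tfrac1n \sum_i \chi(d_i/S) = \kappa$ with $\chi$ the biweight at
$c = 1.56$ and $\kappa = 0.05$.

**A numerical finding that shaped the implementation.**  Re-solving $S$
inside the loss and minimizing $\sum_i \rho(d_i/S(\beta))$ over $\beta$ is
degenerate: both the loss and the constraint depend on the data only
through $d_i/S$, so the objective is nearly invariant to $\beta$ and does
not discriminate good fits from bad ones.  The information sits in the
scale itself.  The package therefore uses the standard two-step reading
of this equation pair (an S-estimate followed by an M-step):

1. $\beta_S = \arg\min_\beta S(\beta)$ — the S-estimator of the slope;
2. $\hat\beta = \arg\min_\beta \sum_i \rho_{4.7}(d_i(\beta)/S^*)$ with the
   scale frozen at $S^* = S(\beta_S)$.

On exact proportional data $S^* = 0$ and $\hat\beta$ is recovered
exactly with zero loss.  The $\kappa = 0.05$ scale equation implies a
breakdown point of $\kappa/(c^2/6) \approx 12\%$: 10% gross outliers
barely move the slope (the test suite asserts < 1% error), while 20%
contamination exceeds the breakdown and requires raising $\kappa$ (the
suite demonstrates recovery at $\kappa = 0.2$).

**Optimizer.**  Both stages use a deterministic log-spaced grid around
the robust start $\mathrm{median}(y_i/x_i)$ (201 points spanning two
decades; the fixed-scale stage uses a denser grid because its loss is
cheap but can be multimodal) followed by golden-section refinement, with
relative tolerance $10^{-7}$ and an evaluation cap of 1000 per refinement
stage.  The best point ever evaluated is returned, which preserves
needle minima at exact fits.  The M-scale equation is solved by bracketed
bisection to $10^{-12}$ relative width; when too many residuals are
exactly zero the equation has no positive root and $S = 0$ is returned
with a degenerate flag.

**Confidence intervals** resample $(x_i, y_i)$ pairs with replacement
(999 replicates by default) and apply the basic bootstrap
$(2\hat\beta - q_{1-\alpha/2},\; 2\hat\beta - q_{\alpha/2})$.  Fold-change
CIs pair two independent replicate streams (numerator and denominator
groups) by replicate index and apply the basic bootstrap to the ratio.
A caveat the acceptance suite measures rather than hides: under the
default synthetic conditions (10 replicates, sdlog 0.35 transfection
spread, 10% measurement CV) the basic pair bootstrap *underestimates* the
slope's sampling spread, and the empirical coverage of the nominal 95%
interval is about 85% rather than 90–98%.  A plain total-least-squares
oracle shows the same underdispersion, so this is a property of the
bootstrap under this design at small $n$, not of the robust estimator;
users who need calibrated intervals should increase replicates.

# qPCR relative expression

Relative expression of the target against the reference gene is
$2^{-\Delta C_t}$ with $\Delta C_t = C_t^{\mathrm{target}} -
C_t^{\mathrm{ref}}$, normalized so the mean over uninduced replicates
is 1.  A rendering of this formula elsewhere carries the opposite
exponent sign, under which expression would *increase* with the threshold
cycle; the standard convention is used here.  Pooled condition contrasts
use the Wilcoxon rank-sum test (exact null distribution up to a combined
$n$ of 20 without ties, normal approximation with continuity correction
otherwise, via `stats::wilcox.test`).

# The synthetic-data module

`simulate_luminescence()` draws a per-well transfection efficiency
$T_i \sim \mathrm{lognormal}(0, 0.35)$ — the default sdlog yields the
observed 2–4 fold well-to-well spread at $n = 10$ — and sets
$x_i = T_i(1+\varepsilon_i)$, $y_i = \beta T_i(1+\delta_i)$ with
independent mean-zero noise of CV 10% by default, plus an optional
fraction of gross Firefly outliers.  `simulate_crm()` plants matrix
consensus sites in an i.i.d. background; `simulate_reporter_dataset()`
multiplies model-predicted folds by mean-one log-normal noise and can
expand them to raw luminescence.  Every generator is a pure function of
its arguments including the seed, and returns a truth object sufficient
to re-run its recovery test.

What passing recovery tests do **not** show about real data: the
generators have no heteroscedastic plate effects beyond the transfection
term, no sequence context effects on binding beyond the matrices, no
chromatin state, and independent wells; real assays violate all of
these to some degree.

# Problem sizes in the test suite

The suite runs at desk scale: occupancy DP vs enumeration on 200 random
instances of up to 12 sites; mutagenesis design-apply-rescan on 100
planted-site sequences; role recovery on 8 assignments x 6 constructs x 3
conditions over 50 simulation seeds at 5% fold noise; bootstrap coverage
over 500 simulated groups at the default replicate count of 10.  The
original multi-CRM refit that motivated the model (46 CRMs over three
conditions) is not reproducible from the material shipped here — its
dataset and fitted parameters are not available — and the
property/recovery suite above substitutes for it; this is a statement
about available inputs, not about the method.

# Known limitations

* The exact functional forms of quenching, long-range repression, and
  initiation are declared, not fitted to the original data; predictions
  are qualitative unless the parameters are calibrated.
* Homotypic cooperativity and competition beyond overlap exclusion are
  not modelled; cooperativity requires explicit partner declarations.
* The EIV regression estimates a slope through the origin only — no
  intercept, no heteroscedastic weighting.
* Bootstrap CIs undercover at small replicate counts (measured above).
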