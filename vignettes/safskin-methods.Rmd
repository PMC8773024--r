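---
title: "Methods: fractionation response surfaces and the epidermal resistance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractionation response surfaces and the epidermal resistance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safskin)
```

safskin analyses supercritical antisolvent fractionation (SAF) campaigns
and screens the skin penetration of the recovered compounds. It has two
computational cores: ordinary-least-squares response-surface modelling of
yields and enrichment ratios over a two-factor central composite design
(CCD), with multi-response desirability optimization; and a compartmental
series–parallel resistance model of epidermal permeability. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions taken where the analysis was genuinely open.

## Yields and enrichment ratios

A SAF run splits an ethanolic feed solution into a precipitated fraction
(PV, the antisolvent-insoluble solutes) and a downstream fraction (DV, the
solutes carried along with the CO2–ethanol phase). All recoveries are
carried as weight percentages on the 0–100 scale throughout the package —
fractions of one are never exposed, because every number a practitioner
reads or reports is in wt%:

* vessel yield: $Y_i = 100\, m_i / m_\mathrm{FS}$, where $m_i$ is the mass
  collected in vessel $i$ and $m_\mathrm{FS}$ the extract mass fed;
* overall yield: $Y_\mathrm{SAF} = Y_\mathrm{PV} + Y_\mathrm{DV}$;
* enrichment of compound $i$ in fraction $j$:
  $E_{i/j} = C_{i/j} / C_{i/\mathrm{FS}}$, with concentrations in wt%;
* joint enrichment: $E_{\mathrm{ALL}/j} = \sum_i C_{i/j} \big/ \sum_i
  C_{i/\mathrm{FS}}$, a concentration-weighted mean of the individual
  ratios, so it is always bracketed by their extremes.

`validate_mass_balance()` checks $Y_\mathrm{SAF} = Y_\mathrm{PV} +
Y_\mathrm{DV}$ with a default tolerance of 0.05 wt%: one half-unit of the
last digit at which yields are reported (0.1 wt%). `read_saf_runs()` runs
the check on every load and reports violations as warnings, never errors,
because a discrepant row is a data-quality signal, not a reason to refuse
the table.

## The central composite design

The packaged design (`calendula_design()`) crosses pressure (80–160 bar)
with CO2 flow rate (10–60 g/min): four factorial points at coded
$(\pm 1, \pm 1)$, four axial points at the star level, and five replicated
center points at (120 bar, 35 g/min) — 13 runs. Natural levels are stored
verbatim per coded level rather than derived from a star distance
$\alpha$. This matters: the tabulated natural levels imply
$\alpha \approx 1.43$ for pressure and $\approx 1.39$ for flow rather than
a single nominal star distance, and we treat the printed operating
conditions — the pressures and flows actually set on the rig — as the
ground truth for fitting.

## Quadratic response-surface fitting

Each response is modelled as the full second-order polynomial

$$ y = \beta_0 + \beta_1 P + \beta_2 Q + \beta_{11} P^2 + \beta_{22} Q^2
   + \beta_{12} P Q, $$

fit by OLS. Term sets are user-specified per response
(`"full"`, `"no_q2"`, `"no_interaction"`, or an explicit term vector);
no automatic stepwise reduction is performed, because reduced published
models come with their term set already decided and an automatic rule
would silently diverge from it. Standard errors use the unbiased residual
variance, p-values are two-sided t-tests on the residual degrees of
freedom, $R^2$ is reported on the percent scale, and
$s = \sqrt{SS_\mathrm{res}/(n-k)}$.

### Natural versus coded units

`fit_response_surface()` fits in natural units (bar, g/min) by default and
offers `units = "coded"` (affine centring/scaling by the design's center
and factorial step). Predictions, $R^2$, $s$ and the natural-unit
coefficient vector are parametrization-invariant (and tested to be); the
*individual coefficient p-values are not*, because centring removes the
strong correlation between a linear term and its own square. For the
packaged dataset the published significance pattern is only reproduced by
a coded fit whose axial runs sit at codes $\pm\sqrt 2$ — the rotatable
star distance for two factors — which strongly suggests the original
analysis was run in coded units with $\alpha=\sqrt 2$ and back-transformed
for display (the test suite verifies this correspondence). We nevertheless
default to natural units on the as-recorded conditions: that is the
transparent reading of the run table, the fitted surfaces and optima are
identical either way, and the coded mode remains available for
significance cross-checks.

Refits of the packaged 13-run table reproduce the published coefficient
tables to within a few tenths of a percent up to a few percent per
coefficient, not to printed precision: the packaged responses are rounded
to 0.1 wt% (enrichments to 0.01), and the interaction coefficient of the
overall yield, for example, is pinned to exactly $12.6/504 = 0.025$ by the
four rounded factorial responses whatever the parametrization. The
reproduction report (`reproduce_report()`) pairs every computed value with
its published counterpart and the absolute difference rather than hiding
this behind a verdict.

### Surface analysis

`stationary_point()` solves the $2\times 2$ gradient system and
classifies the critical point by the Hessian's eigenvalue signs; a Hessian
singular at relative tolerance $10^{-10}$ (scaled by its largest entry) is
reported as degenerate rather than solved. `contour_grid()` evaluates the
surface on an inclusive, evenly spaced lattice in row-major order — the
numeric backing for contour maps; `autoplot()` methods draw them. For the
packaged joint-enrichment response the fitted surface has an interior
maximum near 130 bar and 31.5 g/min, at intermediate values of both
factors.

## Desirability optimization

Multi-response optimization uses Derringer–Suich ramp desirabilities with
equal weights and geometric-mean composition — the standard construction
behind "composite desirability" readouts in commercial DOE software. For
a maximized response, $d = 0$ at or below the lower anchor $L$, 1 at or
above the target ($=U$), and $((y-L)/(U-L))^w$ between; minimization
mirrors the ramp and target goals ramp both ways. The geometric mean
annihilates: any $d_i = 0$ forces $D = 0$, so no response can be traded
away entirely.

Anchors default to the observed range of each response in the run table —
the least-informative defensible choice when no specification limits are
stated — and are fully overridable. The search is deterministic: a dense
grid scan (201 × 201 by default) followed by a Nelder–Mead polish from
the best cell, with bounds enforced by clamping. A simplex polish is used
deliberately: the composite surface is continuous but kinked wherever a
ramp saturates, which defeats finite-difference gradient methods. An
all-zero desirability landscape is returned as a flagged degenerate
result with $D = 0$, not an exception, so batch optimizations over many
specifications do not abort.

For the packaged campaign (maximize overall yield and joint enrichment,
observed-range anchors), the optimizer lands at about 152.5 bar and
51 g/min with $D \approx 0.83$. The published joint optimum (153 bar,
42 g/min, $D = 0.673$) used optimizer settings — in particular anchor
bounds and possibly the response set — that are not stated, so exact
agreement is not expected or claimed; the pressure coordinate agrees
closely, the flow coordinate does not. `reproduce_report()` documents
both triples and their differences.

## The compartmental skin model

The epidermis is modelled as four compartments in series — stratum
corneum (SC), granulosum (SG), spinosum (SS), basale (SB), outermost to
innermost — each crossed by two parallel routes, intercellular and
transcellular:

$$ \frac{1}{R_i} = \frac{1}{R_{i,\mathrm{inter}}} +
   \frac{1}{R_{i,\mathrm{trans}}}, \qquad
   R_\mathrm{cells} = R_\mathrm{SC} + R_\mathrm{SG} + R_\mathrm{SS} +
   R_\mathrm{SB}, \qquad
   \frac{1}{R_\mathrm{skin}} = \frac{1}{R_\mathrm{cells}} +
   \frac{1}{R_\mathrm{shunt}}. $$

The appendageal shunt (hair follicles and glands) is a fixed conductance,
default $1/R_\mathrm{shunt} = 2\times 10^{-11}$ m/s. Resistances are in
s/m; the permeability coefficient is $K_p = 1/R_\mathrm{skin}$, converted
from m/s to the customary cm/s before logging:
$\log K_p = \log_{10}(100/R_\mathrm{skin})$. This unit convention is fixed
by the packaged data: $R_\mathrm{skin} = 7.74\times10^7$ s/m must map to
$\log K_p = -5.89$. Predictions are corrected by a constant additive
offset, default $-1.12$ log-units, an empirical calibration of
continuum-solvation resistance predictions against measured
permeabilities.

Decisions fixed by the data or by physical reasoning:

* **Rate-limiting compartment** is the one with the largest combined
  resistance; ties go to the outermost layer, which the permeant meets
  first.
* **Preferred pathway** per compartment is simply the arm with the smaller
  resistance (ties count as intercellular); no attempt is made to infer
  pathways from any other signal.
* **Per-layer log-permeability** is reported as $\log_{10}(100/R_i)$ —
  the layer's own conductance on the cm/s log scale. (Published per-layer
  "log R" rows for this system are internally inconsistent between table
  and text; the text values equal the layer log-permeability in cm/s,
  which is what we compute.)
* **Deviation sign** against a reference system is reference minus
  corrected prediction — the only convention consistent with all the
  packaged reference comparisons. Under it, the ferulic-acid deviation
  against the calculated-epidermis reference is genuinely $-0.46$ (the
  prediction overshoots the reference), where the source table prints the
  magnitude 0.46.
* **Desquamation comparison** is made in m/s: the corrected cm/s value is
  shifted by $-2$ before comparing to the turnover coefficient
  $\log K_D = -9$. Only under this reading does a compound with corrected
  $\log K_p = -8.39$ cm/s ($-10.39$ m/s) fall below the desquamation rate.
* **Classification**: a permeant whose rate-limiting layer is the SC is
  `"retained in SC"` (the SC is considered a safe, dead-cell layer); one
  that penetrates deeper but more slowly than desquamation is
  `"safe - below desquamation"`; anything faster is `"flag for review"` —
  a prompt for scrutiny, deliberately not a toxicity verdict.
* **Blocked pathways** are infinite resistances; input files accept an
  empty cell or the token `inf`.
* A nonzero vehicle/water partition term shifts the predicted log
  permeability additively; it is zero for the packaged aqueous-vehicle
  profiles and carried as a documented extension point.

## Synthetic data

Two seeded generators make every stage testable without measured data.

`simulate_saf_table()` draws one response per design row as the quadratic
surface mean plus independent homoscedastic Gaussian noise — exactly the
implicit error model of the OLS analysis. Negative draws are clipped to
zero with a warning and a flag, since a recovery cannot be negative even
though the linear model is unconstrained; no heteroscedastic option is
provided in this version. With the published overall-yield surface as
truth and noise $\sigma = 2.66$ wt% (the refit residual SD), 500
replicate campaigns at the 13-run design recover every coefficient with
mean bias within Monte-Carlo error of zero and 95% confidence intervals
covering at nominal rate — the test suite runs exactly this harness.

`simulate_profiles()` draws each pathway resistance independently and
log-uniformly within per-compartment ranges (default $10^6$–$10^{12}$
s/m) — a broad scale-free prior over layered barriers used to
property-test the network (parallel/serial bounds and monotonicity on
1,000 profiles).

What the generators do **not** emulate: correlation between responses
measured on the same run, heteroscedastic measurement error, rounding of
recorded responses, correlated inter/trans resistances within a layer, or
any actual fractionation physics. Passing parameter-recovery and
property tests therefore demonstrates the estimators and the network
algebra are correct under their stated assumptions — not that the
quadratic model or the resistance decomposition is an adequate
description of any particular rig or skin sample.

## Problem sizes and tolerances

The test suite works at desk scale: the 13-run packaged table, 500
Monte-Carlo replicates for parameter recovery, 1,000 random profiles for
the network properties, and 201–401 point grids for optimizer stability —
all chosen so the full suite runs in well under a minute while leaving
Monte-Carlo error far below the tested effect sizes. Numerical
tolerances: Hessian singularity at $10^{-10}$ relative; coded/natural
equivalence at $10^{-8}$ relative; published-value comparisons at the
precision the source values are printed with (three significant digits
for resistances, two decimals for log-permeabilities).

## Known limitations

* Only the epidermis stack is modelled: no dermis, no blood compartment,
  no finite-dose kinetics.
* Per-compartment resistances are inputs; computing them from molecular
  structure (continuum-solvation membrane thermodynamics) is out of
  scope.
* The quadratic model is a local response-surface approximation; the
  stationary-point and optimization machinery will happily analyse an
  extrapolated surface, and `predict_surface()` only warns when asked to
  leave the factor bounds.
* Composite-desirability results depend materially on anchor choices;
  the defaults are a convention, not a recommendation, and should be
  replaced by process specifications where they exist.
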