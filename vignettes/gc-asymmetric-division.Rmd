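---
title: "Modeling asymmetric division of antigen and transcription factors in the germinal center"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling asymmetric division of antigen and transcription factors in the germinal center}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcasym)
```

## The model

`gcasym` simulates a germinal-center (GC) reaction over 21 days (504 h) as a
two-compartment agent-based model in which every B cell carries an embedded
three-factor gene-regulatory network (GRN). The two scales are coupled in
both directions: light-zone signalling events (antigen collection, T-cell
help) feed signals into each cell's GRN, and each cell's BLIMP1 level feeds
back into its fate (plasma-cell differentiation and exit).

### The intracellular network

Each cell carries concentrations of BLIMP1 ($p$), BCL6 ($b$) and IRF4 ($r$),
in units of $10^{-8}$ M, evolving as

$$
\begin{aligned}
\dot p &= \mu_p + \sigma_p\frac{k_b^2}{k_b^2+b^2}
        + \sigma_p\frac{r^2}{k_r^2+r^2} - \lambda_p p,\\
\dot b &= \mu_b + \sigma_b\frac{k_p^2}{k_p^2+p^2}\frac{k_b^2}{k_b^2+b^2}
        \frac{k_r^2}{k_r^2+r^2} - (\lambda_b + \mathrm{BCR})\, b,\\
\dot r &= \mu_r + \sigma_r\frac{r^2}{k_r^2+r^2} + \mathrm{CD40} - \lambda_r r,
\end{aligned}
$$

with $\mathrm{BCR} = \mathrm{bcr}_0\,\mathbb{1}_{\text{FDC contact}}
\,k_b^2/(k_b^2+b^2)$ and $\mathrm{CD40} = \mathrm{cd}_0\, a\,
k_b^2/(k_b^2+b^2)$, where $a \in (0,1]$ is the cell's receptor affinity.
BCL6 maintains the GC phenotype by repressing BLIMP1; IRF4 activates itself
and BLIMP1; BLIMP1 and IRF4 both repress BCL6. BcR signalling degrades BCL6;
CD40 signalling induces IRF4 in proportion to affinity.

With the default kinetic constants ($\mu_p = 10^{-6}$, $\mu_b = 2$,
$\mu_r = 0.1$, $\sigma_p = 9$, $\sigma_b = 100$, $\sigma_r = 2.6$,
$k = 1$, $\lambda = 1$; concentration unit $10^{-8}$ M, time unit hours) the
autonomous network is bistable:

```{r}
grn_steady_states()
```

The BCL6-high state is the phenotype of centroblasts, centrocytes and memory
B cells; the BLIMP1-high state (IRF4 $\approx 2$ units) is the plasma-cell
state. A cell whose BLIMP1 reaches 8 units ($8\times10^{-8}$ M, inclusive)
is committed to the plasma-cell program. The IRF4 subsystem is autonomous
under zero signals and nearly tangent to its low fixed point: the unstable
threshold sits at $r \approx 0.219$, only 0.02 units above the stable
resting level 0.2. This near-tangency matters: a small CD40 kick commits a
cell, but with a long, affinity-dependent delay through the slow channel,
which is the source of the gradual progression to the BLIMP1-high state
seen in the daughter-cell experiments.

### Division of antigen and transcription factors

A division distributes internalized antigen (Ag) and the three factors
between the daughters. Each species class divides asymmetrically with
probability $P$ (one shared Bernoulli draw when `coupling = "coupled"`,
independent draws otherwise); an asymmetric division gives one daughter the
fraction $L \in [0.5, 1]$ (the polarity level) and the other $1-L$, with the
high Ag and high TF shares directed to the same daughter. $P = 0$ is by
definition $L = 0.5$. Conservation is exact: the daughters' amounts always
sum to the parent's.

### The cellular reaction

Founder cells (default 100) enter the dark zone (DZ) over the first four
days with the founder TF state $(0, 5, 0)$ and a receptor genotype placed
5-10 lattice steps from the shape-space optimum (4-D integer lattice,
Gaussian affinity $a = e^{-d^2/\gamma^2}$). Centroblasts (CBs) divide every
7 h ($\pm 10\%$ jitter), mutating one genotype coordinate by $\pm 1$ with
probability 0.5 per daughter per division. After the founder expansion
(6 divisions) a CB differentiates over `cb_to_cc_delay` hours into a
centrocyte (CC) in the light zone (LZ).

A CC occupies a free FDC site and tests it twice per hour for 3 h; each test
captures one antigen portion with probability $a$ and refreshes the
apoptosis clock; BcR signalling is active throughout the contact. A CC that
captured nothing dies at the end of the window. Otherwise it competes for
Tfh help for up to 3 h: each of the `n_tfh` Tfh cells helps one contacted CC
per step, preferring the largest retained antigen load (ties to the lowest
cell id), delivering the CD40 signal scaled by affinity. Accumulating 0.7 h
of contact selects the cell, which recycles to the DZ as a CB with 2
further divisions; a CC that exhausts its search window unselected dies.
Selection is therefore a single attempt — this choice keeps the LZ residence
time short (3-6 h) and is what places the CB-to-CC ratio in the
experimentally observed range; letting failed CCs cycle back to the FDCs
until their 10-h clock expires inflates the LZ compartment several-fold.

### Output-cell fates

When a recycled CB finishes dividing:

* BLIMP1 $\ge 8$: exits as a **plasma cell** (PC), whatever its antigen
  status;
* BLIMP1-low but carrying the parent's **whole** antigen load (only possible
  through asymmetric Ag division with $L_{Ag} = 1$): exits as a **memory B
  cell** (MBC);
* no antigen: returns to the LZ as a CC, with any antigen advantage erased;
* a partial antigen load (from a symmetric split of a carrier): the cell is
  retained in the DZ and exits as a PC if its BLIMP1 later crosses the
  threshold.

In addition, any cell past its division phase — a returned CC, a
differentiating CB, or a retained cell — exits as a PC the moment its
BLIMP1 reaches the threshold. This threshold-triggered egress is essential:
under symmetric TF division every split halves BLIMP1, so no cell can be
BLIMP1-high exactly at division completion, yet plasma cells demonstrably
arise in that regime; they are cells whose network completes the transition
shortly after their last division.

Antigen positivity for output-cell typing means "inherited the entire load",
not merely "carries some antigen". With the literal `ag > 0` reading, a
fully symmetric run would flood the output with MBCs (every endpoint
carries a quarter of the collected load), while the whole-load reading
reproduces the expected regime: symmetric division produces no MBCs at all,
terminates the reaction prematurely for lack of returning CCs, and sends
the DZ-to-LZ ratio to infinity once the CC count reaches zero.

## Observables

The DZ-to-LZ ratio is the number of centroblasts divided by the number of
non-apoptotic centrocytes, recorded hourly, with an infinity marker when no
live CC exists. Cells retained in the DZ awaiting threshold crossing are
tracked separately (`await` column) and are not counted as centroblasts;
they are differentiating cells, and counting them would let their slow
accumulation dominate the ratio late in the reaction. The temporal switch is
summarized by the fraction of PC exits after the day-6 peak (boundary 144 h,
strictly-greater counts as after; the `switch_flag` requires at least 80%
of PCs after the peak and the first MBC before it — an explicit
operationalization, since the switch is qualitative). Cumulative output
curves and cross-scenario fold changes are computed at the end of the run.

## Calibrated defaults

The simulation is desk-scale: populations of a few thousand live cells
rather than the much larger reactions in vivo, so absolute output counts
are not comparable across model families; ratios, fractions and fold
changes are. Parameters fall into three groups.

**Fixed by design** (units h): duration 504; engine step $dt = 0.1$ with GRN
substeps of 0.05 (classical 4th-order fixed-step integration; halving the
substep changes 504-h endpoints by $<10^{-6}$ units); CB cycle 7; founder
divisions 6; recycle divisions 2; CC lifetime 10; collection window 3 at 2
tests/h; help requirement 0.7 within a 3-h search window.

**Structural choices**: founder influx over 92 h (a multi-day influx gives
the founder wave the temporal width seen in its output kinetics; a 24-h
influx compresses all founder-derived selections into days 2-4);
CB-to-CC differentiation delay 2 h; 600 FDC sites and 30 Tfh cells, so Tfh
help, not FDC access, is the binding constraint — making competition for
help the engine of affinity maturation; retained (awaiting) cells die by
neglect after 24 h if their network never completes the transition.

**Calibrated signal scales**: $\gamma = 5$ lattice units,
$\mathrm{bcr}_0 = 16$, $\mathrm{cd}_0 = 7.5$. These three interact:

* $\gamma$ sets capture probabilities. Founders at distance 5-10 then have
  $a \approx 0.02$-$0.37$, enough for the reaction to be self-sustaining
  while leaving room for maturation.
* $\mathrm{bcr}_0$ sets how deeply BCL6 collapses during antigen collection.
  The collapse both elevates BLIMP1 toward (but, at the default, not past)
  the threshold and opens the $k_b^2/(k_b^2+b^2)$ gate that amplifies the
  subsequent CD40 signal. Because BCL6 rebounds within 1-2 h, cells helped
  promptly after collecting receive a far stronger effective CD40 kick than
  cells that queued — commitment is gated by competitive success, not by
  affinity alone.
* $\mathrm{cd}_0$ scales the CD40 kick itself and thereby the fraction of
  selected cells whose network commits, the quantity behind both the
  temporal switch and the memory/plasma fold changes across polarity
  regimes.

All of these are configuration fields; none is hard-coded.

## What the simulations show, and what they do not

The scenario sets sweep asymmetric-division regimes: nine simulations with
cosegregating TFs (fully symmetric; TF-only asymmetry; Ag-only asymmetry,
the reference; coupled at $P = 0.72$; uncoupled with $P_{TF} = 1$) and 27
coupled simulations with per-factor polarity levels over
$\{1.0, 0.9, 0.75\}$ (IRF4 outermost, BCL6 middle, BLIMP1 innermost in the
canonical ordering). The reference scenario reproduces a DZ-to-LZ ratio
fluctuating in the 2-4 band from day 4 on, plasma-cell output concentrated
(~90%) after the day-6 peak, and continuous memory output; the fully
symmetric scenario produces no memory cells, concentrates ~9 in 10 plasma
cells in the first six days and collapses; lowering the common coupled
polarity level from 1.0 to 0.75 multiplies memory output several-fold at
the expense of plasma cells.

The generator emulates a single idealized reaction: one antigen, a fixed
Tfh pool, no antibody feedback, no re-entry of output cells, discrete
antigen portions, and a caricature memory definition (antigen-retaining,
BLIMP1-low exiting cells). Passing tests therefore demonstrate internal
consistency of the mechanism — which division regimes can and cannot
produce the observed zone ratio and temporal switch — not quantitative
agreement with any particular in vivo dataset. Absolute cell counts depend
on the LZ capacities chosen here and are intentionally out of scope.

## Numerical and reproducibility notes

One global Mersenne-Twister stream per run, seeded at entry; draws occur in
a fixed order (founder arrivals and genotypes; per-division mode, side,
cycle jitter and hypermutation in cell-id order; FDC tests). Identical
seed, configuration and package version give bit-identical outputs, which
is asserted by round-tripping the configuration echo written to
`summary.json`. Threshold crossings are refined by bisection to 0.01 h.
Steady states come from Newton iteration with the analytic Jacobian from a
deterministic 216-point grid, de-duplicated at $10^{-6}$ and classified by
Jacobian eigenvalues; residuals are below $10^{-9}$. Concentrations are
clipped at zero only within one-step integration error. The engine aborts
with a diagnostic if any live cell's state becomes non-finite or any count
goes negative.

Test-suite problem sizes: the unit tests use shortened reactions (40-60
founders, 120-360 h); the end-to-end suite and `scripts/acceptance.R` run
the full default configuration (100 founders, 504 h) with five seeds per
stochastic scenario and compare cross-seed medians.

## Known limitations

* The Ag-full/BLIMP1-low memory definition classifies rather than models
  memory commitment; no transcriptional memory program is represented.
* Spatial structure is reduced to two well-mixed compartments with
  capacity-limited contact processes; migration and chemokine dynamics are
  not modeled, so trans-zone migration rates are not an observable here.
* The probability of asymmetric TF division is treated as a free scenario
  parameter; measured per-factor asymmetry rates differ between factors.
* Selection is single-attempt; allowing failed centrocytes to re-enter the
  FDC queue changes compartment sizes materially (see above) and would
  require re-calibration of the LZ capacities.
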