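---
title: "A paracrine model of symmetry breaking in the avian marginal zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A paracrine model of symmetry breaking in the avian marginal zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(axisbreak)
```

## The biological problem

Before gastrulation the chick embryo is a flat, radially symmetric disc, one
cell thick, with no preferred direction. The first morphological sign of
bilateral symmetry is the primitive streak, which emerges from the posterior
marginal zone — the annular rim of cells surrounding the area pellucida. Two
TGF-beta-family ligands bracket this event: Vg1/GDF1, expressed posteriorly
and both necessary and sufficient for streak initiation, and BMP4, expressed
anteriorly and inhibitory to streak formation. Strikingly, both genes start
out expressed throughout the embryo and only later segregate to opposite
poles. The geometry of the early blastodisc (a large, thin disc suspended
between two fluid volumes, with almost no extracellular space) makes stable
long-range diffusion gradients implausible, so the segregation must arise
from short-range, cell-to-cell (paracrine) signalling.

This package implements a lattice model of that process: the marginal zone is
a closed ring of `n_cells` identical cells; each cell secretes extracellular
BMP4 (`B`) and Vg1 (`V`) and maintains two intracellular factors, `FB`
(candidate: Gata2) and `FV` (candidate: Pitx2). All interactions are local
Hill-type responses to *perceived* signals — windowed means of the ligand
fields over the `2r + 1` cells within the coupling radius `r`.

## The model

Per cell \(i\), with perceived signals \(S^B_i\), \(S^V_i\) and Hill
activation \(h^+(x,K) = x^n/(K^n + x^n)\), inhibition \(h^- = 1 - h^+\):

\[
\begin{aligned}
dF_{B,i}/dt &= \alpha_B\, h^+(S^B_i, K_{BB})\, h^-(S^V_i, K_{VB}) - \delta_F F_{B,i}\\
dF_{V,i}/dt &= \alpha_V\, h^-(S^B_i, K_{hi})\,\bigl[h^+(S^V_i, K_{VV}) + c_{BV}\, h^+(S^B_i, K_{lo})\bigr] - \delta_F F_{V,i}\\
dB_i/dt &= \beta_B F_{B,i} - \delta_B B_i + \mathrm{src}^B_i\\
dV_i/dt &= \beta_V F_{V,i} - \delta_V V_i + \mathrm{src}^V_i
\end{aligned}
\]

The wiring encodes four qualitative facts: BMP4 sustains its own branch
(\(K_{BB}\)); Vg1 shuts the BMP4 branch down (\(K_{VB}\)); Vg1 sustains
itself (\(K_{VV}\)); and BMP4 has a *biphasic* effect on the Vg1 branch — the
band-pass pair \((K_{lo}, K_{hi})\) makes intermediate perceived BMP4 induce
`FV` (weight \(c_{BV}\)) while high perceived BMP4 extinguishes it. The
band-pass term is this package's mechanistic reading of the central
experimental paradox: the same BMP4 source suppresses Vg1 when grafted
posteriorly (where baseline BMP4 plus the bead pushes \(S^B\) past
\(K_{hi}\)) but induces Vg1 when grafted anteriorly (where the flanks of the
bead sweep \(S^B\) through the rising side of the band).

The model is fully dimensionless: time is measured in intracellular factor
lifetimes (\(1/\delta_F\)) and concentrations on the scale of the Hill
constants. No mapping to hours or protein concentrations is attempted.

## Why a pattern forms: the instability route

`steady_states()` enumerates the homogeneous fixed points; at the calibrated
defaults there are three relevant ones: a BMP4-dominant attractor, a
Vg1-dominant attractor, and a doubly-active state (both ligands on, as in the
pre-stage-X embryo) that is a saddle. `mode_spectrum()` gives the growth rate
of every spatial Fourier mode around a homogeneous state, using the circulant
structure of the coupling: each mode's 4x4 Jacobian is the single-cell
Jacobian with signal-mediated entries scaled by the window transfer factor
\(g(k)\).

A systematic scan of this model family (thousands of parameter sets, all
admissible Hill constants and coupling radii) shows that the leading growth
rate is *monotone* in \(g\): with one shared coupling radius for both
ligands, no parameter set yields a finite-wavelength (Turing-type) maximum.
The uniform mode is always the fastest. Symmetry breaking therefore proceeds
by the bistable route:

1. the doubly-active launch state is unstable, with a *difference-type*
   unstable direction (BMP4 up / Vg1 down, or the reverse);
2. seeded cell-to-cell noise makes different stretches of the ring commit to
   the BMP4- or Vg1-dominant attractor, at a spatial grain set by the
   coupling window;
3. domain walls then interact: walls bounding a narrow BMP4 stretch overlap
   through the band-pass term (each wall's flank elevates Vg1 production a
   coupling-window deep into the BMP4 side), so narrow BMP4 gaps collapse
   and the pattern coarsens;
4. the surviving walls are pinned: the band weight `c_BV` is calibrated to
   the front's Maxwell point, where an isolated BMP4/Vg1 interface is
   stationary on the lattice, so the final bipolar pattern is stable.

`launch_base()` returns the launch state displaced by a small uniform factor
(`bias`) towards the Vg1 basin. The displacement is *spatially* uniform — it
carries no positional information, and the broken symmetry (where the BMP4
domain ends up) is still chosen entirely by noise. It encodes the
observation that the early embryo is streak-competent throughout: most of
the ring resolves towards Vg1, and the anterior (BMP4) territory nucleates
from local fluctuations.

## Calibration

The rate and Hill constants are not observable; the committed defaults in
`default_parameters()` were fixed by a staged, seeded search
(`calibrate()` exposes the machinery):

1. *structure*: both single-ligand attractors and a doubly-active saddle must
   exist; the saddle's leading eigenvector must be difference-type; the
   BMP4-dominant level must sit on the rising flank of the band so that an
   ectopic anterior source has induction headroom;
2. *front balance*: the wall-speed assay (half ring in each attractor)
   must give a near-stationary interface — `c_BV` is the tuning knob;
3. *behaviour*: seed ensembles of the unperturbed run must reach bipolar
   patterns, and the grafting/knockdown/fragmentation experiments must
   reproduce their qualitative outcomes.

Two parameters deserve comment. The coupling radius (`coupling_radius = 3`,
a 7-cell window on a 100-cell ring) controls the commit grain: smaller radii
leave frozen multipolar patterns, larger radii make whole fragments commit
to a single fate. Each lattice site should be read as a small patch of
marginal-zone cells rather than a single cell, so the window remains a
short-range, paracrine neighbourhood. The Hill exponent 4 is the usual
choice for cooperative transcriptional responses.

## The in-silico experiments

`run_experiment()` encodes seven protocols (see `?run_experiment`). All
perturbation positions are defined relative to each seed's *realised* axis
(posterior = the Vg1 centroid), because the model is rotation-equivariant.
Every verdict is paired: the perturbed trajectory is compared with the
same-seed unperturbed continuation. Beads and pellets are constant-rate
sources (a reservoir releasing ligand), not concentration clamps — clamps
would break the smoothness the integrator relies on. Knockdowns scale the
production term of the targeted factor by `1 - efficiency`, matching
antisense semantics. Grafting experiments (E2-E6) are run on seeds whose
unperturbed pattern is bipolar, as the wet-lab manipulations are performed
on embryos with a normal axis.

Induction readouts (E3's and E5's ligand responses) average over the
perturbation footprint plus two coupling radii (direct influence extends one
window; induced relays a second). Suppression at the posterior bead (E2) is
read over the bead's own cells, and the intracellular-factor (E3) and
knockdown (E6) responses over the covered cells, since those responses are
local to the source. The anterior bead of E3 (and the paradox sign test)
uses a sub-saturating "band dose", `1.2 * K_hi`: the paradoxical induction
requires the ectopic source to lift perceived BMP4 into the band, while the
suppressive posterior bead far exceeds it.

The ensembles have partial penetrance, as the embryological experiments do.
At the committed defaults roughly three quarters of seeds complete bipolar
symmetry breaking; the remainder commit the whole ring to one attractor
before spatial structure can lock in (the uniform mode of the initial noise
grows as fast as any spatial mode in this model family, so a fraction of
global commitments is intrinsic to the shared-radius paracrine coupling).
After fragmentation, most fragments organise a Vg1 domain but a minority
commit uniformly to the BMP4 state; the typical outcome is three of four
Vg1-positive fragments. These penetrances are reproduced, not asserted, by
the acceptance script and the ensemble tests.

Fragment scoring (E7) runs `call_domains()` on the full Vg1 profile with the
cuts as hard breaks, so all fragments share one threshold: a fragment
uniformly at the Vg1-attractor level is streak-competent tissue and counts
as containing a Vg1 domain, while a fragment uniformly at the BMP4-domain
baseline does not. Renormalising within each fragment would misread a
uniformly Vg1-positive fragment as empty.

## Pattern readouts

`call_domains()` turns a profile into discrete domains with a relative
threshold (`min + 0.5 (max - min)`), merging across sub-threshold gaps of at
most 2 cells and dropping domains narrower than 3 cells; profiles whose
relative range is below 5% are flat and yield no domains. `polarity_index()`
is the magnitude of the first circular harmonic of the mass distribution.
`predict_streaks()` calls Vg1 domains whose peak exceeds half the Vg1 level
of the doubly-active state — an absolute threshold tied to the model's own
scale, so streak calls do not depend on a run's maximum. `pattern_summary()`
classifies a state as bipolar only if exactly one domain of each ligand is
called with centroids more than \(2\pi/3\) apart.

## Numerics

Integration is fixed-step classical RK4 (`dt = 0.01` by default in
`integrate_state()`; the experiment ensembles use `dt = 0.02`, which the
step-halving check shows is well inside the accuracy plateau for these
smooth, bounded dynamics). Adaptive stepping was rejected for
bit-reproducibility. Perturbations are held constant within a step on
half-open windows `[t_on, t_off)`. Optional intrinsic noise is applied
post-step as multiplicative lognormal factors, which preserves
non-negativity; any field driven below zero by round-off is clamped with a
warning above 1e-9. A run is converged when the maximum absolute derivative
falls below 1e-6; a hard cap of 1e6 on any field aborts with a diagnostic.
Uniform fixed points are found by continuation seeding (bracketing the
Vg1 equation along a BMP4 grid) polished with a damped 2x2 Newton using
analytic Hill derivatives, and verified against the full lattice RHS at
1e-10. The linear-stability module uses closed-form Hill derivatives;
finite differences on the RHS serve as the independent oracle in the tests.

Ensembles in the tests and the acceptance script use 100-cell rings,
20 seeds, and horizons of a few hundred dimensionless times; these sizes
were chosen so a full battery runs in minutes on a laptop while leaving the
qualitative outcomes unchanged under doubling.

## What the synthetic fixtures do and do not show

`profile_fixture()` and `state_fixture()` generate idealised circular
expression profiles (uniform, von-Mises bumps, k-modal, step blocks) with
known ground truth, so the metrics layer is validated independently of the
simulator. They emulate smooth, well-separated domains with additive noise;
they do not emulate in-situ staining artefacts, cell-number variation around
the ring, or correlated biological noise. Metric tests passing on fixtures
therefore validate the *readout definitions*, not the model's fit to any
real embryo.

## Known limitations

* The ring is one-dimensional; radial structure of the blastodisc (area
  opaca / marginal zone / area pellucida) is collapsed onto the annulus
  where the patterning decision is made, and disc images are presentation.
* With a single shared coupling radius the model cannot produce
  finite-wavelength mode selection; domain scale is set by initial noise,
  coarsening and pinning, not by a Turing wavelength.
* Receptor kinetics, cell movement and division are absent; beads are
  constant sources without depletion.
* Because every destabilising loop is transmitted through the same coupling
  window, the uniform mode always outgrows spatial modes; whole-ring (and
  whole-fragment) commitments to a single attractor occur in a minority of
  seeds, and the twinning experiment yields all four fragments
  Vg1-positive only in a minority of seeds (three of four is typical).
* At the calibrated constants the BMP4-branch response `h+(S_B, K_BB)` is
  saturated throughout the BMP4 domain, so an anterior bead reproduces the
  anterior localisation of `FB` but not a further bead-induced `FB` rise;
  the E3 verdict is scored on both clauses and is red on that one.
* Molecular identities are hypotheses: `FB` behaves like Gata2, `FV` is an
  abstract Vg1-branch factor.

## A minimal session

```{r, eval = FALSE}
p <- default_parameters()
steady_states(p)                          # attractors and the launch saddle
tr <- simulate_embryo(p, seed = 1, t_end = 500, dt = 0.02,
                      base = launch_base(p))
plot(tr)                                  # space-time heatmaps of B and V
pattern_summary(final_state(tr), p)       # domains, polarity, streaks
run_experiment("E2", p, n_seeds = 5)      # posterior bead: Vg1 loss, 2 streaks
```
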