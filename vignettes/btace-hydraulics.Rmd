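---
title: "Hydraulics of balloon-occluded TACE in a bench-top circuit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulics of balloon-occluded TACE in a bench-top circuit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btaceflow)
```

## The physical problem

Balloon-occluded transarterial chemoembolization (B-TACE) treats liver
tumors by infusing chemoembolic agents distal to a microballoon that
temporarily occludes a hepatic artery. After inflation, the upstream and
downstream compartments remain connected through collateral arteries (the
communicating arcade between the right and left hepatic arteries, hilar and
peribiliary connections), so the pressure just distal to the balloon — the
balloon-occluded arterial stump pressure, BOASP — does not fall to zero.
When collaterality is high the BOASP stays high, the distal pressure field
barely changes, and the injectate spreads as it would without occlusion.
When the BOASP falls low enough, the normal-to-tumor pressure gradient
drives flow from normal-tissue territories toward the tumor territory
through the collaterals: the pressure-gradient effect (PGE), which is what
makes B-TACE concentrate the agent in the tumor.

`btaceflow` models a bench-top hydraulic analogue of this situation: a
pump-fed, real-scale hepatic artery phantom whose eight segmental outlets
drain through three-way stopcocks either to an upper reservoir (modeling
normal-tissue pressure) or to a lower reservoir (modeling the lower
tumor-tissue pressure). Gravity between the two free surfaces plays the
role of the physiological normal-to-tumor gradient; the upper-reservoir
pressure (URP) is the circuit's equivalent of the clinical BOASP threshold.

## The 0D model

Steady, laminar flow of a Newtonian fluid in each straight tube obeys

$$\Delta p = R\,q, \qquad R = \frac{128\,\mu\,l}{\pi d^4},$$

and each reservoir or pump is a constant-pressure source $p = \rho g z$
(fluid–electric analogy: resistances and voltage sources). Kirchhoff's
laws on the network yield a linear system. The package solves it by
**nodal analysis**: one mass-conservation equation per interior node in the
unknown interior pressures, boundary pressures folded into the right-hand
side, blocked branches removed. (An equivalent formulation writes the
system in the branch flowrates; the contract asserted by the tests —
$\Delta p = Rq$ on every branch, conservation at every node — is
formulation independent, and the test suite checks the nodal solution
against an independent least-squares solve of that full redundant
constraint set.)

Assumptions inherited from the bench circuit:

* steady state — no pulsatility, no compliant (RC/RLC) elements;
* Newtonian fluid, laminar flow — no turbulence or minor-loss terms;
  `branch_reynolds()` reports per-branch Reynolds numbers as a diagnostic
  (all < 100 in the shipped circuit);
* the pump is an ideal constant-pressure source $\rho g H$ (no pump
  curve/working-point model);
* reservoir free surfaces are held constant by the drain, so reservoirs
  are ideal sources too;
* the artery phantom is horizontal: gravity enters only through the
  reservoir and pump heads, measured from the pump datum. The height
  ordering is $z_{LR} < z_{HA} < z_{UR}$ — the upper reservoir sits above
  the lower one, which is precisely what lets gravity drive
  upper-to-lower flow when the pump supply is cut off.

## Parameters, units, defaults

Internally everything is SI (Pa, m³/s, m); reporting helpers convert to
mmHg (÷ 133.322) and mL/min (× 6·10⁷). The seven sizing parameters of the
circuit default to the values found adequate for demonstrating PGE:

| parameter | meaning | default |
|---|---|---|
| `l_lr`, `d_lr` | outlet tubes to the lower reservoir | 40 mm, 1.2 mm |
| `l_ur`, `d_ur` | outlet tubes to the upper reservoir | 40 mm, 1.2 mm |
| `z_lr` | lower-reservoir free surface | 80 mm |
| `z_ur` | upper-reservoir free surface | 110 mm |
| `h_pump` | pump head | 200 mm |

With water (ρ = 1000 kg/m³, g = 9.8 m/s²) these give LRP = 784 Pa,
URP = 1078 Pa and a pump source of 1960 Pa. Water viscosity is not a
printed bench parameter; the default is μ = 0.001 Pa·s (≈ 20 °C), and
`blood_mimic_fluid()` provides the water–glycol surrogate
(ρ = 1050 kg/m³, μ = 0.0035 Pa·s) for future blood-like experiments.

The artery geometry itself (per-generation lengths and diameters, the
collateral tubes, the inflow tube) is not fully printed in the bench
description; the package ships **calibration defaults**, chosen once from
the real-scale constraint — diameters tapering 4.0 → 3.0 → 2.5 → 2.0 mm
over 30/30/25/20 mm generations, 15 mm × 1.2 mm collaterals (thinner, so
of higher resistance, than same-generation main branches), a
300 mm × 4 mm inflow tube — and documented as such. Their only contract
is reproducing the qualitative bench behaviour (all criteria in the
acceptance suite); every value is overridable through `hepatic_tree_spec()`,
`collateral_spec()`, `ivm_config()` or the JSON config file. With these
defaults the baseline circuit carries ≈ 340 mL/min total, inside the
pump's 0–500 mL/min delivery envelope.

## Topology and the balloon-site ladder

The phantom is a full binary tree: PHA → {LHA, RHA} → four sectional →
eight segmental arteries (Couinaud S2, S3, S4a, S4b, S5, S6, S7, S8).
Collaterals join each sibling pair at two attachment points, at one and two
thirds of the branch length; the lobar-level pair forms the two pathways of
the communicating arcade. On the unique PHA → RHA → right-posterior → S7
path this yields the nine-site occlusion ladder `a`–`i`: per level
(RHA / sectional / segmental), one sub-branch proximal to both attachments,
one between them, one distal to both. The clinically reported
"location 1" (RHA distal to the arcade) is site `c`, "location 2"
(between the pathways) is site `b`. The exact positions of `d`–`i` are not
derivable from the bench description alone; this 3-level × 3-position
reconstruction is anchored by the documented `b`/`c` placements and is
flagged as the package's own. Sites `a`, `d`, `g` (and `i`) could not be
physically ballooned on the bench because of the balloon length; the
package simulates all nine and marks the tested subset `{b, c, e, f, h}`.

## Numerical choices

* **Solvability.** After removing blocked branches, every connected
  component containing an interior node must contain a boundary node;
  violations raise an error naming the component (never silent NaNs).
* **Occlusion.** The blocked branch is removed from the system rather than
  assigned a huge resistance, avoiding conditioning problems; a test
  confirms the removed-branch solution matches the $R \times 10^{12}$
  limit to 1e-6 relative.
* **Accuracy.** The nodal solve is followed by up to three steps of
  iterative refinement against the *per-branch* conservation defect (the
  same arithmetic the verification uses); solutions satisfy
  $\Delta p = Rq$ and node conservation to better than 1e-9 relative, the
  tolerance `verify_solution()` enforces by default.
* **PGE detection.** Strict window $LRP < BOASP < URP$ with a 1e-6 Pa
  guard band (equality, a measure-zero event, maps to "no PGE" — e.g. the
  fully stagnant stump at site `i`, whose BOASP equals LRP exactly). The
  window is always cross-checked against the flow criterion (≥ 1 reversed
  normal-segment outlet tube); disagreement raises an error since it
  signals an inconsistent configuration.
* **Injectate tracing.** The injectate is a passive tracer: an
  infinitesimal infusion at the stump node, advected only along branch
  flow directions. Branches whose occluded flow is below 1e-12 m³/s are
  direction-less in the base field; their direction is taken from the
  infinitesimal-injection limit (re-solve with homogeneous boundary
  pressures plus a unit source at the tip, use the perturbation's sign).
  This matters in exactly-symmetric situations: with tumors in S5 and S7
  and the balloon at `c`, the downstream compartment is mirror-symmetric,
  the stump node is exactly stagnant, yet a real injection plainly splits
  both ways — the limit reproduces the observed delivery to both tumor
  segments, while a naive "never traverse zero flow" rule would return an
  empty set. On branches with nonzero flow the limit changes nothing.
* **Outcome.** "Successful" is the strict reading: the injectate reaches
  at least one outlet and only tumor-bearing outlets. Site `h` is
  therefore successful *without* PGE — the collateral feed enters the S7
  branch distal to the balloon and the smaller resistance toward the S7
  outlet (relative to the path back toward S6) carries everything to the
  tumor. Whether "effective" should instead mean merely preferential
  delivery is left open by the bench description; the strict definition is
  the one implemented.

## Sizing

`check_design_criteria()` automates the manual sizing of the seven
parameters: it runs both cancer scenarios (tumors in S7; tumors in S5 and
S7) under three catheter states (no occlusion, site `c`, site `b`) and
checks that the baseline feeds every outlet, that tumor outlets out-flow
normal ones, that PGE arises at `c` and not at `b`, and (optionally) that
outlet flows respect bounds such as the pump's 0–500 mL/min envelope.
`search_sizing()` evaluates a finite grid exhaustively and ranks passing
candidates by the PGE margin (URP − BOASP at site `c`, Case 1) — the
ranking score is the package's own choice and is stated in the output.
Note that the defaulted criteria are sign conditions: some degenerate
directions (e.g. choking the upper-reservoir tubes) only drive flows
toward 0⁺ and are caught by the optional flow floor, not by the sign
checks; the per-parameter destabilizing directions are documented in the
test suite.

## What the shipped geometry does and does not establish

The default circuit reproduces, with no per-result tuning: baseline
perfusion of all eight segments with tumor preference; PGE with reversed
S5/S6/S8 outlet flows and tumor-only delivery at `c`; flow re-routing
through the arcade (throttled but everywhere positive) at `b`; PGE exactly
at `{c, f}` and effectiveness exactly at `{c, f, h}` across the tested
ladder; strictly decreasing proximal-to-distal baseline pressure with all
BOASP values in [LRP, IP]; and exact left–right mirror symmetry. These are
*qualitative* contracts of a deliberately simple phantom: two pressure
levels only (all tumors at one pressure, all normal tissue at another), an
idealized symmetric tree, no portal vein, no particle/lipiodol deposition,
no pulsatility, and absolute pressures well below physiological arterial
pressure because the working fluid is water. A green test therefore
establishes the flow-redistribution *mechanism*, not patient-specific
hemodynamic magnitudes.
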