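---
title: "Modeling coronary blood-flow heterogeneity with coroflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling coronary blood-flow heterogeneity with coroflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`coroflow` simulates the human coronary arterial circulation at organ scale
and quantifies how heterogeneously the resulting blood flow is distributed
through the ventricular myocardium. The pipeline has four stages.

**1. Stochastic tree topology.** Arterial trees are described in Strahler
order (SN): terminal modeled arterioles are SN 6, the main coronary trunks
(RCA, LAD) are SN 11, and the LCX is an SN 10 sub-tree attached at a
bifurcation on the proximal third of the LAD trunk. A *segment* is the vessel
piece between two bifurcation nodes; an *element* is a chain of same-order
segments sharing one constant radius. Trees are generated stochastically from
a morphometry table giving, per order, the mean element radius, the segment
length distribution, and the segments-per-element ratio, plus an element
connectivity matrix `C[m, n]` (expected order-`n` daughters per order-`m`
element). The generative rule is: an order-`m` element draws its segment
count `k` as `1 + Poisson(ratio - 1)`; each of its `k - 1` internal junctions
spawns one lower-order side branch with order probabilities proportional to
the connectivity row (less the two structural end daughters); the element
terminates in two order-`(m-1)` daughters, or is a terminal when `m = 6`.
Since no order below 6 exists, an order-6 element cannot host side branches
and is represented as a single terminal segment carrying the element's total
sampled length; this keeps the tree strictly binary. Trunk elements draw
their segment count around the bound-implied expectation and are resampled
until the total trunk length falls inside the anatomical bounds (RCA
120–192 mm, LAD and LCX 100–160 mm).

**2. Steady-state hemodynamics.** Each segment's resistance is the
Poiseuille value `R = 8 mu L / (pi r^4)` with blood viscosity
`mu = 3.6e-3` Pa·s. Pressures are fixed at 100 mmHg at the ostia and 20 mmHg
at every SN 6 terminal (the control condition). The network is reduced
recursively — series along chains, parallel at bifurcations — and flows are
propagated from the root, splitting at each bifurcation inversely to the
downstream equivalent resistances. Units are SI internally (Pa, m³/s);
interfaces use mmHg and mm³/s with 1 mmHg = 133.322 Pa.

**3. Space-filling 3D geometry.** The ventricles are idealized as truncated
ellipsoids: LV endo/epicardial surfaces with semi-axes (30, 30, 58) and
(40, 40, 68) mm about the origin, an RV pair centred at (-15, 0, 8) mm with
semi-axes (40, 33, 53) and (45, 38, 58) mm forming a crescent free wall of
about 5 mm, truncated by a basal plane 10 mm above the equator. Trunks are
laid along parametric epicardial paths (RCA: right AV groove then posterior
descent; LAD: anterior interventricular groove from base to apex, wrapping
posteriorly when long; LCX: left AV groove from its LAD attachment). Every
other junction is processed root-outward (breadth-first, larger radius
first): branching angles come from the law-of-cosines construction on
vectors of magnitude `Q / r^2`; a self-avoidance vector sums, over placed
nodes of calibre at least the smaller daughter's, unit vectors away from
those nodes weighted `(Ls/d)^xi / (1 + (Ls/d)^xi)` with `xi = 2`; a
boundary-avoidance vector sums inward wall normals weighted `exp(-d / 2L)`;
their normalized halves (`c_s = c_b = 0.5`) combine into the branching
direction, which is rotated about the branching-plane normal
`(s_p x v_d) x v_d` by `+theta_L` / `-theta_R` to give the daughter
directions. Positions falling outside tissue are moved back along the
boundary direction in steps of `L/20` (direction refreshed every 10 steps,
budget 200 iterations); sub-trees that cannot be repaired are pruned and
flows are re-solved on the placed tree.

**4. Voxel maps and heterogeneity.** Terminal outflows are binned into
1 mm³ voxels at each terminal's distal node, then averaged over a seeded
ensemble of instances (instance `i` uses seed `base + i`; the study-scale
ensemble is 540 instances). On the masked map we compute: the blood-flow
histogram (100 bins); the relative-flow distribution
`d_j = (a_j / m_j) / (A / M)` whose mass-weighted mean is one by
construction; the relative dispersion RD (mass-weighted SD of `d_j`); and
the fractal dimension `D` from RD at two resolutions,
`RD_low = RD_high * ratio^(1 - D)`. Transmural heterogeneity is measured by
assigning each voxel's flow to a 1 mm layer by distance from its own
ventricle's endocardial surface; the sub-endocardial layer is 1–2 mm.

# Virtual experiments

Structural interventions change radii only, so ensemble geometry is
generated once and each condition re-solves flows on the placed trees:

* **Pressure sweep** — inlet pressure 30–200 mmHg in 10 mmHg steps. The
  network is linear, so total flow scales exactly with `P_in - 20 mmHg` and
  all relative-flow quantities (RD, FD) are invariant.
* **Single-segment stenosis** — the LAD trunk segment whose chain midpoint
  is nearest half the trunk length (a deterministic stand-in for the study's
  arbitrarily chosen segment) is constricted to 1.53, 0.25, 0.075 or
  0.01 mm.
* **Order-wise blocking** — the root segment of every sub-tree of a given
  order (6–10) loses 70/80/90% of its control radius; order 6 means every
  terminal.
* **Combined grids** — blocking crossed with inlet pressures 30/100/200.

# Default parameter choices

The study's own supplementary morphometry and anatomy tables are not
published with the text, so the packaged fixture encodes literature-plausible
values, all user-replaceable through the YAML interface:

* Radii grow by `sqrt(3)` per order from 0.103 mm (SN 6) to 1.600 mm (SN 11)
  after human scaling; the uniform human diameter multiplier 1.25 anchors
  the main-coronary diameter at 3.2 mm, the only calibre the study text pins.
* Segment lengths are positive-truncated normals with means 1.0–14 mm
  rising with order; segments-per-element ratios are 2.0–3.5 (trunk
  excepted).
* The connectivity matrix concentrates daughters at order `m - 1` with a
  tail of small side branches; each row's side-branch total equals
  `segments_per_element - 1` by construction, which makes the junction-level
  generative rule reproduce the row expectations exactly.
* Viscosity is stored in Pa·s (the printed unit "Pa" is an evident typo;
  the resistance law is otherwise dimensionally inconsistent).

The branching-angle formula as printed has its daughter indices swapped
relative to the law-of-cosines construction it cites: in the
straight-continuation limit (one daughter vanishing, the other continuing
the parent) it yields 90° instead of 0°. The corrected convention
(same-side daughter term positive in the numerator) is the default;
`avoidance_params(convention = "printed")` restores the printed form.

Two readings exist for the dispersion statistic printed for
SN 6 blocking (the study's figure caption uses "relative dispersion (RD),
also termed fractal dimension (FD)" interchangeably). We compute both; the
FD reading is adopted because (i) the quoted value sits just above the
control FD, matching the reported *increase* of FD under terminal blocking,
and (ii) the RD of a zero-inflated relative-flow distribution is far larger
than any printed value under any plausible parameterization.

# Numerical choices

* **Flow solver.** The forward pass propagates the drop-to-terminal
  multiplicatively (`delta_dist = delta_prox * R_sub / R_down`) instead of
  subtracting cumulative drops from node pressures; this conserves flow to
  ~1e-15 relative even on trees whose flows span many decades. Node
  pressures are reconstructed as `P_term + delta`, which pins terminals at
  the terminal pressure exactly. Pass-through (single-daughter) nodes left
  by pruning are treated as series resistances.
* **Nearest point on an ellipsoid** is found by safeguarded bisection on the
  Lagrange parameter of the projection equations (100 iterations; exact
  zeros of the centred coordinates are nudged by 1e-9 mm to avoid the
  measure-zero axis degeneracy).
* **Tissue-side resolution.** When repairing an outside position, the
  tissue side of each wall is resolved by probing 0.5 and 1.5 mm on both
  sides of the nearest surface point; walls with no adjacent tissue (e.g. a
  surface stretch bordered by cavities) are skipped rather than guessed.
* **Degenerate fallbacks.** Zero self-avoidance and boundary vectors fall
  back to the parent direction; a branching plane for parallel inputs is
  built by orthogonalizing a fixed reference axis against the branching
  direction; arccos arguments are clamped to `[-1, 1]`.
* **Coarsening.** "Low resolution" is read literally off the scaling
  relation's mass symbols as a voxel-mass ratio of 2, implemented as
  aggregation of adjacent voxel pairs along one axis; a `2 x 2 x 2` mode
  (ratio 8) is available. Trailing partial blocks at non-divisible extents
  are truncated and reported. Coarse-voxel masses count constituent tissue
  voxels, and RD is mass-weighted accordingly.
* **RD on raw values.** RD is computed from the per-voxel relative flows
  directly; the binned density is for display only, removing bin-width
  sensitivity.
* **Zero-flow voxels.** Tissue voxels that no terminal hits stay in the
  mask with flow 0 — they are genuinely unperfused at SN 6 granularity —
  and any voxel that receives flow but whose centre falls marginally
  outside the tissue mask is added to it, so the mapping pipeline conserves
  total outflow exactly.
* **Mode counting** uses a 5-bin moving average and a prominence threshold
  of 5% of the maximum smoothed density; plateaus count once.
* **Dual engines.** The space-filling placement exists twice by design: the
  exported R primitives are the readable reference, and a compiled C++
  engine repeats the identical arithmetic (same probe deltas, bisection
  schedules and tolerances) for ensemble-scale runs. A test pins the two to
  within 1e-6 mm on a full tree; a fixed seed reproduces byte-identical
  instances.

# What the generator does and does not emulate

The synthetic ensemble reproduces: the binary Strahler-ordered topology
statistics of the morphometry table; bounded trunk lengths; flow-weighted
branching angles; space-filling growth confined to an idealized
biventricular wall; and ensemble-averaged voxel perfusion maps with their
two-resolution scaling. At the study-scale ensemble (540 instances) the
control map's fractal dimension and its convergence asymptote land close to
the reported values, the pressure-sweep invariances are exact, and the
directional responses to interventions (severe stenosis induces bimodal
relative-flow distributions; terminal blocking raises FD; SN 10 blocking
lowers FD and total flow) reproduce.

It does not emulate several features of the real data, and tests passing
here do not certify them:

* **Absolute flow scale.** With orders 6–11 only and the fixture's terminal
  density (~1300 SN 6 outlets per instance), the mean per-voxel flow is an
  order of magnitude below the printed value; that number is controlled by
  the unpublished morphometry (terminal counts and radii), not by the
  algorithms. All relative quantities are unaffected by this scale.
* **Low-flow tails under intervention.** Statistics that hinge on the
  extreme low-flow tail (the dispersion value under SN 6 blocking, the FD
  drop under severe stenosis) are sensitive to the sampling dispersion left
  at this terminal density and land above the printed values.
* **Transmural profile shape.** In the default anatomy, per-layer flow
  rises monotonically from endocardium to epicardium (the trunks and
  high-order elements are epicardial and the wall is thin relative to
  element lengths), so the reported sub-endocardial minimum does not emerge
  here; it evidently depends on the unpublished anatomy/morphometry
  combination.
* No diameter asymmetry within an order, no capillary orders (SN 0–5), no
  pulsatile flow, no haematocrit-dependent viscosity, no autoregulation.

# Problem sizes

The packaged defaults produce instances of roughly 2–6 thousand segments
across RCA + LAD/LCX with ~900–1800 terminals. The test suite exercises the
full 540-instance study ensemble for the headline statistics (about three
minutes of compute) and small seeded ensembles for exact invariances; the
acceptance script regenerates the 540-instance ensemble from scratch for
every run.
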