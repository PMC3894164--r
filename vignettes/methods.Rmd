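---
title: "Coarse-grained Go-model simulation of receptor kinase autophosphorylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained Go-model simulation of receptor kinase autophosphorylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Receptor tyrosine kinases such as the EGF receptor signal by
phosphorylating tyrosines (P-sites) in their own long, disordered
C-terminal (CT) tails.  In the active asymmetric dimer only one kinase
domain — the *receiver* — is catalytically engaged; the other — the
*activator* — stimulates it allosterically.  Before any P-site can be
phosphorylated, the disordered tail must deliver its tyrosine into the
receiver's catalytic cleft, either from the receiver's own tail (*cis*) or
from the partner's (*trans*).  Which P-sites get used, and how often, is
therefore set jointly by conventional substrate recognition and by
topology: tether length, dimer geometry, membrane anchoring, and
electrostatics.

`gophos` implements the simulation machinery needed to ask such questions
at residue resolution: a structure-based (Go-type) energetic model in
which only native contacts attract, implicit-solvent Brownian dynamics
between membrane planes, first-passage "binding event" campaigns with a
native-contact trigger, and the statistics used to interpret them.

## The coarse-grained model

Each amino-acid residue is one pseudo-atom centered on its C-alpha
(hydrodynamic radius 5.3 Å).  A bound nucleotide–2Mg complex is nine
finer-grained beads (radius 3.5 Å) centered on the adenine C2/C6/N9,
ribose C4', the three phosphorus atoms, and the two Mg ions, fully
interconnected by harmonic bonds (36 per complex; the full distance set
fixes the internal geometry, so no separate angle terms are enumerated
for it).

The energy is the sum of:

* **Bonded terms.** `k_bond (r - r_eq)^2` with `k_bond = 20` kcal/mol/Å²,
  `k_angle (θ - θ_eq)^2` with `k_angle = 10` kcal/mol/rad², and a
  two-component cosine dihedral `½V1(1+cos(φ - φ1)) + ½V3(1+cos(3φ - φ3))`
  with `V1 = 0.5`, `V3 = 0.25` kcal/mol.  All equilibrium values come from
  the reference structure.  The harmonic convention is `k·Δ²` *without* the
  factor ½, so the printed constants act exactly as written; this is
  stated prominently because the convention is genuinely ambiguous in the
  field.  Dihedral phases are chosen so the native dihedral is the energy
  minimum (`φ1 = φ_native + π`, `φ3 = 3φ_native + π`).
* **Native-contact attraction.** Residue pairs (sequence separation ≥ 3)
  whose all-atom reference has any atom pair within 5.5 Å, restricted to
  regions of known structure, get
  `ε[13(σ/r)¹² − 18(σ/r)¹⁰ + 4(σ/r)⁶]` with `ε = 0.6` kcal/mol and `σ`
  the *pseudo-atom* separation in the reference (the energy acts on
  beads, so the bead separation is the only consistent minimum).  The
  12-10-6 form has its minimum exactly at `(σ, −ε)`; a 12-10 alternative
  is available behind `go_forcefield(contact_form = "12-10")`.  No single
  canonical attractive form exists in the Gō-model literature, so both
  common forms are provided and the choice is explicit.
* **Generic repulsion.** All other non-bonded pairs:
  `ε(σ_vdw/r)¹²`, `σ_vdw = 4` Å, `ε = 0.6` kcal/mol.
* **Screened electrostatics.** Asp/Glu −1, Lys/Arg +1, His by
  Henderson–Hasselbalch at pH 7.6 then zeroed below |q| = 0.1 (the
  "significant charge" threshold is our choice; at 7.6 His carries ~0.024
  and drops out, and a flag retains the fraction), free termini ±1,
  phosphate beads −4/3 and Mg +2: the natural ATP-like split that makes
  the nucleotide complex net neutral.  Charged beads interact by
  Debye–Hückel `332.0637 q_i q_j e^{−r/λ_D}/(ε_s r)` with `ε_s = 78.4`
  and `λ_D` *derived* from the 0.15 M ionic strength and temperature
  (≈7.85 Å at 298 K); the screening length is never set independently.
  No cutoff is applied.
* **Membrane slab.** Two planes at z = ±16.5 Å.  Transmembrane beads are
  restrained to their reference z with 5.0 kcal/mol/Å²; extracellular and
  intracellular beads feel half-harmonic walls (5.0 kcal/mol/Å²) that keep
  them out of the slab.  Compartment membership comes from the region
  labels, with structured/modeled regions falling back to the sign of
  their reference z.

Temperature defaults to 298 K and viscosity to 0.89 mPa·s (water at
25 °C); both are configurable.

## Dynamics

Propagation is overdamped (inertialess) Brownian dynamics,
`Δx = (Δt/kBT)·D·F + √(2Δt)·B·ξ`, at a 125 fs production step.  At these
bead radii and step the inertial correlation time is orders of magnitude
below Δt, so an inertial thermostatted integrator would add nothing.
Free-draining diagonal Stokes mobilities are the default; a pairwise
Rotne–Prager–Yamakawa tensor (overlap-regularized, refreshed every 24 ps)
is available with either an exact Cholesky noise factor or a first-order
truncated-expansion factor (off-diagonal weight β = ½ with a
variance-corrected diagonal, matching each marginal variance exactly).

The production schedule is respected throughout: non-bonded pairs within
12.5 Å are evaluated every step; pairs between 12.5 and 25 Å every 1 ps
with forces held in between; lists rebuilt every 6 ps (with a 2 Å skin so
they stay valid between rebuilds); electrostatic pairs beyond 25 Å are
assigned to the 1 ps cadence (electrostatics carries no cutoff, so it
needs a cadence class).  Event monitors are checked every 6 ps, tied to
the list rebuild.  The RNG is a fixed, named
algorithm (mt19937-64 with an explicit Box–Muller transform), so
trajectories are bit-reproducible from the seed across platforms.

### Numerical choices and safeguards

* The Euler–Maruyama scheme is weak order 1.  For the stiffest term
  (bonds, curvature 2k = 40 kcal/mol/Å²) the stationary variance carries a
  known O(α) inflation with α = 2k·D_rel·Δt/kBT ≈ 0.78 at 125 fs.
  Distribution-level checks (Boltzmann sampling, equipartition) are
  therefore run in the small-step regime (5–15 fs), where the bias is far
  below statistical resolution; the production step is used everywhere
  else, exactly as in production practice.
* A dihedral's torque arm `|b2|/|n|` diverges when three consecutive beads
  become collinear.  Dihedral terms whose *native* geometry is degenerate
  are never created, and at run time the term is switched off within ~4°
  of collinearity (sin²θ < 5·10⁻³), which caps the force it can exert.
  Near-collinear angle gradients are regularized with a 10⁻⁸ floor on
  sin θ.
* Per-step displacements are clamped at 1.5 Å — about 15 thermal step
  lengths, unreachable in equilibrated dynamics.  The clamp matters in one
  situation only: campaign trials that restore P-site attractions on a
  randomized structure in which a tyrosine happens to sit inside its
  (previously disabled) docking funnel, where the re-enabled well wall
  would otherwise produce kcal-scale gradients.  With the clamp the start
  relaxes in a few steps; with it disabled (`max_step_A = Inf`) any
  displacement above 10 Å raises an instability error.  Capped step counts
  are reported in every trajectory.
* Overlapping beads (r < 10⁻⁶ Å) raise a singular-geometry error; NaN
  coordinates abort the run with the last good frame retained.

## Binding events and protocols

Each P-site contributes a nine-residue window (N−4…N+4).  The docked
reference defines the tyrosine/active-site contact set; the simultaneous
formation of all nine tyrosine contacts is the event trigger, in analogy
to a fraction-of-native-contacts reaction coordinate.  A contact counts as
formed when `r ≤ 1.2 σ` — the standard fraction-of-native-contacts
convention.  The three γ-phosphate contacts of the docked tyrosine are
attractive terms but not trigger members; the trigger is the nine
tyrosine/active-site-residue contacts.  Each site's
contact template is mirrored, with identical σ, onto the activator active
site as a non-terminating monitoring group, because stable nonproductive
binding there is part of the observed phenomenology.

Protocols compose as in the production study:

1. **Randomization.** All P-site attractive terms are removed (repulsion
   remains, so the active sites are not artificially sticky), independent
   trajectories are run, and members are sampled at fixed intervals.  The
   production shape is 5 × 10 µs sampled every 0.1 µs → 500 members;
   tests and the worked examples use scaled-down shapes and state them.
2. **First-event campaigns.** Each trial draws a start uniformly with
   replacement (per-trial seeds derive from the campaign seed), restores
   the attractions, and runs to the first trigger or to the timeout
   (default 5 µs; conceptually trials run until an event occurs, so the
   timeout is a practical bound — timeouts are reported separately and
   never silently retried).
3. **Charge-stripped variants.** `zero_ct_charges()` zeroes tail-residue
   charges while leaving all attractive terms intact.
4. **Second events.** `mimic_phosphorylation()` gives the bound tyrosine a
   formal −1 (a flag allows −2), removes every attractive term touching
   the site's nine window residues, and campaigns restart from bound-state
   final frames, so each trial begins with the release of the
   phosphorylated site.
5. **Nonproductive episodes.** Distance traces to the activator's
   catalytic aspartate are segmented with a ~12 Å threshold and a 1 ns
   dwell debounce, which makes plateau identification explicit and
   reproducible.

## Analysis

`multinomial_test()` implements the exact equiprobable goodness-of-fit
test: two categories reduce to the exact two-sided binomial (summing all
outcomes no likelier than the observed one — the two-sidedness convention
is documented because several exist); more categories are enumerated
exactly when feasible and otherwise estimated by seeded Monte Carlo with a
reported standard error.  Proximity censuses (40 Å) and distance subsets
(30 Å) use closed balls.  `predict_vphos()` multiplies each site's
relative binding frequency (receiver + activator copies summed, from
charge-stripped campaigns) by the peptide catalytic efficiency kcat/KM;
the quantity is relative, so any positive scaling of the frequencies
preserves the ratios, and the default normalization (sum to 1) can be
disabled when already-relative frequencies are supplied.
`correlation_audit()` compares same-site event pairs' start-structure time
gaps against the triangular null `p(Δt) = (2/T)(1 − Δt/T)` for two times
drawn uniformly from [0, T].

## The synthetic toy dimers

No receptor structure can be shipped, so `make_toy_dimer()` generates the
essential topology from scratch: two compact folded pseudo-kinases
(serpentine paths through a 3×3×L lattice, 3.8 Å spacing) held together by
interface contacts, membrane-spanning helices confined in the slab,
extracellular stubs, and disordered tails carrying P-site tyrosines at
chosen tether distances.  Each fold carries a nine-bead catalytic patch on
opposite faces of the two monomers (receiver/activator asymmetry), a
γ-phosphate stand-in bead bonded into the patch, and a designated
catalytic-aspartate bead.  Trigger σ values are measured from a docking
point 5.5 Å above the patch; toys therefore exercise the production
trigger machinery unchanged.

Three fixture-specific choices deserve emphasis:

* Toy native contacts are defined at the pseudo-atom level (8 Å bead
  cutoff) because generated toys have no all-atom reference; this is a
  documented divergence from the 5.5 Å all-atom rule used on real
  structures.
* The lattice geometry makes the toy folds stiffer than a real C-alpha
  fold (shortest contact σ 3.8 Å versus ≳4.5 Å, and a denser contact
  net), which puts some collective modes near the Euler stability bound at
  125 fs.  Toy simulations therefore integrate at 62.5 fs.  This is a
  property of the synthetic lattice, not of the model: the bare-chain and
  real-geometry terms are comfortably stable at the production step.
* The shortest-tether site of each chain is built with its initial tail
  path skirting the mouth of its own monomer's docking funnel (well
  outside the contact minima), emulating the kinase-proximal architecture
  in which an ideally-sized tether threads a surface cleft to the
  catalytic site.  Longer tethers get unbiased self-avoiding walks.  This
  is what makes sequence proximity translate into spatial proximity in the
  toys — exactly the topological effect the cis-bias property measures.
  Because bonded equilibria come from the built structure, tails retain a
  weak memory of their built shape; this mirrors the production treatment
  of modeled segments and is shared by all sites equally.

What passing toy tests shows — and what it does not: the toys validate the
machinery (energetics, scheduling, triggering, campaign bookkeeping,
statistics) and qualitative topological effects (short tethers beat long
ones for their own catalytic site).  They say nothing quantitative about a
real receptor: binding times, cis/trans ratios and site frequencies in the
toys are properties of the generated geometry at desk scale, reached in
nanoseconds rather than the microseconds of the production system.

## Problem sizes used in tests and the acceptance script

Distribution checks use a 2-bead bond (KS at α = 0.01, ~2000 decorrelated
samples) and a 1000-replicate free-bead gas over 10⁵ production steps.
Ensembles in examples are 3 trajectories × 20 ns sampled every 2 ns;
cis-bias campaigns run 100 trials with a 6 ns timeout on the default
three-site toy (tethers 10/20/60).  These sizes were chosen so the full
pipeline exercises every code path at workstation scale; all of them are
plain parameters that scale up unchanged.

## Known limitations

* Euler–Maruyama order-1 bias at the production step (quantified above);
  no higher-order or Trotter-split scheme is provided.
* The hydrodynamic tensor path is O(N²) storage and O(N³) factorization
  per refresh — fine for toys, expensive for receptor-scale systems;
  free-draining is the tested default.
* Electrostatics is Debye–Hückel on net charges; no dielectric boundary,
  no polarization, no Ewald (the slab is aperiodic by construction).
* Peptide docking to derive P-site contact lists is out of scope; docked
  contact templates are inputs (`build_psite_groups()`), with only their
  mirroring automated.
* One accumulated phosphorylation per campaign: the protocol stops at the
  second binding event.
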