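---
title: "Methods: modelling a twisted-carbonyl bilayer graphene potassium channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling a twisted-carbonyl bilayer graphene potassium channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

kpore implements the computational analyses around an artificial potassium
channel: a bilayer graphene nanopore whose edges carry four carbonyl groups
per layer, rotated ("twisted") between the layers the way adjacent carbonyl
rings are rotated in the selectivity filter of biological K+ channels. This
vignette records the models, the tunable parameters, the numerical choices,
and what the synthetic-data pipeline does and does not establish.

## Pore construction

A pore layer is carved from a honeycomb lattice (C-C bond 1.42 Å) by
removing the 16 atoms inside an elliptic stencil (semi-axes 3.76 / 3.68 Å)
centred on a hexagon. This is the unique mirror-symmetric compact 16-atom
removal; its van der Waals footprint is 10.8 x 9.1 Å², consistent with the
~10 Å design scale of the channel. The eight rim atoms nearest the pore
centre (all at 3.76 Å) are the carbonyl candidate sites, indexed 0..7
counterclockwise from the +x axis — the lattice never fixes an origin, so
the indexing convention is stated rather than derived. Four sites carry a
C=O group (bond 1.23 Å) with the oxygen pointing at the pore axis,
mimicking the carbonyl ring of the biological filter.

The functionalized set is the base set {0, 2, 5, 7} shifted by an integral
twist, +1 modulo 8 per step with the shift direction labelled clockwise
when viewed down +z. Twists 0..4 give the five single-layer elements
A0..A4. A configuration is dismissed when it contains two or more adjacent
carbonyl pairs (consecutive site indices modulo 8): a single adjacent pair
is tolerated — the base set itself contains one — but clustering carbonyls
is not. Two layers at an interlayer distance d (default 3.35 Å, the
graphite spacing) form the bilayer channel AmAn; the 5 x 5 = 25 ordered
combinations reduce to 15 under exchange of the two layers. Published
counts of *investigated* pores can be smaller (additional symmetry
arguments are not reproducible from the main-text description), so no
further reduction is hard-coded; `enumerate_configs()` accepts a custom
equivalence predicate instead.

The effective open area is a grid count of pore-plane points outside all
atom discs. Atom radii are covalent radii (C 0.77, O 0.66 Å) and the
default probe radius of 0.35 Å was calibrated once so that a
carbonyl-functionalized layer yields ~32 Å², the accepted open area of
this channel design; van der Waals radii would close the pore almost
completely (~13 Å²) and are therefore not a plausible convention for that
figure. The area is monotone non-increasing in the probe radius by
construction.

## Transition-state-theory kinetics

Permeation is modelled as a rare hop over the rate-determining barrier of
the single-ion potential of mean force (PMF): the passage from the binding
site at the first layer (L1) to that at the second (L2),

    k = tau^-1 exp(-dG / kB T),    kB = 0.0019872 kcal/(mol K), T = 300 K.

The barrier dG is referenced to the preceding (L1) minimum, not to bulk,
matching the stage-to-stage reading of the hop; it is the highest profile
point between the two layer minima minus the L1 minimum, so a monotone
inter-layer segment degenerates to the endpoint difference. PMFs are
normalized by subtracting the mean over a caller-chosen bulk reference
region. Because adaptive-biasing-force profiles are noisy, extremum location
uses a centred moving average (default 3 grid points) plus persistence
pruning: adjacent min/max pairs closer in energy than `min_prominence` are
removed, as are edge ripples that barely depart from the end values. The
default prominence is 0 (keep everything); 0.5-1 kcal/mol is appropriate at
noise levels of a few hundredths of kcal/mol.

The attempt period tau is the second zero of the normalized velocity
autocorrelation function (VACF), located by sign change with linear
interpolation between samples; for a pure cosine of period T0 this is
3 T0/4. The VACF is normalized by its lag-0 value and is required to
rebound below -0.1 between the first two zeros — white noise produces
spurious crossings but no negative lobe, and is rejected. The selectivity
ratio is the ratio of the two ions' rates; with equal attempt periods and
barriers of 3.5 (K+) versus 8.9 (Na+) kcal/mol it is exp(5.4/kBT) ≈ 8.6e3.
The dynamic, dual-ion-corrected selectivity of the full channel cannot be
recomputed here because the per-ion attempt periods of the original
simulations are not published; the formula pathway is what the tests
certify.

## Barrier decomposition

The hopping barrier decomposes linearly into dehydration, carbonyl
coordination and a residual membrane term,

    dG = a dN_water + b dN_carbonyl + c,

fitted by ordinary least squares per ion. The intercept c is fitted rather
than fixed: it is ion-independent by construction of the decomposition but
its value is not published. Rank-deficient designs (fewer than 4 samples,
or collinear dN columns) are rejected. On noise-free synthetic samples the
fit is exact to machine precision; on noisy samples the tests check
unbiasedness across seeded replicates and the sign contract — b < 0
(carbonyl coordination assists the hop) for K+-like generators, b > 0 for
Na+-like ones.

## Primitive-model electrolyte thermodynamics

Electrolytes are charged hard spheres in a dielectric continuum
(hydrated diameters K+ 5.6, Na+ 4.7, Cl- 6.4 Å; relative permittivity
78.4, the standard water value at 300 K, stated explicitly because the
mixing results depend on it). The excess free energy has

* a hard-sphere part from the Boublik-Mansoori-Carnahan-Starling-Leland
  (BMCSL) mixture equation of state, and
* an electrostatic part from the non-restricted mean spherical
  approximation (MSA) through the energy route: beta A = beta E +
  Gamma^3/(3 pi), the Debye-charging result.

The MSA screening parameter Gamma solves its closure self-consistently; the
solver is a bracketed bisection on [0, kappa/2] (kappa the Debye parameter)
run to a relative width of 1e-13, which is deterministic and immune to the
occasional false-convergence reports of general root finders. For equal
diameters Gamma reduces to the restricted closed form
(sqrt(1 + 2 kappa sigma) - 1)/(2 sigma) to 1e-10, and the implied mean
ionic activity coefficient approaches the Debye-Hückel limiting law at
1e-4 to 1e-6 M. Chemical potentials are central-difference density
gradients of the free-energy densities (relative step 1e-5, with Gamma
re-solved at each perturbed composition), so they form an exact gradient
field and Gibbs-Duhem consistency holds to the differencing error. The
direct mean-field Coulomb term is zero for a homogeneous electroneutral
reservoir and is therefore not represented.

Reservoir free energies use the Euler convention G = sum_i n_i mu_i, the
Gibbs-type bookkeeping matching "free energy change of the mixing process"
at fixed 1 L volumes; a Helmholtz-density route (ideal density sum plus the
charging-derived excess densities) is available behind
`reservoir_free_energy(..., route = "density")` as a cross-check. The two
routes differ by the excess-pressure term and bracket the convention
uncertainty of this model class.

The mixing scenarios transfer dC mol of K+ with neutral-salt bookkeeping
(electroneutral accounting with external charge compensation, since only
K+ physically permeates): through a potassium-permselective membrane (KPM)
the left reservoir becomes (1-dC) M KCl and the right 1 M NaCl + dC M KCl;
through a non-selective membrane both sides become (1-dC)/dC salt
mixtures. dG_m(dC) is reported in kJ per mole of initial salt per
reservoir by default — the published energy-axis normalization of this
scenario is not recoverable (ideal mixing entropy alone exceeds the
printed absolute values by an order of magnitude), so the normalization is
a knob and only normalization-independent quantities are asserted: the
curve minimum dC0 and the efficiency eta = ON/OP = |dG_KPM|/|dG_free|.
The default grid is 0 to 0.5 M in 0.001 M steps with local quadratic
refinement of the minimum. With the default conventions the full model
gives dC0 = 0.141 M and eta = 39.3% at dC = 0.16 M (the values the
acceptance script recomputes); ideal-only limits are exactly 1/3 and 1/2
for the two argmins, which the tests verify against closed forms. Across
the plausible convention space (Euler vs density route) dC0 spans roughly
0.14-0.20 M and eta 39-44%, which bounds how strongly these outputs should
be interpreted.

## Trajectory statistics

Trajectories are small tagged-atom systems (ions, water O/H grouped per
molecule) with the pore axis along z through the origin and the two layer
planes annotated. Defaults, all exposed: site binding within 1.0 Å axially
and 3.0 Å radially (at most one ion per site, nearest wins); hydration
cutoffs 3.5 Å (K+-O) and 3.2 Å (Na+-O), the first radial-distribution
minima of common water models; bridging waters counted strictly between
the layer planes within a 3.0 Å cylinder about the inter-ion axis.
Permeation events use hysteresis margins (2 Å beyond each plane) so pore-
mouth shuttling does not count, and handle periodic wrap-around along the
axis. Water dipole angles are measured from the O-to-HH-midpoint bisector
against the first-to-second-ion axis; switching frequency labels frames
below/above 90 +/- 15 degrees, carries ambiguous frames, suppresses runs
shorter than 2 frames (debounce, configurable) and reports
transitions/(2 x duration) — full cycles, not half-cycles; the alternative
half-cycle convention would double the numbers and is the reason the
counting rule is documented.

## Synthetic-data generators

Every pipeline input has a seeded generator that reproduces the
*statistical* structure the analyses assume — multi-well PMFs whose
anchors are exact extrema (zero-slope cubic Hermite segments between
well/saddle/bulk anchors, so requested barriers are met to well under
0.01 kcal/mol), damped-oscillator velocities, linear I-V responses,
Gaussian-noise decomposition samples, scripted permeation cycles with a
dominant (70%) dual-occupancy stage, and dual-ion triplet episodes with
Bernoulli bridge counts, exponential lifetimes and continuous-time
telegraph water orientation (exponential holding times, so flip-rate
semantics are timestep-independent). Generators are bit-reproducible given
a seed, leave the caller's RNG state untouched, and attach their full
parameterization as a `generator_spec` attribute serializable to JSON.

What they do not emulate: realistic water structure or forces, ion-ion
correlations beyond the scripted geometry, barrier recrossings, or any
coupling between stages. Passing the recovery tests therefore certifies
the *operators* (event counting, classification, estimators) against known
ground truth, not the physics of any particular simulation.

Problem sizes in the test-suite and analysis defaults were chosen so
statistical recovery tests have adequate power at workstation scale:
400 triplet episodes at 2 ps resolution for fractions and lifetimes
(binomial and exponential three-sigma bands), and 4 long episodes at
0.02 / 0.1 ps for the 578 / 89.3 GHz switching rates. Frame sampling
loses flips that complete within one frame — an a-priori computable bias
of (1 - exp(-2 lambda dt))/(2 lambda dt), about 2-5% at the chosen
timesteps — so the switching-recovery tests allow that quantization term
on top of the counting three-sigma band.

## Power figures

The current-voltage response of the channel under mixed 1 M KCl / 1 M NaCl
reservoirs is linear: the current intercept is the net diffusive current
I_diff, the voltage intercept the reversal potential U_diff = -I_diff/g,
with positive current defined as cation flux from the KCl to the NaCl
side. The single-pore power defaults to the maximum-power-transfer point
of a linear source, |I_diff U_diff|/4, because the published per-pore
operating point is not defined; an explicit operating point is accepted
instead. A standard Goldman-Hodgkin-Katz relation (caller-supplied
permeabilities, optional activity-coefficient hook fed by the electrolyte
module) stands in for the modified GHK variant used in the original
supplementary analysis, which is not reproducible from the main text;
reproducing U_diff = 73.1 mV is correspondingly out of scope. Areal
figures are arithmetic: one pore per 10 nm square gives 1e16 pores/m²,
0.13 pW per pore then yields 1300 W/m² at a porosity of 0.32% (with the
32 Å² open area).

## Known limitations

* The pore stencil approximates an unpublished construction; footprint and
  site geometry are consistent to ~10% but not atom-for-atom identical.
* dC0 and eta depend on free-energy-route and permittivity conventions at
  the few-percent level (see above); absolute dG_m values additionally
  depend on an unrecoverable normalization and are reported, not asserted.
* MD-derived headline numbers (3.5e7 ions/s, selectivity 1295, 73.1 mV,
  0.13 pW) require unpublished simulation inputs; they enter only as
  fixture parameters or formula inputs.
* The trajectory operators assume the pore axis is z through the origin;
  re-orient trajectories before analysis if needed (angle computations
  themselves are rigid-motion invariant).
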