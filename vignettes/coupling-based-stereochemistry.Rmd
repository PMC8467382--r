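---
title: "Coupling-based stereochemistry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling-based stereochemistry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicinalJ)
```

## The model

A vicinal proton–proton coupling constant reports on the H–C–C–H torsion
angle $\phi$ through a Karplus-type relation. `vicinalJ` uses the
generalized Haasnoot–de Leeuw–Altona (HLA) form, which corrects the basic
cosine dependence for the electronegativity and orientation of the
non-hydrogen substituents on the two coupled carbons:

$$^3J(\phi) \;=\; P_1\cos^2\phi + P_2\cos\phi + P_3
  + \sum_i \Delta\chi_i\left[P_4 + P_5\cos^2(\xi_i\phi + P_6\,|\Delta\chi_i|)\right]$$

* $\Delta\chi_i$ is the electronegativity-difference parameter of
  substituent group $i$ relative to hydrogen. The built-in table carries
  five groups (H 0, CHMeOH 0.62, CH$_2$C(O)R 0.72, CH$_2$CH$_2$R 0.76,
  OH 1.33); custom values, including negative ones (legal in the general
  HLA framework), are accepted, and $|\Delta\chi_i|$ is used inside the
  phase term exactly as written.
* $\xi_i = \pm 1$ encodes which side of the coupled proton the substituent
  occupies in the Newman projection along the C–C bond.
* The default coefficients $(P_1,\dots,P_6) = (14.64, -0.78, 0.58, 0.34,
  -2.31, 18.40)$ are the MestReJ parameterization for vicinal proton
  couplings. $P_1$–$P_5$ set amplitudes on the Hz scale; $P_6$ is a phase
  **in degrees**. That is why the entire coupling machinery works in
  degrees and converts to radians only inside the trig calls.

For a conformer ensemble, the package evaluates $^3J$ on every frame from
that frame's torsion and averages the couplings arithmetically:
$\hat{J} = \langle J(\phi)\rangle$. The order matters: the Karplus curve is
strongly nonlinear, so $J(\langle\phi\rangle)$ is badly wrong for
multimodal rotamer populations. A regression test pins a bimodal
$\pm 60^\circ$ case where the two orders differ by more than 3 Hz.

The model's assumptions are those of any Karplus-based analysis: the
parameterization transfers to the fragment at hand, the ensemble is an
equilibrium sample of the relevant torsion populations, and couplings are
insensitive to degrees of freedom other than the listed substituent
pattern and $\phi$.

## Orientation factors

The sign convention of $\xi$ matters for chirality discrimination, and the
HLA literature states it through Newman-projection pictures rather than a
formula. The package uses an explicit geometric rule. For a substituent
$S$ on the carbon bearing $H_A$, define $\theta$ as the signed dihedral
$S{-}C_A{-}C_B{-}H_B$ (for $S$ on $C_B$, use $H_A{-}C_A{-}C_B{-}S$), with
the same right-handed convention as $\phi$ itself. Then

$$\xi = +1 \iff \mathrm{wrap}(\theta - \phi) \in (0^\circ, 180^\circ).$$

At an sp$^3$ carbon the geminal offset $\mathrm{wrap}(\theta-\phi)$ sits
near $\pm 120^\circ$; a value within $15^\circ$ of $0^\circ$ or
$180^\circ$ would mean a near-planar substituent and is rejected as a
validation error. Mirror reflection negates every dihedral, hence flips
every $\xi$, and the HLA equation is invariant under the joint flip
$(\phi, \xi) \to (-\phi, -\xi)$ — so enantiomeric ensembles predict
identical couplings, which the test suite asserts to $10^{-9}$ Hz. Because
published statements of the convention are pictorial, the absolute (as
opposed to relative) sign of this rule should be checked against worked
HLA examples before trusting absolute configuration calls on real data
whose decision rests on a single substituent orientation; all
synthetic-recovery results in this package are invariant under a global
sign flip.

$\xi$ is assigned on the first frame and re-checked on a 1% random sample
of frames (at least 5): a sign change mid-ensemble would mean the ensemble
inverts configuration, and the run aborts rather than average over it.

## Ensemble statistics

* **Frame budget.** The default probe is 2000 frames, a conventional
  statistical sample from a long trajectory; longer inputs are subsampled
  with a uniform stride. At typical per-frame coupling spreads
  (SD $\approx$ 3–4 Hz) this puts the naive standard error near 0.08 Hz,
  far below the Hz-scale differences that drive epimer decisions.
* **Uncertainty.** Frames from dynamics are autocorrelated, so alongside
  SD/$\sqrt{n}$ the report carries a block-averaging estimate (block = 50
  frames). For the independent-sampling synthetic generator the two agree;
  on real trajectories the block estimate is the honest one.
* **Convergence.** A run passes if the cumulative mean moves by no more
  than 0.2 Hz (configurable) over the trailing 200 frames. This guards the
  frame-budget choice; it cannot detect unsampled basins.
* **Rounding.** All statistics are computed and stored at full precision.
  Table-style display output rounds half away from zero to 0.1 Hz, so a
  mean disagreement of 0.275 Hz displays as 0.3 Hz.

The package is deliberately agnostic about where ensembles come from:
frames in, couplings out. It makes no assumptions about trajectory length
or provenance, and no reweighting by energy is attempted.

## Epimer decision

Each candidate configuration is scored by the per-coupling absolute
disagreement $|J_\mathrm{meas} - \hat{J}_\mathrm{pred}|$, summarized as
the mean (the decision statistic) with the maximum reported alongside. The
winner is the smallest mean; if the two best means differ by less than a
margin (default 0.5 Hz) the result is "ambiguous" rather than a forced
call. The margin is this package's conservative tie-break — a
well-separated case (means differing by an Hz or more) never touches it.
With only a handful of couplings, a mean disagreement difference below
half a Hertz is within what parameterization error alone can produce,
hence the default.

## J-threshold geometry rules

Two quantitative classification rules are included because they are part
of the same coupling-based workflow:

* **Olefinic E/Z**: trans couplings cluster near 15–16 Hz, cis near
  11–12 Hz. Defaults call E at $J \ge 14.0$ Hz and Z at $J \le 12.5$ Hz,
  with an explicit "ambiguous" band between.
* **sp$^3$ diaxial-range**: anti (diaxial) arrangements give
  $\approx$ 9–12 Hz, gauche below $\approx$ 6 Hz. Defaults: diaxial-range
  at $J \ge 9.0$ Hz, small at $J \le 6.0$ Hz, intermediate between.

The thresholds are midpoints between the ranges observed in the motivating
data, not universal NMR constants; both are configurable arguments.

## The synthetic generator

The study design that motivates this package relies on unpublished MD
trajectories, so validation needs ensembles with *known* stereochemical
ground truth. The generator samples torsion space directly: the HLA
machinery consumes only torsion statistics, so a rotamer-level model
reproduces exactly the feature of a trajectory that the analysis depends
on, with none of the energetics.

The built-in fragment is a six-heavy-atom chain
C39–C40–C41(OH)–C42–C43 with explicit hydrogens and one stereocenter
(C41), built from an internal-coordinate template (bond lengths 1.0–1.6 Å,
sp$^3$ angles 105–115°) by natural-extension placement. Two backbone
torsions are sampled per frame, independently, from von Mises rotamer
mixtures:

* `chi1` (C42–C41–C40–C39): staggered centers $60/180/-60^\circ$, default
  weights $0.65/0.25/0.10$, $\kappa = 20$ ($\approx \pm 13^\circ$ spread,
  resembling room-temperature torsional fluctuation).
* `chi2` (C43–C42–C41–C40, stereocenter-adjacent): by default replaced by
  a narrowed single-center distribution ($180^\circ$, $\kappa = 60$). This
  is the minimal encoding of an intramolecular hydroxyl/carbonyl hydrogen
  bond that locks the stereocenter-to-carbonyl stretch: in the anti basin
  the hydroxyl oxygen sits $\approx 2.9$ Å from C43, and the narrowed
  distribution sharply reduces conformational freedom there.

The default basin choices follow from the fragment's geometry: with the
dominant `chi1` basin at $60^\circ$ and `chi2` at $180^\circ$ the R
fragment places H40a and H42a gauche to H41 and H40b/H42b anti, producing
the alternating small/large/small/large coupling pattern of the measured
data; the skewed basin weights make the torsion distribution chirally
informative (a perfectly symmetric distribution would render the two
epimers indistinguishable, since they are exact mirror images of each
other within the fragment). The S template carries every constant torsion
offset negated, so S at mirrored torsions is the exact per-atom mirror of
R — verified to $10^{-6}$ Å in the tests.

Sampling uses the Best–Fisher rejection method for von Mises draws,
validated against the analytic mixture density by a $\chi^2$ goodness-of-fit
test at $n = 50000$. All generation is seeded and reproducible; ensembles
are written as multi-model PDB with a JSON truth sidecar (chirality, seed,
specs).

**What the generator does *not* emulate:** torsion–torsion correlations,
autocorrelation in time, solvent effects, bond-length/angle fluctuation,
and any energetic coupling between the stereocenter and remote parts of a
real macrolactone. Passing the synthetic recovery tests therefore shows
that the pipeline is internally consistent and statistically powered for
torsion-population differences of the modeled kind — it does not certify
force-field or parameterization accuracy on real molecules.

## Numerical conventions and degenerate inputs

* Angles in degrees throughout the public API, wrapped into
  $(-180^\circ, 180^\circ]$; coordinates in Å; couplings in Hz.
* Signed dihedrals use the right-handed (IUPAC) convention; the
  implementation is cross-checked against an independent torsion oracle.
* Collinear atom triples (cross-product norm $< 10^{-6}$ on normalized
  bond vectors — far below any thermal geometry) raise a geometry error
  naming the frame rather than returning NaN.
* Frame indexing is 1-based in the API and reports, matching PDB MODEL
  numbering.
* Multi-model PDB reading validates that every model carries the same atom
  table and rejects mismatches with the offending model named. XYZ
  round-trips preserve coordinates to the format's $10^{-3}$ Å precision.
* Topology is user-declared and validated against frame-0 geometry
  (covalent distances 0.7–1.9 Å by default); no connectivity perception is
  attempted, because substituent group assignment cannot be perceived
  reliably from coordinates.

## Validation problem sizes

The shipped tests run the full pipeline at the sizes the analysis itself
uses: 2000-frame ensembles for predictions and epimer recovery (20 seeded
replicates, requiring $\ge 19$ correct), 50000-frame samples for
distributional checks and the zero-fluctuation limit
($\kappa = 1000$ two-state ensemble within 0.05 Hz of the
population-weighted closed form), and 1000-configuration random sweeps for
the equation-level oracle and mirror-symmetry properties.

## Design choices on genuinely open points

* **Substituent group mapping.** The published group table does not state
  which group attaches to which substituent for the four C40–C42
  couplings. The shipped example topology assumes OH for the C41 hydroxyl,
  CH$_2$CH$_2$R for the chain carbon on the C39 side and CH$_2$C(O)R for
  the chain carbon toward the carbonyl; CHMeOH (0.62) is in the table but
  unused by the example. This is documented as the package's assumption,
  not a published assignment.
* **Decision margin** (0.5 Hz) and the classification thresholds
  (14.0/12.5 Hz olefinic, 9.0/6.0 Hz sp$^3$) are this package's defaults,
  chosen as midpoints or conservative guards as described above; all are
  configurable.
* **Pre-computed prediction tables** are accepted as compare inputs, so a
  published measured/calculated table can be re-scored without any
  ensemble — that is what makes printed results reproducible here.

## Known limitations

* The HLA parameterization targets H–C(sp$^3$)–C(sp$^3$)–H couplings;
  olefinic and heteronuclear couplings are handled only by the threshold
  rules, not predicted.
* No energy reweighting or time-correlation analysis beyond block
  averaging.
* The absolute $\xi$ sign convention is validated by internal mirror
  properties and synthetic recovery (which are invariant under a global
  flip); see the orientation-factor section above.
* The ambiguity margin treats candidates as exchangeable; it does not
  model systematic parameterization bias shared across couplings.
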