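---
title: "Methods: contact modulation of disordered-protein ensembles by a polyvalent ligand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact modulation of disordered-protein ensembles by a polyvalent ligand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibmod)
```

## The question and the protocol

Intrinsically disordered proteins (IDPs) such as Tau, alpha-synuclein and
amyloid-beta interconvert among a vast set of conformations, and their
aggregation into amyloid fibrils begins with transient intrachain contacts
in the monomer.  A polyvalent cation like spermine binds such chains weakly
but at many sites at once, and can therefore shift which contacts the
monomer samples.  The protocol implemented here asks a precise version of
that question: *for the residue pairs that form the core of known disease
fibrils, does the ligand make the monomeric chain sample those pairings
more or less often as its concentration rises?*

The pipeline has three legs that meet in the contact-modulation map:

* **Ensemble leg** — per-condition conformational ensembles are reduced to
  contact-probability maps `P_ij`;
* **Fibril leg** — deposited fibril structures are reduced to per-monomer
  native contact sets and clustered into polymorph families;
* **Regression** — for every fibril-native pair, `P_ij` is regressed
  against the ligand:protein molar ratio; the slope `k_ij` is the
  contact-modulation coefficient (probability per unit ratio).

Around the core sit the supporting analyses: ligand occupancy and
residence-time statistics, global chain metrics (radius of gyration,
radial distribution function, Flory exponent, secondary-structure
fractions), contact-relaxation times as a sampling-adequacy check, and
logistic fits of ThT aggregation kinetics for the wet-lab counterpart.

## Definitions and parameters

All coordinates are handled in nanometres and times in nanoseconds;
Angstrom file formats are converted on read.  Only heavy (non-hydrogen)
atoms enter any distance computation; hydrogens are discarded when a
topology is built.

| Parameter | Default | Meaning |
|---|---|---|
| contact cutoff | 0.45 nm | residue pair "in contact" when any heavy-atom pair is closer |
| sequence-separation floor | 4 | pairs separated by at least three other residues (`j - i >= 4`) |
| mediated cutoff | 0.6 nm | ligand-residue distance for ligand-*mediated* contacts |
| twin cutoffs `r_on`/`r_off` | 0.45 / 0.6 nm | hysteresis for binary contact states and binding events |
| QC threshold | 0.3 nm | periodic-image minimum distance below which a frame is excluded |
| block count | 4 | contiguous blocks for the R<sub>g</sub> standard error |
| Flory prefactor | 0.55 nm | fixed; only the exponent ν is fitted |

The separation floor is read strictly: "at least three other residues"
means three residues strictly between the pair, i.e. `j - i >= 4`.  The
same rule, with the same cutoff, defines both ensemble contacts and
fibril-native contacts, so the two legs share one pair universe; this is a
deliberate harmonisation — the alternative (a different fibril-side
cutoff) would make `k_ij` depend on an arbitrary mismatch between the two
definitions.

Residue-residue distance is the minimum over heavy-atom pairs, and under
periodic boundaries the minimum-image distance (general triclinic
reduction; the quality-control check instead enumerates all 26 neighbour
images explicitly, which is exact for any reduced box).  QC-flagged frames
are excluded *per frame* by default — an ensemble is a bag of
configurations, and a transient self-image approach invalidates only the
frames it occurs in; `exclude_qc_frames(whole = TRUE)` rejects the whole
trajectory for workflows that prefer the stricter reading.

## The modulation regression

`modulation_coefficients()` fits, for each fibril-native pair, ordinary
least squares of `P_ij` on the *numeric* molar ratio (0, 1, 5, 10, ...),
not on the condition rank — the quantity of interest is sensitivity to
concentration, and unevenly spaced ratios carry that information.  Two
choices matter:

* a pair absent from a sparse contact map contributes `P_ij = 0` at that
  condition: absence means no frames in contact, an observation, not
  missing data;
* the regression is unweighted by default.  Frame counts per condition are
  often equal by design; when they are not, `weights = "frames"` switches
  to frame-count-weighted least squares.

With exactly two conditions the OLS slope reduces algebraically to
`delta P / delta ratio`, which ties the regression to `contact_delta()`
and is enforced by test.  No multiple-testing machinery is applied to
`k_ij`; the map is descriptive, and `modulation_map_report()` exposes only
a sign threshold for classifying pairs as promoted / suppressed /
unchanged.  `r2` is reported per pair and is `NA` for a flat series (zero
variance leaves the coefficient of determination undefined).

## Fibril clustering

Polymorph families are the connected components of the graph whose nodes
are structures and whose edges join pairs sharing at least one native
contact (`min_shared = 1`).  Components — rather than centroid or
density-based clustering — because shared-contact counts are sparse,
integer-valued similarities for which exact membership is meaningful, and
because a structure sharing no contact with any other is then *exactly* a
singleton, the natural notion of a unique polymorph.  A Jaccard-index
threshold (`min_jaccard`) is available for sensitivity analysis; raising
either threshold can only split clusters, never merge them (tested as an
invariant).  Cluster order is deterministic (size, then lexicographic
first member), making clustering invariant to input order.

One representative monomer is taken per deposited entry; under the default
`central` chain policy it is the chain whose centroid is nearest the
assembly centroid — an interior protofilament layer, avoiding stack-edge
effects.  Mapping between construct numbering and full-length isoform
numbering is explicit (`renumber_offset`), never inferred by alignment.

## Ligand binding and residence times

A binding event at a residue starts when a ligand's heavy-atom distance to
that residue drops below `r_on = 0.45` nm while previously unbound there,
and ends at the first frame the distance exceeds `r_off = 0.6` nm;
excursions into the dead zone between the cutoffs do not end the event.
`tau_residue` is the event duration; `tau_protein` extends the same event
until the ligand is beyond `r_off` of *every* residue (complete
dissociation), so `tau_protein >= tau_residue` by construction.  Events
still open at the end of the trajectory are reported as censored and
excluded from means rather than silently truncating them.  The exchange
rate is completed events per residue divided by total analysed time, so
`rate x time` is always an integer event count.

A ligand may be bound to several residues simultaneously; events are
tracked per (ligand, residue) pair independently.  One caveat the package
flags but cannot remove: apparent dwell times depend on the output
cadence.  A ligand that unbinds and rebinds within one frame interval is
never seen to leave, which biases dwell times upward by roughly
`pi_bound * (1 - exp(-(k_on + k_off) dt))` per sampling step.  The
validation suite therefore exercises the estimator under conditions where
binding kinetics are slow on the frame interval (`k_off dt = 0.04`,
`k_on = k_off / 2`), where the residual discretisation bias is about 3%,
well inside the 10% recovery tolerance; analyses of real trajectories
should use the finest cadence available (the residence analyses this
protocol is modelled on were saved every 0.25 ps).

## Contact dynamics and relaxation times

Binary contact trajectories use the same 0.45/0.6 nm hysteresis
(`contact_state_trajectory()`).  When a series *starts* inside the dead
zone the first unambiguous state is back-filled by default — dropping the
head is available as a switch (`initial = "drop"`); back-fill was chosen
because it preserves trajectory length and the head's true state is, by
construction, within one hysteresis width of the back-filled one.

`contact_relaxation_time()` computes the normalised fluctuation
autocorrelation C(t) by FFT and fits a single exponential by log-linear
least squares through the origin, lag 0 excluded, over lags up to where
C(t) first falls below 0.05 (capped at 10% of the trajectory length).
Through the origin because C(0) = 1 exactly by normalisation; the 0.05
floor keeps the noisy tail out of the fit.  The RMS log-residual is
returned as `fit_quality`; degenerate decays (e.g. strictly periodic
states, whose autocorrelation oscillates) are flagged rather than fitted,
and constant series raise an error identifying the pair as
non-fluctuating.  For a two-state telegraph contact the autocorrelation is
exactly `exp(-(k_on + k_off) t)`, giving the analytic oracle
`tau = 1/(k_on + k_off)` used throughout the tests.

## Chain metrics

*Radius of gyration* is mass-weighted over protein heavy atoms by default
(the convention behind standard MD analyses); `weighting = "uniform"`
suits single-bead synthetic chains.  The error is the SEM over four
contiguous blocks — block averaging being the standard variance estimate
for correlated series; with fewer frames than blocks the mean is still
returned and the error is `NA` with a warning.

*The radial distribution function* between protein C-alpha atoms and
ligand heavy atoms is normalised by shell volume, frame count, pair count
and the instantaneous box volume (NPT-compatible), so an ideal gas gives
g(r) = 1; `r_max` may not exceed half the smallest box extent, where the
minimum-image convention stops being injective.

*The Flory fit* uses C-alpha positions and a fixed 0.55 nm prefactor:
`log(R(s)/0.55) = nu * log s` by least squares through the origin over
separations `s in [5, N-1]`.  The lower bound skips local-stiffness
separations where no power law holds; both the range and the prefactor are
arguments.  Because the prefactor is fixed, ν absorbs any mismatch between
the true `R(1)` and 0.55 nm — that is inherent to the fixed-prefactor
convention, not a defect; `flory_fit_profile()` accepts precomputed
distance profiles for fitting published curves directly.  Intrachain
distances are computed without minimum-image reduction, assuming whole
(unwrapped) molecules.

*Secondary structure* is consumed, not assigned: per-frame per-residue
codes (e.g. DSSP letters) are reduced to helix/sheet/coil fractions under
an explicit grouping (default `H,G,I -> helix; E,B -> sheet; rest coil`,
recorded in output headers).  Unknown codes are an error rather than
silently becoming coil.

## ThT kinetics

The mean of the replicate traces is fitted (with SEM retained), matching
plate-reader practice of reporting the mean of independent repeats, to the
logistic `F(t) = F0 + (Fmax - F0)/(1 + exp(-k (t - t_half)))` by bounded
Levenberg-Marquardt least squares.  Initial values are deterministic:
`F0 = min`, `Fmax = max`, `t_half` from the interpolated half-rise
crossing, `k = 4 / (t90 - t10)` (the exact identity for a noiseless
logistic).  Bounds: `k > 0`, `t_half` within the observed window extended
by half its span; fits returning `Fmax < F0` are flagged `poor_fit`, never
raised as exceptions.  The lag time is `t_half - 2/k`, the
tangent-intersection identity, and holds exactly for every `ok` fit.

Uncertainties are 2.5/97.5 percentiles over seeded residual resampling on
the mean trace (replicate-level case resampling via
`bootstrap = "replicates"`).  Traces that never rise are not fitted: the
rise of a lightly smoothed (5-point moving average) mean trace must exceed
5 times the high-frequency noise SD, estimated as `sd(diff(y))/sqrt(2)`.
The smoothing matters — the range of ~100 independent noise points is
itself about 5 SD, so an unsmoothed rise cannot separate pure noise from
signal at that multiplier, while smoothing shrinks a noise rise by
`sqrt(5)` and leaves a genuine sigmoid untouched.

## The synthetic-data generators

Every stage is validated against data with known ground truth:

* `generate_ensemble()` builds bead-per-residue random-flight chains (one
  heavy atom per residue, 0.38 nm bond), centred in a cubic box at least
  2.5x the maximal chain extent — so generated ensembles pass the 0.3 nm
  periodic-image QC by construction.  Programmed contact pairs override
  the second residue's position to 0.40 nm (contact) or 0.80 nm (no
  contact) from the first, with per-frame states drawn at occupancy
  `intercept + slope * ratio`; ligand particles follow continuous-time
  two-state (telegraph) binding with prescribed rates, placed 0.40 nm from
  their residue when bound and uniformly in the box (rejected within
  0.7 nm of any residue) when unbound.
* `generate_fibril_set()` writes coarse C-alpha traces folded so exactly
  the designed pairs touch: beads on a 0.6 nm line with each contact's
  second bead moved to 0.40 nm from its first, at golden-angle offsets so
  moved beads cannot collide.  Every written file is re-read and its
  realised contact set verified against the design; an unrealisable
  design fails with the offending pair named.
* `generate_tht_curves()` produces logistic traces plus seeded Gaussian
  noise.

Fixed seed implies byte-identical output.  What the generators *emulate*
is the statistical structure the analyses assume — prescribed occupancies,
exponential dwell times, designed shared-contact blocks, sigmoidal
kinetics.  What they do *not* emulate: excluded volume and chain
thermodynamics, correlated contact formation, many-body ligand effects,
fibril side-chain packing, or instrument drift.  Passing tests therefore
demonstrate that the estimators recover known truth from data of the
assumed form, not that any particular biological system behaves that way.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run, among others: 50 random
contact-map instances (up to 20 residues, 5 atoms/residue, 100 frames)
against a brute-force oracle; slope recovery at ratios {0, 1, 5, 10} with
2000 frames/condition over programmed slopes ±0.02..0; telegraph residence
recovery at `k_off` in {0.01, 0.05, 0.2} /ns with over 1000 events each;
relaxation recovery from 5x10^5-step telegraph series; Flory recovery on
noiseless power laws and 10^4 Gaussian chains; RDF flatness on 10^6
sampled pairs; and bootstrap coverage over 200 noisy logistic curves with
200 resamples each.  These sizes were chosen so each statistical check has
comfortable margin against its tolerance while the whole suite stays quick
on a single CPU.

## Known limitations

* Intrachain (monomeric) analysis only; no inter-chain contacts,
  oligomers, or fibril growth modelling.
* XTC trajectories are not read (multi-model PDB, DCD and a plain-TSV
  dialect are); convert externally if needed.
* Residence times are cadence-dependent (see above); the package reports,
  but does not correct, discretisation bias.
* The logistic is the only kinetic model offered — no
  nucleation-elongation mechanisms.
* Fibril-construct mapping is by explicit offset; structures whose author
  numbering does not map affinely onto the simulated construct need
  preprocessing.
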