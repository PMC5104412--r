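---
title: "Linear QSPR modelling with qsprlm: models, descriptors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear QSPR modelling with qsprlm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsprlm)
```

## The modelling problem

A quantitative structure-property relationship (QSPR) model predicts a
molecular property $P$ — the log of aqueous solubility, of the blood/brain
concentration ratio, of Caco-2 permeability — as a linear function of
numeric *descriptors* $d_1,\dots,d_N$ computed from the molecular
structure:

$$ P = c_0 + \sum_{i=1}^{N} c_i\, d_i .$$

The coefficients are fitted by ordinary least squares on a *training set*
of molecules with measured property values, and the fitted model is then
applied to new molecules. qsprlm implements the full cycle: reading
multi-record SD files, computing descriptors, fitting, persisting models as
JSON, predicting, and scoring predictions with the four statistics used in
the QSPR literature — the coefficient of determination $r^2$, the residual
standard deviation $\sigma$, the mean unsigned error (MUE), and the largest
*signed* deviation $\Delta_{max}$.

## Fitting algorithms

Four algorithms are exposed through `fitQSPR()` / `trainQSPR()`:

* **mlr** — plain least squares on the raw descriptor columns.
* **centered** — columns are mean-centered first. This is an affine
  reparameterisation: fitted values are identical to mlr (asserted to
  1e-10 in the suite), but the stored column means make the intercept
  interpretable as the mean response.
* **mcuv** — mean-centered unit-variance autoscaling (z-scoring). Again
  prediction-equivalent to mlr; the standardized coefficients are
  comparable across descriptors of different units.
* **klopman** — the solubility-specific variant: the property is first
  mapped onto a bounded interval by a stereographic projection, the
  projected property is fitted with MCUV scaling, and predictions are
  mapped back to property units.

The solver is a QR decomposition with an explicit rank check; a
rank-deficient design names the dependent columns and aborts rather than
falling back to a pseudoinverse. At least $p+2$ usable rows are required so
the df-corrected $\sigma$ is always defined. Rows with a missing property
value are excluded and counted, never imputed.

### The projection

The original group-contribution solubility method fits a stereographic
projection of the property rather than the property itself; the exact
projection formula and scale constant live in the original
group-contribution paper, not in sources available to this package, so the
projection is isolated behind `projectProperty()` / `unprojectProperty()`
with a documented stand-in:

$$\theta = 2\,\arctan(y/s), \qquad y = s\,\tan(\theta/2),$$

a strictly increasing, odd bijection from the real line onto
$(-\pi,\pi)$, with scale $s$ (default 1, property units) as a tunable.
A faithful replacement can be swapped in behind the same interface without
touching the fitting code. Inputs to the inverse are clamped to the open
interval at a margin of 1e-9 so any finite linear-model output maps to a
finite property value; the clamp makes the inverse weakly rather than
strictly monotone in the far tails, which in practice only matters for
models extrapolating far outside their training range.

### Statistic conventions

The published tables this engine mirrors never define whether $\sigma$
carries a degrees-of-freedom correction. We default to the residual
standard error $\sigma = \sqrt{SS_{res}/(n-p-1)}$ and expose
$\sqrt{SS_{res}/n}$ under `sigmaDf = "plain"`; the convention used is
recorded inside every saved model and report. Test-set $\sigma$ reuses the
training convention with $p$ taken from the model, so columns of one
comparison table are computed identically. Test-set $r^2$ is
$1 - SS_{res}/SS_{tot}$ (not the squared Pearson correlation — the two
differ off the training set, where $r^2$ can go negative).
$\Delta_{max}$ is the *signed* residual of largest magnitude under the
experimental-minus-predicted convention (configurable), with ties broken
by first occurrence so results are deterministic given file order.

## Descriptors

`descriptorRegistry()` covers the descriptors used by the published linear
models for the three properties above, plus a generic SMARTS group-count
family (`smartsCountSpec()`) standing in for full group-contribution
tables. Numerical choices that the literature leaves open are fixed as
follows:

* **Polar surface area** — the fragment-based Ertl *topological* PSA is
  the default polar-surface descriptor because it is exactly reproducible;
  a 3-D PSA (`psa_3d`, polar-atom contribution to a sampled
  solvent-accessible surface) is a separate descriptor, and model recipes
  choose explicitly.
* **Surface construction** — Shrake-Rupley style numeric sampling with a
  deterministic Fibonacci sphere of 960 points per atom, probe radius
  1.4 Å, Bondi van der Waals radii.
* **Partial charges** — Gasteiger-Marsili iterative partial equalisation
  of orbital electronegativity, 8 damped iterations, formal charges as the
  seed. The suite pins the implementation against an independently
  computed PEOE reference on ethanol; conjugation corrections applied by
  some modern toolkits are not reproduced, so charges on carboxyl oxygens
  differ from e.g. RDKit in the second decimal (asserted qualitatively
  instead).
* **pnsa2** — the Stanton-Jurs *total-charge-weighted partial negative
  surface area*: the summed solvent-accessible surface of negatively
  charged atoms multiplied by the total negative charge (hence itself
  negative).
* **clogp and TPSA** — delegated to Open Babel through ChemmineOB: the
  Wildman-Crippen atomic-contribution logP and the Ertl fragment TPSA are
  standard published schemes and the installed implementation is used
  rather than re-deriving the contribution tables.
* **molecular_volume** — additive van der Waals sphere volume without
  overlap correction: deterministic and monotone in molecular size, which
  is the role the "volume" descriptor plays in the two-descriptor
  blood-brain-barrier model.
* **hba_count** — "number of hydrogen-bond acceptors" is ambiguous in the
  source models; the fixed, auditable definition here is: N and O atoms,
  not positively charged, excluding pyrrole-type aromatic nitrogens and
  amide nitrogens.
* **Hydrogens** — implicit hydrogen counts follow standard valence rules
  with formal-charge adjustment. Descriptors that need explicit hydrogens
  (volume, surfaces) add them with idealized, rotation-equivariant
  geometry built from the neighbour directions, and log that they did.

### Invariance and its limits

All descriptors are invariant under atom-order permutation, and analytic
descriptors (masses, counts, radius of gyration) are exactly invariant
under rigid-body motion. Sampled-surface descriptors are made
rotation-invariant by canonicalising coordinates into a deterministic
principal-axes frame before sampling; this is exact whenever the
coordinate covariance has distinct eigenvalues, i.e. for every molecule
that is not a highly symmetric top. For degenerate cases (methane,
planar benzene) surface values can shift by ~0.1% under rotation — a
documented limitation of point-sampled surfaces, asserted only on
non-degenerate fixtures.

Molecules whose coordinates are degenerate (all atoms coincident, or the
all-zero z column characteristic of 2-D SD files) make 3-D descriptors
unavailable: the cell is flagged in the missing mask and the molecule
excluded from prediction, with a named log entry — guessing a conformer
is out of scope.

## The synthetic generator

`generateSyntheticSet()` exists so every pipeline stage is testable
without redistributing external training databases. Molecules are
assembled from a fragment library — alkyl chains of 1-6 carbons, an
optional benzene ring (probability 0.4), and OH/NH2/COOH/F/Cl
substituents — with idealized geometry and fully explicit hydrogens;
fragment assembly guarantees chemically valid valences and real
functional groups, which descriptors like HBD or TPSA need to show
variance. The property is written as
$c_0 + \sum c_i d_i + \mathcal{N}(0, \sigma_{noise})$
into an SD field at 17 significant digits. The default configuration —
four weakly correlated descriptors (molecular weight, HBD count,
rotatable bonds, aromatic proportion), intercept 0.5, noise 0.5 property
units — gives a signal-to-noise ratio typical of desk-scale QSPR fits
($r^2 \approx 0.8$ at $n = 200$). Structure sampling and noise use
separate seeded streams, and the caller's RNG state is left untouched.

What the generator does *not* emulate: realistic drug-likeness
distributions, conformational flexibility, tautomers, or the property
ranges of the published training databases. Green tests therefore
demonstrate the *engine* (parsing, descriptor computation, fitting,
round-trips, statistical conventions) — not chemical transferability of
any particular fitted model.

## Validation problem sizes

The suite and the acceptance script validate, at sizes chosen to keep a
desk-scale run in minutes: 50 random fixtures for the OLS-vs-normal-
equations oracle (agreement ~1e-15); prediction equivalence of the three
affine algorithms (1e-10); exact recovery of ground-truth coefficients
from a noiseless 30-molecule set (1e-8); a 100-replicate Monte-Carlo
study at $n = 200$, noise 0.5, checking every coefficient's mean estimate
within 3 standard errors of truth and $r^2$ strictly below 1; projection
round trips over the full aqueous-solubility range ($-11.6$ to $1.6$ log
units); hand-arithmetic evaluation statistics including both
$\Delta_{max}$ signs; fixture descriptor values derived by hand; and
byte-exact SDF/model round trips.

## Known limitations

* Aromaticity perception covers benzenoids, pyridine-type rings and
  five-membered heteroaromatics via Kekulé-pattern matching; fused or
  charged exotic aromatics are out of scope.
* The Gasteiger parameter table covers H, C, N, O, S, P and halogens;
  other elements keep their formal charge and do not exchange.
* V3000 SD records are skipped with a warning; only V2000 is parsed.
* No variable selection, regularisation or cross-validation: descriptor
  lists are fixed a priori by the recipe, matching how the reproduced
  literature models were specified.
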