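---
title: "Models and methods behind clusterpdf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clusterpdf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterpdf)
```

`clusterpdf` determines the solution-state structure of small metal
clusters — the motivating system is the DNA-stabilized Ag16Cl2 core, 16 Ag
atoms in four axial channels capped by two chloride ions and wrapped by two
DNA decamers — from X-ray total-scattering data. This vignette explains the
models, the defaults and the numerical choices, and states plainly what the
method can and cannot deliver.

## The observable

Total scattering measures both Bragg and diffuse intensity, so it works for
dissolved, non-crystalline samples. The reduced structure function F(Q) is
sine-transformed to the pair distribution function,

$$G(r) = \frac{2}{\pi}\int_{Q_\min}^{Q_\max} F(Q)\,\sin(Qr)\,\mathrm{d}Q,$$

evaluated here by trapezoidal quadrature (`fq_to_gr()`, defaults
$Q_\min = 0.7$, $Q_\max = 20\ \mathrm{\AA^{-1}}$ — typical rapid-acquisition
bounds, configurable). Before the transform the aqueous-DNA signal is
subtracted in Q space (`subtract_background()`); the scale of that
subtraction is the most delicate step of the reduction, so `auto_scale()`
only *suggests* a least-squares scale over a user-chosen
background-dominated window and nothing is ever applied silently. Full
intensity normalisation (Compton, polarisation, absorption) belongs to
beamline software and is out of scope: the module accepts pre-reduced F(Q).

## Simulating G(r) from a model

For an atomic model the PDF is a sum over unordered pairs,

$$G(r) = \frac{s}{r}\sum_{i<j} 2\,w_{ij}\,
  \mathcal{N}(r;\, r_{ij},\, \sigma_{ij}), \qquad
  w_{ij} = \frac{f_i f_j}{\langle f\rangle^2}, \qquad
  \sigma_{ij}^2 = \frac{B_i + B_j}{8\pi^2} + \sigma_0^2 .$$

Choices worth stating:

* **Scattering weights** are atomic numbers ($f = Z$, the $Q\to 0$ limit of
  the X-ray form factor). The relative weighting of Ag–Ag against Ag–Cl or
  DNA-atom pairs is dominated by $Z$; Q-dependent form factors would be an
  optional refinement, not a change in kind.
* **Resolution floor** $\sigma_0 = 0.05\ \mathrm{\AA}$ is added in
  quadrature to every pair width: finite $Q_\max$ always broadens
  experimental PDFs, and the floor keeps sharp pairs from aliasing on the
  grid.
* **No $4\pi\rho_0 r$ baseline**: a dissolved cluster after background
  subtraction is an isolated scatterer; solvent restructuring is handled by
  the explicit solvation wave instead.
* **Grid** 0–30 Å in 0.01 Å steps; Gaussians are truncated at $\pm 8\sigma$
  (relative error below $10^{-14}$), which is what lets `calc_pdf()` agree
  with a brute-force pair sum to $10^{-8}$ in the tests.
* For thousand-atom DNA models at uniform Biso, `dna_pdf()` bins distances
  into 0.001 Å bins and convolves once by FFT, with within-bin Taylor
  moment corrections through third order so the fast path matches the
  direct sum to better than $10^{-6}$.

Misfit is the weighted profile residual
$R_w = \sqrt{\sum(G_{obs}-G_{calc})^2 / \sum G_{obs}^2}$ over a fit range
of 1.7–15 Å by default: below 1.7 Å there are no physical contacts in
these systems, and beyond ~12–15 Å a cluster this size has no coherent
features.

## Two-stage refinement

Stage 1 refines the $3N$ Cartesian coordinates plus one overall scale — 55
parameters for the 18-atom core — by bounded Levenberg–Marquardt least
squares on the pointwise residual (an analytic Jacobian, assembled in
compiled code, makes a 50-model ensemble a minutes-scale computation).
Numerical policy:

* **Bounds** of $\pm 1$ Å per coordinate around the start model. The PDF is
  invariant to rigid motions, so unbounded positions are unidentifiable;
  the bounds keep every refinement in the start model's frame.
* **Collisions**: steps bringing two atoms closer than 0.5 Å are repelled
  by a hinge penalty added to the residual (LM steps cannot be intercepted
  individually).
* **Continuation**: the problem is optionally solved at mildly broadened
  resolution first (extra widths 0.1 Å, then 0), each level smoothing the
  data to match. Pair peaks only attract an atom from within about one
  peak width, so this widens basins; levels much wider than the pair width
  are deliberately avoided — heavy smoothing merges peaks into a surface
  whose minimum is a *different* geometry, and we verified that
  refinements seeded at such coarse minima end up in the wrong basin.
* Everything is deterministic: no random restarts, bit-identical reruns.

Stage 2 adds the empirical solvation wave
$A\sin(2\pi r/\lambda + \varphi)\,e^{-r/\xi}$, the standard description of
solvent-restructuring residuals around dissolved particles, and refines
$(A, \lambda, \varphi, \xi)$ *jointly with the scale*: a scale fitted
against wave-containing data is biased, and refitting it is what lets the
tests recover generating wave parameters essentially exactly. The
wavelength is bounded below by 1 Å (and the decay length likewise): a
"wave" below the solvent-shell scale can only chase noise. The
zero-amplitude wave reproduces stage 1, and the better of the refined and
zero-wave solutions is kept, so stage 2 never increases $R_w$.
`refine_two_stage()` optionally alternates the two stages: the fitted wave
is subtracted, positions re-refined against the wave-free signal (bounds
still anchored at the original start), and the wave refit.

The exponential-decay parameterisation $e^{-r/\xi}$ is one of several in
the literature; it is the one implemented and documented here.

## Ensemble refinement

Refining one start model is not enough: the information content of a
cluster PDF is limited, and perturbed starts refine to slightly different
structures. The ensemble module therefore perturbs every coordinate by an
independent uniform draw from $\pm 0.2$ Å (the per-model seed is
`base_seed + index`, so runs are reproducible and parallelisable), refines
each copy independently, and aggregates: the per-atom mean structure, the
box-plot spread of each atom's positions about its mean, and the mean
stage-1 residual (which averages refinement noise down as $\sqrt{n}$ and
exposes common unmodelled components — for DNA-wrapped clusters, the
conformational signature of the DNA itself). The production-scale default
of 500 models follows the ten-starts-per-parameter heuristic; the test
suite and the acceptance script use 20–50, which keeps the full study
inside a few minutes on one CPU. No superposition is applied before
averaging: the bounds keep all models in one frame.

## Distortion geometry

The refined average is compared with the reference through per-atom
displacement vectors and signed rotation angles about the cluster's
principal axis — the leading eigenvector of the covariance of the
*reference* coordinates (unweighted; using the reference keeps the axis
independent of refinement noise). The sign convention makes the largest
axis component positive (ties toward +z), and positive angles are
counterclockwise looking down the +axis; only relative senses between
groups are physically meaningful, since no absolute viewing direction
exists in the data. Atoms within 0.1 Å of the axis (the Cl caps) have an
undefined angle and are excluded from summaries. Channel and strand
assignments are input metadata, as in the crystallographic practice of
identifying the four Ag channels by inspection.

## DNA conformation

The mean stage-1 residual of the ensemble is the PDF of the DNA around the
cluster. It is compared with the crystal-DNA model over a Biso grid
(default 0.25–6 Å² in 0.25 steps, bracketing the crystalline 0.5 Å² and
highly mobile 5 Å² regimes): for each trial Biso the model PDF's scale is
refined in closed form, optionally with a rigid r-axis offset of up to
±0.5 Å that mirrors solvent swelling, and $R_w$ over 3–10 Å — the region of
the medium-range conformational features near 5.2 and 7.7 Å, clear of the
sharp bonded-distance peaks — is minimised on the grid. The optimum
converts to a one-dimensional RMS displacement via
$u = \sqrt{B_{iso}/8\pi^2}$; 2.0 Å² corresponds to 0.16 Å of instantaneous
motion. The "simple statistical model" is thus scale-and-offset-refined
$R_w$ minimisation — the minimal defensible choice, and configurable.

Aqueous DNA's sharp low-r structure (1.46 and 2.43 Å from bonded C–C/P–O
and O–O distances) is reproduced by `nucleobase_model()`: idealized
base fragments (regular aromatic rings at standard bond lengths with
exocyclic substituents) combined in the ratio the bases occur in the
sequence — 3:4:2:1 for A:C:G:T in CACCTAGCGA — plus, by default, one
sugar-phosphate unit per residue, since the 1.46 Å peak has backbone
character. These are distance-distribution stand-ins, not crystallographic
geometries.

## The synthetic study, and what passing it shows

The generator builds a chiral, helically twisted four-channel prism of 16
Ag with two Cl caps (nearest contacts 2.8 Å, Biso 1.0 Å² — a typical
room-temperature heavy-atom value giving experimental-like pair widths),
applies a known distortion (per-channel twists about the principal axis
plus 0.05 Å Gaussian jitter) and produces the observable as
PDF + damped-sine wave (A = 2, roughly a few percent of the first-shell
peak; λ = 3 Å, ξ = 4 Å) + 1% i.i.d. Gaussian noise. Three generator
choices deserve emphasis:

* The cluster is **chiral** (helical twist 12° per level). A PDF sees only
  internal distances and cannot tell a structure from its mirror image; an
  achiral reference would make the *sign* of any rotational distortion
  unrecoverable in principle.
* The four channels are **crystallographically inequivalent** (distinct
  radii and axial offsets), as in the real motif. With identical channels
  the ring of inter-channel gaps is homometric — cyclic or reflected
  reassignments of the gaps leave the distance histogram unchanged — and
  per-channel distortions would again be unidentifiable.
* The noise is i.i.d. on G(r), the simplest stand-in for propagated
  counting noise. Real noise is correlated over roughly a resolution
  element; i.i.d. noise at 0.01 Å spacing is, if anything, *harder* on the
  refinement, because 54 free coordinates can chase it.

What the tests demonstrate: the machinery is internally exact (oracle
equivalence, rigid-rotation identities, wave and Biso self-recovery), and
the ensemble recovers the **mean displacement magnitude** of the generating
distortion to better than 0.1 Å.

What they also demonstrate, and what users must know: **per-channel
rotation means are not quantitatively recoverable at this scale.** Two
independent reasons, both verified here by direct experiment. First, the
rotational gauge: a rigid rotation of the whole cluster about its axis
changes no distance, so only the de-meaned twist pattern is in the data at
all. Second, and more biting: a 54-parameter refinement of an 18-atom
cluster reaches the noise floor of the data ($R_w \approx 0.04$ here)
within tens of LM iterations from *any* nearby start, absorbing the twist
signal into distance-equivalent rearrangements; replicate ensembles with
different perturbation seeds return channel-mean "rotations" of a few
degrees with essentially random signs. Experimental studies of this kind
operate at $R_w \approx 0.12$–0.19, where a systematic misfit floor
prevents such overfitting — their rotation fields are therefore plausible,
but a synthetic study with a known truth shows that ensemble means of this
estimator should be read as qualitative at cluster scale. The package
reports what it measures; the acceptance suite asserts the quantitative
twist criterion faithfully and documents its failure rather than relaxing
it.

## Degenerate and edge inputs

Coincident atoms (pair distance below $10^{-6}$ Å) are a hard error;
zero-width pairs off the grid warn about aliasing; an observed curve that
is zero over the fit range makes $R_w$ undefined (error); on-axis atoms are
flagged rather than given meaningless angles; ensembles tolerate
individual refinement failures up to a 20% failure rate. All file formats
are plain text: XYZ and PDB/mmCIF (via bio3d) for structures, '#'-commented
two-column text for G(r) and F(Q), CSV for strand maps.
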