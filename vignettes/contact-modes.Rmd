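---
title: "Contact-based conformational dynamics: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-based conformational dynamics: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactmodes)
```

## The model

`contactmodes` describes the conformational state of a membrane-embedded
peptide not by Cartesian coordinates but by its **residue–residue contact
degrees of freedom**. For a frame of an MD trajectory, the contact variable
$u_{ij}$ is 1 when any atom of residue $i$ lies within a distance cutoff
(default 4.2 Å) of any atom of residue $j$, and 0 otherwise. Contacts are a
natural coordinate system for large-scale structural change: they connect
directly to interaction energetics, they are insensitive to rigid-body
motion, and they make "formation" and "breaking" of structure explicit.

The analysis chain is:

1. **Mean contact matrix.** Averaging $u_{ij}$ over frames gives the contact
   frequency $\langle u \rangle_{ij} \in [0, 1]$ for every pair.
2. **Dynamic-contact selection.** Pairs that are almost never or almost
   always formed carry no usable signal. Pairs with
   $\langle u \rangle_L < \langle u \rangle_{ij} < \langle u \rangle_H$
   (defaults 0.1 and 0.9, strict inequalities) are retained as the dynamic
   contact degrees of freedom; everything else is static and dropped.
3. **Contact PCA.** The $D$ retained binary coordinates are mean-centered
   and the sample covariance matrix is diagonalized. The orthonormal
   eigenvectors $d^{(k)}$ (loadings) are collective contact modes, ordered
   by eigenvalue $\lambda_k$; projecting frames onto them yields PC scores.
   For display, a loading can be scaled by its fluctuation amplitude —
   either $\lambda_k$ (the default here) or $\sqrt{\lambda_k}$; both
   conventions are provided because only relative patterns within a map are
   interpreted.
4. **Contact LDA.** PCA is unsupervised; to ask *which* contact changes
   track an experimental condition (salt concentration, redox state of the
   disulfide bonds, membrane composition), Fisher linear discriminant
   analysis is fit on the top $k$ PC scores (default $k = 8$). Each
   discriminant is $LD_l = \sum_j C_l^{\,j}\, PC_j$, where the rows of $C$
   maximize between-class over within-class scatter. A condition with $g$
   classes yields $\min(g - 1, k)$ discriminants.
5. **Back-mapping.** Because both transforms are linear, a discriminant has
   an exact contact-space representation $\sum_k C_l^{\,k} d^{(k)}$, rendered
   as a signed symmetric residue×residue *contact displacement map*:
   negative entries mark contacts that break, positive entries contacts that
   form, as the score increases. These maps can be exported as 3-D cylinder
   edge lists over a structure for molecular-viewer rendering.

Alongside the contact chain, the package implements the conventional
trajectory analytics used in membrane-peptide studies: superposition RMSD
(Kabsch), radius of gyration, protein–bilayer center-of-mass displacement
along the membrane normal, donor-centered hydrogen-bond counting,
periodic-boundary-aware counting of complete membrane crossing events, and
radial lipid number densities around the protein.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `contact_cutoff_A` | 4.2 | Å | any-atom contact distance |
| `u_low`, `u_high` | 0.1, 0.9 | – | dynamic-contact frequency window |
| `n_pcs` | 8 | – | PC truncation before LDA |
| `hbond_distance_A` | 3.5 | Å | donor–acceptor heavy-atom cutoff |
| `hbond_angle_deg` | 20 | ° | donor-centered angle cutoff |
| `membrane_normal_axis` | z | – | axis for COM displacement / crossings |

The frequency window bounds are applied **strictly**: a pair formed in
exactly 90% of frames is treated as static. This follows the
"more than / less than" reading of the filter and is measure-zero on real
data; it is decided once and documented so results are reproducible at the
boundary.

No sequence-separation exclusion is applied when enumerating pairs:
covalently adjacent residues are in near-permanent contact and are removed
by the static filter anyway, so an explicit exclusion would only add a
parameter.

The hydrogen-bond criterion is the donor-centered convention (angle between
the D→H and D→A vectors ≤ 20°), matching the cutoff semantics of the VMD
program. Note that many other tools use the D–H⋯A angle with a ≥ 160°
cutoff; the two conventions are similar but not identical, and the choice is
deliberately surfaced here.

## What the synthetic generators emulate — and what they do not

Reference MD ensembles at the microsecond scale cannot be regenerated at
desk scale, so validation rests on synthetic data with *recorded ground
truth*:

* `generate_switching_ensemble()` builds bead-resolution systems in which
  disjoint residue pairs toggle between a contact distance (3.8 Å) and a
  broken distance (8.0 Å). Each planted **mode** draws one latent Bernoulli
  state per frame with a class-dependent occupancy and moves all of its
  pairs together; independent per-pair flip noise (default rate 0.01)
  corrupts the geometry; additional background pairs switch independently
  with occupancies drawn in (0.2, 0.8) to give PCA genuine nuisance
  variance. Contacts are planted *geometrically*, so the distance kernel,
  cutoff logic, dynamic-pair filter, PCA and LDA are exercised end to end,
  not merely the linear algebra.
* `generate_slab_world()` simulates continuous biased random walks first,
  extracts true crossing events from the continuous paths, and only then
  wraps the coordinates into the periodic box — so the wrapped trajectory
  plus ground truth form an exact oracle for the unwrap-and-count chain.
* `generate_hbond_fixture()` places donor–hydrogen–acceptor triads whose
  satisfaction of the geometric criteria is planned per triad.
* `generate_lipid_shell_fixture()` thins uniform samples to plant a known
  radial density enrichment around a central bead.

Latent mode states are i.i.d. across frames. Real MD frames are strongly
autocorrelated, real contacts are not geometrically independent, and real
ensembles mix many partially overlapping modes. Passing the recovery tests
therefore demonstrates the correctness of the estimators under their own
assumptions — not that any particular biological ensemble satisfies those
assumptions. The frame-independence assumption is inherited by the LDA
(frames are treated as independent observations); no autocorrelation
correction is attempted.

Study-condition sizes used by the validation suite were chosen once:
planted-mode recovery uses a single 12-pair mode at occupancy 0.5 with
flip noise 0.01 over 5000 frames (where the rank-one closed form
$\lambda_1 = 12\,p(1-p) = 3.0$ applies); the two-class contrast plants six
independent two-pair modes at occupancies 0.9 vs 0.1 over 2500 frames per
class. The six-mode layout matters: with one fully collective mode, a class
at occupancy 0.9 still spends 10% of its frames in the opposite latent
state, so the class-conditional score distributions are irreducibly mixed
and no discriminant can push their overlap below ≈ 0.2. Splitting the
planted set across six independent modes makes the per-frame score
effectively a sum of six latent Bernoullis (Binomial(6, 0.9) vs
Binomial(6, 0.1)), whose overlap is below 0.02 while keeping the planted
contrast "0.9 vs 0.1 on the planted set".

## Numerical choices

* The **covariance** (not correlation) matrix of contacts is diagonalized;
  binary variables share a natural scale, so correlation normalization
  would only inflate near-static pairs. The unbiased $1/(N-1)$ estimator is
  used.
* Frames from all conditions are **pooled** for PCA and mean-centered by
  the pooled mean; per-condition PCA is out of scope.
* Eigenvector signs are fixed so each loading's largest-magnitude
  coefficient is positive; LDA row signs are fixed so the first-listed
  class has the lower mean score (so "class listed first sits on the left"
  is a convention, not an outcome). Degenerate eigenvalue ties keep the
  solver's stable order.
* When the within-class scatter is numerically singular, a ridge of
  $10^{-6}\,\mathrm{tr}(S_w)/k$ is added with a loud warning; LDA inputs
  are raw (variance-bearing) PC scores, not standardized per PC, because
  the transform is defined directly on the PC projections.
* Class score densities use a Gaussian kernel with a single Silverman
  bandwidth computed on the pooled scores, evaluated on one shared grid
  spanning the pooled range ± 3 bandwidths, and renormalized to integrate
  to exactly 1 (trapezoid rule) so overlap coefficients are comparable
  across classes.
* The crossing counter is a three-state automaton (below / inside / above)
  driven by the unwrapped normal coordinate, with slab images replicated
  every box length; positions exactly on a boundary count as *inside*, so
  touching a boundary and retreating is never an event.
* Residue and atom indexing is 1-based throughout, matching both R
  convention and the residue numbering used in structure files; there is no
  separate internal 0-based representation.
* Matrix text output carries 12 significant digits; bit-exact round-trips
  across platforms are not promised, 12-digit agreement is.

## Interfaces

All functionality is exposed as documented R functions; the file formats
are PDB/GRO for structures, multi-model PDB (per-model CRYST1 boxes) and
DCD for trajectories, and tab-separated text for every analysis product.
XTC is not supported: no installed R-level reader exists, and the
multi-model PDB dialect covers the text-only use cases. A thin command-line
wrapper (`inst/cli/contactmodes.R`) chains the stages
(`simulate`, `contacts`, `pca`, `lda`, `membrane`) over a working directory
for shell-driven use.

## Worked example

```{r example, eval = FALSE}
modes <- lapply(1:6, function(q)
  list(pairs = rbind(c(4 * q - 3, 4 * q - 1), c(4 * q - 2, 4 * q)),
       occupancy = c(wt = 0.9, analog = 0.1)))
spec <- switching_spec(n_residues = 36, n_frames = 1000, modes = modes,
                       trajectories = data.frame(id = c("wt", "an"),
                                                 redox = c("wt", "analog")),
                       n_background = 4, flip_noise = 0.01, seed = 1)
g <- generate_switching_ensemble(spec)
cp <- contact_pipeline(g$trajectory)
basis <- fit_contact_pca(cp$ct)
scores <- project_onto_pcs(cp$ct, basis, 8)
model <- fit_lda(scores, g$labeling$redox, condition = "redox")
ld1 <- lda_scores(model, scores)[, 1]
overlap_coefficient(class_score_density(ld1, g$labeling$redox))
map <- ld_loading_in_contact_space(model, basis, 1)
```

## Known limitations

* Contact states are binary; no distance-weighted (soft) contact variant.
* No time-lagged / relaxation-mode analysis; frame order is ignored by the
  statistics.
* No chain-swap minimization in multimer RMSD.
* The crossing automaton can miss a traversal if a particle jumps across an
  entire water or slab region between two saved frames; save frames densely
  relative to the diffusion step.
* The bundled hBD-3 reference model carries the real 45-residue sequence
  but synthetic idealized coordinates; it supports sequence-derived
  quantities (residue count, formal charge), not geometric ones.
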