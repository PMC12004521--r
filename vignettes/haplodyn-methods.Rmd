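---
title: "haplodyn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplodyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodyn)
```

haplodyn links two layers of evidence about protein-coding genetic
variation: sequence-level plausibility scores for the protein haplotypes a
population actually carries, and structural/dynamic differences between
those protein variants as seen in molecular-dynamics (MD) trajectories. The
package was built around the analysis of EXO5, a DNA-repair exonuclease
whose common human haplotypes (wild-type, G172V, G172V + D115N, L151P)
differ sharply in predicted fitness and in the stability of the
conditionally folded helix over its DNA channel, but every component is
generic: any transcript with phased genotypes, and any protein with
trajectories, can be pushed through the same pipeline.

## Haplotypes and their protein products

Chromosome-level allele patterns over a transcript's missense variants are
counted directly from phased genotypes (`read_phased_vcf()`,
`enumerate_haplotypes()`). Frequencies are counts over all chromosomes —
never averages over populations — and per-population columns are computed
over each population's chromosomes alone, so both sum to one. Common
haplotypes are those with frequency *strictly* greater than the threshold
(default 0.01); a haplotype at exactly the threshold is dropped.

Design choices worth stating explicitly:

* genotypes must be phased (`|` separator); unphased records are rejected
  rather than imputed, because phase is an upstream responsibility;
* multi-allelic sites are decomposed into biallelic records on load, and the
  haplotype key is the allele pattern, not the variant id;
* CDS coordinates are 1-based inclusive;
* only substitutions are supported. Indel haplotypes (such as the
  frameshifting deletion haplotype of EXO5) must be set aside upstream; the
  translator raises an `unsupported_variant_error` rather than guessing.

Translation uses the standard genetic code and truncates at the first stop
codon. Haplotypes yielding the identical protein (synonymous patterns) are
deduplicated and flagged wild-type when they match the reference protein.

## Pseudo-log-likelihood-ratio scoring

A *position scorer* is any object that returns, for a sequence, the
log-probability of the residue present at each position. The pseudo
log-likelihood (PLL) of a sequence is the sum of those log-probabilities
from a single unmasked pass; the pseudo-log-likelihood ratio of a variant
against wild-type is

$$\mathrm{PLLR} = \mathrm{PLL}(\text{variant}) - \mathrm{PLL}(\text{wild-type}),$$

averaged over an ensemble of scorers. Positive values mean the model finds
the variant more plausible; negative values flag potential disruption. The
wild-type scores 0 by construction and is included when computing a
transcript's *score variability*, the maximum pairwise difference
(max − min) of its haplotype scores. With the published EXO5 haplotype
scores (0, 5.05, 4.51, −2.74) this statistic is 7.8.

The package ships a fully testable toy scorer (`gen_toy_scorer()`,
`uniform_scorer()`) backed by explicit per-position tables. An ensemble of
learned protein language models can be dropped in behind the same
`score_positions()` contract; the core package does not download or load
external weights. Length normalization of the PLLR is deliberately not
applied — scores are comparable within a transcript, which is the only
comparison the variability statistic makes. For cohort screens,
`cohort_score_table()` reports the share of haplotypes with |PLLR| above a
threshold both with and without wild-type rows, since conventions differ on
whether the reference counts as an observation.

## Trajectory metrics

Trajectories are frames × atoms × 3 arrays (Å) with a topology table and a
`numbering_offset` mapping construct numbering to full-protein numbering
(for the EXO5 constructs, −68). All "equilibrated" statistics exclude a
configurable initial span (default 960 ns) and sample at a configurable
stride (200 ps for RMSD/RMSF, 100 ps for networks, 0.5 ns for PCA).

**Superposition** is least-squares (Kabsch) on a named selection, typically
the rigid protein core excluding mobile regions; RMSD is computed after the
fit, RMSF about the trajectory-average structure with replicas processed
separately and combined as mean ± sd/√R.

**Secondary structure** uses a simplified three-state DSSP-style scheme.
Hydrogen bonds between carbonyl and amide groups are scored with the
classic electrostatic model
$E = 0.084 \cdot 332 \,(1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN})$
kcal/mol, a bond requiring $E < -0.5$ and a sequence separation of at least
3. Helix needs two consecutive (i, i+3) or (i, i+4) turns; strand needs an
exact parallel or antiparallel bridge pattern, so β-bulges fall through to
loop. Amide hydrogens are read from the input, never guessed; residues
without one (prolines, the N-terminus) are never donors. The assignment is
cross-checked in the test-suite against mdtraj's DSSP on ideal helix and
hairpin constructs; agreement is exact away from segment ends, where a
simplified scheme is conservative (it does not extend helices to the final
acceptor-only turn).

**Ordered fraction** is the frame-average share of region residues labeled
helix or strand; **kink angle** is the planar angle at the middle of an
ordered residue triple, measured on α-carbons (the choice of atom is
configurable; only residue names are fixed by convention);
**displacement maps** average $d_{ij}(\text{frame}) - d_{ij}(\text{ref})$
over frames, positive meaning the pair moved apart.

## Uncertainties: autocorrelation and the moving block bootstrap

The autocorrelation time τ is the smallest lag at which the biased-
normalized empirical ACF drops to $e^{-1}$; for an AR(1) process with
coefficient ρ this converges to $-1/\log\rho$. The SEM of a time-series
mean is estimated with a moving block bootstrap: ⌈n/b⌉ overlapping blocks
of length b (default ⌈τ⌉) resampled with replacement, the SEM being the
standard deviation of resampled means. Replicas are processed separately
and combined with `replica_mean_sem()`.

A documented limitation: a block bootstrap with block length b estimates
the triangular-windowed variance
$\sigma_b^2 = \sum_{|k|<b}(1-|k|/b)\,\gamma_k$, which undershoots the
long-run variance when b is comparable to the correlation time. For AR(1)
with ρ = 0.9 and b = ⌈τ⌉ = 10 the expected SEM is ≈ 0.62 of the asymptotic
value $\sqrt{(1+\rho)/(1-\rho)}/\sqrt{n}$, approaching it only for
b ≳ 3–4 τ. The default follows the e-folding rule for comparability with
the originating analysis; users wanting asymptotically calibrated errors
should pass a larger `block_length`. The test-suite pins the estimator to
its exact closed-form expectation and verifies convergence at generous
block lengths.

## Interaction networks

Residue graphs are built per interaction type from side-chain geometric
criteria: salt bridges (oppositely charged side-chain group atoms within
4.5 Å; representative atoms follow the zeta-carbon/gamma-carbon
convention), hydrogen bonds (donor–acceptor ≤ 3.5 Å and donor-H-acceptor
angle ≥ 120°), and hydrophobic contacts (apolar side-chain centers of mass
within 5 Å), always excluding sequence-adjacent pairs. Edges are weighted
by *occurrence* — the fraction of sampled equilibrated frames in which the
interaction is present — then combined across types by taking the maximum
occurrence per edge, binarized at a strict 20 % cutoff, and compared across
trajectories with the Jaccard coefficient (common edges over the union;
two empty graphs are defined as identical). Protein–DNA interfaces are
integer contact maps: atomic contact weights (1 below 4 Å, 0 above 5 Å,
cosine ramp in between — the switch is pluggable, and any smooth monotone
ramp with the same endpoints leaves the integer-rounded maps essentially
unchanged) summed per residue–nucleotide pair and rounded.

## Essential dynamics and conformational clustering

PCA runs on α-carbon coordinates after aligning every sampled frame to a
reference on the core α-carbons (mobile regions excluded from the fit).
Two essential subspaces, each spanned by the first D = 30 components, are
compared with the root mean square inner product,
$\mathrm{RMSIP} = \sqrt{\tfrac1D \sum_{ij} (u_i \cdot v_j)^2}$,
which is 1 for identical and 0 for orthogonal subspaces and is invariant to
re-basis within either span.

Conformations are clustered with a density-peaks scheme on either backbone
φ/ψ dihedrals (periodic-angular metric on raw angles; a sin/cos embedding
was considered and rejected as the default because it distorts the
angular-difference semantics) or flattened interface maps (Manhattan
metric). The estimator is a self-contained member of the point-adaptive
k-NN family: intrinsic dimension from the two-nearest-neighbour ratio
estimator; per-point neighbourhood size grown while an inner-ball/outer-
shell likelihood-ratio test (χ², 1 df, 1 % level) accepts local uniformity,
capped at k_max = 100; log-density $\log k^* - \log(n\,\omega_d r_{k^*}^d)$
with statistical error $1/\sqrt{k^*}$. Peaks are points not dominated
within their own adaptive neighbourhood; other points join their nearest
higher-density point, ties broken by lowest index so the procedure is
deterministic. Clusters merge while the smaller of the two peak-minus-
saddle log-density gaps is below Z times the propagated error (the two peak
errors and the saddle error summed in quadrature); saddles are the densest
inter-cluster border contacts, falling back to the closest inter-cluster
pair when no neighbourhood-level contact exists, which makes the Z → ∞
limit collapse everything into one cluster. Z = 5 is used for the
conformationally decisive mobile-helix dihedral set and Z = 3 elsewhere.
This implementation is validated against ground-truth generative oracles
(single vs well-separated Gaussian clouds, ≥ 99 % membership agreement)
rather than claimed line-for-line identical to any external library.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth:

* **phased panels** — chromosomes drawn i.i.d. from declared haplotype
  frequencies, with the generating haplotype stored per chromosome so
  enumeration is validated by exact counting;
* **toy scorers** — explicit per-position log-probability tables;
* **helix/coil trajectories** — per frame, the whole chain is either an
  ideal α-helix (φ = −57°, ψ = −47°) with probability `helix_probability`
  or a coil with per-residue dihedrals uniform in the β/PPII basin
  (φ ∈ [−180°, −60°], ψ ∈ [60°, 180°]), a basin chosen because it can never
  satisfy the helical hydrogen-bond pattern — so the planted probability is
  the exact ordered-fraction ground truth. Coordinates are rebuilt by
  sequential internal-coordinate chain construction with canonical bond
  geometry (exact to 10⁻⁶ Å when noiseless), amide hydrogens placed
  analytically on the in-plane bisector of the two nitrogen bonds, optional
  isotropic Gaussian noise, and planted atom-pair contacts realized by
  rigidly displacing only the designated atom to a closed or open distance
  per frame — decoupling contact statistics from dihedral statistics;
* **AR(1) series** — unit marginal variance, closed-form ACF ρ^k, for
  validating τ estimation and the bootstrap.

What the generator does *not* emulate: physical force fields, solvent,
realistic transition kinetics (frames are exchangeable, not Markovian),
side chains beyond the backbone, or correlated noise. Passing tests
demonstrate statistical correctness of the estimators under known truth,
not fidelity of any MD engine.

## Problem sizes and determinism

The shipped tests and examples run on deliberately small instances chosen
as the package's own validation conditions: panels of a few hundred
individuals, trajectories of 10–15 residues and 500–3000 frames, AR(1)
series up to 10⁵ points, clustering instances of ≤ 1000 observations.
Every stochastic function takes an explicit seed and restores the caller's
RNG state; identical spec + seed reproduces outputs bit-for-bit, which the
pipeline manifest (`run_pipeline()`) records together with input hashes and
parameters.

## Known limitations

* The secondary-structure scheme is three-state by design; no 8-class DSSP,
  no helix end extension.
* The block-bootstrap SEM inherits the e-folding block-length convention
  and is conservative-biased low for strongly correlated series (see
  above).
* Hydrogen-bond donor/acceptor typing is geometric and element-based, not
  force-field-derived; all cutoffs are exposed in `contact_params()`.
* The density-peaks implementation is a documented simplification of the
  adaptive family, validated on oracles, and its adaptive-k rule is not
  guaranteed to match any specific external implementation point-for-point.
* Indel haplotypes and water-mediated or π-system interactions are out of
  scope.
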