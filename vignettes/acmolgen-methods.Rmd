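---
title: "Conditional molecular generation in latent space: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional molecular generation in latent space: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Generative models of molecules explore chemical space well, but most cannot
be *steered into an interval* of a property: "give me molecules with logP in
(0, 1]" is not a query a plain VAE answers.  `acmolgen` implements a
conditional pipeline for exactly that task.  A continuous attribute — the
Crippen octanol–water partition coefficient (logP), the quantitative
estimate of drug-likeness (QED, in [0,1]) or the Ertl–Schuffenhauer
synthetic accessibility score (SAS, 1 easy to 10 hard) — is partitioned into
interval categories, and an auxiliary-classifier GAN (AC-GAN) is trained to
generate molecular *latent vectors* conditioned on the category label.  A
molecule–latent codec maps molecules into and out of the 250-dimensional
latent space, so the GAN never touches molecular graphs directly.

# Attribute binning

The three binning schemes (left-open/right-closed intervals; boundary
values belong to the lower-indexed interval):

* logP, 6 categories: (−∞,0], (0,1], (1,2], (2,3], (3,4], (4,∞).  The 0–3
  window is the usual oral-absorption sweet spot, hence the finer division
  there.
* QED, 6 categories: [0,0.5], then steps of 0.1 up to 1.  Values outside
  [0,1] are an error.
* SAS, 7 categories: (0,2], then steps of 0.5 up to 4.5, then (4.5,10].

Cleaning drops SMILES the toolkit cannot sanitize and, when a codec is
supplied, molecules outside its representable set; both are counted, not
raised.  Class balancing is by seeded random oversampling up to the largest
category; duplicated records are flagged so novelty and uniqueness
computations can de-duplicate the training reference.

# The codec contract and the surrogate

A pretrained hierarchical graph VAE is the natural encoder/decoder for
this pipeline.  Training one is deliberately out of scope here: `acmolgen`
defines a codec *contract* — `encode` to length-250 finite vectors,
`decode` returning a valid molecule, `latent_dim = 250` — and ships a
deterministic surrogate satisfying it:

* **encode**: principal-component projection of Morgan radius-2/1024-bit
  fingerprints, zero-padded when the library rank is below 250, with a
  deterministic sign convention (largest-magnitude loading positive);
* **decode**: nearest library molecule by Euclidean distance, ties broken
  by lexicographically smallest canonical SMILES;
* **representable set**: a molecule is encodable only if all of its
  fingerprint bits occur in the fitting library, mirroring an encoder with
  a fixed motif vocabulary.

The surrogate was chosen over training a small SMILES VAE because it is
deterministic, fits in seconds, guarantees 100% decode validity by
construction, and cleanly separates GAN behaviour from decoder behaviour in
tests.  Its obvious limitation is that decoding cannot leave the library:
novelty of decoded sets is bounded by the gap between the decode library
and the training subset, and validity is 100% *by contract*, not as an
empirical finding about a learned graph decoder.  Any object implementing
the contract (e.g. a real graph VAE) plugs in unchanged.

The latent dimensionality 250 matches the generator's output length; the
codec contract pins both sides of the interface to it.

# Networks

Both networks translate between the 250-vector latent space and a 64×64×3
"quasi-image" so that convolutional units can extract structure.

**Generator.**  The category label is embedded as a 50-vector and
concatenated with 50 standard-normal noise coordinates (the noise width is
a package choice, symmetric with the embedding).  A two-layer fully
connected block (hidden 128, Tanh) maps to 64×64×3; four convolutional
units (3×3 convolution, LeakyReLU slope 0.2, then BatchNorm, in that
order), the first two with a 2× stride downsample, yield a 16×16×30
feature block; flattening and a two-layer fully connected block with a
500-wide middle layer produce the length-250 latent.  The narrow 128-wide
first block is a deliberate part of the architecture contract even though
it bottlenecks the mapping; it is configurable.

**Discriminator.**  Latent 250 → two-layer FCN (hidden 512, LeakyReLU) →
64×64×3 → four convolutional units with an extra dropout layer (ratio
0.25, applied after BatchNorm), units 1–3 downsampling 2× (64→8), channel
progression 3→16→32→64→128 (only the endpoints are prescribed; the
intermediate widths are the natural doubling), with a residual connection:
the unit-3 output joins the unit-4 output through a 1×1 convolution
projection (needed because the channel counts differ).  The resulting
8×8×128 block feeds two heads, each a two-layer FCN with a 128-wide hidden
layer: a sigmoid real/fake confidence and a softmax class-probability
vector.

Weight initialization is seeded He/Xavier by activation.  The compiled
kernels run the dense/convolution algebra in single precision; training
dynamics are far above float resolution, and the finite-difference tests
bound the backprop error at ~1e-3 relative under float arithmetic (exact
to 1e-9 in the double-precision reference path used during development).

# Losses

All objectives are minimized negative cross-entropies under one convention.
Writing `D(x)` for the confidence and `p(c|x)` for the class head:

* **Original AC-GAN objectives** (kept as an ablation baseline): the
  source term `L_T` is the real/fake cross-entropy over both batches, the
  class term `L_C` the classification cross-entropy over both batches;
  `L_D = L_T + L_C`, `L_G = L_C − L_T`, realized as standard binary
  cross-entropies (the only bounded reading of the max-likelihood
  objectives).
* **Adjusted discriminator loss**: adversarial cross-entropy plus the
  classification term on *real* samples only.  Fake samples contribute no
  classification signal, so the discriminator cannot collude with the
  generator on labels and learns category features from ground truth alone.
* **Adjusted generator loss**: non-saturating adversarial term, the
  classification term on fakes, plus a Euclidean anchor
  `λ · mean_i min_j ||z_fake_i − z_real_j||²` over same-category real
  latents of the batch.  The anchor pairing is not prescribed; nearest
  same-category neighbour within the minibatch matches the stated intent of
  learning near the ground-truth manifold and costs O(batch²).  λ defaults
  to 0.1 ("a small value"); λ = 0 disables the term exactly.

Probabilities are clipped to [1e-7, 1 − 1e-7] inside the losses, so all
values stay finite for degenerate inputs.

# Adaptive balance-factor training

The balancing rule is specified here by its contract — it takes the two
running losses, outputs a factor α ∈ [0,1], and reallocates update steps —
and this module fixes one concrete, tested realization of that contract.

* α = (L_G + ε/2) / (L_G + L_D + ε), ε = 1e-8 split so that two vanishing
  losses give the symmetric 1/2.  α near 1 means the generator is behind.
* Step allocation: steps_G = max(1, round(α·K)), steps_D = max(1,
  round((1−α)·K)) with a per-loop budget K (default 4).  Each step consumes
  the next minibatch of the shuffled epoch stream, so an epoch is one pass
  over the data and the factor shifts the *share* of updates, not the total
  work.
* The running losses are exponential moving averages (decay 0.9) so a
  single noisy batch cannot flip the allocation.
* Balancing could equally modulate step counts, learning rates, or both;
  step counts were chosen, and the choice is isolated in `allocate_steps`.

The optimizer is RMSprop (momentum-free adaptive gradient; lr 2e-4, decay
0.9, ε 1e-8).  The stop rule ends training at the first epoch whose mean
adjusted discriminator loss is ≤ 0.5 (that loss is a sum of cross-entropies
in [0, ∞), so 0.5 marks near-converged discrimination); setting the
threshold to 0 disables the rule and the loop runs exactly `max_epochs`.

# Synthetic fixtures

`make_library()` enumerates ~10³ candidate molecules from a fixed fragment
grammar (aromatic/saturated cores × substituents × polar or lipophilic left
groups, plus a dihydroquinazolinone family that reliably lands QED > 0.9)
and greedily retains, in seeded random order, at least `target_per_bin`
valid distinct molecules per category of all three attributes (19 bins).
Halogen- and alkyl-rich pieces reach high logP, polyols and amines low
logP, fused stereocentre-bearing cores high SAS.  A deliberately truncated
`grammar = "minimal"` cannot fill the extreme bins and raises
`BinUnfillable` naming them — a tested outcome, not a silent shortfall.
The library spans all bins by construction but makes no claim of ZINC-like
realism: it is a test instrument.  Passing fixture tests therefore
demonstrates the machinery (conditioning, decoding, metrics), not
performance on real screening collections.

`make_latent_clusters()` draws balanced Gaussian classes with means at
`separation` along orthogonal axes of the 250-space.  Two presets are used
throughout the tests: *convergent* (3 classes, separation 10, spread 1,
600/class — cleanly separable) and *collapse-prone* (separation 0.5,
spread 1, 120/class — heavily overlapping classes that invite conditional
collapse).  The preset sizes are the package's desk-scale study conditions;
the collapse preset is smaller because ten paired runs are compared on it.

# Metrics

Validity (parse + sanitize rate), novelty (canonical SMILES absent from
the training set) and uniqueness (distinct/total) use string identity on
canonical SMILES — deterministic and standard practice.  The
distribution-level suite works on Morgan radius-2/1024 fingerprints:

* IntDiv_p = 1 − (mean over all ordered pairs, self-pairs included, of
  Tanimoto^p)^(1/p) — a single molecule scores exactly 0;
* SNN: mean best-match Tanimoto from each generated molecule to the
  reference set;
* Frag/Scaf: cosine similarity of BRICS-fragment and Bemis–Murcko-scaffold
  count vectors over the union key set.  An uncleavable molecule counts as
  its own single fragment.  If both profiles are empty the cosine is
  undefined and an error is raised; if exactly one is empty the similarity
  is 0.  Acyclic molecules contribute no scaffold key.
* Fréchet activation distance: ||μ_G − μ_R||² + Tr(Σ_G + Σ_R −
  2(Σ_G Σ_R)^{1/2}).  The matrix square root is computed by symmetric
  eigendecomposition of Σ_G^{1/2} Σ_R Σ_G^{1/2}; eigenvalues above −1e-6
  are clipped to zero, more negative ones are an error.  The activation
  model is pluggable; the default is a fixed seeded random tanh projection
  of fingerprint bits and the three normalized attributes.  It is *not* a
  trained bioactivity network — distances under it are internally
  comparable across runs of this package but are not on the scale of
  Fréchet ChemNet distances computed with real ChemNet weights, which are
  accordingly not test oracles here.

MACCS-key Dice similarity serves as the drug-database comparison measure;
1.00 flags an exact structural-key match.

# What the tests do and do not show

The acceptance-style tests pin down, at desk scale: the three reference
worked-example property values (logP 1.735, QED 0.927, SAS 2.246, each to
±0.005, with their bins 3/6/2); 100% validity of a 6×1000-molecule
pipeline run (a consequence of the decode contract, and documented as
such); exact self-similarity under MACCS/Dice; the stop rule firing within
two epochs on the convergent preset in at least 4 of 5 seeds; and the
adaptive allocator matching or beating the fixed 1:1 baseline's final
per-category accuracy on the collapse-prone preset across 5 paired seeds.

Full-scale benchmark quantities — per-category generation accuracies on a
250k-molecule screening corpus, novelty and uniqueness percentages, and
ChemNet-based Fréchet distances — require that corpus, a pretrained graph
VAE and trained ChemNet weights, none of which ship here; the
property-based and scaled-down checks above stand in for them, and the
package makes no claims about those quantities.

# Numerical and design notes

* All randomness flows from one root seed, split per pipeline stage with a
  fixed affine rule; identical configurations reproduce byte-identical
  outputs.
* Latent-space category accuracy (the training diagnostic) scores a
  generated latent by the label of its nearest real latent; molecule-level
  accuracy decodes and re-computes the attribute.  Chance level for k
  balanced categories is 1/k.
* Training problem sizes in the tests (600/class convergent runs, 120/class
  collapse runs, 2–3 epoch budgets, batch 64) are the package's chosen
  desk-scale study conditions.
* Binary artifacts (codec, checkpoints) are runtime `saveRDS` files; the
  repository itself is text-only and all fixtures are generated by code.
* Known limitations: no Wasserstein or spectral-norm variants; no 3-D
  structure; the surrogate codec cannot produce molecules outside its
  library; the Python RDKit subprocess is a hard runtime requirement.
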