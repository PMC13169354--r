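---
title: "Conditional SMILES generation with functional-group and scaffold constraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional SMILES generation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The generative model

`molforge` treats a molecule as a SMILES token sequence
$Y = (y_1, \dots, y_m)$ and models it with a decoder-only Transformer
conditioned on a context $C = (X_\mathrm{SMARTS}, X_\mathrm{Scaffold})$: a
set of functional-group descriptor tokens drawn from a hierarchical SMARTS
ontology, and optionally the SMILES of a Bemis–Murcko scaffold to preserve.
The joint conditional probability factorizes autoregressively,
$$P(Y \mid C) = \prod_{t=1}^{m} P(y_t \mid y_{<t}, C;\, \theta),$$
realized by causal masking: position $t$'s logits depend only on tokens at
positions $\le t$ (a property the test suite verifies bitwise by perturbing
future tokens). Training sequences interleave context and target with
`[SEP]` delimiters — `[SMARTS, SEP, Target]` in the semantic-only setting,
`[SMARTS, SEP, Scaffold, SEP, Target]` in the hybrid setting — framed by
`[START]` and `[END]`; at inference the prompt is the context prefix and
decoding continues until `[END]` or the position budget.

The architecture is the standard pre-norm decoder block (LayerNorm →
masked multi-head self-attention → residual; LayerNorm → ReLU FFN →
residual), fixed sinusoidal positional encodings, and a linear output head.
The reference configuration is 6 layers, 6 heads, $d_\mathrm{model} = 512$,
FFN width 2048, dropout 0.1; every size is a `model_config()` field, and the
package's experiments use a tiny instance (2 layers, 4 heads,
$d_\mathrm{model} = 64$, FFN 128) that trains end-to-end on one CPU in about
a minute. Pre-norm placement was chosen (where the layer-norm position was
otherwise unspecified) because it trains stably at small scale without
schedule tuning. The forward and backward passes are written directly on R
matrices; a finite-difference gradient check in the test suite pins the
backpropagation to the analytic gradients.

## Objective, schedule, curriculum, augmentation

The objective is sparse categorical cross-entropy with an explicit mask
excluding `<PAD>` positions from loss and gradients. By default the loss
covers *all* non-PAD positions, context tokens included; a
`loss_span = "target"` switch restricts it to the target span. The
distinction matters for interpretation: context tokens carry irreducible
marginal entropy (nothing predicts the first descriptor from `[START]`
alone), so a memorization experiment — whose question is "can the model
reconstruct $Y$ given $C$?" — is measured under the target-span objective,
while ordinary training keeps the default.

Optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.98$,
$\epsilon = 10^{-9}$) under the inverse square-root warmup schedule
$\mathrm{lr}(s) = d_\mathrm{model}^{-1/2}\min(s^{-1/2},\,
s\,w^{-3/2})$ with warmup $w = 4000$ steps by default. Desk-scale corpora
see only hundreds of optimizer steps, so the package's own experiments set
$w = 200$ — a configuration choice scaled to the corpus, fixed before any
result was read off. Fine-tuning uses a constant reduced rate of
$5\times10^{-5}$ and batch size 32, early-stopped on validation loss with
the best-validation checkpoint retained.

Curriculum learning orders training molecules by topological complexity —
ascending (ring count, branch points, sequence length), where ring count is
the SSSR size (the cyclomatic number) and a branch point is an atom of
heavy-atom degree ≥ 3 carrying at least one acyclic bond (pure ring-fusion
atoms are not branch points; a flag restores the raw-degree variant). The
sorted corpus is cut into 4 quantile stages; a stage unlocks when validation
loss fails to improve by ≥ 10⁻³ for 2 consecutive epochs, *or* after 10
epochs in one stage regardless — the cap exists because a steadily improving
run would otherwise never see the harder molecules. "Plateau" is not
quantified in the source protocol; these are the package's explicit
substitutes, all configurable.

Augmentation replaces the target span, with probability 0.1 per
presentation, by a randomized SMILES rendering of the same molecule (random
DFS atom order), re-tokenized under unchanged context. The augmentation rate
is itself under test (binomial interval over 4000 draws), as is molecule
identity preservation via re-canonicalization.

## Sampling

Decoding samples from $\mathrm{softmax}(z/T)$ at each step. $T = 0$ is
greedy argmax with lowest-id tie-break. The raw distribution ranges over the
whole vocabulary, specials included; a record whose target span contains a
special token is marked invalid at decode (a `forbid_specials` flag masks
them instead). Scaffold retention is exact canonical-scaffold equality by
default, with a substructure-containment mode, because "scaffold match" is
ambiguous between the two readings. The mean per-step sampling entropy is
recorded per batch; it is the quantity compared across temperatures in the
temperature-decomposition experiment.

# The chemistry layer

No installed R package provides canonical nonisomeric SMILES with
randomized re-rendering, Murcko scaffolds, or hashed Morgan fingerprints,
so the package carries a compact SMILES graph engine: parser (organic
subset, bracket atoms, multi-digit ring closures; stereo markers are
stripped at parse time), writer, and a Morgan-style canonicalizer
(invariant refinement with a branching lexicographic-minimum tie-break,
capped at 64 leaf evaluations, falling back to first-member tie-break
beyond the cap). The canonical dialect is the engine's own — idempotent and
atom-order invariant by property test, but not byte-identical to other
toolkits' canonical forms. OpenBabel (via ChemmineOB) performs SMARTS
substructure matching and supplies logP and TPSA; it also serves as an
independent cross-check that the engine's canonical SMILES re-parse
externally with matching molecular formula.

Aromaticity is accepted as written (lowercase SMILES) rather than
re-perceived: a Kekulé benzene and an aromatic benzene are different
renderings with different canonical strings. Validity additionally requires
every aromatic atom to lie in a ring composed of aromatic atoms, and
isolated (non-fused) aromatic rings to satisfy the Hückel $4n+2$ π-electron
count (π contributions: 1 for carbons and pyridine-type nitrogens, 2 for
lone-pair donors such as `[nH]`, `o`, `s`); fused systems are exempted from
the electron count. This rejects strings like `c1ccc1` without attempting
full aromaticity perception.

Standardization selects the largest fragment containing carbon (ties broken
lexicographically on canonical SMILES; no carbon anywhere → rejection as
inorganic), then neutralizes simple charged centres — cations with
hydrogens are deprotonated, anions protonated where a neutral valence-legal
form exists — while quaternary nitrogens and charge-separated groups (an
anion bonded to a cation, e.g. nitro) are kept as written. The exact
salt/charge rules of the source pipeline are not public; these are the
package's documented substitutes, and standardization is idempotent by
test.

Fingerprints are radius-2 circular (Morgan) environments hashed to 2048
bits from iterated atom invariants (element, degree, H count, charge,
aromaticity, ring membership); Tanimoto similarity operates on set bits.
The fingerprint is internally consistent and deterministic but its bit
assignments are not interchangeable with other toolkits' ECFP4 bits.

# Evaluation machinery

Validity is the fraction of generated strings the chemical parser accepts;
uniqueness the fraction of distinct canonical SMILES among valid outputs;
novelty the fraction of those absent from the training set. Distribution
distances are the two-sample KS statistic, a histogram KL divergence
(shared equal-width bins, additive smoothing $10^{-10}$), and the Fréchet
distance $\lVert\mu_a-\mu_b\rVert^2 +
\mathrm{tr}(\Sigma_a+\Sigma_b-2(\Sigma_a\Sigma_b)^{1/2})$ computed through a
symmetric eigendecomposition with negative eigenvalues within $10^{-8}$
clipped to zero. The embedding behind the Fréchet distance is a frozen
Gaussian random projection of the 2048-bit fingerprints (fixed internal
seed): values are internally consistent across runs and seeds but on a
different scale from chemistry-network embeddings, so reports carry an
`embedding_backend` label. All distributional comparisons run under the
repeated size-matched subsampling protocol (20 independent subsets, mean ±
SD).

Rediscovery metrics use ECFP4 Tanimoto at threshold 0.6: RR$_T$ is the
percentage of training actives with ≥ 1 generated molecule at or above the
threshold; RS$_T$/RS$_H$ the percentage of training/holdout scaffolds
exactly matched among generated scaffolds; SNN the mean nearest-neighbor
similarity of generated molecules to training; IntDiv $= 1 -$ mean pairwise
similarity (the $p = 1$ form, since the source cites it without a formula).

QED uses the published desirability-function coefficients and mean weights;
its logP and TPSA inputs come from OpenBabel, so absolute QED values differ
slightly from implementations built on other property calculators (the
component breakdown, including the ALERTS count, is exposed). The
structural-alert census is the unwanted-functionality list from the QED
definition; PAINS is a representative subset of the published catalog, and
both are documented as such. The SA score keeps the Ertl-style structure —
fragment familiarity minus complexity penalties on a 1–10 scale — but
derives fragment contributions from Morgan-fragment log-frequencies of a
user-supplied reference corpus, because the original precomputed fragment
library is a large binary artifact; scores are comparable within one
reference corpus only.

The leakage-safe split assigns whole scaffold groups (shuffled under the
seed, filled greedily to the requested fraction) and then removes every
preliminary-holdout molecule with Tanimoto ≥ 0.6 (inclusive) to any
training molecule. The audit recomputes maximum cross-set similarity and
shared-scaffold count by exhaustive pairwise scan, independent of the
construction path, and errors on any violation.

The UMAP projection fits on train ∪ generated only (Jaccard metric over
boolean fingerprint vectors, n_neighbors 30, min_dist 0.1, generated capped
at 10,000) and transforms holdout into the fitted manifold afterwards; the
test suite verifies that removing the holdout leaves every fitted
coordinate unchanged. The computation runs in the python `umap-learn`
library through a subprocess, there being no R UMAP implementation in the
supported environment.

# The synthetic fixture generator

The toy corpus emulates a small drug-like collection by a fragment grammar:
one of six ring cores (benzene, pyridine, thiophene, cyclohexane,
piperidine, naphthalene) substituted at one or two positions from a pool of
sixteen substituents (halides, phenol/alcohol, ethers, amines, amide,
ester, acid, ketone, nitrile, nitro, sulfonamide, thioether, Michael-
acceptor enone), attached directly or through a short alkyl linker. Each
molecule carries ground truth: its core (hence scaffold) and the
descriptors its fragments must trigger — by construction a subset of the
realized ontology profile, which the tests assert. Alert-bearing fragments
(nitro, enone) are down-weighted (weight 0.35 vs 1) so alert content is a
controllable minority, which is what makes the temperature-decomposition
experiment meaningful: cooling the sampler concentrates probability on the
majority (alert-poor) modes, so the mean alert count should not increase —
a directional prediction, tested directionally.

Two generator options exist for specific measurements: `n_overlength`
plants deliberately over-long molecules to exercise both branches of the
[5, 140] token length filter, and `unique_profiles` additionally
deduplicates on the realized (descriptors, scaffold) key. The latter is a
precondition of the conditional-reconstruction experiment — if two training
molecules shared a context, greedy decoding could reproduce at most one of
them, and the measurement would report grammar degeneracy rather than model
capacity. What the toy corpus does *not* emulate: the property
distributions, scaffold diversity, and functional-group co-occurrence of a
real screening corpus. Passing tests demonstrate the correctness of the
machinery, not chemical performance at scale.

# Problem sizes and numerical choices

The package's own experiments (test suite and `scripts/acceptance.R`) use:
a 50-molecule unique-profile corpus, 200 epochs, batch 16, warmup 200 for
the reconstruction experiment; a 120-molecule corpus, 80 epochs, for the
unconditional sampler; 320 samples per temperature; 20–50 random datasets
of ~18 molecules for the split guarantee; 20 subsampling repetitions for
Fréchet means. These sizes were chosen so each experiment is unambiguous at
desk scale.

Degenerate inputs are handled explicitly: empty corpora, all-PAD loss
masks, singleton Fréchet sets, a single scaffold covering all molecules,
and generation batches with zero valid molecules all raise typed errors or
NA-with-warning rather than silent results. Ties in greedy decoding break
to the lowest token id; ties in fragment selection break lexicographically;
curriculum sorting is stable.

# Limitations

The engine supports the organic subset plus common bracket atoms, not the
full periodic table; aromaticity is trusted as written; canonical SMILES,
fingerprint bits, QED values and SA scores are internally consistent but
not byte-compatible with other toolkits. Training is plain-R CPU
matrix arithmetic — ample for the tiny configuration and correct for any
size, but not performant at the reference scale (~40 M parameters on
millions of molecules), which the package does not attempt to reproduce.
The PAINS list is a subset; the full hierarchical SMARTS ontology is an
external input for which a miniature stands in throughout the tests.
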