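---
title: "Methods: paired-Fv generative language modelling at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-Fv generative language modelling at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its model and design
decisions: what is being modelled, which choices were forced by the
problem, which were genuinely open, and what the bundled synthetic data
can and cannot tell you about real antibody repertoires.

## The model

An antibody Fv is a pair of variable domains — heavy (VH) and light (VL)
— whose developability and pairing behaviour depend on the combination of
the two chains. `fvgen` models a paired Fv as a single token sequence:
the light chain concatenated onto the heavy chain, tokenized at residue
level, wrapped in a start sentinel (`"1"`) and an end sentinel (`"2"`).
One sentinel pair wraps the whole concatenation; no per-chain separator
token exists. The separator question is genuinely open in decoder-only
antibody LMs; we chose the single wrap because the paired training unit
is the concatenation and a separator adds a token the vocabulary does not
need — the chain boundary is recoverable from germline structure instead
(see "Chain boundary recovery").

The density model is a decoder-only autoregressive transformer (GPT-2
block structure: pre-layer-norm, multi-head causal self-attention,
tanh-GELU feed-forward) with rotary position rotation of queries and keys
over the full head dimension in every layer. Training minimizes mean
next-token cross-entropy; both sentinels are predicted targets — the end
sentinel is the stop signal and must be learned — and padding is
excluded.

Every sequence is presented in a random direction each epoch (forward or
reverse with probability 1/2). A model trained this way supports
completion of either chain from the other at inference: a light-chain
prompt is presented reversed behind the end sentinel, and the sampled
heavy continuation is un-reversed.

### Parameter accounting

The full-scale configuration is 3 layers, 12 heads, embedding size 768,
feed-forward size 2048, for 17,349,888 trainable parameters. The printed
total does not by itself determine vocabulary size, embedding tying, or
whether an absolute-position table coexists with rotary attention, so the
configuration here is reverse-engineered to match it exactly and labelled
as such: vocabulary 26 (20 amino acids, `X`, two sentinels, padding, two
reserved), tied input/output embeddings with no output bias, a learned
position table of 1024 retained alongside rotary, and GPT-2-style biases
and layer norms (two per layer plus a final one). The closed form is

    per layer: 4 d^2 + 2 d f + 9 d + f
    total:     n_layers * per_layer + V d + P d + 2 d

which `count_parameters()` evaluates and the test suite cross-checks
against enumeration of every parameter tensor.

### Numeric choices

All computation is in R doubles (64-bit). Layer norm uses eps = 1e-5.
Softmax stability uses a global max shift (attention scores are bounded
at these scales). GELU is the tanh approximation, the GPT-2 convention,
chosen also because its cached forward term makes the hand-derived
backward pass cheap. Gradients are derived analytically and validated
against central finite differences in the test suite. Adam uses
beta = (0.9, 0.999), eps = 1e-8, no weight decay; the published recipe
says only "Adam". The learning-rate schedule is linear warmup (default
1% of steps — warmup is our addition, the published schedule mentions
only cosine decay) into cosine decay to `min_lr = 0.1 * peak_lr`.
Gradient accumulation is token-weighted so that (batch 2b, accumulation
1) and (batch b, accumulation 2) produce identical trajectories.

## Sampling

Generation composes, per step: temperature scaling of logits, then
nucleus (top-p) truncation — smallest prefix of highest-probability
tokens reaching mass `top_p`, ties broken by token index — then a
categorical draw. Temperature-before-nucleus is the standard composition;
the published text does not state an order. The published operating point
is temperature 1.2, top-p 0.95; the developability-biased variant uses
1.25 to maintain diversity.

After generation, the bottom 5% of sequences by model likelihood are
discarded. Whether that filter used raw or length-normalized likelihood
is not stated; we default to length-normalized (per-token) so long
sequences are not preferentially discarded, with the raw sum available
by option. The discard count uses floor semantics: with 19 sequences and
fraction 0.05, nothing is discarded.

Unconditional sampling prompts forward and reverse starts 50/50 by
default, matching the bidirectional training distribution. Streams that
never emit a closing sentinel are flagged truncated, never raised;
`generate_pairs()` resamples them up to 3x the requested count before
raising a generation-quality error.

## Chain boundary recovery

Numbering tools are out of scope, so generated concatenations are split
by a germline-anchored heuristic: for every candidate split index, score
the prefix against the best VH germline and the suffix against the best
VL germline by global alignment (match +1, mismatch -1, gap -2), and take
the index maximizing the combined score (lowest index on ties). A
one-pass dynamic program per germline yields all prefix scores at once.
Below a configurable floor (default 0) the string is unsplittable:
unrelated sequences align with negative expected score under this
scheme, while even heavily mutated antibody sequences stay far above
zero. The annotation interface is pluggable, so a numbering tool can
replace the heuristic for real data.

## Evaluation panel

- **Novelty**: per-sequence nearest-neighbour distance to a reference
  set; Hamming for equal lengths, alignment mismatch+gap count otherwise.
  Whether published Hamming novelty used per-alignment-position or raw
  distances is unstated; raw Hamming on equal lengths is the default
  here. Self-matches are excluded when a set is scored against itself.
- **Diversity**: mean nearest-neighbour cosine distance between sequence
  embeddings. The encoder behind the published diversity convention is
  external; to keep the artifact self-contained we embed with the model
  under evaluation (mean-pooled final hidden states of the forward
  stream) and expose the embedding function as a pluggable argument.
  Diversity numbers are therefore comparable within a model, not across
  packages.
- **Pairing signal**: Pearson correlation between per-pair VH and VL
  mutation counts from germline, with a random-pairing control (uniform
  permutation of light chains, self-pairing allowed) expected to sit
  near zero.
- **Pairing-likelihood discrimination**: for each VH, the true pair is
  scored against decoy VLs drawn without replacement from sequences whose
  mutation count lies within +/-2 of the true VL's (mutation-rate
  control). VHs with too few eligible decoys are skipped and reported.
  Ranks break ties at random, which makes the constant-score null
  exactly uniform over ranks — a property the test suite checks against
  binomial bounds.
- **Zero-shot fitness**: Pearson correlation between forward-stream
  perplexity and a measured fitness, reported with its natural sign.
- Distribution comparisons use two-sided Mann-Whitney U tests
  (exact for small untied samples, tie-corrected normal approximation
  otherwise).

## Developability biasing

The developability stage consumes externally computed structure-based
flags (PSH, PPC, PNC, SFvCSP as green/amber/red); computing them
requires structural modelling and is out of scope by design. The default
corpus policy keeps antibodies with all four structural flags green and
deliberately does not filter on the sequence-based total-CDR-length
metric, which remains cheap to filter post hoc. The CDR-length flag's
numeric risk bands are not published here and stay pure configuration
(defaults: green 40-60, amber margin 3). Biasing is plain finetuning of
all layers on the filtered corpus — no reinforcement learning, no
property predictor — with split labels preserved across stages so
held-out sets stay held out.

## The synthetic repertoire

All tests and the acceptance experiments run on a fully seeded simulator
whose defaults are the package's study conditions:

- Four VH and four VL invented germline families (~110-125 residues)
  with plausible framework/CDR layout and deliberately different heavy
  CDR3 lengths. They are fixtures, not biological references.
- Somatic hypermutation: mean per-chain mutation rate 5% of chain length
  (about 6 substitutions on a typical chain — a realistic memory-compartment
  load), with VH/VL counts coupled through a shared latent gamma
  intensity (G ~ Gamma(a, a); counts conditionally Poisson). The shape
  `a` is solved analytically from the target correlation rho = 0.5, the
  magnitude natural paired repertoires show; the mapping is
  simulation-tested. Negative rho is unreachable by this construction
  and is rejected.
- Pairing preference: each VH family prefers one VL family with
  adherence pi = 0.9, else uniform.
- Heavy CDR3 length jitter of +/-2 residues
  (probabilities 0.05/0.15/0.60/0.15/0.05), applied at the loop midpoint.
- Fitness datasets: fitness = -(mutation load) + Gaussian noise, so
  "more germline-like is fitter" and zero-shot tests have a recoverable
  signal with a closed-form attenuation (1/sqrt(1 + sigma^2/Var)).

What the simulator does **not** emulate: V(D)J junctional diversity,
insertion/deletion profiles of real somatic hypermutation, allelic and
isotype variation, position-dependent mutation hotspots, and repertoire
clonality. Passing tests therefore demonstrate that the machinery
recovers planted structure of these kinds at these scales — not that the
model reproduces real-repertoire biology.

## Desk-scale experiment sizes

The package's own validation experiments (test suite and acceptance
script) use a deliberately small but non-trivial scale, chosen so the
full battery runs on a single CPU in tens of minutes: a 2-layer,
64-dimensional, 4-head model (d_ff 256, max positions 280, untied
embeddings — at this width untying measurably speeds optimization, and
the parameter-count accounting only binds the full-scale configuration)
trained for 10 epochs on 2,000 simulated pairs; 2,000 generated
sequences for the metric panel (the published comparisons also used
2,000); about 150 VH cases with 50 mutation-matched decoys for pairing
discrimination; 500 generated sequences before/after
developability-style finetuning. The training recipe for this scale
(peak learning rate 2e-3, batch 8, 20 epochs, cosine schedule) was
selected by a small grid on validation loss before any downstream
pairing or developability quantity was measured.

Two sampling choices differ from the full-scale operating point, both
re-derived by the same calibration logic that produced the published
1.2/0.95/5% settings (match natural mutation rate, stay valid):

- **Temperature 1.05.** The published 1.2 presumes a converged model; a
  desk-scale model is less confident, and at 1.2 its generations carry
  several-fold the natural mutation load and drift off the germline
  manifold. 1.05 is where generated mutation loads match the simulated
  repertoire's.
- **Forward-direction generation.** Autoregressive sampling noise
  accumulates along the stream, so the second-generated chain is always
  noisier. Pooling forward and reverse generations therefore mixes
  (clean-VH, noisy-VL) with (noisy-VH, clean-VL) records, which induces
  a spurious *negative* association between the chains' apparent
  mutation counts — an artifact of the measurement mixture, not of the
  model. The desk-scale studies generate forward-only so that pairing
  statistics are not confounded; both directions remain available
  (`direction` argument), and chain completion uses the reverse
  direction as designed.

## Known limitations

- Pure R execution: the full-scale (17M-parameter) configuration is
  instantiable and scoreable but not practically trainable here; training
  at that scale needs a GPU framework. The architecture is
  configuration-identical, so weights could in principle be ported.
- The germline-anchored splitter assumes germline-like framework
  flanks; it is not a numbering tool and will refuse heavily divergent
  or non-antibody sequences (by design).
- Embedding-based diversity depends on the model under evaluation;
  comparisons across differently trained models should use a fixed
  external encoder through the pluggable embedding argument.
- Corpus hygiene is a composition of pluggable predicates
  (`filter_corpus()`), because redundancy and sequencing-error rules for
  real repertoire data are protocol-specific. The defaults are
  deliberately minimal: valid residues, an `X`-fraction cap (default 0),
  and the model's position budget. They do not attempt to reproduce any
  database-specific cleaning pipeline.
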