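---
title: "Discourse atom topic modeling: model, estimation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discourse atom topic modeling: model, estimation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datm)
```

## The model

`datm` treats a corpus as the output of a log-linear latent-variable
language model. A latent *discourse vector* (the "gist") $c_t$ moves slowly
through an $N$-dimensional semantic space; at each position a word $w$ with
vector $\mathbf{w}$ is emitted with probability

$$\Pr[w \mid c_t] \;=\; \alpha\,p(w) \;+\; (1-\alpha)\,
  \frac{\exp(\langle \tilde c_t, \mathbf{w}\rangle)}{Z_{\tilde c_t}},
  \qquad \tilde c_t = \beta c_0 + (1-\beta)\,c_t,\; c_0 \perp c_t,$$

where $p(w)$ is the unigram frequency, $c_0$ is a corpus-wide *global
context vector* (shared syntactic/semantic content), and $\alpha,\beta$
trade off frequency against context and local against global context.

Three estimation problems follow, and the package solves each:

1. **Which directions in semantic space are topics?** K-SVD sparse
   dictionary learning factors the $V \times N$ matrix of (unit-normalized)
   word vectors into $V \times K$ sparse codes times $K \times N$ unit-norm
   *atoms*, so that every word is approximately a sparse linear combination
   of at most $s$ atoms. Each atom, read through its nearest vocabulary
   terms, is a topic.
2. **Where in semantic space is an observed window of text?** The MAP
   estimate of $\tilde c_t$ given a window $C$ is the smooth-inverse-frequency
   (SIF) weighted sum $\sum_{w \in C} \frac{a}{p(w)+a}\,\mathbf{w}$ with
   $a = (1-\alpha)/(\alpha Z)$, treated as a single tunable. The global
   component is estimated as the first (uncentered) principal component of a
   sample of window embeddings and projected out, leaving the local gist
   $c_t$. Down-weighting frequent words is also why no stopword list is
   needed anywhere in the pipeline.
3. **Which topic does a window express?** The atom with the largest cosine
   similarity to $c_t$ (`assign_topic()`). Scanning a document with rolling
   windows yields a topic sequence, a distribution, and — the coding used
   downstream — a binary presence vector per document.

Because topics are vectors in the embedding space, embedding methods apply
to them directly: `build_dimension()` spans a semantic axis (for instance
gender) as the renormalized mean of normalized anchor-pair difference
vectors, and `topic_loading()` is the cosine of an atom with that axis.

## Tunable parameters

| Parameter | Default | Where | Meaning and rationale |
|---|---|---|---|
| `min_count` | 5 | `build_vocabulary()` | drop terms seen fewer times; standard embedding practice |
| `delta`, `threshold`, `passes` | 5, 10, 2 | `merge_phrases()` | discounted collocation score $(c_{ab}-\delta)V/(c_a c_b)$; two passes allow multiword terms |
| `dim`, `window` | 100, 5 | `train_embedding()` | embedding dimension and co-occurrence window |
| `K`, `s`, `iters`, `restarts` | –, 5, 30, 3 | `ksvd_fit()` | atoms, sparsity, alternations, multi-start |
| `a` | 1e-3 | `sif_config()` | SIF smoothing; the literature's recommended range is 1e-3–1e-4 |
| `window_size`, `stride` | 10, 5 | `sif_config()` | rolling windows with 50% overlap; fixed-length token spans rather than parsed sentences |
| `top_n` | 10 | `score_model()` | words per atom entering coherence |

Unigram probabilities are computed on the *post-phrase-merge* corpus, so the
SIF weights match the tokens actually embedded.

## Design choices made where the design was open

* **Embedding estimator.** The semantic space is produced by positive
  pointwise mutual information over a symmetric context window followed by a
  truncated SVD with square-root singular-value scaling — the classical
  count-based factorization whose implicit objective matches skip-gram with
  negative sampling. Its advantages here are exact determinism (a
  requirement for the pipeline's byte-level reproducibility contract) and
  zero training hyperparameters beyond `dim` and `window`. Externally
  trained vectors in word2vec text format can be substituted via
  `read_embedding()`.
* **Sparse coder.** K-SVD's pursuit stage is orthogonal matching pursuit
  with a full least-squares refit at each greedy step. The exported
  `omp_code()` additionally guarantees the *optimal* support by enumeration
  whenever $\binom{K}{s} \le 120$ — greedy pursuit, however polished, is
  measurably suboptimal on a few percent of small coherent dictionaries —
  and polishes larger problems by single-atom swaps.
* **Local minima.** Like $k$-means, K-SVD can converge with two atoms
  splitting one true direction. `ksvd_fit()` therefore runs seeded
  restarts (default 3) and keeps the fit with the lowest final residual;
  near-duplicate atoms (|cosine| > 0.99) are re-seeded from the
  worst-reconstructed word each iteration, the standard housekeeping.
* **Atom sign.** An atom and its negation code equally well; each atom is
  flipped so its largest-|coefficient| word loads positively, making
  top-word lists stable.
* **Model selection.** `select_k()` scores each $K$ by coherence (mean
  pairwise cosine among each atom's top words), distinctness (one minus the
  mean pairwise |cosine| among atoms), and reconstruction $R^2 = 1 -
  \|X - CD\|_F^2/\|X\|_F^2$ (uncentered: word vectors have no natural
  origin), then picks the $K$ maximizing the mean of min-max-normalized
  metrics, ties to the smallest $K$. The full table is always returned; the
  rule is a default, not a verdict.
* **Axis construction.** Mean of normalized differences rather than a PCA
  over differences: both are standard, the simpler is the default, and the
  choice is recorded in the output metadata.
* **Degenerate inputs.** Windows with no in-vocabulary token produce a
  flagged empty gist, are assigned the sentinel topic `NA`, and are excluded
  from the distribution normalization. A trailing partial window is kept
  only if it holds at least ⌈window/2⌉ in-vocabulary tokens. Zero-cell
  prevalence ratios are reported as `NA` and dropped (with a count) from the
  loading–prevalence correlation, rather than continuity-corrected.
* **Ties.** Nearest-word and nearest-atom ties break to the lowest
  vocabulary/topic index; the first-PC sign is fixed by making the
  largest-|entry| coordinate positive.

## What the simulator emulates

`sim_config()` / `plant_space()` / `generate_corpus()` generate corpora from
the same generative model the estimator assumes, with ground truth for every
stage:

* $K_{true}$ orthonormal atoms; word vectors are sparse *signed*
  combinations of at most `s_true` atoms plus Gaussian noise, scaled to a
  common norm (`word_scale`, default 5) that controls how concentrated the
  emission softmax is. Signed coefficients matter: all-positive codes would
  plant a spurious shared mean direction that dictionary learning then
  wastes an atom on.
* A Zipfian unigram law (exponent 1), the empirical shape of word
  frequencies.
* A planted binary semantic axis in the orthogonal complement of the atom
  span. Words are offset along the axis by their dominant atom's pole
  (`axis_gap`), and — crucially — each document's emitted gist carries a
  small axis component signed by its dominant atom's pole (`axis_tilt`,
  default 0.5). Without the tilt the axis would be invisible in the token
  stream (it is orthogonal to every emission logit), which is the generative
  way of saying that gendered language must actually co-occur with gendered
  topics to be learnable.
* Anchor word pairs planted as mid-frequency words aligned with the axis
  poles, so `build_dimension()` has the same inputs it would have on real
  text.
* A document-level group label that tilts the dominant-atom choice toward
  pole-matching atoms (`group_effect`), emulating the association between
  victim sex and gendered topics.
* The gist walk is mean reversion toward the document's dominant atom inside
  the atom span, with Gaussian innovations at rate `drift`; `drift = 0` pins
  the gist to the atom exactly. The emission partition function is computed
  exactly over the synthetic vocabulary, so tests carry no sampling
  approximation beyond the draws themselves.

What the simulator deliberately does **not** emulate: syntax, morphology,
polysemy, document length variation, and any real narrative content.
Passing the validation suite shows the estimator recovers the model's own
structure at realistic sizes — it does not certify performance on real
administrative text, where the model is at best a useful approximation.

## Problem sizes used by the validation suite

The suite and `scripts/acceptance.R` run at sizes chosen to finish in
minutes on one CPU while staying in the regime where the method is
meaningful: dictionary recovery on a planted $V = 1000$, $N = 50$,
$K = 20$, $s = 3$ space (noiseless and at noise SD 0.05); a full
simulate → preprocess → embed → fit → assign pipeline at $V = 2000$,
2000 documents × 100 tokens, fitting $K = 30 > K_{true} = 20$ atoms
(overcomplete fitting, the method's own convention, protects against
planted clusters being left without an atom); and a five-seed
loading-vs-prevalence experiment at $V = 1000$, 800 documents. The
$K$-selection grid {5, 20, 80} brackets the planted $K$. The $R^2$-in-$K$
monotonicity check uses the noisy fixture because the noiseless one
saturates $R^2$ at exactly 1 at $K = K_{true}$, a ceiling no larger
heuristic fit can exceed.

## Known limitations

* **Global-component removal can eat a topic.** The first principal
  component of the window embeddings is interpreted as $c_0$. When the
  corpus has few topics or one dominant topic, that PC *is* a topic
  direction, and removing it destroys assignments for that topic. This is
  intrinsic to the SIF recipe, not an implementation artifact; it is why
  the validation corpora use 12–20 balanced topics, and a caution for small
  or skewed real corpora.
* **Only the first component is removed** (the model's $c_0$ is a single
  vector); removing more components is a common empirical tweak but is out
  of scope.
* Hard assignment (argmax cosine) is the model's reading of a window; no
  soft posterior over atoms is computed.
* The gender axis depends on the anchor list supplied; the shipped default
  pairs are data, not a claim about any particular corpus, and loadings
  should always be audited against `rank_topics()`'s top terms.
* With a spectral embedding, `train_embedding()` holds the whole $V \times V$
  PPMI matrix densely; vocabularies beyond ~20k terms need external vectors
  instead.
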