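---
title: "Multimodal representation learning for protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal representation learning for protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Experimentally confirmed protein–protein interactions (PPIs) are scarce
relative to the number of sequenced proteins, so computational predictors
that score candidate pairs are widely used to prioritize experiments.
`ppimm` implements a multimodal predictor that represents each protein by
two independently learned vectors — one from its amino-acid sequence, one
from its position in the known interaction graph — fuses them, and trains
supervised heads for two downstream tasks: deciding whether a pair of
proteins interacts, and assigning a protein to its family.

## The model

**Sequence modality.** Each sequence is converted to a fixed 468-dim
descriptor: amino-acid composition (AAC, 20 residue frequencies), grouped
composition (GAAC, 5 physicochemical classes), conjoint triads (CT, counts
of overlapping 3-mers after mapping residues to 7 classes, 7³ = 343
coordinates normalized as `(f − min f)/max f`), and quasi-sequence-order
descriptors (QSO, composition terms damped by sequence-order coupling
numbers `τ_d = Σ_i d(s_i, s_{i+d})²` computed from residue-distance
matrices; with two matrices and `nlag = 30` this block has 100
coordinates). A stacked autoencoder (468–256–128–64–128–256–468, ReLU
hidden layers, linear output, plain SGD on mean squared reconstruction
error) compresses the descriptor to a 64-dim deep feature at its
bottleneck.

**Topology modality.** From every node of the training interaction graph,
`neighborSize = 4` bounded random walks of `length = 10` are generated
("homogeneous metapaths"; neighbours are sampled uniformly, with no degree
bias, since no bias scheme is specified for the walk statistics). A CBOW
model with window 1 — contexts are exactly the walk-adjacent nodes — is
trained for 10 epochs to predict each walk position from the average of
its context vectors, yielding a 128-dim embedding per node. Test-split
edges are never walked; they are held out before walk generation.

**Fusion and heads.** The two vectors are concatenated (`[topological 128
| sequence 64]` = 192). The interaction head passes the two proteins of a
pair through twin branch networks (one hidden ReLU layer of 64 units
each), concatenates the branch outputs into one fully connected layer of
64 units, and emits a sigmoid probability, trained with binary cross
entropy. The family head is a three-layer DNN (128–64–C, dropout 0.5,
softmax, categorical cross entropy). Both heads use SGD with learning
rate 0.01 and batch size 64. Families with 15 or fewer members are
dropped before training (strict "> 15" rule).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `qso_w` | 0.1 | weight of the sequence-order coupling terms (dimensionless) |
| `qso_nlag` | 30 | maximal residue lag for `τ_d`; sequences must be longer than this |
| `sae_layers` | 256-128-64-128-256 | symmetric hidden widths; middle = bottleneck |
| `embedding_dim` | 128 | CBOW vector width |
| `walk_length`, `neighbor_size` | 10, 4 | walk length in nodes; walks started per node |
| `window` | 1 | CBOW context radius (adjacent walk nodes only) |
| `cbow_epochs`, `sae_epochs`, `dnn_epochs` | 10, 50, 200 | SGD passes per stage |
| `learning_rate`, `batch_size`, `dropout` | 0.01, 64, 0.5 | shared SGD settings; dropout applies to the family DNN |
| `split_ratio` | 0.8 | train fraction of the shuffled balanced dataset |
| `family_min_count` | 15 | strict lower bound on family size |

## Design choices where the design was open

* **`neighborSize` interpretation.** The fanout parameter is described
  only as "how many neighbors we take into account". Since the window
  size already fixes the context radius, we read it as the number of
  walks started per node; an alternative reading (subsampling candidate
  neighbours at every step) is available via
  `metapath_config(per_step_sampling = TRUE)`.
* **CBOW estimation.** The exact softmax over the vocabulary is
  implemented (`softmax_mode = "full"`) and used in tests, but the
  default is negative sampling (k = 5, unigram^0.75 noise), the standard
  scalable CBOW estimator. The objective in both modes is the negative
  log-likelihood of the center node given averaged context vectors; the
  training criterion is the log of the softmax probability, not the raw
  probability, which we take to be the intended objective.
* **CT normalization.** The printed normalization divides by `max f`
  alone; we implement that form and offer the conventional
  `(f − min)/(max − min)` behind `conventional = TRUE`. When all triad
  counts are equal the descriptor is all zeros, as the printed form
  implies.
* **QSO composition.** Only one 20-value equation is printed, yet the
  descriptor budget (468 − 20 − 5 − 343 = 100) requires the iFeature
  QSOrder convention: two distance matrices × (20 composition + 30
  coupling) values. The Grantham matrix is regenerated exactly from its
  published composition/polarity/volume formula. The Schneider–Wrede
  values are not redistributable here, so the second default matrix is a
  clearly labelled *synthetic* stand-in built from three published residue
  scales (Kyte–Doolittle hydrophobicity, Hopp–Woods hydrophilicity,
  side-chain mass, z-scored, RMS difference). Both matrices are
  injectable through `qso_config()`; all correctness tests are
  matrix-agnostic.
* **QSO residue term.** `f_r` is the raw residue count (iFeature
  convention); since the denominator contains `Σ f_r`, the homopolymer
  zero-coupling limit reduces to the composition fraction either way.
* **SAE activation and scaling.** The nonlinearity is unspecified; we
  default to ReLU hidden layers with a linear output because descriptor
  coordinates are not bounded to [0, 1] after the per-column z-scoring we
  apply (descriptor blocks differ in scale by orders of magnitude;
  statistics are estimated on the training split only). Sigmoid and tanh
  variants are available. Weights are untied between encoder and decoder.
* **Pair-order symmetry.** The twin-branch head is not symmetric in its
  two inputs. By default each training pair is augmented with its swap
  and predictions average the two orders, so
  `predict(m, n) = predict(n, m)` exactly; `symmetrize = FALSE` restores
  the strict asymmetric architecture.
* **Branch/hidden widths.** The branch depth before the 64-unit merge
  layer and the family DNN hidden widths are not specified; we use one
  64-unit branch layer and 128–64 hidden layers respectively, both
  configurable.
* **Cross-validation.** Folds are stratified: the datasets are balanced
  by construction, and stratification is the lower-variance choice.
* **Undefined metrics.** Ratios with zero denominators are reported as
  `NA` with an `undefined` flag, never silently replaced by 0 (the
  absent-class-0 convention applies only inside macro-F1).
* **Config files.** Pipeline configurations serialize as JSON (no YAML
  parser is available in the supported dependency set); precedence is
  CLI flag > config file > built-in default.

## The synthetic world

The fixture generator emulates the four inputs the pipeline consumes:
random sequences with a per-family multinomial composition bias
(`composition_shift` extra frequency mass on 5 family-preferred residues,
default 0.1), a planted-partition interaction graph (blocks double as
families), block-disjoint subcellular-location labels (so location-based
negative sampling aligns with cross-block non-edges), and positive pairs
= sampled edges. The default end-to-end fixture is 120 proteins, 2
blocks, `p_in = 0.3`, `p_out = 0.02`, lengths 60–200 — sized so the full
pipeline runs in about a minute on one CPU while leaving both heads a
learnable but non-trivial signal.

What a green test does **not** establish: real interactomes are not
planted partitions (degree distributions are heavy-tailed, communities
overlap, location annotations are incomplete and non-disjoint), and real
family signal is not perfectly aligned with graph communities. The
synthetic results demonstrate that the implementation recovers structure
it is pointed at, not that it reproduces benchmark accuracies on DIP or
HPRD, which require the original downloads and are out of scope.

## Numerical notes

* Epoch counts vs. optimization budget: the published epoch settings were
  tuned against datasets of ~36,000 pairs (hundreds of minibatches per
  epoch). On a 500-row fixture, 50 nominal epochs is only ~400 SGD
  updates, far short of that budget, so the rank-8 compression test
  trains for 2000 epochs (~16,000 updates — the equivalent budget). All
  configuration defaults remain the published values; the end-to-end
  acceptance run uses them unchanged.
* Probabilities inside both cross-entropy losses are clipped to
  `[1e-7, 1 − 1e-7]`.
* CBOW learning rate decays linearly to 1e-4 of its initial value; the
  full-softmax loss history records the exact corpus NLL at each epoch
  end, while the negative-sampling history records the running sampled
  objective.
* Nodes absent from training walks (cold start) receive the zero vector
  by default (`"mean"` available); the fusion layer logs them.
* Ties in similarity queries break lexicographically by node ID, making
  ranked lists deterministic.
* Degenerate inputs: empty sequences, sequences shorter than 3 (CT) or
  not longer than `nlag` (QSO), single-class training sets, families with
  one member, and single-node vocabularies are all rejected with
  explanatory errors; isolated graph nodes yield length-1 walks and a
  warning.

## Known limitations

* The CBOW and SAE trainers are plain-R SGD implementations intended for
  the scale of the synthetic fixtures and modest real datasets; they are
  not tuned for interactomes with tens of thousands of proteins.
* Negative sampling of location-disjoint pairs is rejection sampling; it
  errors out (reporting the achievable count) when the location structure
  leaves too few eligible pairs, rather than switching to exhaustive
  enumeration.
* The nearest-neighbour query is exact and O(|V|) per query; no
  approximate index is provided.
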