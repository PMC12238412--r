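---
title: "Simulating federated-learning benchmarks for multi-site tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated-learning benchmarks for multi-site tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsim)
```

## The problem

Federated learning (FL) trains one model across many institutions that
exchange model parameters, never data. Benchmarking FL *algorithms* fairly is
hard: every candidate aggregation or client-selection rule must run under
identical data partitions, identical local-training code, and identical
(simulated) wall-clock constraints, because training time per round is set by
the slowest participating site. `fedsim` is a desk-scale simulator of exactly
this setting for brain-tumor segmentation: it generates synthetic
multi-institution datasets with the statistical structure of real federations
(a few dominant sites, many small ones, site-specific intensity shifts, nested
tumor sub-regions), trains a miniature segmentation model locally at each
simulated site, and scores algorithms with the segmentation and efficiency
metrics used in federated segmentation challenges.

## The data model

A case is a 4-channel image (channels mirror the standard mpMRI sequences T1,
T1-Gd, T2, T2-FLAIR) with an integer label map in the standard convention:
0 background, 1 necrotic core (NCR), 2 peritumoral edema (ED), 4 enhancing
tumor (ET). Evaluation uses the three nested regions: whole tumor
WT = {1,2,4}, tumor core TC = {1,4}, enhancing tumor ET = {4}.

The phantom generator places a random ellipsoidal lesion in each case: an
outer ED shell, and a core split into a central connected ET blob and
surrounding NCR. Tissue classes are intensity-coded per channel — ET is
elevated only on the T1-Gd channel, ED is bright on T2/FLAIR, NCR is dark on
T1 — and each site applies its own intensity scale/offset and Gaussian noise,
emulating scanner and protocol differences. The default geometry is 2-D 32×32
so that whole-federation experiments finish in minutes; label-map metrics and
post-processing also support 3-D volumes. What the phantoms deliberately do
*not* emulate: MRI physics, anatomy, registration or skull-stripping
artifacts, or full-resolution 3-D volumes. Passing tests on phantoms
demonstrate correctness of the *benchmarking machinery* (metrics,
aggregation, timing, ranking), not clinical-grade segmentation.

Defaults chosen once for the study conditions: tumor radius uniform in 4–9
voxels, ET fraction of the core uniform in 0.2–0.6, per-channel noise sigma
0.05, core radius fraction uniform in 0.4–0.8. The validation split is fixed
per client at `n_val = max(1, round(0.2 n))`, drawn once from the federation
seed. Two study federations are packaged: `homogeneous_federation()` (4 × 20
statistically identical sites) and `skewed_federation()` (one site holding
about half the cases plus four small, mildly shifted sites).

Size laws for `make_federation()` mirror how real federations are skewed:
per-site case counts can be drawn Poisson or log-normal; draws of zero are
redrawn so no client is ever empty. `partition_artificial()` reproduces the
challenge-style refinement that sub-divides the largest institutions into
equal parts after sorting cases by whole-tumor size (stable sort, ties by
case index), which yields sub-sites with systematically different lesion
sizes.

## The local model

Each collaborator trains a deliberately small 2-level residual
encoder–decoder (one residual block per level, 2×2 mean-pool downsampling,
nearest-neighbor upsampling, additive skip, 1×1 output convolution over the
four classes). Parameters live in a single flat vector plus a layout — the
object actually exchanged and aggregated — so any two models from the same
configuration combine linearly and fold back losslessly. Inputs are z-scored
per case and channel, the standard input transform of segmentation pipelines.
The loss is cross-entropy plus soft Dice over the three foreground classes in
equal 1:1 weighting (the dominant combination in practice); cross-entropy is
computed through the log-softmax identity so it stays differentiable under
softmax saturation. The optimizer is plain SGD without momentum; batch order
is seeded per (client, round) so any simulation replays exactly. Default
learning rate 0.2 with batch size 1, chosen for stable convergence: on these
phantoms it overfits a single case within tens of epochs and makes 20-round
federations learn visibly across seeds (larger rates occasionally collapse to
all-background predictions early and stall), which is the regime the
benchmarks need. Forward/backward passes are
hand-written array operations validated against numerical differentiation in
the test suite.

## Metrics

* **DSC** `2|Y ∩ Ŷ| / (|Y| + |Ŷ|)` per region. Conventions (the formula is
  undefined for empty sets): both masks empty → 1; exactly one empty → 0.
* **HD95**: boundary voxels are mask voxels with at least one face-adjacent
  non-mask neighbor (out-of-grid counts as outside); directed distances are
  taken between boundary point sets scaled by voxel spacing; the score is the
  maximum of the two 95th percentiles, with the linear-interpolation
  percentile definition. If either mask is empty, a penalty sentinel is
  returned (default 373.13, the image-diagonal penalty conventional in this
  community; configurable and flagged in outputs).
* **Convergence score**: federated runs produce a validation-DSC-over-
  simulated-time curve; the projected curve `DSC_proj(t) = max_{t'≤t} DSC(t')`
  removes late drops (the best model is kept as the final model), and the
  score is the area under the projected curve divided by the time budget,
  giving a value in [0, 1]. The curve is integrated as a step function —
  validation DSC is only observed when a round completes, so interpolating
  between rounds would credit unobserved performance. Point 0 is the initial
  model at time 0; the round that exceeds the budget is not credited. The
  normalization by the budget is a choice made for comparability across
  budgets and is recorded in run metadata.

## Simulated time

Per round, collaborator k's time is
`T_k = T_down + T_up + T_val · N_val + T_train · N_train`, each component
drawn from a client-specific normal law; the round time is `max_k T_k` over
the selected clients. One draw per component per round is used (an
alternative reading would redraw per sample; the single draw is simpler and
changes nothing qualitative). Negative draws are floored at `10⁻³·mu`.
Communication times are per-round constants — transmission is negligible next
to training in this regime — with a model-size-proportional mode available in
configuration. The "size_proportional" profile makes per-sample training time
dominate (default 60 s/sample train, 6 s/sample validation, 300 s
communication, ±20% per-client jitter, 5% relative noise), so large sites are
the slowest — the regime in which client selection matters. Timing draws come
from a dedicated stream seeded by (master seed, round) and are drawn for
*all* clients every round, so changing the aggregator or the selection policy
can never perturb the clock: all compared algorithms face identical timings.
The default budget is one week of simulated time (604 800 s); benchmark runs
in the tests and acceptance script use a 12-hour budget so that roughly 15–25
rounds fit and the budget actually binds, with `max_rounds = 40` as a hard
cap — problem sizes chosen so a full three-policy comparison runs in about
two minutes.

## Aggregation catalogue

All methods follow the two-step scheme: compute normalized weighting terms
`p_i^k` per client, combine them additively (`Σ β_i p_i^k`) or
multiplicatively (`Π p_i^k`), renormalize, and aggregate
`w_{t+1}^g = Σ_k p̄^k w_t^k`. Implemented terms:

| term | weight ∝ | idea |
|---|---|---|
| `fedavg` | local dataset size N_k | the universal baseline |
| `val_loss` | validation loss after local training | potential for local optimization |
| `cost_ratio` | DSC after / DSC before local training | reward local improvement |
| `inv_param_distance` | 1 / distance to the uniform mean model | downweight outlier updates (whole-model, per-tensor L1, or per-scalar absolute difference) |
| `inv_train_dsc` | 1 / training DSC | penalize overfitting clients |
| `pid_d`, `pid_i` | loss reduction; summed loss over the last 5 rounds | derivative / integral controller terms |

Server optimizers rewrite aggregation as a pseudo-gradient step
`w ← w − λ_s · step(w_t^g − aggregate)` with SGD or Adam steps. A
parameter-change regularizer can rescale weights by `‖w_t^k − w_{t−1}^k‖^s`;
the sign of `s` is genuinely ambiguous in the source descriptions, so the
preset uses `s = −1` (down-weighting large movers, the stability-motivated
reading) with the exponent exposed.

Numerical conventions, all logged: derivative-term losses that worsened are
floored at 0 before normalization (weights must stay a convex combination);
zero denominators and zero distances clamp to 10⁻⁸; an all-zero term falls
back to uniform and is flagged. In multiplicative combinations the
normalization order (before vs. after the product) only matters when a term
is exactly zero; terms are normalized at construction and the product is
renormalized once at the end.

## Client selection

Six policies: all clients; the k largest sites; random groups of k cycled
per round with periodic regrouping; k per round without replacement
(restarting once everyone participated, so all data are seen); alternating
full participation (even rounds) with dropping clients whose previous-round
time exceeded 0.75× the mean (odd rounds); and a one-time Poisson outlier
drop of over-large sites (λ = mean site size, default 97.5% tail; fixed once
because the size distribution is static, with re-randomization available).
The mean in the slow-client rule is taken over the previous round's
participants. An empty selection falls back to all clients, flagged. All
selections are deterministic given (policy, seed, round, federation).

## Ranking schemes

The case-based scheme ranks algorithms per test case on 3 regions × 2 metrics
(DSC high-good, HD95 low-good) and appends the convergence-score rank three
times per case — efficiency carries triple weight — so each algorithm collects
N·9 ranks; its ranking score is the mean of those ranks (the mean preserves
the ordering of the rank sum and matches the scale on which such scores are
usually reported, e.g. 2.75 for the winner of a seven-team field). The
per-institution scheme ranks within each institution per case, region and
metric, averages over cases to per-institution ranks per region-metric, and
scores each algorithm by the mean of its K·3·2 per-institution ranks — every
institution weighs equally regardless of its case count. The per-institution
averages are not re-ranked to integers before the final mean: this keeps the
single-institution case exactly consistent with the case-based scheme. Ties
always receive the minimum rank; non-finite values (the HD95 sentinel, failed
evaluations) rank last; institutions where some algorithm has no evaluable
case are excluded entirely and reported, mirroring how incomplete multi-site
evaluations are handled in practice.

The QC screen sorts cases by the DSC between a strong reference model's
prediction and the provided annotation and flags the bottom `ceil(q·n)`
(default q = 0.2) as candidate annotation errors; with a ground-truth list of
corrupted cases it reports the captured fraction. The packaged error
simulators produce "major" errors (half the lesion's annotation erased along
a random plane) on top of mild uniform relabeling noise.

## Post-processing operators

`fill_tc()` relabels voxels fully enclosed by tumor core to NCR, slice-wise
with 4-connected background regions, one pass each in the axial, coronal and
sagittal orientations (in that order). A convergence mode that repeats the
cycle to a fixed point exists behind a flag; on the packaged fixtures one
cycle is already a fixed point. `small_et_to_ncr()` relabels the ET prediction
to NCR when its volume is below a threshold (strict `<`; optionally per
connected component), and `drop_small_components()` removes small components
of a region mask (face connectivity by default, corner connectivity
available). All operators preserve the label alphabet and are idempotent.

## Reproducibility design

A master seed fans out through a label-hashing function (`derive_seed()`)
into independent named streams — data generation, model initialization, batch
order, timing, selection — so changing one component never shifts the
randomness consumed by another. Two runs with the same configuration are
byte-identical including their run logs; two runs differing only in the
aggregator share the timing stream exactly. These two properties are asserted
in the test suite.

## Known limitations

* The phantom task is nearly voxel-wise separable by intensity; it exercises
  the benchmarking machinery, not segmentation difficulty. Rankings among
  aggregators on phantoms should not be read as predictions for real data.
* The trainable model is 2-D; 3-D support covers label maps, metrics and
  post-processing only.
* Timing magnitudes are synthetic analogues of a real federation's
  measurements (which are not public), so convergence scores are comparable
  within a simulation, not across to real deployments.
* No straggler failures, privacy mechanisms, or communication-size modeling.

## A minimal experiment

```{r example, eval = FALSE}
fed <- skewed_federation(seed = 1)
timing <- make_timing_profile(fed, "size_proportional", seed = 1)
cmp <- compare_aggregators(list(
  all_clients = experiment_config(fed, aggregator_fedavg(),
                                  selection_policy("all"),
                                  timing = timing, budget = 43200,
                                  max_rounds = 40, seed = 1),
  drop_slow = experiment_config(fed, aggregator_fedavg(),
                                selection_policy("alternate_drop_slow"),
                                timing = timing, budget = 43200,
                                max_rounds = 40, seed = 1)
))
cmp$table
autoplot(cmp$runs$drop_slow)
```
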