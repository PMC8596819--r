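---
title: "screendock: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{screendock: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`screendock` orchestrates molecular docking experiments and evaluates their
results, and builds the scoring layer used when docking steers a generative
molecular-design agent. This vignette explains the models and procedures, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic test bed does and does not show about
real docking data.

## 1. The pipeline model

A docking experiment is one JSON configuration: an `embedding` block (ligand
input, state enumeration, 3D coordinate generation, parallelization), a
`docking` block (backend, receptor, poses-per-ligand, write-out mode) and an
`output` block (scores CSV, poses SDF). Validation is strict and total:
every configuration either parses into a fully defaulted
`run_configuration` or fails with the offending key path named. Unknown keys
are rejected deliberately — in free-form JSON a typo like
`"maxcompounds_per_core"` silently reverts a setting to its default, and a
docking benchmark that silently ran with the wrong parallelization is worse
than one that refused to run. Relative paths resolve against the
configuration file's directory, so configuration bundles can be moved as a
unit. A `schema_version` field exists from the start (absent means 1), so a
future dialect change does not have to guess.

Ligands are carried through the pipeline as records, never dropped: an
unparsable SMILES or a failed embedding becomes a flagged record with a
reason, and every run summary reports ligands read / parsed / embedded /
docked / failed. This mirrors how real benchmarking campaigns account for
engines that fail on a subset of ligands.

### State enumeration

A compound expands into *enumerations* — tautomer/stereoisomer states — that
are embedded and docked independently. Two engines are built in:

- **Stereoisomers.** Unspecified tetrahedral carbons are found at the
  canonical-SMILES level: for each eligible atom token the two chirality
  markers are inserted and the atom counts as a stereocentre only if the
  canonicalizer keeps the two variants distinct (the canonicalizer removes
  meaningless markers, which makes this test sound). All marker assignments
  are then enumerated, canonicalized and deduplicated. Atoms whose
  configuration the input already specifies are bracket tokens and are never
  touched, so partial specifications are preserved exactly. The engine
  covers neutral tetrahedral carbons; double-bond (E/Z) and heteroatom
  stereo are out of scope.
- **Tautomers.** A deterministic rule engine applies 1,3 keto–enol
  bond-order flips on the kekulized connection table, in both directions,
  restricted to acyclic sites. The ring guard keeps aromatic systems (e.g.
  phenol) untouched; the price is that alicyclic keto–enol pairs
  (cyclohexanone) are not expanded. This reproduces the *contract* of a
  tautomer enumerator — deterministic state expansion with stable ordering —
  not the rule book of any production tool.

States are deduplicated on canonical SMILES and ordered lexicographically,
which makes enumeration idempotent and run-order independent. `max_states`
(default 32) bounds the combinatorial explosion of polyols; truncation is
flagged on the ligand. The default leaves typical drug-like molecules
untruncated while keeping worst cases (2^k states for k unspecified
centres) bounded.

### 3D embedding

Coordinates come from Open Babel. The primary path is the fast 3D builder
(ring templates plus force-field cleanup, no stochastic conformer search),
which is bit-reproducible. For some fused and 1,2-disubstituted ring systems
that builder fails silently (all-zero coordinates); such molecules fall back
to a deterministic bootstrap — 2D layout, a fixed per-atom out-of-plane
offset (0.15 Å, period 7) so a minimizer has a gradient in z — and
degenerate geometry is detected and flagged rather than passed on. An
optional refinement stage minimizes with a selectable force field (UFF
default, 600 iterations by default) and reads a convergence flag from the
energy trace (plateau at the trace's printed precision). The refinement is
numerically stable but not bit-reproducible across processes (floating-point
association order inside the backend), which is why it is a separate,
skippable stage: workflows that need bit-identical artefacts set
`minimize = FALSE` and keep the deterministic builder output.

### Backends, write-out and parallelization

A backend registers a name, a score direction and a dock function that never
raises for a single bad ligand. Direction is declared at registration
because engines genuinely disagree (energy-like scores are lower-better;
fitness-style scores are higher-better), and every downstream "best"
selection honours it. The three write-out modes reduce the pose stack:
`all`, `best_per_enumeration` (best pose per state) and `best_per_ligand`
(best over all states — the default, matching the common benchmarking
convention of keeping only the best tautomer/ionization state per ligand).
Ties break on (enumeration index, pose index) ascending, so output is
deterministic. Parallel dispatch chunks enumerations
(`max_compounds_per_core` per task) over a process pool and re-sorts results
by (ligand, enumeration), making the report provably independent of core
count and input order — a property the test suite asserts rather than
assumes.

### The synthetic backend

The built-in backend makes the whole framework executable without any
external engine. A receptor is a target vector **t** in a small
physicochemical descriptor space (heavy atoms, rings, H-bond donors and
acceptors, molecular weight, logP, TPSA) with weights **w** and per-axis
length scales **s**; optionally a reference ligand adds a hashed-fragment
(circular fingerprint) Tanimoto term. The score of a ligand with descriptor
vector **d** is

    score = − Σ_i w_i / (1 + ((d_i − t_i) / s_i)²)  [ − w_frag · T(fp, fp_ref) ]

a pure, deterministic function of the canonical SMILES and the receptor
payload: lower is better, the minimum −Σw is attained exactly on target, and
the score degrades monotonically with descriptor distance. The bounded
(Cauchy-type) similarity keeps every component in (0, 1], so no single axis
can dominate unboundedly. Default length scales are set to roughly one
"chemically meaningful step" per axis (e.g. 75 Da molecular weight, 1.5 logP
units). None of this imitates any real engine's scoring function — it is a
test oracle with docking-like structure (direction, poses, failures).

## 2. The analysis suite

**Enrichment.** The logarithmic ROC AUC is the mean over actives of
log10(1/β_i), where β_i is the fraction of decoys ranked better than the
i-th active in the direction-aware ordering. Two policies the underlying
formula leaves open are fixed explicitly:

- β = 0 (an active recovered before any decoy) diverges under the log;
  it is clipped below at 1/n_decoys — the resolution limit of the screen —
  and the number of clipped actives is reported rather than hidden.
- Score ties between an active and a decoy rank the decoy first. This makes
  reported enrichment conservative and deterministic; the classical ROC AUC
  gives ties the standard half credit via average ranks.

Under these conventions random scores give 0.434 (= log10 e) in expectation
and the statistic is invariant under any strictly monotone transform of the
scores; both facts are asserted in the tests. The upper bound is
log10(n_decoys) (all actives clipped), not 1.

**Correlation.** Spearman's ρ is computed as the Pearson correlation of
fractional ranks, which handles ties and reduces exactly to the
rank-difference closed form 1 − 6Σd²/(n(n²−1)) on tie-free data (the closed
form serves as the test oracle, the implementation is cross-checked against
`stats::cor` as an independent route). Kendall's τ-b classifies all
n(n−1)/2 pairs; pairs tied on both variables are excluded from every count,
per the τ-b convention. Constant vectors leave either coefficient undefined
— flagged, not thrown — because an all-censored assay column is a real
occurrence, not a programming error. Both statistics orient each variable
to "better is larger" first, so perfectly co-monotonic data scores +1
regardless of the sign conventions of the inputs.

**Thresholds.** Each compound is classified against hard boundaries on both
axes, with *better than or equal to* the threshold counting as active on
that axis. The boundary rule matters precisely at censored
limit-of-quantification values, which sit exactly at a natural threshold;
one consistent rule beats a configurable one here, and it is stated in the
output.

All modes accept any number of inputs; a corrupt or empty score file fails
that input's row and the rest proceed.

## 3. Agent-side scoring

**Transforms.** Raw property values map onto [0, 1] through `sigmoid`,
`reverse_sigmoid`, `linear_clip` or `step` specs parameterized by two
anchors and a steepness `k` (gain over the anchor span). Both sigmoids pass
through 0.5 at the anchor midpoint; the default k = 10 puts them above
0.99 / below 0.01 at the anchors, so the anchors effectively bracket the
dynamic range. For lower-better docking scores the natural choice is a
reverse sigmoid anchored at the observed score range of known actives — the
transform is where calibration knowledge about the target enters. Which
functional form a production system uses is not prescribed anywhere
authoritative; this family is this package's own choice and is pluggable. A
non-finite raw value (the sentinel for failed docking) maps to 0: the agent
is penalized for unscorable molecules rather than having them dropped, which
would otherwise make failure invisible to learning.

**Aggregation.** The total score is the weighted geometric mean
S(x) = (Π P_i^{w_i})^{1/Σw_i} ∈ [0, 1]. Its algebra is the point: any
component at zero annihilates the total (every property must be reasonably
satisfied), scaling all weights by a constant changes nothing, and equal
weights (the default, weight 1) give the plain geometric mean. QED-style
published descriptors are deliberately *not* reimplemented — a function
provider hooks any external descriptor into a component.

**Diversity filter.** Compounds are keyed by their generic scaffold: the
ring-and-linker framework (iterative terminal-atom pruning) with every atom
made carbon and every bond single, canonicalized; ring-free molecules share
the designated `acyclic` key. Keys are heteroatom- and
decoration-insensitive by construction (benzene and pyridine collide, as do
toluene and phenol). Buckets hold up to 25 compounds (the conventional
capacity); a compound scoring at least `min_score` (default 0.4) occupies
bucket space, and once a bucket is full every further matching compound is
penalized to total score 0 — permanently, which the tests assert as the
monotone-penalization property. Exact duplicates are always penalized. The
similarity threshold for "matching" defaults to exact key equality
(threshold 1.0) with an optional Tanimoto-on-scaffold-fingerprint
relaxation; the capacity is conventional, but the threshold value and the
minimum score are this package's own defaults, since no authoritative
values exist.

**Harness.** `rl_step_harness()` runs the proposal loop the way an RL agent
experiences it — one batch per epoch (default 128), scores computed, the
diversity filter applied, the scored batch fed back — while remaining
agent-agnostic. Per epoch it records mean/max total score, mean raw docking
score and the cumulative number of unique compounds passing a total-score
threshold (a nondecreasing curve by construction). A deterministic
hill-climbing toy proposer over a fixed library stands in for a generative
model in tests; it demonstrates that docking-guided selection pressure
improves mean raw docking scores across epochs, nothing more. Inception /
experience replay is out of scope; the harness keeps a top-compound table so
an agent implementation could plug one in.

## 4. Epoch-similarity analytics

The average-linkage similarity between two epoch batches is the mean
pairwise Tanimoto over all cross pairs, L ∈ [0, 1], computed on circular
fingerprints (radius 3, folded to 1024 bits — the spec used for chemical
space visualization elsewhere; the Tanimoto fingerprint is configurable
since no single authoritative choice exists). `L(b, b)` includes self-pairs,
so the matrix diagonal is intra-batch similarity and equals 1 for
single-molecule batches. A run of n epochs sampled at stride 5 (the
conventional stride; cell k covers epoch 1 + 5(k−1)) gives a
ceil(n/5) × ceil(n/5) symmetric matrix — 200 × 200 for a 1000-epoch run.
Batches are not deduplicated before averaging (duplicates are information
about agent focus, and no authoritative convention says otherwise).
Fingerprints are computed once per distinct molecule across the run, which
is what makes long-run matrices affordable.

## 5. The synthetic test bed — what it shows and what it does not

`generate_screen()` emulates the composition of a curated enrichment
benchmark target: 40 actives and 1200 decoys, decoy scores from a Gaussian
baseline centred at −6 score units (a typical docking-score magnitude) with
unit noise, actives shifted δ noise units toward better (a heavy-tailed
t₃ baseline is available to stress the FPR clipping policy). δ = 0 is
exactly the uninformative screen, so the analytic anchors (0.434 / 0.5)
apply; δ > 0 plants recoverable enrichment that grows monotonically with δ.
`generate_toy_library()` assembles valid-by-construction drug-like SMILES
from a fixed ring–linker–ring–cap grammar (7040 combinations), sampled
deterministically per seed.

These fixtures make every module executable and falsifiable offline, but
they are *not* chemistry: passing tests show the statistics, bookkeeping,
invariances and contracts are right, not that any docking engine ranks real
actives well. Real screens have property-matched decoys, correlated scores,
engine-specific failure modes and pose geometry that no part of this test
bed models. Conclusions about a real target still require a real engine
behind the backend contract and a real benchmark set.

## 6. Numerical choices and problem sizes

- Enrichment/correlation oracles: simulation means use 1000 replicates
  (standard error of the random pROC mean ≈ 0.002, an order of magnitude
  inside the ±0.01 check); monotonicity of planted enrichment uses 100
  replicates per δ ∈ {0, 1, 2, 4}.
- Pipeline invariance checks use a 20-ligand embedded fixture and compare
  reports bit-for-bit across core counts {1, 4}.
- Harness tests run 4–6 epochs of batch 4–16 over a 40-compound library —
  enough to exercise saturation, accounting and the hill-climbing trend
  while keeping the chemistry budget of the whole suite under two minutes.
- Rank-statistic oracle equivalence uses 1000 random instances of n ≤ 50,
  alternating tied and tie-free designs.
- Bit-reproducibility is asserted for everything except the optional
  force-field refinement stage (see §1); all stochastic fixtures take
  mandatory seeds and restore the caller's RNG state.

## 7. Known limitations

- Stereo enumeration covers neutral tetrahedral carbons only; tautomer
  rules cover acyclic 1,3 keto–enol shifts only.
- The synthetic backend's poses are pass-through geometries; pose quality
  metrics (e.g. RMSD to a reference) are out of scope.
- External engine adapters are contract stubs: they validate in
  configurations and refuse to run until an executable is configured.
- pKa/protonation-state prediction, receptor preparation and binding-cavity
  detection are out of scope; the receptor cavity fields are carried for
  adapters, not interpreted by the synthetic backend.
- Correlation pair counting is O(n²); fine for calibration-set sizes
  (hundreds), not for screens of millions.
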