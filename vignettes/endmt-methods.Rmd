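---
title: "Methods: a synchronous Boolean model of endothelial-to-mesenchymal transition"
author: "endmtbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synchronous Boolean model of endothelial-to-mesenchymal transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Endothelial cells (ECs) lining blood and lymph vessels can be activated
into migratory tip cells or proliferative stalk cells during angiogenic
sprouting, or differentiate fully into mesenchymal cells (MCs) through the
endothelial-to-mesenchymal transition (EndMT). `endmtbn` implements a
29-node synchronous Boolean network of the molecular regulatory circuitry
behind these decisions: the VEGF, HIF, NOTCH, FGF, TGF, WNT and PDGF
signaling pathways, the endothelial identity factors FLI1 and GATA2, and
the mesenchymal program drivers SNAI1, SNAI2, TWIST1, ZEB1 and ZEB2.

Each molecule is binary (active/inactive). All nodes update
simultaneously: `x(t+1) = f(x(t))`, each component a Boolean expression
over its regulators. Seven nodes — DLL4, FGF2, HIF1a, PDGF_AB, TGFB, WNT5b
and WNT7a — carry identity rules; their values are constants of the
dynamics and encode the extracellular microenvironment, so the model sees
`2^7 = 128` microenvironments. Because the update is deterministic on a
finite space, every trajectory reaches an attractor: a fixed point or a
cycle, read as a stationary or cyclic pattern of molecular activation and
interpreted as a cell type or cellular behavior.

One textual repair was needed when transcribing the published rules: the
ETS1 equation names a regulator "VEGF2" that is not a model node. We read
it as VEGFR2 — the only consistent interpretation, since ETS1 and VEGFR2
are co-activated throughout the tip-cell patterns — and record the
substitution in the model's provenance metadata rather than silently
fixing it (`build_endmt_network()$provenance`).

## Exhaustive attractor enumeration

The source nodes are invariants of the dynamics, so the `2^29` state space
decomposes exactly into 128 independent functional graphs over the 22 free
nodes. For each environment the engine

1. compiles every rule to a postfix program and evaluates it bit-parallel,
   64 states per machine word, over all `2^22` free-node configurations;
2. transposes the output bit-slices (a 64x64 bit-matrix transpose per
   block) into a successor array;
3. finds all cycles of the functional graph with a colored O(N) walk, and
4. canonicalizes each cycle by rotating it to its smallest integer
   encoding.

The enumeration is exact: every free-node configuration is visited, so the
union of basins over the returned attractors is the whole state space.
This was chosen over a SAT-based attractor search (used in the original
analysis) because both approaches are exact and must agree, while the
direct enumeration is simpler to verify against a brute-force oracle and
takes roughly ten seconds for the full model on one CPU. For the same
reason we use the colored walk rather than pointer doubling — one linear
pass instead of 22 gather passes over each 4M-entry array — and build each
successor map whole (16 MB per environment) rather than in chunks; peak
memory stays below 100 MB. Single trajectories
(`simulate_to_attractor()`) use Brent's cycle detection with a default
bound of 10,000 steps; observed transients are shorter than ~60 steps.

Conventions fixed once and asserted in tests: node index 1 (AP1,
alphabetical order) is the least significant bit of the integer state
encoding; truth-table rows read the regulator tuple as a binary number
with the first-listed regulator as the most significant bit.

## Cell-type classification

A state is labeled by marker predicates:

* **EC** — FLI1 and GATA2 active;
* **MC** — ZEB1, ZEB2, TWIST1 and (SNAI1 or SNAI2) active;
* **Phalanx** — EC with NRP1, CTNNB, SNAI1, SNAI2 all inactive;
* **Tip** — EC with NRP1 and ETS1 active;
* **Stalk** — EC with NRP1 inactive plus a positive stalk marker.

A label applies to a cyclic attractor only when it applies to *every*
state of the cycle; the absence markers are treated symmetrically (the
node must be 0 in every state). The five overlapping labels collapse into
nine disjoint classes (`nECsnMCs`, `EConly`, `Phalanx`, `nMCStalk`,
`MCStalk`, `nMCTip`, `MCTip`, `MCEConly`, `MCsnECs`) that partition any
attractor set; the partition property is asserted in the test suite.

The stalk predicate required a design decision. The biological stalk
marker JAG1 is not a network node, so a proxy had to be calibrated
against the published outputs rather than guessed silently. Candidate
predicates over the canonical-Wnt drivers of JAG1 and the EC activation
factor SNAI2 were screened against three discriminating observables: the
wild-type stalk attractor set (and hence the stalk signature and its
26.57% trap fraction), the published mutation-response table, and the
perturbation-transition table. CTNNB alone, LEF1 alone and CTNNB AND LEF1
all label the correct wild-type attractors (except LEF1 alone) but
misclassify clamped mutants: a LEF1 knockout must leave the stalk classes
intact while a SNAI1 gain or SNAI2 loss must abolish them. The unique
candidate satisfying every check is **CTNNB AND SNAI2** — a stalk cell is
an activated EC (SNAI2 expressed, as tip/stalk biology requires) with
canonical Wnt signaling on (CTNNB, the JAG1 driver) and no tip marker
NRP1. That is the default; `endmt_classifier()` keeps the predicate
configurable (`"CTNNB_SNAI2"`, `"CTNNB_LEF1"`, `"LEF1"`, `"CTNNB"`).

## Trap spaces

Because one attractor can carry several labels and one label many
attractors, basins are aggregated per label: the *trap space* of a class
is the union of the basins of all attractors carrying it. Sizes are
estimated by Monte Carlo: uniform random 29-bit states (sources included),
each walked to its attractor — the walk runs along the known attractor
states of the precomputed atlas, so each sample needs only its transient —
and the fraction per label is reported with a binomial standard error.
Sampling uses R's RNG under an explicit seed recorded in the output. The
reference protocol uses `10^7` samples (about half a minute); the test
suite uses smaller sizes with correspondingly wider binomial tolerances,
and checks estimator consistency between sample sizes.

## Interaction graph and feedback circuits

A regulator j is a *functional* activator (inhibitor) of node i when some
pair of states differing only in j raises (lowers) f_i. Since f_i depends
only on its own regulators, witnesses are scanned over the `2^k`
truth-table rows instead of all `2^n` states. Witness row pairs are stored
with each edge and re-checked in tests. The seven identity self-loops of
the source nodes hold inputs constant rather than describing regulation;
they are excluded from the interaction graph by default (the derived graph
then has 77 signed edges), and can be included with
`include_source_autoregulation = TRUE`.

Elementary circuits are enumerated with Johnson's algorithm (implemented
here because the installed igraph predates its cycle enumerator), with
self-loops counted as length-1 circuits; the sign of a circuit is the
parity of its inhibiting edges. A circuit traversing a dual-signed edge
would be enumerated once per sign assignment; the EndMT graph contains no
dual edges, so its circuit count (74) is unambiguous.

Circuit *functionality* is assessed with a single-context criterion: a
circuit is functional if one joint assignment to the non-circuit
regulators of its targets makes every circuit edge carry a definite sign
witness simultaneously. This is a deliberate simplification of the full
context algebra of logical-modeling tools; it flags all three published
negative circuits (SNAI1 self-inhibition, NOTCH–NRARP, SMAD1–SMAD6) as
functional, but it is more permissive overall (32 functional circuits
against 11 reported by the original GINsim analysis). The package reports
its computed number rather than forcing agreement; treat the flag as a
screen, not as a replica of GINsim's semantics.

## Perturbation protocols

Four robustness protocols are implemented:

1. **Clamp mutants** (`apply_mutations`, `scan_single_mutations`,
   `double_mutant_analysis`): gain/loss of function clamps a rule to the
   constant 1/0; the mutant network is re-enumerated exhaustively and its
   qualitative profile (the set of nine classes with at least one
   attractor) is compared to the wild type. Per-class robustness is the
   fraction of the 58 single clamps preserving at least one attractor of
   the class. A clamped source node stops being a source, so the mutant's
   environment space halves — the enumeration stays exact.
2. **Rule bit-flips** (`rule_flip_robustness`): instances differing by one
   flipped truth-table output bit (node uniform, then row uniform; a
   pooled-row alternative is provided because the reference protocol's
   "random component" is ambiguous) are enumerated and classified, and
   per-class attractor-count statistics aggregated. The reference
   population of 100,000 instances is a cluster-scale run; the default here
   is 100 and the test suite exercises the machinery with an exhaustive
   flip set on a toy network plus a reproducibility check on the full
   model.
3. **State-noise sensitivity** (`rule_sensitivity`): for each component
   f_i and flip count k, the fraction of random states whose k-bit
   corruption changes f_i's output. For an identity rule the analytic
   values are k/29; Monte Carlo estimates must agree within three binomial
   standard errors.
4. **Cell-fate transitions** (`perturbation_transitions`): for every
   attractor and each of the 1024 patterns over DLL4, FGF2, FLI1, GATA2,
   HIF1a, PDGF_AB, TGFB, VEGFA, WNT5b, WNT7a, the pattern bits are
   overwritten in an attractor state (an instantaneous kick, not a
   sustained clamp — though for the seven source nodes the two coincide)
   and the free dynamics converge; destinations are aggregated per
   (source class, destination class) with the nodes constantly active or
   inactive across contributing patterns.

For cyclic attractors the reference protocol does not state whether one or
all cycle states were perturbed. Both modes are provided; the all-states
mode (a pattern counts if it causes the transition from at least one cycle
state) reproduces the published 9x9 transition table exactly, cell by
cell, so it is the default.

## Problem sizes and determinism

The full enumeration visits `2^29` states (~10 s); a mutant scan is 58
such enumerations (~7 min); trap-space estimation at `10^7` samples takes
~30 s. The test suite runs reduced but statistically controlled versions:
trap spaces at `10^6` samples (tolerances widened by the corresponding
binomial factor), sensitivity at 60,000 samples, and a ten-mutant smoke
subset of the scan alongside the full-scan functions. Every stochastic
operation takes an explicit seed and records it in its output; identical
seeds give identical results, which the suite asserts.

## What the model does and does not capture

Attractors and their basins describe the autonomous dynamics of a single
cell's regulatory state under a fixed microenvironment. The model does not
represent multicellular coupling (lateral inhibition between neighboring
tip cells is mimicked only through the DLL4 input), mechanical signals
such as shear stress except through the chosen clamp analogies,
continuous dose responses, or asynchronous/stochastic update semantics.
Marker proteins that act as network sinks (VE-cadherin, PECAM1, vWF and
similar) are not nodes; their activity is read from the included
transcription factors. Passing the bundled checks therefore shows fidelity
to the published discrete model and its analysis protocols, not validity
of those simplifications themselves.
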