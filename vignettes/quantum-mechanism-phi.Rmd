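---
title: "Computing mechanism integrated information for quantum systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing mechanism integrated information for quantum systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qphi)
```

## Scope and model

`qphi` evaluates the irreducible causal information that subsets of a
small quantum register specify about other subsets, across one unitary
update. The system is `n` qubits (the package targets `n` = 2–3; the
algorithms are exhaustive and scale super-exponentially) in a state `ρ`
given as a density matrix, updated as `ρ_{t+1} = U ρ_t U†`. Only unitary
channels are executable: the backward analysis relies on the adjoint
`U†` being the inverse, which fails for general CPTP maps (measurements,
decoherence), so those are rejected with an explicit error rather than
given an ill-defined answer.

The analysis is *compositional*: every nonempty subset `M` of the
register, in its reduced state `m = tr_{M'}(ρ)`, is a candidate
mechanism. Each mechanism is scored by how irreducibly it constrains a
purview `Z` forward (effect) or backward (cause).

## Repertoires and causal marginalization

The conditional state of a purview given a mechanism replaces everything
outside the mechanism by independent maximally mixed noise before
applying the channel. This *causal marginalization* is what makes the
analysis causal rather than correlational: a unit outside the mechanism
that feeds several purview qubits would otherwise induce correlations
that get credited to the mechanism. The classic example is the XOR input
of a COPY-XOR/CNOT gate: by itself it constrains nothing, but naive
conditioning would show a spurious output correlation.

With qubits a second mechanism appears: purview qubits can be genuinely
entangled, and naive per-qubit products would destroy that. The package
therefore factorizes the conditional purview state over its maximal
separability partition `P*` — the finest grouping of qubits such that the
state is a convex mixture of products across groups, with one shared
grouping for the whole mixture. Entangled blocks are treated as
indivisible units; each block's state is recomputed with independent
noise, and blocks are tensor-composed. A pure conditional state passes
through unchanged; a fully entangled purview is kept whole.

The cause repertoire is asymmetric by design: the *mechanism* state is
`P*`-factorized, each part is propagated backwards through `U†` with its
complement noised, and the per-part operators over the purview are
combined by a matrix product and trace-normalized. Causal units are
conditionally independent in the present given the past, not vice versa,
so the backward object is an inference, not a product state.

### Determining P*

Deciding multipartite separability of mixed states is an open research
problem; the package uses a cascade that is exact on every regime the
intended inputs occupy and explicit about its one heuristic:

1. **Pure states** — exact: a candidate grouping is separable iff every
   part's reduced state is pure (checked via `tr(ρ²)`).
2. **Two-qubit mixed states** — exact: the positive-partial-transpose
   (PPT) criterion is necessary *and sufficient* for 2×2 cuts.
3. **Product-basis diagonal states** — exact: if the state is diagonal in
   some product basis across the candidate parts (candidates per part:
   computational, Hadamard, and the part's reduced-state eigenbasis),
   each joint eigenvector is a product, so the state is manifestly a
   mixture of products under one shared grouping.
4. **Everything else** — PPT across every part-vs-rest cut, which beyond
   2×2 is only necessary: a negative partial transpose still rejects
   definitively, but a pass is tagged `method = "ppt-heuristic"` in the
   returned partition so downstream reports can surface it. Bound
   entanglement would be misclassified here; no tractable exact test
   exists, and none of the gate/state families the package ships
   scenarios for reaches this regime.

Candidates are scanned finest-first with a deterministic tie order, so
`P*` is the maximal (finest) separable grouping found.

## The difference measure

With spectral decompositions `ρ = Σ_i p_i |i⟩⟨i|`, `σ = Σ_j q_j |j⟩⟨j|`
and overlaps `P_ij = |⟨i|j⟩|²`, the quantum relative entropy is
`S(ρ‖σ) = Σ_i p_i [log₂ p_i − Σ_j P_ij log₂ q_j]` and the quantum
intrinsic difference takes the *maximum* of the same terms instead of the
sum. The grouping of `p_i` with the whole bracket is a deliberate
resolution of a typesetting ambiguity: it is the only reading that (a)
reduces to the classical intrinsic difference `max_a p_a log₂(p_a/q_a)`
when `ρ` and `σ` commute, and (b) makes the optimizer against a maximally
mixed `σ` the leading eigenvector, so that the intrinsic state is simply
the most probable purview eigenstate. Both reductions are enforced by
tests.

Two conventions: eigenvalues that are zero within tolerance are dropped
(`0·log 0 := 0`), and a zero eigenvalue of `σ` overlapping a contributing
eigenvector of `ρ` yields `+Inf`, reported as such — never silently
clipped — because it flags a genuine support mismatch in a partitioned
repertoire. Against the maximally mixed unconstrained repertoire this
cannot occur.

Relations between QID and S worth knowing when interpreting values: they
coincide when `ρ` is pure (one spectral term); QID is subadditive over
tensor products; but QID is **not** bounded by S in general — a mixed
`ρ` concentrated on one eigenstate can have a single term exceed the sum
when other terms are negative (e.g. `ρ = diag(0.9, 0.1)` against `I/2`).
The test suite asserts the first two properties, not the non-theorem.

## Partitions, φ, and the MIP

A disintegrating partition θ splits `(M, Z)` into at least two parts,
either cutting the mechanism or severing all mechanism–purview
connections; a part carrying the whole mechanism must carry an empty
purview. Enumeration is exhaustive and validated in tests against an
independent brute-force generator. The partitioned repertoire composes
per-part repertoires (empty mechanism part → maximally mixed purview
part), each itself `P*`-factorized, so entanglement destroyed by the
partition counts toward φ.

φ(m, Z, θ) evaluates the QID bracket at the *fixed* intrinsic state
selected against the unconstrained repertoire, with the partitioned
repertoire's spectrum supplying the `q_j`. Numerical conventions:

- **Degenerate intrinsic states.** If the leading eigenvalue of the
  repertoire is degenerate (grouping tolerance `1e-8`), the intrinsic
  state is the whole eigenspace; φ is evaluated for each basis vector of
  the eigenspace and the maximum taken. All downstream quantities are
  invariant to the arbitrary basis the eigensolver returns because
  overlap weights enter only summed against degenerate `q` groups; the
  worked examples additionally have symmetric partitioned repertoires.
- **Clamping.** A raw φ below zero (the partition *increases* the weight
  of the intrinsic state) is clamped to 0, retaining the raw value in the
  score object: irreducibility is non-negative by construction.
- **Normalization.** The MIP minimizes `φ(θ) / n(θ)` where `n(θ)` counts
  mechanism-unit × purview-unit pairs whose connection crosses parts
  (`|M||Z| − Σ_i |M_i||Z_i|`) — the number of possible pairwise
  interactions the partition affects. This reconstruction is isolated in
  `normalization_factor()` so an alternative convention can be swapped
  without touching the search; the shipped examples' MIP identities are
  insensitive to it, which the tests confirm. The reported φ is the
  *unnormalized* value at the MIP.
- **Ties.** Equal normalized φ across partitions: the first in canonical
  enumeration order wins and the rest are recorded. Equal φ across
  purviews: the larger purview wins; same-size ties keep the first in
  canonical subset order and record the rest.

Since the total cut always yields the maximally mixed repertoire with the
maximal normalization, φ at the MIP never exceeds the intrinsic
information — a bound the property tests exercise on random channels.

## Unfolding and modes

`unfold()` analyzes a transition: effect-side mechanisms are reductions
of `ρ_t`, cause-side mechanisms reductions of `ρ_{t+1}`. This avoids
attributing both directions to one "current" state, which is ill-defined
for non-self-adjoint channels. Zero-φ mechanisms stay in the report so
reducibility claims are themselves testable output.

In *self mode* the channel is the identity and forward and backward
constraints coincide; each mechanism is reported once with side
`"constraint"` carrying the single value (not a min over two copies of
the same number). This mode exposes structure due purely to entanglement:
a classical basis state shows only first-order constraints, the GHZ state
a single third-order constraint, and the W state constraints at every
order — the package's canonical demonstration that states with identical
single-qubit reductions can have entirely different internal causal
structure.

## Randomized instances and what tests show

`random_instance()` generates reproducible property-test scenarios: Haar
unitaries (QR of a complex Gaussian with phase-fixed diagonal),
uniform random permutation gates, random product states, and random mixed
states (eigenvalues from a uniform simplex draw, Haar eigenbasis). These
emulate the space of small closed-register systems the method is defined
on; they deliberately do not emulate open-system noise, non-unitary
measurement dynamics, or registers beyond three qubits, so passing
property suites says nothing about those regimes.

Problem sizes in the shipped tests: two-qubit registers for all gate
analyses and the exhaustive classical–quantum convergence sweep (all 24
reversible 2-bit gates × 4 basis states × every mechanism, both
directions, exact equality of φ, purviews, and intrinsic states against
the TPM engine), three-qubit registers for the GHZ/W constraint analyses
and the spectator-qubit embedding. The full suite completes in well under
a minute on one core.

## Known limitations

- Unitary dynamics only; no measurement operators, no open-system maps.
- The `P*` cascade is heuristic (necessary-only PPT) for mixed states of
  three qubits that are neither product-basis diagonal nor detected
  entangled; the `method` tag makes this visible.
- The matrix product in the cause repertoire can be non-Hermitian for
  non-commuting part constraints; the package symmetrizes
  `(X + X†)/2`, warns, and proceeds. On all shipped scenarios the
  operands commute and the symmetrization is a no-op.
- System-level integrated information, relations between distinctions,
  and coarse-graining/black-boxing are out of scope; the unit of analysis
  is the mechanism.
- Registers are closed: there is no background-conditioning of an
  environment, and purviews range over the full register.
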