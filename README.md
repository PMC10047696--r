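# qphi — mechanism integrated information for quantum logic gates

`qphi` computes the **integrated information (φ) of mechanisms** in small
quantum systems evolving under unitary dynamics. It is aimed at researchers
in integrated information theory (IIT), quantum causal modeling, and
quantum information who want to analyze the *compositional* causal
structure of density matrices and quantum gates — which subsets of qubits
irreducibly constrain which other subsets, and by how much — rather than
only whole-system or single-qubit quantities.

## The measure

A system is a register of `n` qubits in state `ρ` (pure or mixed) updated
by a unitary `U`. For a mechanism `M ⊆ Q` in its reduced state
`m = tr_{M'}(ρ)`:

- The **effect repertoire** `π_e(Z|m)` over a purview `Z` is the state of
  `Z` after the update with everything outside `M` replaced by independent
  maximally mixed noise (*causal marginalization*), factorized over the
  entanglement structure `P*` of the conditional purview state
  `π_e(Z|m) = ⊗_i ρ_{t+1}^{Z(i)|m}`. The factorization discounts
  correlations induced from outside the mechanism while preserving genuine
  entanglement inside the purview. The **cause repertoire** propagates the
  `P*`-parts of the mechanism state backwards through `U†` and combines
  them by a trace-normalized matrix product.

- The **quantum intrinsic difference** between `ρ = Σ_i p_i |i⟩⟨i|` and
  `σ = Σ_j q_j |j⟩⟨j|`, with overlaps `P_ij = |⟨i|j⟩|²`, is

  ```
  QID(ρ‖σ) = max_i  p_i [ log₂ p_i − Σ_j P_ij log₂ q_j ]   (ibits)
  ```

  the state-specific counterpart of the quantum relative entropy
  `S(ρ‖σ)` (the sum over `i` of the same terms). The maximizing
  eigenvector (or degenerate eigenspace) is the **intrinsic state**.

- **φ(m, Z, θ)** evaluates that difference between the repertoire and its
  version under a *disintegrating partition* `θ` of `(M, Z)`, at the fixed
  intrinsic state. An exhaustive search over all `θ` finds the **minimum
  information partition** (MIP), minimizing φ normalized by the number of
  severed mechanism–purview connections; `φ(m, Z)` is the unnormalized
  value at the MIP, and `φ(m)` maximizes it over all purviews (larger
  purviews win ties). **Unfolding** repeats this for every mechanism
  subset, giving the system's cause-effect structure.

For a reversible classical gate applied to a computational basis state the
whole pipeline reproduces the classical IIT 4.0 mechanism analysis exactly;
the package ships a TPM-based classical engine (`classical_phi()`) used as
an independent cross-check.

## Worked example

The CNOT gate on the basis input `10` (first qubit = control):

```r
library(qphi)
U   <- named_gate("CNOT", c("A", "B"))
ces <- unfold(U, parse_state("10", c("A", "B")), "transition")
print(ces)
#> <cause-effect structure> mode = transition, register [A B]
#>    side mechanism mechanism_state order phi  ii purview   intrinsic_state
#>  effect         A               1     1 1.0 1.0       A                 1
#>  effect         B               0     1 0.0 0.0      AB span{11,10,01,00}
#>  effect        AB              10     2 1.0 2.0      AB                11
#>   cause         A               1     1 1.0 1.0       A                 1
#>   cause         B               1     1 0.5 0.5      AB       span{01,10}
#>   cause        AB              11     2 1.0 2.0      AB                10
```

Reading the table: the control qubit in state `1` irreducibly fixes its
copy (φ = 1 ibit); the joint mechanism `10` fixes the joint output `11`
(φ = 1); the lone XOR input `0_B` specifies nothing once the control is
noised (φ = 0). Backwards, the XOR output `1` narrows the input to the
tied pair `{01, 10}` — worth only φ = 0.5 ibit because the remaining
two-way uncertainty halves the weight of the pointwise information.
Entangling inputs behave differently: `unfold(U, parse_state("+0",
c("A","B")), "transition")` yields *only* the second-order mechanisms
`+0 → B+` with φ = 2 ibits (every single qubit is fully reducible), and
the identity-channel self-analyses of the GHZ and W states
(`run_scenario("ghz_self")`, `run_scenario("w_self")`) show a bare
third-order constraint versus constraints at every order.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/qphi phi --register AB --state "+0" --channel CNOT --mechanism AB
Rscript inst/cli/qphi unfold --register AB --state "0.5*00+0.5*11" --channel CNOT
```

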