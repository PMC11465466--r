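---
title: "Methods: spin-adapted DMRG for active-space Hamiltonians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spin-adapted DMRG for active-space Hamiltonians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcdmrg)
```

## The problem and the model

`qcdmrg` computes variational ground states of active-space
quantum-chemistry Hamiltonians

$$
H \;=\; E_\mathrm{core}
  + \sum_{pq}\, h_{pq} \sum_\sigma a^\dagger_{p\sigma} a_{q\sigma}
  + \tfrac12 \sum_{pqrs} (pq|rs)
    \sum_{\sigma\tau} a^\dagger_{p\sigma} a^\dagger_{r\tau}
                      a_{s\tau} a_{q\sigma},
$$

with $(pq|rs)$ in chemists' notation and the 8-fold index symmetry of real
orbitals, over the space of matrix product states (MPS): a chain of $N$
order-3 tensors $A^{i_n}[\alpha_{n-1}, \alpha_n]$, one per spinful spatial
orbital, with local dimension 4 (empty, up, down, doubly occupied) and bond
dimensions $D_n$.  The density matrix renormalization group (DMRG)
optimizes the tensors one bond at a time: each update solves the lowest
eigenpair of the two-site effective Hamiltonian with a preconditioned
Davidson iteration, truncates the bond back to the cap by discarding the
smallest Schmidt coefficients, and moves on.  A full pass over all bonds is
a *sweep*; the bond dimension $D \equiv \max_n D_n$ controls the accuracy,
and the truncation-free limit is reached as $D \to \infty$.

The package's analysis layer contains the two standard post-processing
steps for such calculations: second-order polynomial extrapolation of
converged energies in $1/D$ to estimate the truncation-free energy (and
spin gaps between separately extrapolated states, reported in mHartree),
and first-order log-log fits of computational cost against $D$ to verify
the expected scaling regime of the bond-update kernel.

## Symmetry handling: the two accounting modes

Every tensor in the engine is block-sparse over conserved quantum numbers.
Two modes are available and share one interface:

* **`"u1"`** — $U(1)_N \times U(1)_{S_z}$: sectors are (particle count,
  $2S_z$) pairs; the bond cap counts individual states.  This mode is the
  correctness baseline: it makes no assumption beyond exact charge
  conservation.

* **`"su2"`** — total-spin targeting with SU(2) multiplet accounting.  The
  tensors remain $S_z$-resolved, and spin adaptation is enforced through
  three ingredients:

  1. *Singlet embedding.*  For a target spin $S > 0$, a non-interacting
     ancilla site of spin $S$ (local dimension $2S+1$, zero particles) is
     appended to the chain and the global sector is the singlet.  The
     physical state is then the spin-$S$ component coupled against the
     ancilla, and — because the total state is a singlet — every reduced
     density matrix along the chain commutes with the total spin of its
     block.  Bond bases therefore organize into exactly degenerate,
     complete SU(2) multiplets.
  2. *Spin penalty.*  The optimized operator is $H + \lambda S^2_\mathrm{tot}$
     (default $\lambda = 1$ Hartree).  In the embedded $S_z=0$ sector the
     penalty vanishes exactly on (and only on) states whose physical part
     has total spin $S$, so the converged minimizer is the lowest
     spin-$S$ eigenstate and the reported energy
     $\langle\psi|H|\psi\rangle$ carries no penalty bias.  $\lambda$ must
     exceed the amount by which any wrong-spin state undercuts the target
     state; for the molecular and lattice scales treated here (spectral
     spreads of order 1 Hartree) the default is ample, and
     $\langle S^2\rangle$ of the result is reported so a too-small
     $\lambda$ is immediately visible.
  3. *Multiplet bookkeeping.*  Bond caps count multiplets, degenerate
     multiplet partners are never split by truncation (degeneracy grouping
     at relative tolerance $10^{-8}$), and the per-bond multiplet content
     is recovered by character peeling of the $S_z$-resolved state counts:
     repeatedly remove, from the extremal projection inward, one spin-$s$
     multiplet per surviving extremal state.  The $U(1)$-equivalent
     dimension of a retained basis is $\sum_m (2S_m + 1)$, the accounting
     that relates the multiplet count $D$ to $D_{U(1)}$.

  This realizes exact spin targeting and exact multiplet accounting
  without Wigner-Eckart reduced tensors.  The trade-off is deliberate: a
  reduced-tensor engine stores one block per multiplet and gains the
  corresponding factor in memory and flops, which matters at production
  scale but not at the desk scale this package targets; the $S_z$-resolved
  representation keeps one code path for both modes and makes the U(1)
  mode a direct oracle for the SU(2) mode (equal energies on equal
  targets).

## Hamiltonian construction

The Hamiltonian is built as a matrix product operator (MPO) from its
symbolic second-quantized term list.  Fermionic signs use a Jordan-Wigner
string in site-major spin-orbital order (up before down within a site);
the orbital ordering of the input table is used as-is.  Terms are laid out
as a finite-state automaton whose bond states are distinct operator
prefixes, with coefficients riding on each term's closing transition; the
automaton is then compressed exactly by iterated deparallelisation
(merging bond states with proportional rows or columns) and by per-charge
SVD rank reduction of the bond-state row spaces, swept right to left.  The
rank reduction is what discovers the complementary-operator structure
automatically: for a dense two-electron table on $n$ orbitals the operator
bond dimension comes out at the $O(n^2)$ scale (e.g. 226 for $n = 8$)
instead of the $O(n^3)$ prefix count or the $O(n^4)$ term count.  The
construction is validated elementwise against a dense Fock-space
Hamiltonian assembled through Slater-Condon rules on determinant bases,
which locks the two sign conventions to each other.

The total-spin operator $S^2$ used for penalties and diagnostics is built
by the same machinery from its two-site term list (spin operators are
parity-free, so no strings appear).

## The optimization loop

* **Eigenproblem.** Two-site effective Hamiltonians are applied as
  $\sum_\gamma L_\gamma \Psi R_\gamma^T$ over the compressed operator
  channels $\gamma$, with dense sector blocks on the fused (bond x
  physical) spaces.  The Davidson solver uses the operator diagonal as
  preconditioner, a subspace cap of 20 vectors with restarts onto the two
  lowest Ritz vectors, and a per-stage residual tolerance ($10^{-10}$ by
  default; tightened settings change iteration counts, not results).  When
  the preconditioned residual collapses onto the search space (exactly
  diagonal operators do this) the raw residual is used instead.
* **Truncation.** After each solve the two-site wave function is split by
  SVD per symmetry sector; the retained set sorts squared singular values
  across sectors globally, with ties broken toward the smaller
  (particle number, spin label) sector for determinism.  Discarded weight
  is the discarded squared-singular-value fraction.  Singular values below
  $10^{-14}$ of the sector-global maximum are always dropped.
* **Two-site updates** were chosen over single-site updates: from a random
  start they let the solver discover symmetry sectors on the bond that a
  one-site scheme can never repopulate, and they are the scheme for which
  the reported discarded weights are meaningful.  A small seeded
  wave-function noise (off by default) is available to escape sector
  starvation in difficult schedules.
* **Schedules and convergence.** A run follows a staged schedule of
  non-decreasing bond caps (ramping avoids random-start metastability);
  after the staged sweeps, sweeping continues at the final settings until
  the change in sweep energy drops below `energy_tol` ($10^{-8}$ Hartree
  by default; production-scale work typically uses $10^{-5}$, and
  `sweep_report()` flags both thresholds).  The recorded sweep energy is
  the minimum Davidson eigenvalue encountered during the sweep.  Every
  run is deterministic given (table, target, schedule, seed): starting
  states are drawn from a locally seeded stream that restores the caller's
  RNG state.

## Operation accounting

All dense block multiplications are tallied in a ledger as $2mnk$ per
block, split by phase: `heff` for effective-Hamiltonian applications
(the analog of the Davidson-kernel cost that dominates production DMRG
runs), `env` for environment updates, and so on.  Factorizations are
deliberately counted as zero — SVD flop counts are library- and
path-dependent, while multiply counts are exact integers reproducible
across platforms — and retained state counts are reported instead.

For cost-scaling analyses, `scan_bond_dimension()` runs a ladder of caps
(warm-starting each cap from the previous state, as production codes do;
a cold-start mode exists for variational-monotonicity checks) and then
performs one *measurement sweep* per cap with a fixed Davidson iteration
budget, so that the recorded per-sweep `heff` count reflects the matvec
cost at that bond dimension rather than a varying iteration count.

## What the synthetic generators emulate

The FCIDUMP reader accepts real active-space integral tables, but the test
and acceptance fixtures are generated:

* `hubbard_chain(n, t, u)` — an open Hubbard chain in the chemists'
  convention (`g[i,i,i,i] = U`), the standard exactly-solvable benchmark
  family; the dimer's singlet energy $(U - \sqrt{U^2 + 16t^2})/2$ is used
  as a closed-form anchor.
* `random_cas(n, n_elec, seed, scale)` — dense hermitian one-body and
  exactly 8-fold-symmetric two-body integrals drawn from a seeded normal
  stream.  Such tables are near-maximally entangled and exercise every
  operator channel and symmetry sector at once, which real molecular
  integrals (with their locality structure and near-degeneracies) do not;
  conversely they lack the small gaps and multireference character that
  make real systems hard.  Passing the oracle checks on these fixtures
  demonstrates correctness of the machinery, not chemical accuracy on any
  particular molecule.

A full configuration interaction oracle (determinant bases as bitstrings
in the same Jordan-Wigner convention, sparse Hamiltonians via spin-summed
excitation operators, dense diagonalization below 2000 determinants and
deterministic full-reorthogonalization Lanczos above, capped at $10^5$
determinants) provides exact reference energies and total-spin labels for
every fixture the solver runs in the tests.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at sizes chosen so that every
energy can be checked against the exact oracle: Hubbard chains of 2-6
sites, random tables of 3-6 orbitals (both modes, spin targets up to
$2S = 3$), an 8-orbital table for the cost-scaling scan with caps
$D_{U(1)} \in \{8, \dots, 128\}$, and a 6-site chain for the $1/D$
extrapolation study with multiplet caps 4-16.  On one CPU core these
complete in minutes.  Two desk-scale caveats are documented rather than
hidden: on 8 orbitals the finite Fock space (interior bonds cap at
$4^{\min(b, N-b)}$ states and single sectors at their combinatorial sizes)
compresses the window in which the bond-update cost can scale as a clean
$D^3$, so scaling fits are reported on an explicit window together with
their residuals; and extrapolations from small caps carry fit residuals
that the `extrapolation_fit` object exposes instead of suppressing.

## Known limitations

* No point-group symmetry, orbital reordering, or dynamical-correlation
  post-processing; one state per run (no state averaging).
* The SU(2) mode pays U(1)-mode storage and flop costs (see above); its
  benefit here is exact spin targeting and multiplet accounting, not the
  production-scale speedup of reduced tensors.
* Warm-started bond-dimension scans can mask non-monotonicity of
  converged energies in $D$; cold-start scans are available and are what
  the monotonicity tests use.
* The FCI oracle is limited to small active spaces by design; above its
  cap the engine's results are cross-checked only between its own two
  modes.
* Per-sweep energies are not guaranteed monotone under truncation: the
  recorded value is the minimum pre-truncation Davidson eigenvalue of the
  sweep, and at very small caps (a few states per bond) the two-site
  sweep map can settle into a two-cycle between the sweep directions
  rather than a fixed point.  Converged energies remain variational upper
  bounds and monotone in the cap; only the sweep-by-sweep trace
  fluctuates at the truncation-error scale.
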