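---
title: "Exhaustive methyl resonance assignment by satisfiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive methyl resonance assignment by satisfiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Methyl-TROSY NMR extends solution-state NMR to large proteins by observing
only the slowly relaxing $^{13}$CH$_3$ groups of (typically) Ile, Leu and
Val side chains. Before any structural or dynamic interpretation, every
cross-peak in the 2D $^1$H-$^{13}$C HMQC reference spectrum must be
*assigned* to a specific methyl of the protein. Without backbone
assignments, the principal source of assignment information is the network
of NOE cross-peaks between methyls, which reports through-space proximity
(up to roughly 10 Å), together with a known 3D structure or structural
model.

`methylsat` treats this as an exact combinatorial problem: the NOE-derived
*data graph* $H$ (nodes: 2D reference peaks; edges: symmetrized NOE
connectivities) must embed into the structure-derived *methyl connectivity
graph* $G$ (nodes: labeled methyls; edges: pairs within NOE-observable
distance) — a subgraph isomorphism. Instead of searching for one good
embedding, the package encodes *all* constraints in propositional logic and
enumerates, for every reference peak, its complete **support set**: the set
of methyls the peak maps to in *some* globally consistent assignment. A
peak with a singleton support is proven unique; a peak with three options
is guaranteed to be one of those three. This exactness is the point of the
approach: no heuristic pruning step can silently discard the true
assignment.

## The structure graph

For two methyls $p, q$ with protons $p_i, q_j$ in model $s$, the effective
distance is the multiplicity-corrected $r^{-6}$ average over the nine
proton pairs,

$$\Delta_s(p,q) = \Bigl(\tfrac{1}{9}\sum_{i=1}^{3}\sum_{j=1}^{3}
d(p_i,q_j)^{-6}\Bigr)^{-1/6},$$

and across a conformational ensemble $S$ the adjacency is the minimum
$\Delta(p,q)=\min_{s\in S}\Delta_s(p,q)$, so that a contact present in any
plausible rotamer state is representable. The averaged form (rather than
the plain $r^{-6}$ sum) stays within the range of the individual
interproton distances — for distances 4, 5.5 and 7 Å the sum gives 3.9 Å
while the average gives 4.7 Å — which is the appropriate convention for
upper-bound distance thresholds; because the thresholds are generous and
ensembles are used, the exact averaging convention is not critical.

Edges are classed **geminal** (the $\delta_1/\delta_2$ or
$\gamma_1/\gamma_2$ pair of one Leu/Val; categorical, always present),
**short** ($\Delta \le$ `short_radius`) and **long** (`short_radius`
$< \Delta \le$ `long_radius`). Defaults are 8 Å and 10 Å; recommended
ranges 6–8 Å and 10–12 Å, matching what short (~50 ms) and long (~300 ms)
NOESY mixing times can detect. Rotamer sampling is *not* performed
internally: the same contract is met by accepting multi-MODEL PDB
ensembles (NMR ensembles, pre-relaxed or predicted model sets) and taking
the ensemble minimum. Missing methyl protons are constructed at ideal
tetrahedral geometry (C–H 1.09 Å, 109.47°) from the heavy atoms.

For oligomers with identical chains, methyls are collapsed to their
(residue, atom) identity and $\Delta$ is minimized over all intra- and
inter-chain pairings, so interface NOEs are representable
(`oligomer_chains=`).

## Deriving all candidate data graphs

The raw inputs are peak lists, not an annotated network; every
interpretation step that a spectroscopist would do by hand is instead kept
ambiguous and resolved globally:

1. **Diagonal elimination.** A 3D NOESY maximum $(C_1, C_2, H_2)$ with
   $|C_1-C_2| <$ `diagonal_tol` (default 0.15 ppm, the same scale as the
   clustering tolerance; the parameter is tunable) is a diagonal peak and
   is dropped. Retained peaks are upper-diagonal ($C_1>C_2$) or
   lower-diagonal.
2. **Clustering.** A NOESY peak may project onto reference peak $(C,H)$
   iff $|C_2-C| < C^{\mathrm{cluster}}_{\mathrm{tol}}$ and
   $|H_2-H| < H^{\mathrm{cluster}}_{\mathrm{tol}}$ (defaults 0.15 and
   0.02 ppm; strict inequalities throughout). *All* peaks satisfying both
   are retained as candidates; peaks with none are dropped
   ("unclustered").
3. **Symmetrization.** A true connectivity appears as an upper-diagonal
   peak plus its mirrored lower-diagonal counterpart. Peaks $k$ (upper)
   and $k'$ (lower) of the same mixing-time spectrum are potentially
   symmetric iff $|C_2-C_1'| < C^{\mathrm{sym}}_{\mathrm{tol}}$ and
   $|C_1-C_2'| < C^{\mathrm{sym}}_{\mathrm{tol}}$. This yields a bipartite
   *symmetrization graph*; its connected components of 2–3 nodes (≤2
   edges, "simple") become constraints directly, peaks with no potential
   mirror are dropped, and larger ("complex") components are reduced by
   explicit satisfiability (below). Symmetrization is computed within each
   mixing-time spectrum separately: a 50 ms peak's mirror is sought among
   50 ms peaks, since cross-spectrum pairs would mix distance classes.
   For 4D peak lists the indirect $^1$H dimension must mirror as well,
   which collapses most symmetrization ambiguity.

## The Boolean encoding

Variables: $X(i,j)$ — 2D peak $i$ is assigned to methyl $j$ (created only
for methyls compatible with the peak's residue-type, stereospecificity,
geminal and fixed-assignment annotations); $Y(k,l)$ — NOE $k$ clusters to
peak $l$; $Z(k,k')$ — NOEs $k,k'$ are truly symmetric. Constraints:

1. exactly one $X(i,\cdot)$ per peak;
2. at most one $X(\cdot,j)$ per methyl (missing resonances are allowed,
   so peaks ≤ methyls is required but not equality);
3. exactly one $Y(k,\cdot)$ per NOE in the symmetrization graph;
4. $Z$ follows the component rules: forced for size-2 simple components,
   exactly-one over the two alternatives for size-3;
5. if $Z(k,k') \wedge Y(k,l) \wedge Y(k',l') \wedge X(l,m)$, then
   $X(l',m')$ for some $m'$ adjacent to $m$ in $G$ with a class compatible
   with the mixing time (short-mixing NOEs need a geminal or short edge;
   long-mixing NOEs any edge).

Annotated geminal 2D pairs additionally satisfy
$X(i,m) \rightarrow X(\mathrm{partner}(i), \mathrm{gem}(m))$, and partial
assignments become unit clauses. Constraint (5) is emitted in the standard
subgraph-isomorphism *support-clause* form — one clause per
($Z$ edge, cluster pair, methyl) listing the compatible neighbour
assignments — which, given the exactly-one constraint on the partner peak,
is logically equivalent to blocking every incompatible methyl pair but
generates an order of magnitude fewer clauses. Exactly-one cardinality uses
pairwise encoding for domains up to 30 and the sequential (ladder)
encoding above that; the semantics are identical.

The package carries its own complete CDCL solver (two-literal watches,
first-UIP clause learning, VSIDS activities with phase saving, Luby
restarts, learned-clause reduction), exposed through incremental clause
addition and solving under assumptions. Assumptions are what make the
enumeration cheap: temporary constraints never require rebuilding the
formula. Every model returned is re-checked against every problem clause
before being accepted. A DIMACS export (`write_dimacs()`) allows external
verification of any instance. A per-call conflict budget can be set; a
budget hit is reported as "undetermined", never conflated with
unsatisfiability.

## Complex components and support enumeration

For each complex symmetrization component, all maximum matchings are
enumerated (branch-and-bound with an augmenting-path bound; capped at
10,000 per component, a capped component is left unresolved). Each matching
is adopted as assumed-true $Z$ variables; an edge survives iff it lies in
at least one satisfiable matching. Eliminated edges are fixed false, the
component structure is recomputed, and newly simple components join the
constraint set, iterating to a fixpoint. Whatever remains complex is not
used, and its peaks are flagged in the report so the user can revisit them.

Support sets are then enumerated with the iterative scheme: get one global
model; for one peak at a time, repeatedly forbid its known options (as
assumptions) and re-solve until UNSAT; freeze the peak's domain to its
support; continue with the next peak in ascending domain-size order.
Freezing does not change the global solution set (the support already
contains every value the peak takes in any model), so the final supports
are exact, and each model found along the way seeds the supports of all
other peaks, keeping the number of solver calls near the sum of the
support sizes. The resulting sets are order-invariant, and a methyl proven
unique to one peak can never appear among another peak's options.

On unsatisfiable inputs the per-component guard variables (selector
literals assumed true in every call) allow deletion-based diagnostics:
the report names the NOE symmetry components whose removal restores
satisfiability, or a greedily grown conflicting set, before pointing at
annotation errors.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `short_radius` | 8 | Å | max distance for short-mixing NOEs (recommended 6–8) |
| `long_radius` | 10 | Å | max distance for long-mixing NOEs (recommended 10–12) |
| `c_tol`, `h_tol` | 0.15, 0.02 | ppm | clustering tolerances ($^{13}$C, $^1$H) |
| `c_tol_sym` | 0.15 | ppm | symmetrization $^{13}$C tolerance |
| `diagonal_tol` | 0.15 | ppm | diagonal elimination tolerance |
| `mm_cap` | 10000 | — | maximum matchings enumerated per component |

`optimize_short_radius()` implements the threshold search: start at 8 Å,
lower in 0.1 Å steps until the network no longer fits, and return
$\min(d_{\min} + 0.5, 8)$ Å, each probe being a single satisfiability
check. The 0.5 Å back-off guards against the discreteness of the probe
grid and small structural inaccuracies.

## The residue-type classifier

When a peak has no experimental residue-type annotation, its
$(^{13}C, ^1H)$ position is classified against a binned frequency table
(0.1 × 0.02 ppm bins, matching the tolerance scales): the peak receives the
minimal set of residue types whose ranked cumulative bin frequency reaches
99%. The packaged table is **synthetic**: it is materialised at load time
from per-methyl-type bivariate Gaussian parameters
(`inst/extdata/methyl_shift_params_synthetic.csv`) chosen to match the
canonical methyl-region ranges (Ala β ≈ 19/1.35 ppm, Ile δ1 ≈ 13.4/0.75,
Leu δ ≈ 24–25/0.75, Val γ ≈ 21/0.8, Met ε ≈ 17/1.95), because building the
empirical table requires database access. Densities are evaluated
analytically at bin centres, so no histogram smoothing is needed; an
empirical table with the same parameter layout slots in unchanged. By
construction, sampling from the table's own model contains the true type
in ≥ 99% of draws, which the tests verify by Monte Carlo; accuracy on real
shift distributions depends on how well the Gaussian summaries fit them
and is not claimed here. Geminal-pair prediction from NOE strength is
deliberately out of scope.

## What the simulator emulates — and what it does not

`simulate_instance()` builds ground-truthed instances end to end: methyl
carbons packed at protein-like density (0.003 methyls/Å$^3$, minimum
separation 4 Å, giving nearest-neighbour distances of 4–7 Å), Leu/Val
geminal pairs at the geminal C–C distance (2.55 Å) around a shared parent
atom, protons at ideal geometry; a data graph $H$ sampled from $G$ by
uniform edge removal down to a target degree connectivity
($2E/N$, default 3.5–4.2, i.e. 1.75–2.1 observed NOEs per methyl — the
sparsity regime of real data sets); reference shifts drawn from the
per-type methyl-region distributions with a separation rule unless overlap
is forced (`overlap_rate` moves that fraction of peaks within clustering
tolerance of a same-type neighbour); and per $H$-edge upper/lower NOESY
cross-peak pairs with bounded Gaussian jitter, plus diagonal peaks.
Cross-peaks between methyls whose $^{13}$C shifts differ by less than
`diagonal_tol` + the maximal mirror asymmetry the clamped jitter can cause
are *not* emitted: such maxima sit inside the diagonal ridge and are not
separately pickable, and emitting them would make one mirror of a pair
straddle the diagonal-elimination threshold — an artifact of treating
unobservable peaks as observed, mainly affecting Leu/Val pairs with
near-degenerate carbon shifts.

Because jitter is clamped at 2σ below the tolerance margins and every
emitted cross-peak has its mirror emitted, the planted assignment is
satisfiable by construction, and the planted symmetry pairing is a perfect
matching of every symmetrization component — which is why the reduction
provably never eliminates it. Passing tests therefore demonstrate
*exactness of the enumeration under the stated noise model*; they do not
demonstrate robustness to what the generator does not emulate: false
positive NOEs (spectral artifacts), missing 2D reference peaks with their
NOEs still present, strongly non-Gaussian peak-position errors, intensity
information (deliberately unused), or spin-diffusion-mediated long
transfers beyond the radii. On real data those appear as unsatisfiable
inputs with diagnostics, not as silently wrong assignments.

## Numerical and design choices

* All tolerance comparisons are strict (`<`), following the printed
  inequalities of the clustering and symmetrization rules; a difference
  exactly at tolerance does not match.
* Distances are compared at full precision and reported to 0.1 Å.
* Geminal edges are kept in $G$ irrespective of distance (they are
  categorical); a geminal edge satisfies both short- and long-mixing
  requirements.
* An NOE whose component remains complex is reported
  `unresolved_complex_component`; an NOE isolated before reduction is
  `no_symmetric_partner`. Every NOE lands in exactly one of
  {used, geminal, no_symmetric_partner, unresolved_complex_component,
  diagonal, unclustered}.
* Supports at a smaller short radius are contained in those at a larger
  one *only because* lowering the radius strictly tightens the
  short-mixing compatibility sets while leaving the long-mixing sets
  unchanged; satisfiability is therefore monotone non-decreasing in both
  radii, which is what the radius optimizer exploits. No such containment
  holds for the long radius in general.
* Complex-component reduction adopts the literal reading of constraint
  (4): each assumed pair must lie in *some* maximum matching of its
  component; the chosen pairs are not additionally required to assemble
  into one coherent maximum matching. On every generated benchmark the two
  readings coincide (the planted pairing is a perfect matching); the
  literal reading is also the cheaper one to encode.
* Test problem sizes: the exactness property is exercised on 50 instances
  of 20–120 methyls (the range where the published experimental targets
  and most practical cases live), the brute-force cross-check on ~100
  instances small enough for exhaustive map enumeration (≤6 peaks), and
  the coverage report on 100-methyl instances across six seeds.

## Known limitations

* No maximum-subgraph-matching fallback: inputs whose NOE network cannot
  embed are reported unsatisfiable with diagnostics rather than "repaired"
  by dropping NOEs, because silently removing edges can change the
  solution space globally.
* NOE intensities are never used; ranking within a support set is left to
  the user.
* The geminal/residue-type classifier shipped here is synthetic-table
  based (see above); quantitative classifier accuracy on real proteins is
  not claimed.
* mmCIF files, peak picking from spectra and pulse-sequence concerns are
  out of scope; inputs are peak lists and PDB coordinates.
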