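---
title: "Co-evolutionary contact prediction with coevomap: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-evolutionary contact prediction with coevomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`coevomap` analyses a protein family through a global statistical model of
its multiple sequence alignment. A sequence $X = (X_1, \dots, X_L)$ over
$q = 21$ states (20 amino acids plus the gap) is assigned

$$P(X) \;=\; \frac{1}{Z}\exp\Big[\sum_i h_i(X_i) \;+\; \sum_{i<j} J_{ij}(X_i, X_j)\Big],$$

a Potts model with per-position fields $h_i$ and pairwise couplings
$J_{ij}$; $Z$ is the partition function. The premise of direct coupling
analysis (DCA) is that residues in physical contact cannot evolve
independently, so the *direct* couplings $J_{ij}$ — as opposed to raw
correlations, which propagate transitively — concentrate on structural
contacts.

Two inference routes are implemented:

* **Asymmetric pseudo-likelihood (`fit_plm()`)** — the accurate route.
  Each position $i$ contributes the conditional likelihood
  $P(X_i \mid X_{-i})$, a multinomial logistic model that is convex per
  site. Sites are fitted independently (hence "asymmetric") and the two
  directed estimates of each $J_{ij}$ are averaged. The objective is the
  weighted conditional negative log-likelihood divided by the effective
  sequence number, plus L2 penalties $\lambda_h\|h_i\|^2 +
  \lambda_J\sum_j\|J_{ij}\|^2$ with $\lambda_h = \lambda_J = 0.01$ on that
  per-effective-sequence scale, so $\lambda$ needs no rescaling with
  alignment depth. Optimization is deterministic L-BFGS from a zero start;
  convergence is declared at gradient max-norm $\le 10^{-5}$ (a smooth,
  convex problem — the optimizer must not matter beyond tolerance). The
  inner kernel is compiled (Rcpp), as in every practical plmDCA
  implementation.

* **Mean-field inversion (`fit_mean_field()`)** — the fast, approximate
  route used inside the paralog-matching loop, where hundreds of refits on
  tiny alignments are needed. Pseudocount-regularized weighted frequencies
  $f_i(a)$, $f_{ij}(a,b)$ give the connected correlations
  $C_{ij}(a,b) = f_{ij}(a,b) - f_i(a)f_j(b)$ over $q-1$ states per position
  (gap as reference), and $J = -C^{-1}$. The pseudocount default is 0.5,
  the standard value for this solver; pseudocount 1 gives the uniform model
  (all couplings zero), pseudocount 0 on degenerate data raises a
  singularity error rather than returning noise.

## Sequence weighting

Phylogenetic redundancy is corrected the standard way: sequence $s$ gets
weight $1/|\{t : \mathrm{id}(s,t) \ge 0.9\}|$, and $N_\mathrm{eff} = \sum_s
w_s$. Two conventions are ours to fix, since only the 90% radius is
standard: a pair at *exactly* the threshold counts as similar (the radius
reads as a maximum identity between effective sequences), and identity is
computed over all $L$ columns with the gap as an ordinary 21st symbol —
the simplest deterministic choice; alternatives (ungapped-length
normalization) change $N_\mathrm{eff}$ by little on realistic alignments
but are not implemented.

# From couplings to contacts

The Potts parameterization is redundant (a "gauge freedom"): per-state
offsets can move between $J$ and $h$ without changing $P(X)$. Scores are
therefore computed in the zero-sum gauge (`zero_sum_gauge()`), the unique
representative with zero row and column means in every coupling block.

The raw score is the Frobenius norm of the gauged block. By default the
block is first restricted to the $20 \times 20$ non-gap states *and the
gauge is recomputed on that block* (`exclude_gap = TRUE`): long gap
stretches in real alignments induce strong but structurally meaningless
gap couplings, and restricting before re-gauging removes their influence
entirely rather than just shrinking it.

The **average product correction** (`apc_correct()`) subtracts
$\bar S_i \bar S_j / \bar S$ — the rank-one background that conserved or
high-entropy positions impose on whole rows — with row means taken over
the off-diagonal. For two concatenated families the correction is taken
**asymmetrically** (`apc_correct_asymmetric()`): the two averages run over
the two families separately, accommodating different evolutionary rates;
intra-family blocks keep the symmetric rule.

Predictions are the top $N$ pairs at chain separation $j - i \ge 5$
(`rank_contacts()`), with $N = L$ by default — retaining as many contacts
as alignment columns; `top_n_multiplier = 2` doubles the retention for
exploratory analyses. Ties break lexicographically so ranked lists are
reproducible. For a 109-column family this gives 5460 eligible pairs of
which 109 (~2%) are kept.

Inter-family scores can be placed on a family-independent scale
(`normalized_inter_score()`):

$$\tilde S_{ij} = \frac{S_{ij}}{\,|\min_{(i,j)\,\mathrm{inter}} S_{ij}|\,\big(1 + N/N_\mathrm{eff}\big)}$$

so one acceptance threshold (0.8, strict inequality) serves across
families. The published typography of this expression leaves ambiguous
whether $(1 + N/N_\mathrm{eff})$ multiplies the denominator or the score;
we adopt the denominator reading — it is the one that *shrinks* scores for
shallow alignments (large $N/N_\mathrm{eff}$), matching the stated purpose
of removing the dependence on length and depth — and the choice is
isolated in this single function so it can be flipped. The map is
positive monotone: rankings are unchanged either way.

# Structural validation

Two residues are in structural contact when any pair of heavy atoms lies
**strictly below 8.5 Å** (`contact_map()`); varying this cutoff mostly
rescales the neighborhood rather than changing conclusions. Alignment
columns are tied to structure residues by global alignment of the family
consensus against the structure sequence (match +1, mismatch 0, affine
gaps, via `Biostrings::pairwiseAlignment`); mappings covering under 30% of
columns or under 30% identity are flagged unreliable. The true-positive
rate (`true_positive_rate()`) is the fraction of the first $k$ retained
predictions that are native, reported with the full cumulative curve;
predictions that cannot be mapped onto the structure are excluded from the
denominator and counted separately — the conservative convention, since
the alternative silently scores unresolved regions as failures.

The **shortest-path analysis** (`shortest_path_classes()`) asks, for each
predicted pair, how many structural-contact edges are needed to join the
two residues. Native contacts have SP = 1; SP = 2 predictions are
mediated by one shared neighbor, and so on. The SP graph deliberately
keeps *all* contacts including sequence neighbors — mediation through the
chain is exactly what the analysis measures; the $j - i \ge 5$ rule
applies only to which predictions are made, never to the graph.
`igraph` computes the distances; the test suite checks them against an
independent brute-force BFS.

# Iterative paralog matching

To predict contacts *between* two families A and B, their sequences must
be concatenated partner-with-partner. Organisms with multiple paralogs
make this pairing ambiguous; IPA resolves it by maximizing inter-family
co-evolution self-consistently:

1. Within each organism, randomly match $\min(N_A, N_B)$ pairs (the seed).
2. Fit mean-field DCA on the concatenated matched alignment.
3. Score every candidate pairing in every organism by summing the gauged
   inter-family couplings along the two sequences.
4. Rank all candidates globally; greedily accept the top pairs under the
   one-to-one-per-organism constraint until $N_\mathrm{select}$ are kept.
5. Grow $N_\mathrm{select}$ by 6 per iteration and refit, until
   $N_\mathrm{select} = N_\mathrm{max} = \sum_\mathrm{org} \min(N_A, N_B)$.

The seed is discarded after the first iteration; iteration 1 keeps only
the 6 most confident pairs, which is what lets a random start bootstrap.
Greedy confidence-ranked assignment is the procedure as published; an
exact per-organism assignment (Hungarian) would interact awkwardly with
the global $N_\mathrm{select}$ cap and no assignment solver is available
in the dependency set, so greedy is the only strategy offered.

Robustness comes from repetition (`acceptance_frequencies()`): the whole
procedure is run `n_runs` times from different seeds (child seeds spawned
from the master seed by counter, so ensembles are reproducible); each
final matched alignment gets a full pseudo-likelihood fit, gap-excluded
Frobenius scores, asymmetric APC and normalization; and each inter pair
with $\tilde S > 0.8$ counts as accepted. Whether acceptance should be
recorded at every iteration or on the final alignment is ambiguous in the
method's descriptions; we evaluate the final alignment only — it is the
model the procedure actually converges to, and intermediate alignments
are both small and transient. $N$ and $N_\mathrm{eff}$ in the
normalization refer to the concatenated matched alignment.

# The synthetic world

Real inputs for this kind of study are database retrievals (homolog
searches, PDB entries) that cannot be pinned inside a package. The
generator module replaces them with a world whose truth is known:

* **`generate_topology()`** grows a self-avoiding bead chain (3.8 Å
  steps, 3.4 Å hard core, centroid attraction 0.3) and rejects chains
  until at least `n_long_range` pairs with $j - i \ge 5$ fall within
  8.5 Å. The realized chain's exact contact list is the truth — written
  to a toy PDB by `write_toy_structure()`, it reproduces itself through
  `read_structure()` + `contact_map()`. Because acceptance is
  "first chain meeting the target", realized counts moderately overshoot
  the target; that is inherent to using realized geometry as truth.
* **`plant_potts()`** puts random $\pm$strength patterns (zero-sum
  gauged) on the long-range contacts only — short-range contacts are
  geometric necessities of any chain and carry no evolutionary signal.
* **`sample_sequences()`** draws alignments by single-site Gibbs sampling
  (single chain, burn-in, thinning); a two-site reduced-alphabet model is
  checked exactly against its enumerated Boltzmann distribution in the
  tests, which bounds sampler correctness where enumeration is feasible.
* **`generate_paired_families()`** samples joint A+B sequences from a
  Potts model whose couplings sit on planted inter-family pairs; each
  planted pair couples states through a random permutation, so a true
  partner's states track the planted correspondence. Every organism gets
  $\min(N_A, N_B)$ jointly sampled true pairs; excess paralogs are decoys
  whose sampled partner is discarded. **Each joint draw comes from its own
  freshly burnt-in chain**: organisms are independent, and reusing one
  thinned chain would leak state between consecutive draws — at strong
  couplings that correlation makes decoys resemble true partners and
  silently degrades matching. Defaults (40 planted inter pairs, strength
  5 — partner-state concordance ≈ 0.85 per pair) realize a strongly
  coupled interface of realistic size for an 8.5 Å contact definition.

What a green end-to-end test establishes: that inference, scoring,
structure mapping and matching recover planted truth at desk scale (L =
40, M = 6000 for the monomer benchmark; 20 organisms × 2–3 paralogs for
matching). What it does not establish: behavior under phylogenetic
correlation (our sampler has no tree structure beyond what reweighting
removes), realistic indel processes (gaps appear as just a 21st state),
alignment errors, or database-scale heterogeneity. Recovery floors on
real families will be lower.

# Numerical choices and degenerate inputs

* Residue codes are 1..21 with the gap at 21; B/Z/J/X/U/O map to the gap
  (database alignments contain them routinely, and no standard rule
  exists for treating them as informative).
* APC on an all-zero matrix returns zeros; a zero overall mean with
  nonzero rows is an error, as is a normalization whose inter-score
  minimum is exactly zero.
* `rank_contacts()` truncates with a message when fewer candidates exist
  than requested; tie-breaking is lexicographic.
* Non-convergence of a site fit raises an error carrying the final
  gradient norm rather than returning a half-converged model.
* All randomness flows through the R RNG; every workflow takes a master
  seed and reruns are byte-identical, including tie handling.

# Limitations

Pseudo-likelihood at L ≫ 100 with M ≫ 10⁴ sequences is minutes-to-hours
on one core; the package targets desk-scale studies and method
development, not proteome scans. The mean-field solver inside IPA is
deliberately crude — it is the engine of a matching loop, not a contact
predictor. mmCIF support covers standard single-block `atom_site` loops,
not the full CIF grammar. No phylogenetic correction beyond identity
reweighting is applied.
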