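---
title: "Monte Carlo ligand design in chemical space with molmc"
author: "molmc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo ligand design in chemical space with molmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`molmc` implements a Metropolis Monte Carlo search over small organic
molecules. A current compound is repeatedly modified by elementary chemical
moves; each proposal is scored, and accepted when the score does not
decrease, or otherwise with probability

$$P(\Delta s) = \exp(-\beta\,\Delta s),$$

where $\Delta s = s_\mathrm{cur} - s_\mathrm{new}$ is the magnitude of the
score decrease and $\beta$ an inverse temperature. Note the convention: the
rule is stated for a *maximized* score, so only decreases are ever
penalized; with $\Delta s$ taken as a signed difference a worse move would
receive $P > 1$, which is why the package documents $\Delta s$ explicitly
as the decrease magnitude. Every 100th step the current structure is reset
to the best structure found so far, which limits drift away from good
regions at the cost of making deep "valleys" harder to cross.

Two objectives are provided:

* **Recovery mode** — dice similarity between count-based atom-pair
  fingerprints of the evolving compound and a fixed target. This mode is
  fully self-contained and is how the search machinery is validated: if the
  sampler is ergodic enough, it should re-discover a target constitution
  starting from benzene.
* **Design mode** — the composite
  $s = 0.8\,c + 0.1\,\mathrm{SA} + 0.05\,\mathrm{ESOL} + 0.05\,\mathrm{QED}$,
  where $c$ is the confidence score of a protein–ligand structure-prediction
  backend and the three biases (all normalized to $[0,1]$) penalize hard
  synthesis, poor solubility and non-drug-like property profiles. Real
  co-folding backends are wrapped behind the `PredictorBackend` contract;
  the package ships a deterministic `mockBackend()` whose confidence is a
  smooth function of simple descriptors with a configurable optimum, so the
  engine has a climbable objective in tests and protocol development.

## The move set

The nine atomistic moves and their standard selection probabilities are:
add a small group (.3), remove an atom (.2), change an atom type (.1),
insert an atom into a bond (.15), toggle a bond between single and double
(.025), form a ring (.025), break a ring (.05), toggle a ring's
aromaticity (.05), and rearrange a bond around a branched atom (.1).

Molecules are carried as Kekulé graphs (explicit bond orders 1–3, implicit
hydrogens, neutral atoms); aromaticity is perceived, not stored, using a
Hückel-style electron count over SSSR rings and fused-pair envelopes.
Decisions that the move descriptions leave open were fixed as follows:

* **Group inventory** for `addGroup`: CH3, OH, NH2, F, Cl, Br, =O, OCH3,
  SH, C#N, CF3 — common medicinal-chemistry substituents. The attachment
  point "replaces another group": usually an implicit hydrogen, with a
  25% chance of excising a small terminal substituent first, which lets the
  search swap functional groups in one move instead of a remove/add pair.
* **Element set** for atom-type changes and chain insertion:
  C, N, O, S, F, Cl, Br, P.
* **Ring window**: `formRing` closes rings of 3–8 atoms, drawing uniformly
  over eligible atom pairs; closures where *both* endpoints already lie in
  rings are excluded (they produce bridged cages rather than the fused or
  isolated rings typical of drug-like molecules).
* **Kekulé editing**: bond-order toggles act on the Kekulé graph
  everywhere, including inside aromatic rings. Opening an aromatic system
  locally is essential for gradual ring editing (for example, methylating a
  ring nitrogen requires passing through a non-aromatic intermediate);
  aromaticity is re-perceived after every edit, so valid patterns read as
  aromatic again automatically.
* **Aromatization** (`toggleAromatic`) searches for a Kekulé assignment of
  the chosen ring that makes every ring atom sp² and satisfies the electron
  count: ring atoms with exocyclic double bonds keep their ring bonds
  single and contribute no electrons, carbons must take exactly one in-ring
  double bond, and N/S atoms may either join a double bond or sit on a lone
  pair. This aromatizes pyridazinone- or pyrrole-type rings directly.
  Dearomatization saturates the ring completely, making the move its own
  inverse (cyclohexane ↔ benzene).
* **Disconnection**: removing a cut-vertex atom keeps the largest fragment
  (ties broken deterministically by the internal SMILES string).
* **Infeasible proposals**: `proposeMove` redraws the move kind and site up
  to 25 times; a fully infeasible proposal is returned as such and counted
  as a rejected MC step, keeping step accounting unbiased.
* Stereochemistry is ignored (stripped on input) and all atoms are kept
  neutral; charged input SMILES are neutralized on parsing.

## Fingerprints and dice similarity

The recovery objective uses Carhart-style atom pairs: one feature per
heavy-atom pair, combining each atom's element, heavy-atom degree (capped
at 7) and π-electron count (capped at 3, aromatic atoms counting one π
electron), with the topological distance (up to 30 bonds). Fingerprints
are count multisets; dice similarity is
$2\sum_i \min(x_i,y_i) / (\sum_i x_i + \sum_i y_i)$, so 1.0 certifies
identical fingerprints — at this feature resolution, recovery of the
target's constitution. Counting (rather than binary folding) is the
package default and matches the standard definition for atom-pair
fingerprints; the feature typing makes the fingerprint invariant to atom
order and to the Kekulé assignment inside aromatic rings.

## Recovery protocols

The dice landscape is rough: single chains at $\beta = 50$ reliably polish
a near-target structure (a one-feature-away start reaches dice 1.0 within
about a hundred steps) but often commit early to a wrong scaffold they
cannot leave. The two-stage protocol addresses exactly this:

* **Stage 1**: 30 replicas run *freely* (no within-replica reset) for 5000
  steps; every 500 steps all replicas are set to the best structure found
  by any replica. Free-running segments let replicas cross score valleys
  that the 100-step reset would cut short, and the synchronization pools
  scaffold discoveries.
* **Stage 2**: a single 10 000-step chain with reset-to-best every 100
  steps refines the stage-1 winner.

$\beta = 50$ keeps the acceptance rate low (of order 0.1 or below at
steady state) so that among the very many possible chemical changes mostly
those that improve similarity survive. Replica streams are seeded
deterministically from (master seed, replica, block), so a run is exactly
reproducible and independent of scheduling; ties in the global best are
broken by replica order. Synchronization uses the best across all history,
and the global best is never lost.

At desk scale the package's tests and the acceptance script use a reduced
protocol — 30 replicas × 3000 steps with synchronization every 500, then
one 8000-step chain, with up to three seeded attempts per target and
early stop at dice 1.0 — chosen so the full ligand-recovery benchmark runs
in minutes on one CPU while preserving the two-stage structure.

## Scoring components

* **SA score** (1 easy … 10 hard): fragment-contribution term over
  circular atom environments (radius 0–2) plus size, stereo-center, spiro,
  bridgehead, macrocycle and symmetry penalties, mapped through the
  published calibration onto 1–10. The environment contributions are the
  published frequency-derived values re-keyed to this package's own
  environment identifiers (iterated Weisfeiler–Lehman labels over the
  Kekulé graph, hashed; `inst/extdata/sa_env_scores.tsv`). The shipped
  table covers the packaged reference compounds exactly and the
  surrounding chemical space sampled by the move engine; unseen
  environments fall back to the rare-fragment default of −4, so SA is
  exact on the benchmark chemistry and approximate far from it. Potential
  stereocenters are counted constitution-level (sp³ carbons with four
  distinguishable substituents) even though the search itself ignores
  stereochemistry, because the synthesis-difficulty estimate should see
  them.
* **ESOL**: $\log_{10} S = 0.16 - 0.63\,\mathrm{clogP} - 0.0062\,\mathrm{MW}
  + 0.066\,\mathrm{RB} - 0.74\,\mathrm{AP}$ with clogP from re-keyed
  Crippen-style atomic contributions (same environment-table mechanism,
  radius 2 → 1 → 0 → element fallback), MW the molecular weight, RB the
  strict rotatable-bond count and AP the aromatic proportion of heavy
  atoms.
* **QED without the weight term**: the usual weighted geometric mean of
  asymmetric-double-sigmoid desirabilities over logP, H-bond acceptors and
  donors, polar surface area (Ertl, N/O contributions), rotatable bonds,
  aromatic rings and structural alerts (the published 116-pattern alert
  set, matched via OpenBabel SMARTS), with the molecular-weight
  desirability omitted and the remaining weights renormalized — the
  minimal reading of "neglecting the molecular weight factor".
* **Normalization**: SA is treated as maximal at or below a threshold
  (default 5.0) and decays linearly to 0 at SA = 10; the threshold value is
  not printed anywhere, and 5.0 is consistent with the reference rows (SA
  up to 4.8) behaving as maximal in the back-solved arithmetic. ESOL is
  mapped affinely onto $[0,1]$ between bounds calibrated by least squares
  against the three reference design runs' printed composites
  (`calibrateEsolNormalization()`, defaults lo = −13.705, hi = −1.486);
  the affine-clamp form is itself a choice, since only "normalized to lie
  between zero and one" is specified. With these defaults the three
  reference composites are reproduced to within ±0.001.

## Fragment mode

BRICS decomposition implements the published 16 link-type environments as
graph predicates; a bond is cleaved when its atoms match a permitted pair,
and each side receives a dummy atom labeled with its own link type.
Unlike the common convention that rewrites the 7–7 (alkene) cut as single
bonds to the dummies, `molmc` keeps the double bond on 7-labeled dummies so
that re-joining two fragments restores the exact constitution. Fragment
MC alternates adding a compatible library fragment at a random open
attachment point (probability .6) and removing a random inter-fragment
bond (.4), with $\beta = 5$ (fragment-sized jumps change the score far
more than atomistic steps, so a softer acceptance is needed) and
reset-to-best every 50 steps. Assemblies are H-capped before any scoring;
when a removal disconnects the assembly the larger side is kept (ties
broken by the internal SMILES string). A packaged, clearly synthetic
50-fragment library (drawn from the packaged reference ligands' BRICS
fragments) replaces an external database draw so the protocol runs
offline.

## What the mock backend does and does not show

The mock backend makes design mode testable: it is deterministic, bounded,
and has a known optimum, so a passing test shows the engine can climb a
smooth descriptor landscape under the full composite objective. It shares
nothing with a real co-folding confidence: no pose, no pocket geometry, no
saturation effects, and a far smoother landscape than a learned model
produces. Passing design-mode tests therefore validates the search
mechanics and score plumbing, not the chemistry of any particular protein
target; results against real targets depend entirely on the plugged-in
backend.

## Numerical choices and degenerate inputs

Valence checking uses fixed allowed valences (C 4, N 3, O 2, S 2/4/6,
P 3/5, halogens 1); molecules that fit no valence state are rejected at
parse time with a line-numbered error in list loaders. Single-atom
molecules have empty fingerprints; two empty fingerprints have dice 1 by
convention (identity), and an empty versus non-empty fingerprint has dice
0. Zero-step runs score the start compound once and return it. The
environment-table hashes are 31-bit polynomial string hashes; at the
shipped table sizes the collision probability is far below 1%, and a
collision would only perturb one environment's contribution.

## Problem sizes used by the packaged checks

Statistical checks use 100 000 Metropolis draws (3σ binomial bands),
10 000-proposal random-walk closure fuzzing over 20 seed molecules, and
4000-proposal move-frequency tests. Recovery checks run the reduced
two-stage protocol described above; design-mode checks use short chains
(60–80 steps) against the mock backend. These sizes were chosen so the
whole suite completes in minutes while keeping each statistical band
tight enough to detect real defects.

## Known limitations

* The sampler is validated constitution-level; stereochemistry and
  protonation states are out of scope.
* SA and logP are exact only on chemistry covered by the shipped
  environment tables; far outside it they degrade gracefully toward
  conservative defaults.
* Recovery of large, multi-ring targets at desk scale is stochastic: some
  seeds plateau below dice 1.0, which is why protocols run several seeded
  attempts.
* Aromaticity perception covers SSSR rings and fused-pair envelopes;
  exotic polycyclic aromatics (azulene-like odd-ring systems) may be
  classified conservatively as non-aromatic.
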