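---
title: "Chemical space annealing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical space annealing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemsa)
```

## The optimization problem

`chemsa` searches synthesizable chemical space for molecules that minimize a
user-supplied objective function. Two ideas define the method:

1. **Virtual synthesis as the move set.** New candidate molecules are never
   written atom-by-atom; they are assembled by cleaving existing molecules at
   retrosynthetically meaningful bonds (BRICS rules) and re-joining
   compatible fragment pairs. Every candidate therefore inherits a plausible
   one-step synthesis route by construction.
2. **Niching global optimization (annealing in chemical space).** A
   fixed-size *bank* of molecules is maintained. A niching radius `R_cut`,
   measured in Tanimoto distance between circular fingerprints, decides how
   a new trial molecule competes: trials close to an existing bank member
   compete *locally* with their nearest neighbour, while distant trials
   compete *globally* against the worst bank member. Annealing `R_cut` from
   broad to narrow shifts the search from exploration (preserving many
   diverse niches) to exploitation (refining the best ones).

## The metric space

Molecules are compared through binary circular (Morgan-type) fingerprints,
radius 2, 2048 bits, no counts and no chirality bits; the distance is
`1 - Tanimoto similarity`. These fingerprint parameters are frozen in the
package so every distance, radius and diversity number is reproducible. The
bit layout comes from the package's own deterministic hash, so absolute bit
indices differ from other toolkits while all distances behave the same way.

The chemistry layer underneath (SMILES parsing, canonicalization, valence
checking) is implemented in the package itself because no R cheminformatics
toolkit was available as a dependency. Two consequences matter to users:

* Canonical SMILES are this package's canonical form: stable, order
  independent, and a fixed point of re-canonicalization, but not textually
  identical to other software's canonical strings.
* Aromaticity is read from the input notation (lowercase atoms) and is not
  re-perceived from Kekulé structures, so `c1ccccc1` and `C1=CC=CC=C1` are
  treated as written. The bundled library and all fragments use the aromatic
  form consistently; users supplying their own files should do the same.

## Fragmentation and synthesis

Fragmentation generates, for every cleavable acyclic bond, the two
single-attachment-point fragments of a single cut. A bond is cleavable when
its two end atoms match one of the 16 BRICS chemical environments in an
allowed pairing; ring bonds are never cut. The attachment point is encoded
as an isotope-labelled dummy atom (`[5*]` carries link type 5), so fragments
round-trip through plain SMILES text. Fragments of three or fewer real atoms
are discarded (the filter is strictly "more than three atoms"). The
enumeration was cross-checked bond-for-bond, label-for-label against an
independent implementation of the published BRICS pattern table on 60
bundled molecules, and those results are frozen as test fixtures.

Two details of the rule table follow the modern published adaptation: the
secondary-amine environment (type 2) is folded into the general amine type
5, leaving row 2 of the 16×16 compatibility table inactive, and type-7
pairs (alkene carbons) re-join with a double bond while all other allowed
pairs form a single bond.

Virtual synthesis joins one fragment derived from a *seed* molecule with one
*partner* fragment. Partners come from two sources, mirroring the search's
diversity design: the fragments of one randomly chosen molecule of the
initial bank, and a random sample of 100 fragments from an external fragment
database. Each fragment is drawn with probability proportional to the mean
over its set fingerprint bits of `log(count + pseudocount)` under a
fragment-frequency table; the default table is uniform, which reduces to
uniform sampling. A corpus-derived table can be supplied to bias synthesis
toward substructures that are common in made chemistry.

**Trial budget.** Up to 60 chemicals are synthesized per seed and partner
source, implemented as 60 weighted sampling attempts whose unique successful
products are kept. An earlier draft used a much larger attempt budget with a
stop at 60 unique products; that variant produced roughly an order of
magnitude more unique objective evaluations per run than the operating
regime this method is designed for (a few thousand evaluations), so the
attempt-budget reading was adopted. With it, a default run performs on the
order of 10^3 unique evaluations, which is the regime in which the method's
efficiency claim over brute-force screening is meaningful.

## The annealing loop

A default run uses a bank of `n = 60` molecules, initialized with the best
60 of the supplied pool under the objective (ties broken lexicographically
by canonical SMILES). The initial radius is half the mean pairwise distance
of the initial bank — about 0.42–0.44 for drug-like pools, matching the
regime the defaults were tuned for — and decays by `0.4^0.05` per cycle,
reaching exactly 40% of its initial value at cycle 20 and staying constant
thereafter.

**One cycle is one seed batch**: six molecules are drawn uniformly from the
bank entries not yet used as seeds, each generates up to 60 + 60 trials as
above, and every trial is immediately evaluated and offered to the bank
(sequential updates; the bank may shift mid-batch). When every bank slot has
served as a seed the flags reset and seeding starts over; with the defaults,
50 cycles therefore make five full passes over the bank. Entries that
replace a bank slot mid-pass inherit the slot's used flag, keeping each pass
at exactly ten batches. We chose this reading of the cycle structure over
the alternative (a cycle = a full pass) because only this one reproduces the
expected evaluation budget of a few thousand unique molecules per run; under
the full-pass reading a run would cost ~3×10^4 evaluations and the radius
would floor only after 20 full passes, i.e. never effectively anneal within
a 50-pass budget.

The update rule for a trial with objective value `v`:

* a trial whose canonical SMILES already sits in the bank is discarded;
* else let `d*` be the distance to the nearest bank member (ties go to the
  better-valued entry, then lexicographic SMILES):
  * `d* ≤ R_cut`: replace that nearest member iff `v` is strictly better;
  * `d* > R_cut`: replace the worst-valued member iff `v` beats it;
  * otherwise discard.

Replace-worst is deliberately conditional on improvement, so the multiset of
bank values can only improve; best, mean and worst are monotone
non-increasing over a run, which the test suite asserts over 10^4
randomized updates.

Objective evaluations are cached by canonical SMILES and the run's history
reports the count of unique molecules evaluated per cycle — the honest
currency for comparing against screening budgets.

## Objectives

All objectives are minimized; maximize-better scores are complemented at
registration (`qed` is `1 - QED`). Built-ins: synthetic accessibility (`sa`,
in [1,10]), drug-likeness (`qed`), a logP surrogate (`logp`), Tanimoto
distance to a target (`simtarget`), and `external` for a user function or a
program that reads SMILES lines on stdin. The docking surrogates that a
production campaign would use plug in through `external`.

Two built-ins are deliberately approximate, which is adequate for their role
as optimization test functions but not for property prediction:

* `sa` follows the published score's architecture — a circular-fragment
  familiarity term minus size and ring-complexity penalties, rescaled to
  [1,10] — but calibrates fragment frequencies on the bundled ~300-molecule
  corpus rather than a hundred-million-compound database, and omits the
  stereo/macrocycle penalties (no stereochemistry support).
* `qed` uses the published desirability parameters and weights, but its
  ALOGP input is a crude additive logP and its structural-alerts count is
  fixed at zero (no SMARTS engine). Values stay in (0,1) with sensible
  ordering on drug-like inputs.

## Shape overlap

For 3D work the package scores pre-aligned conformers by atomic sphere
overlap: each atom is a sphere of 0.7 × its Bondi van der Waals radius, and
the score is the summed query–reference intersection volume divided by the
larger of the two self-overlap sums (both including the `i = j` full-sphere
terms, read literally from the double sums; the ordered/unordered choice
cancels in the ratio as long as it is consistent). The score is 1 exactly at
coordinate identity and 0 for disjoint sets, is symmetric, and is invariant
under a common rigid motion to within 1e-9. Two-sphere volumes use the
closed-form lens formula, validated against 10^6-sample Monte-Carlo
integration in the tests. Flexible alignment is out of scope: a Kabsch
superposition helper is provided for matched atom sets, and any external
alignment can be applied before scoring.

## Diversity metrics

`pairwise_distance_stats()` summarizes the unordered-pair Tanimoto
distances. `n_circles()` reports the sphere-packing diversity measure: the
largest subset of molecules whose pairwise distances all *exceed* the
threshold (default 0.7 — we read "within a distance threshold" as the
exclusivity criterion of the packing definition). Exact solving is a
branch-and-bound over the admissibility graph and is capped at 25 molecules;
larger sets use deterministic farthest-point packing, which is a lower
bound, and the report says which mode produced a number.

## Synthetic data: what the bundle emulates and what it does not

The package bundles ~300 drug-like molecules (common drugs, natural
products, and scaffold-enumerated analogues, stored in canonical aromatic
form) plus a small set of rigid 3D conformers. `make_fixtures()` derives
deterministic sub-pools, curated fragment databases (single-cut fragments,
leader-clustered at 0.7 similarity), and conformer files from them. This
stands in for the external libraries a real campaign would curate from
(vendor catalogues, fragment collections) so that every test and example
runs offline.

The stand-in preserves the *mechanics* the optimizer relies on — realistic
BRICS cleavability (several hundred cleavages across the bundle), drug-like
descriptor ranges, initial-bank radii around 0.42–0.44 — but it is three
orders of magnitude smaller than a vendor fragment collection. A green
optimization test therefore establishes that the annealing machinery
improves the bank reproducibly at the published evaluation budget; it does
not establish discovery-scale coverage of chemical space, and #Circles
numbers on bundle-sized sets are not comparable to library-scale ones.

## Numerical choices and degenerate inputs

* Ties everywhere are broken deterministically (value, then lexicographic
  canonical SMILES); runs with the same configuration and seed are
  byte-identical, and all randomness flows from the single `rng_seed`.
* Empty fingerprints (possible only for exotic inputs) fall back to SMILES
  identity for distances, with a warning.
* Fragment weights with a sparse user table can all be zero; sampling then
  falls back to uniform rather than failing.
* A seed with no BRICS bonds contributes no trials (logged, not an error);
  an objective that throws on a trial skips that trial and the run
  continues; an objective returning non-finite values is a hard error.
* Multi-fragment (salt) SMILES keep the largest covalent component, with a
  message.
* `curate_pool()` uses leader (first-seen) clustering after sorting input by
  canonical SMILES: order-independent, deterministic, and standard for
  non-redundancy curation, at the cost of not being a centroid method.

## Configuration

Run configuration files are JSON (schema mirroring `run_config()`); YAML was
avoided to keep the dependency footprint to packages guaranteed in scientific
R installations. The command-line interface (`inst/cli/chemsa.R`) exposes
`run`, `curate`, `fragdb`, `metrics`, `galign` and `fixtures` subcommands as
a thin layer over the exported functions, honours `--rng-seed`, and logs the
configuration, the `R_cut` trajectory and the unique-evaluation count.

## Known limitations

* No stereochemistry, tautomer handling, or aromaticity perception;
  chemistry outside the organic subset plus common charged groups is
  rejected at parse time rather than silently mangled.
* The SA and QED built-ins are surrogates (see above); absolute values
  should not be compared against other software's outputs.
* `n_circles(mode = "exact")` is exponential and hard-capped; published
  numbers at set sizes of hundreds are necessarily greedy lower bounds.
* Flexible molecular alignment is not implemented; shape scores are only as
  good as the alignment supplied.
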