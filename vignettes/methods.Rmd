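---
title: "Methods: trait-tree integration and parsimony reconstruction in fintegrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-tree integration and parsimony reconstruction in fintegrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fintegrate)
```

This vignette explains the models and procedures the package implements,
the choices made where the design was genuinely open, and what the tests do
and do not establish.

## Ontology-based inference of presence and absence

Annotations are flattened Entity–Quality statements: in taxon *t*,
anatomical entity *E* shows quality *q*. The quality `absent` implies the
entity is absent; any other quality implies it is present (one cannot
observe the shape of a structure that is not there). Entities live in a
small typed graph with four relations: `part_of`, `is_a`, `develops_from`
and `depends_on`. The girdle-necessity knowledge ("a paired fin is never
present without its supporting girdle") is stated as an explicit
`depends_on` edge rather than recovered from ontology axioms: an explicit
edge list is inspectable and testable, and nothing in the pipeline needs
OWL-level reasoning.

The closure rules are deliberately asymmetric:

* **Presence flows up composition and subsumption.** A quality on *E*
  implies presence of *E*, of everything *E* is `part_of` (transitively),
  and of every `is_a` supertype. It never flows through `develops_from` (a
  larval fin bud does not imply the adult fin), never through `depends_on`
  (a girdle does not imply its fin), and never downward (a fin does not
  imply any particular part).
* **Absence flows down composition/subsumption and through necessity.**
  `ABSENT(W)` implies absence of every part and every subtype of *W*, and
  of everything that `depends_on` or `develops_from` *W*. Absence of a part
  never implies absence of the whole.

Both closures are transitive reachability over a fixed edge set, so a
single pass is already the fixpoint; the tests check fixpoint,
monotonicity, the four non-inferences on the fin template, and equivalence
with an independent one-step-at-a-time oracle on random graphs.

One point the available descriptions leave open is whether absence should
propagate across `is_a` in both directions. We propagate absence downward
only (absence of the general class implies absence of each subtype in that
taxon); upward absence propagation would let "pectoral fin absent" imply
"paired fin absent" and hence "pelvic fin absent", which is clearly wrong.
Presence is propagated upward across `is_a` (a subtype present implies the
class present), mirroring subsumption.

Conflicting states are findings, never auto-resolved. Every (taxon, entity)
pair with both implied states is classified: both asserted at species rank
is a *true polymorphism*; both states at a supra-specific rank is an
*apparent polymorphism*; otherwise it is an *assertion-vs-inference
conflict*.

## Matrix coding and scrubbing

Cells carry one symbol — `1`/`0` asserted presence/absence, `2`
inferred-only presence, `3` inferred-only absence, `0&1` both states, `?`
missing — plus support counts by provenance. A cell with any author
assertion is coded asserted even when inference agrees. The symbol `3` is
reserved: real exports of this kind have contained no inferred-only
absence, but the synthetic generator produces it freely (an asserted girdle
absence yields an inferred fin absence), so the path is exercised rather
than hypothetical; it is logged whenever produced and merged as absence
with a warning.

Apparent polymorphisms are blanked to `?` at scrubbing: they say only that
unidentified member species differ, which cannot inform species-level
reconstruction. Species-level polymorphisms and conflicts are retained
through propagation — their presence blocks a higher-level state from
overwriting the species — and are down-coded only when the matrix is merged
onto the tree: a true polymorphism becomes the ambiguous state set {0,1},
a conflict becomes missing. This resolves an apparent tension between
"conflicts are replaced by ?" and "conflicts were retained": both are true,
at different stages, and retaining them through propagation is what gives
them their operational effect.

Missing-data percentages are always computed against an explicit
denominator (the species set of the final matrix, or the tip set of the
tree), because the two conventions give very different numbers and both are
legitimate summaries.

## Propagation

Only genus and family rows propagate; ranks above family are too old for a
single state to be a reasonable default for all descendants. Existing
species data are never replaced; a disagreeing higher-level state is
logged, split by whether the blocking species datum was asserted or
inferred. When genus and family both offer a state, the nearest ancestor
(genus) wins and the disagreement is logged — the original descriptions do
not specify this case, and nearest-ancestor is the conservative choice.
Every propagated cell records its source taxon, rank, and whether the
source state was asserted or inferred, so individual propagations can be
audited. The output matrix is species-only.

## Name reconciliation

Two passes: shared external identifiers first (robust to spelling), then
exact equality of normalized names. Normalization replaces underscores with
spaces, collapses whitespace, and truncates a well-formed trinomial to its
binomial; epithets must be at least two letters, so stray one-letter
suffixes are not mistaken for subspecies. Matching is case-sensitive after
normalization; there is no fuzzy matching and no synonym service — those
are explicitly out of scope, and ambiguity (duplicate identifiers on one
side, homonymous tip labels) is flagged rather than guessed. A taxon
matched by identifier is excluded from the name pass, so identifier matches
always win; name discrepancies under identifier matches are recorded.

## Parsimony on multifurcating trees

The character is binary and transitions are unit-cost in both directions.
One postorder dynamic program computes, per node and state, the minimum
subtree cost (Hartigan's generalization of Fitch, exact on hard
polytomies), the exact count of minimum-cost sub-labelings, and the
minimum/maximum number of gain edges among them. An MPR is an assignment of
states to internal nodes achieving the minimum total length; ambiguous tips
(polymorphic or missing) resolve to the parent state at zero cost, so they
neither multiply counts nor create terminal changes. Loss bounds need no
separate program: gains + losses equals the length in every MPR.

Counting uses exact base-10⁴ big-integer arithmetic implemented in the
package; MPR counts on large unresolved trees exceed 10¹⁴ and counting in
floating point would silently lose exactness. Doubles appear only when
counts become sampling weights, where relative error of order 10⁻¹⁵ is
irrelevant. Sampling draws the root state and each child state with
probability proportional to the exact sub-counts, which makes the draw
uniform over the MPR set; uniformity is tested by chi-square against full
enumeration on instances with few MPRs.

Polytomies are treated as hard (simultaneous divergence) by the DP; the
soft-polytomy view is provided by seeded random resolutions, each built by
repeatedly joining two uniformly chosen child lineages. A regain is a 0→1
edge in an MPR; when the root state is ambiguous, gains are counted under
each MPR's own root labeling. `min_regains_over_resolutions()` reports the
exact minimum gain count over replicates and returns the achieving
topology. Note the direction of the resolution effect: every labeling of
the polytomous tree extends to any refinement at equal cost, so a binary
resolution can only preserve or reduce the parsimony length — this is
precisely why resolving polytomies can dissolve spurious regains.

Inferred-only presence (`2`) enters the reconstruction as presence: the
separate symbol tracks provenance, not a third biological state.

## The synthetic study system

The generator is the package's evidence base, so its defaults were fixed
once, to resemble the real data situation at desk scale, and are not tuned
against test outcomes:

| parameter | default | rationale |
|---|---|---|
| `n_families`, `genera_per_family`, `species_per_genus` | 12, 2–5, 2–8 | a few hundred species: large enough for propagation and polytomy effects, small enough for seconds-scale runs |
| `event_count_loss`, `event_count_regain` | 6, 2 | losses several times more common than regains |
| `species_coverage` | 0.25 | direct annotations are the minority; most cells must come from inference and propagation |
| `indirect_fraction` | 0.8 | most real annotations state a part quality or girdle absence, not the fin itself |
| `higher_level_fraction` | 0.3 | a substantial share of literature statements attach to genera/families |
| `conflict_rate` | 0.02 | conflicts are rare but must be surfaced |
| `polytomy_fraction` | 0.25 | species-level trees are heavily unresolved |
| `mismatch_rate`, `extra_tip_rate` | 0.05, 0.15 | taxonomies disagree: some names fail to match, and the tree holds many species unknown to the trait taxonomy |
| `xref_fraction` | 0.5 | only part of the taxonomy carries external identifiers, which is what makes the two-pass reconciliation worthwhile |

Trees are built by random sequential joining within genera, then families,
so taxonomy groups are monophyletic and higher-level propagation is
semantically aligned with clades. Name perturbation is a deterministic
`_x` suffix, so unmatched tips are recognizable in tests.

**Planted histories.** Presence is ancestral; losses and regains are placed
on branches and tip states derived by replay. In sparse mode the placement
enforces structural conditions — losses pairwise non-nested with distinct
parent nodes and a reserved presence-only sibling clade each; each regain
inside its own loss clade with at least three disjoint residual absent
fragments around it — under which an edge-disjoint-path argument makes the
planted history the unique-cost optimum: the parsimony length equals the
number of planted events and the exact minimum gain count equals the
number of regains. This is what licenses the end-to-end recovery test
(pipeline ASR length = planted losses + regains) as an equality rather
than a bound. Note that the stated sparse constraint is necessarily
asymmetric: a regain branch must sit inside a lost clade to be replayable
at all, so "non-nested" applies among losses and among regains, not
between a regain and its host loss. Impossible placements (tree too small
for the requested events) are an error, never silently relaxed. Nested
mode places events without the structural guarantees; recovery claims then
weaken to inequalities.

**What the generator does not emulate.** No branch lengths, no molecular
evolution, no rate heterogeneity, no fossil sampling beyond an extinct
flag, no correlated characters, and conflicts are injected independently
per species rather than clustered by study. Passing tests therefore show
that the pipeline's bookkeeping and algorithms are correct under known
ground truth — not that any particular biological dataset is free of the
curation issues the generator does not model.

## Numerical and degenerate-input choices

Disallowed tip states use a large finite cost sentinel (10⁹) that cannot
propagate because one state of every tip is free. An all-missing character
has length 0 with a warning (and two trivial MPRs: the two constant
labelings). Ties in the DP are kept, not broken: counts, bounds and
sampling all operate over the full tie structure. All stochastic code runs
under a locally seeded RNG that restores the caller's state, and a master
seed fans out to per-stage seeds by fixed offsets, so pipeline artifacts
are byte-reproducible.

## Problem sizes in the test suite

The oracle sweep checks length, MPR count and per-type bounds against
exhaustive enumeration on 1000 random trees of up to 12 tips (binary and
multifurcating, with missing and polymorphic tips). The propagation
contract runs on 100 seeded scenarios of roughly 30 species; the recovery
equality on 50 scenarios of up to 200 tips, both characters each; sampler
uniformity uses 10,000 draws at three fixed seeds on instances with at most
24 enumerable MPRs. These sizes keep the full suite around a minute while
leaving the properties non-trivial.

## Known limitations

* Characters are binary presence/absence; multistate characters and
  asymmetric step costs are out of scope.
* The NeXML reader consumes only the standard-cells subset with binary
  states and cell-level provenance metadata, and the provenance predicate
  is configurable because exporters differ; it is not a general NeXML
  parser, and there is no NeXML writer.
* Without branch lengths there is no likelihood model; parsimony bounds and
  MPR summaries are the entire inferential output, and regain minima over
  random resolutions are conditional on the resolutions visited.
* Reconciliation is deliberately strict; taxa whose names changed between
  taxonomies remain unmatched and are only categorized, not rescued.
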