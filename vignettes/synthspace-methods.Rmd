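---
title: "Synthesizable-space sampling, benchmarking, and analog reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizable-space sampling, benchmarking, and analog reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`synthspace` operationalizes one idea: restrict generative retrosynthesis to a
*synthesizable chemical space*, the closure of a building-block (BB) catalog
under a registry of reaction-SMARTS templates (RXNs) with at most five forward
steps. This vignette is the package's own account of the models and numerical
choices behind each component, in the order data flows through them.

## The space and its compatibility index

A space is a pair (library, registry). Building blocks are held as canonical
isomeric SMILES — every equality comparison in the package goes through one
canonicalization dialect (RDKit's), which makes "same molecule" a string
equality and keeps stereochemistry intact. Multi-fragment (salt) SMILES are
rejected at load time because templates operate on single reactant species.

"Compatible" is read as a plain substructure match: BB *b* can fill slot *s*
of template *t* iff *b* matches *t*'s *s*-th reactant pattern. No
protecting-group or chemoselectivity logic is layered on top; template
authors are expected to encode selectivity in the patterns themselves (the
bundled amine patterns, for instance, exclude amide and sulfonamide nitrogens
so products do not trivially re-react at the newly formed bond). Aromaticity
follows the toolkit's default perception model. Stereochemistry in patterns
and BBs is preserved rather than stripped; match counts may therefore differ
from pipelines that canonicalize it away.

The compatibility index — the map (template, slot) → matching BBs — is stored
as a long tibble and is checked in the test suite against an exhaustive
double loop over reactant patterns.

## Probabilistic route sampling

Routes are grown forward. The initial template is drawn with probability
proportional to

> w(t) = ∏ over slots s of |pool(t, s)|,

the number of realizable reactant tuples. This is the natural reading of
"guided by the number of compatible building blocks": it weights templates by
how much chemistry they can actually express and degenerates to weight zero
whenever any slot is empty. Slots are then filled with uniformly drawn pool
members. Each later step chooses uniformly among templates for which the
current intermediate matches at least one slot and every other slot has a
nonempty pool; the intermediate's slot is drawn uniformly among its matches.
When a forward application yields several products, the sampler picks one
uniformly — at sampling time there is no reference product to prefer. Growth
stops when nothing matches or at `max_steps` (default 5, the cap defining the
space). Intermediates are never returned to the BB pool.

Branched mode grows two independent sub-trees within the step budget, then
searches the registry exhaustively for a template in which both tree roots
can sit in distinct slots; feasible merges are tried in random order. Because
merge feasibility depends on both intermediates retaining a reactive handle,
attempts can fail; the sampler retries up to `branch_attempts` (default 50)
fresh tree pairs before raising a typed error. Every branched route satisfies
the defining predicate: at least one step consumes two or more intermediates
(`route_is_branched()`).

All randomness flows through R's RNG; passing `seed` in `sampler_config()`
runs the sampler in a private RNG scope, so identical configurations
reproduce identical routes byte-for-byte without disturbing the caller's RNG.

## Records and corpora

A training record lists a route in retrosynthetic order — the first reaction
produces the target — with template ids expanded to their full SMARTS and a
`building_blocks` section computed by the *non-product rule*: reactants that
appear as no reaction's product. For branched routes the retro order is the
reverse topological order with ties broken by step index descending; the
inverse mapping (`record_to_route()`) topologically re-sorts, so records with
shuffled but consistent reaction lists still convert. The JSON layout is
versioned as `retro-record/1`; the instruction string is a single fixed
constant, since only the input SMILES varies between prompts.

`generate_corpus()` optionally enforces a drug-likeness filter on targets.
The predicate is Lipinski's rule of five (MW ≤ 500, cLogP ≤ 5, donors ≤ 5,
acceptors ≤ 10) — the exact filter used in the original experiments is not
published, and the rule of five is the field's default proxy. Rejected draws
are resampled under a budget of 50·n and counted in the manifest.

## The inference contract and strict parsing

A backend is any function `(target, sampling_params) → completion text`. The
bundled `sampling_params()` defaults (temperature 0.1, top-p 0.1) mirror the
low-temperature setting used for reproducible benchmarking. Two reference
backends exist: `replay_backend()` (stored golden responses) and
`corrupting_backend()`, which injects three orthogonal error classes for
calibration — trailing prose (breaks JSON parsability only), a decoy product
that no template can produce (breaks Good Products only), and an appended
decoy reactant matching no slot (breaks Matched Reactants only). Keeping the
classes orthogonal is what makes the injected rates recoverable from the
metric estimates.

`parse_response()` is deliberately strict: one JSON object, exactly the
`reactions` and `building_blocks` keys, fully typed fields; any leading or
trailing non-JSON text fails. Partially valid JSON is not salvaged —
parsability is itself one of the benchmarks, and a lenient parser would blur
it. Parse failures are returned as data (`schema_errors`), never raised, and
the parser is fuzz-tested against arbitrary byte strings.

## Benchmark definitions and denominators

Valid JSON is the fraction of *all* responses that survive the strict parse.
The five downstream metrics are computed over the parse-ok subset only — an
unparsable response contains nothing scoreable — with per-reaction metrics
(Template Memorization, Matched Reactants, Good Products) denominated in
predicted reactions and per-response metrics (BB Selection) in responses;
Valid SMILES counts every reactant, product, and building-block string per
occurrence. Published summaries of this kind do not state how their
denominators nest; this nesting is explicit here so numbers are
reproducible.

Three definitional choices matter:

* **Template Memorization** is exact string equality after whitespace
  trimming, not SMARTS-graph equivalence — the criterion is memorization of
  the provided text.
* **Matched Reactants** asks for a *perfect* bipartite matching between the
  reaction's reactants and the template's slots (order-insensitive, since
  slot order in generated text is not meaningful); reactant count must equal
  template arity.
* **Good Products** asks whether *some* injective assignment of reactants to
  slots forward-applies to the predicted product (compared as canonical
  SMILES). Extra, unused reactants therefore fail Matched Reactants but not
  Good Products — the two metrics probe different failures and stay
  independently calibratable.

## Reconstruction

`reconstruct()` turns a parsed response into molecules with executable
routes:

1. Unknown-template reactions are dropped (with a warning); the rest are
   topologically ordered forward.
2. Predicted reactants are assigned to slots by the same bipartite matching
   as the benchmark; all perfect matchings are enumerated.
3. Each predicted BB is replaced by its `k_neighbors` most similar library
   BBs *from the (template, slot) pool* — the search space constraint that
   guarantees the substitute can actually react. A predicted BB present in
   the pool is always its own rank-1 candidate (similarity 1), so exact
   reconstruction dominates analog generation. Predicted BBs absent from the
   library are substituted; setting `allow_novel_bbs = TRUE` additionally
   keeps a parseable novel BB as its own (non-library) candidate.
4. Candidate tuples are forward-applied in batch. A tuple with several
   regio- or symmetry-distinct products forks the beam — each product becomes
   its own state, scored by the similarity of the realized intermediate to
   the predicted intermediate of that step (the intermediates are included
   in responses precisely to guide this). A greedy single-product choice was
   observed to lose exact paths on substrates with two equivalent reactive
   handles, which is why the fork exists; `select_product()` (string-trigram
   argmax, identity short-circuit, lexicographic ties) remains the rule for
   choosing a single product where one is required.
5. States are deduplicated and pruned to `beam_width` by cumulative score;
   final molecules are deduplicated by canonical SMILES, ranked by
   Morgan-Tanimoto similarity to the target, and returned with their routes.
   Every emitted route re-validates against forward application —
   synthesizability by construction.

Defaults: `k_neighbors = 2` (the "top two most similar BBs" choice),
`max_analogs = 10`, `beam_width = 8` (wide enough that the exact path, which
scores 1 at every step, is never pruned). `expand_hit()` widens the search
(`k_neighbors = 4`, beam ≥ 50) to fill a 50-analog budget before applying the
scaffold-retention filter used for local hit expansion.

## Similarity scorers

The reporting metric is Tanimoto similarity |A∩B|/|A∪B| over 4096-bit,
radius-2 hashed Morgan fingerprints; the bit width follows the reporting
convention of the source experiments, the radius is the community default
(the original does not state it). The ratio is computed in R from the
fingerprints' on-bit sets, with RDKit's own Tanimoto kept as an independent
oracle in the tests. Identical canonical molecules score exactly 1 by
construction (this also covers empty-fingerprint corner cases). Scaffold
similarity applies the same metric to Murcko frameworks, with acyclic
molecules compared whole; the 2D-pharmacophore flavor delegates to the Gobbi
pharmacophore fingerprint. The SMILES-string representation used in
nearest-neighbor search is character-trigram Jaccard over canonical SMILES —
the original's exact string algorithm is unpublished, and trigram Jaccard is
a standard, order-robust choice. `batch_similarity_report()` follows the
convention of counting exactly reconstructed targets with similarity 1, with
an excluding-exact mean and an explicit coverage field for targets that
produced no analogs.

## The toy space: what it emulates, and what it does not

`generate_toy_space()` stands in for catalogs of hundreds of thousands of
BBs and ~100-template registries with a seeded library of a few dozen BBs
over five classic reactions (amide coupling, Suzuki coupling, sulfonamide
formation, reductive amination, ester formation). Its design rules:

* every template slot has ≥ 2 compatible BBs (so ablating any single BB
  leaves every slot realizable);
* bifunctional BBs — acids, amines, aldehydes, sulfonyl chlorides and
  alcohols carrying an aryl bromide or boronic-acid handle — are well
  represented, and every bifunctional class contains ≥ 2 positional isomers.
  This mirrors the redundancy of real catalogs and is what makes multi-step
  growth, two-tree merges, and single-BB ablation recovery reachable at toy
  scale;
* realizability of both linear and branched sampling is probed before the
  space is returned.

What passing tests on this space show is *mechanical* correctness:
serialization round-trips, metric ceilings, oracle equivalences, calibrated
degradation. What they cannot show is chemical generality — real catalogs
have heavier functional-group interactions, protecting-group chemistry, and
far sparser compatibility pools, so absolute rates measured here do not
transfer to production catalogs.

## Numerical and engineering choices

* **Problem sizes.** The package's own evaluation uses a 50-BB/5-template
  space, 200-record mixed corpora for ceiling/round-trip/ablation studies,
  and 1,000 linear responses for corruption calibration — sizes chosen so the
  full property suite reruns in a few minutes on one core while keeping
  binomial confidence intervals tight enough to detect miscalibration.
* **Chemistry engine.** All molecular primitives run in one persistent RDKit
  worker subprocess speaking JSON-lines over stdin/stdout; the R side
  memoises canonicalizations, slot matches, reaction applications and
  fingerprints, so repeated queries never cross the pipe twice. The worker
  uses no randomness.
* **Determinism.** Every stochastic component takes a seed and runs in a
  private RNG scope; corpus files are byte-identical across runs, and CLI
  outputs round floating-point fields to 6 decimals at write time.
* **Degenerate inputs.** Empty libraries/registries, all-zero template
  weights, empty slot pools, empty product sets, unparsable SMILES and
  malformed records each raise typed conditions
  (`synthspace_empty_library`, `synthspace_no_realizable_template`, …) so
  callers can distinguish "cannot" from "bug".
* **Known limitations.** Reaction templates are applied without condition,
  yield, or selectivity modeling; purchasability of novel BBs is exposed only
  as a hook (no supplier queries); the branched sampler merges exactly two
  trees (deeper convergence arises only by composition); and template-slot
  assignment trusts the template author's patterns — a pattern matching an
  unintended site will be used as written.
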