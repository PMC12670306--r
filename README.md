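# synthspace

Tools for working with a *synthesizable chemical space*: the set of molecules
reachable from a catalog of purchasable building blocks (BBs) through a fixed
registry of reaction-SMARTS templates (RXNs) in at most five forward steps.
`synthspace` is aimed at groups training and evaluating language models for
retrosynthesis: it generates the training corpora such models learn from,
benchmarks the chemical validity of their raw text responses, and converts
their predictions back into molecules that are synthesizable *by
construction* — either the requested target or its nearest synthesizable
analogs, each with an executable route.

The package implements four connected pieces of machinery:

1. **Space definition** (`bb_library()`, `template_registry()`,
   `build_compatibility_index()`, `synth_space()`): load `.smi` building-block
   files and reaction-SMARTS TSVs, validate them, and precompute which BBs can
   fill which reactant slot of which template.
2. **Route sampling and corpora** (`sample_routes()`, `generate_corpus()`):
   grow synthesis routes forward — the initial template *t* is drawn with
   probability proportional to its number of realizable reactant tuples,
   w(t) = ∏ₛ |pool(t, s)|, slots are filled with uniformly drawn compatible
   BBs, and the running intermediate recruits further templates until nothing
   matches or the five-step cap is hit. Branched mode grows two trees and
   merges their intermediates in one template application. Routes serialize to
   retrosynthesis-ordered JSONL records (`"retro-record/1"`).
3. **Response benchmarking** (`parse_response()`, `benchmark_report()`): a
   strict JSON parser plus the six response-quality metrics — Valid JSON,
   Template Memorization, BB Selection, Valid SMILES, Matched Reactants
   (order-insensitive bipartite matching of reactants to slot patterns), and
   Good Products (forward derivability of the predicted product, compared as
   canonical SMILES).
4. **Reconstruction** (`reconstruct()`, `nn_search()`, `expand_hit()`): replay
   the predicted retro reactions forward, substituting each predicted BB by
   its most similar library BBs *constrained to the predicted template slot*
   (Tanimoto over 4096-bit Morgan fingerprints, or character-trigram Jaccard
   over canonical SMILES), beam-search the candidate combinations, and rank
   the resulting molecules by similarity to the target.

All molecular primitives (canonicalization, SMARTS matching, reaction
application, fingerprints, Murcko scaffolds) are delegated to RDKit through a
persistent Python worker process, so results match the de-facto standard
toolkit exactly.

## Worked example

```r
library(synthspace)

space <- generate_toy_space(seed = 7, n_bbs = 50)
space
#> <synth_space 'toy-50-bbs': 50 building blocks x 5 templates, 104 index entries>

route <- sample_linear_route(space, sampler_config(seed = 11))
route
#> <synthesis_route: 3 step(s) -> CCC(=O)Nc1ccc(-c2ccc(N(C)S(=O)(=O)c3ccc(OC)cc3)cc2)cc1>
#>   1. RXN 76: CCC(=O)O + Nc1ccc(B(O)O)cc1 >> CCC(=O)Nc1ccc(B(O)O)cc1
#>   2. RXN 72: CNc1ccc(Br)cc1 + CCC(=O)Nc1ccc(B(O)O)cc1 >> CCC(=O)Nc1ccc(-c2ccc(NC)cc2)cc1
#>   3. RXN 31: COc1ccc(S(=O)(=O)Cl)cc1 + CCC(=O)Nc1ccc(-c2ccc(NC)cc2)cc1 >> CCC(=O)Nc1ccc(-c2ccc(N(C)S(=O)(=O)c3ccc(OC)cc3)cc2)cc1
```

The route reads forward: propionic acid is coupled to 4-aminophenylboronic
acid (RXN 76, amide coupling), the surviving boronate is arylated with
4-bromo-N-methylaniline (RXN 72, Suzuki coupling), and the remaining
secondary aniline is sulfonylated (RXN 31). Serializing, replaying and
benchmarking a golden corpus reproduces the training-data ceiling:

```r
g <- golden_eval_set(space, 100, sampler_config(mode = "mixed", seed = 42))
batch <- run_batch(replay_backend(g$replay_map), g$targets)
benchmark_report(batch, space$registry)
#> <benchmark_report: 100 responses (100 parse-ok), registry 'RXN-mini'>
#>   valid_json             100.00%  (100/100)
#>   template_memorization  100.00%  (399/399)
#>   bb_selection           100.00%  (100/100)
#>   valid_smiles           100.00%  (1687/1687)
#>   matched_reactants      100.00%  (399/399)
#>   good_products          100.00%  (399/399)
```

Reconstruction with the full library recovers every target exactly; after
deleting a route's building block it returns ranked synthesizable analogs
instead:

```r
res <- reconstruct(batch$parsed[[1]], space)
res$exact_match
#> [1] TRUE

victim <- g$records[[batch$target[1]]]$building_blocks[1]
res <- reconstruct(batch$parsed[[1]], remove_building_block(space, victim))
res$exact_match
#> [1] FALSE
head(tidy(res)[, c("smiles", "similarity")], 3)
# ranked analogs, each carrying an executable route in res$analogs$route
```

A thin command-line interface wraps the same functions
(`exec/synthspace`): `make-fixtures`, `sample-routes`, `build-corpus`,
`benchmark`, `reconstruct`, and `expand-hit` (scaffold-constrained hit
expansion).

## The methods vignette

`vignettes/synthspace-methods.Rmd` documents the model and its assumptions:
the probabilistic route sampler, the record schema, the benchmark
denominators, the beam-search reconstruction algorithm, all tunable
parameters with their defaults, and what the toy space does and does not
emulate about real catalog chemistry.
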