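# Shared fixtures, built once per test run and cached in this environment.
# All chemistry fixtures are generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

toy_space_fixture <- function(seed = 7L, n_bbs = 50L) {
  cached(sprintf("space-%d-%d", seed, n_bbs), generate_toy_space(seed, n_bbs))
}

golden_fixture <- function(n = 40L, mode = "mixed", seed = 42L,
                           space = toy_space_fixture()) {
  cached(
    sprintf("golden-%d-%s-%d-%s", n, mode, seed, space$label),
    golden_eval_set(space, n, sampler_config(mode = mode, seed = seed))
  )
}

golden_batch_fixture <- function(...) {
  g <- golden_fixture(...)
  key <- sprintf("batch-%d", length(g$targets))
  cached(key, run_batch(replay_backend(g$replay_map), g$targets))
}

amide_smarts <- function() toy_templates()$smarts[1]

# A minimal one-template space: amide coupling only, with amine patterns that
# exclude the amide product, so every route is exactly one step.
amide_only_space <- function() {
  cached("amide-only", {
    registry <- template_registry(
      data.frame(template_id = 76L, name = "amide coupling",
                 smarts = amide_smarts()),
      label = "amide-only"
    )
    library <- bb_library(c("CC(=O)O", "CCC(=O)O", "CN", "CCN"))
    synth_space(library, registry, label = "amide-only")
  })
}

# Character-trigram Jaccard reimplemented independently for oracle checks.
oracle_trigram_jaccard <- function(a, b) {
  grams <- function(s) {
    if (nchar(s) < 3L) return(s)
    unique(substring(s, seq_len(nchar(s) - 2L), seq(3L, nchar(s))))
  }
  ga <- grams(a); gb <- grams(b)
  length(intersect(ga, gb)) / length(union(ga, gb))
}
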