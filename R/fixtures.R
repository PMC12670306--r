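# Seeded miniature chemical spaces: a stand-in for the hundreds of thousands
# of catalog building blocks and the full reaction-template sets, small enough
# that every invariant can be checked exhaustively but rich enough to support
# multi-step linear and branched synthesis.

toy_template_table <- function() {
  tribble(
    ~template_id, ~name, ~smarts,
    76L, "amide coupling",
    "[C:1](=[O:2])[OX2H1].[NX3;H2,H1;!$(NC=O);!$(NS(=O)=O);!$(N-O):3]>>[C:1](=[O:2])[N:3]",
    72L, "Suzuki coupling",
    "[c:1][Br].[c:2]B(O)O>>[c:1][c:2]",
    31L, "sulfonamide formation",
    "[S:1](=[O:2])(=[O:3])Cl.[NX3;H2,H1;!$(NC=O);!$(NS(=O)=O);!$(N-O):4]>>[S:1](=[O:2])(=[O:3])[N:4]",
    47L, "reductive amination",
    "[CX3H1:1]=[OX1].[NX3;H2,H1;!$(NC=O);!$(NS(=O)=O);!$(N-O):2]>>[C:1][N:2]",
    58L, "ester formation",
    "[C:1](=[O:2])[OX2H1].[OX2H1:3][CX4:4]>>[C:1](=[O:2])[O:3][C:4]"
  )
}

#' The toy reaction-template registry
#'
#' Five classic two-component reactions (amide coupling, Suzuki coupling,
#' sulfonamide formation, reductive amination, ester formation) written
#' against the toolkit's default aromaticity model. Amine patterns exclude
#' amide/sulfonamide nitrogens so products do not trivially re-react at the
#' newly formed bond.
#'
#' @param label Registry label.
#' @return A `template_registry`.
#' @export
toy_templates <- function(label = "RXN-mini") {
  template_registry(toy_template_table(), label = label)
}

# Core building blocks guaranteeing >=2 compatible BBs per template slot and
# the bifunctional species (acid+aryl bromide, amine+boronic acid, halide or
# boronic acid carrying an aldehyde) that make multi-step growth and
# two-tree merges reachable.
toy_core_bbs <- function() {
  c(
    # carboxylic acids (several carrying a cross-coupling handle, so amide and
    # ester products can stay reactive for later or merging steps)
    "CC(=O)O", "CCC(=O)O", "OC(=O)C1CC1", "OC(=O)c1ccccc1",
    "OC(=O)c1ccc(Br)cc1", "OC(=O)Cc1ccc(Br)cc1", "OC(=O)c1ccc(B(O)O)cc1",
    "OC(=O)c1cccc(B(O)O)c1", "OC(=O)CCc1ccccc1",
    # amines (primary, secondary, and halide/boronate-bearing)
    "CN", "CCN", "NCc1ccccc1", "NC1CCCC1", "C1CCNCC1", "CNC",
    "NCc1ccc(B(O)O)cc1", "Nc1ccc(B(O)O)cc1", "Nc1ccc(Br)cc1",
    "NCc1ccc(Br)cc1", "CNc1ccc(Br)cc1",
    # boronic acids (each bifunctional class has >=2 members, mirroring the
    # positional-isomer redundancy of real catalogs)
    "OB(O)c1ccccc1", "OB(O)c1ccc(C)cc1", "OB(O)c1ccc(C=O)cc1",
    "O=Cc1cccc(B(O)O)c1",
    # aryl halides
    "Brc1ccccc1", "Brc1ccc(C)cc1", "Brc1ccc(C=O)cc1", "O=Cc1cccc(Br)c1",
    # sulfonyl chlorides
    "CS(=O)(=O)Cl", "O=S(=O)(Cl)c1ccccc1", "O=S(=O)(Cl)c1ccc(C)cc1",
    "ClS(=O)(=O)c1ccc(Br)cc1", "ClS(=O)(=O)c1cccc(Br)c1",
    # aldehydes
    "CC=O", "O=Cc1ccccc1", "O=CC1CC1",
    # alcohols
    "CCO", "OCc1ccccc1", "OC1CCCCC1", "OCc1ccc(Br)cc1", "OCc1cccc(Br)c1",
    "OCc1ccc(B(O)O)cc1", "OCc1cccc(B(O)O)c1"
  )
}

# Decoration grid for extra diversity beyond the core.
toy_extra_bbs <- function() {
  # Groups written with the aryl attachment point last, so pasting the ring on
  # the right yields the intended functional group (e.g. "OC(=O)" + ring ->
  # aryl carboxylic acid, "ClS(=O)(=O)" + ring -> aryl sulfonyl chloride).
  groups <- c("OC(=O)", "N", "CN", "OB(O)", "Br", "ClS(=O)(=O)", "O=C", "OC", "OC(=O)C")
  aryl <- c("c1ccccc1", "c1ccc(C)cc1", "c1ccc(F)cc1", "c1cccnc1", "c1ccc(OC)cc1",
            "c1ccsc1")
  out <- character()
  for (g in groups) {
    for (a in aryl) {
      out <- c(out, paste0(g, a)) # directly attached
    }
  }
  # a few aliphatic variants
  out <- c(
    out,
    "OC(=O)CC1CCCCC1", "OC(=O)C1CCOCC1", "NC1CCCCC1", "NCC1CCCCC1",
    "OCC1CCCCC1", "OCCC1CC1", "CC(C)C=O", "O=CC1CCCCC1", "CCCCN", "CCCCO",
    "CC(C)(C)C(=O)O", "CCS(=O)(=O)Cl"
  )
  out
}

#' Generate a seeded toy synthesizable space
#'
#' Enumerates building blocks from small scaffolds decorated with the
#' functional groups the registry consumes (carboxylic acids, amines, boronic
#' acids, aryl bromides, sulfonyl chlorides, aldehydes, alcohols), keeps a
#' fixed core that guarantees realizability, and fills up to `n_bbs` with a
#' seeded draw from the decoration grid. The returned space is verified:
#' every template slot has at least 2 compatible building blocks, and both a
#' linear and a branched route can be sampled.
#'
#' @param seed Integer seed; the same seed always yields the same space.
#' @param n_bbs Library size (at least 20; at most the enumerable total).
#' @return A `synth_space` whose `seed` is recorded as an attribute.
#' @export
generate_toy_space <- function(seed = 1L, n_bbs = 50L) {
  if (n_bbs < 20L) {
    stop_synthspace("space_unrealizable", "a toy space needs at least 20 building blocks")
  }
  registry <- toy_templates()
  core <- cs_canon_strict(toy_core_bbs())
  extras <- setdiff(unique(cs_canon_strict(toy_extra_bbs())), core)
  total <- length(core) + length(extras)
  if (n_bbs > total) {
    stop_synthspace(
      "space_unrealizable",
      sprintf("n_bbs = %d exceeds the %d enumerable toy building blocks", n_bbs, total)
    )
  }
  smiles <- with_seed(seed, {
    extra_n <- n_bbs - length(core)
    c(core, if (extra_n > 0L) sample(extras, extra_n))
  })
  library <- bb_library(smiles, bb_id = sprintf("BB%04d", seq_along(smiles)),
                        source = "train")
  space <- synth_space(library, registry, label = sprintf("toy-%d-bbs", n_bbs))
  pools <- count(as_tibble(space$index), .data$template_id, .data$slot)
  expected <- sum(registry$arity)
  if (nrow(pools) < expected || any(pools$n < 2L)) {
    stop_synthspace(
      "space_unrealizable",
      "generated space violates the >=2 compatible building blocks per slot invariant"
    )
  }
  # Probe realizability of both sampling modes.
  probe <- sampler_config(max_steps = 5L, seed = seed)
  sample_linear_route(space, probe)
  sample_branched_route(space, sampler_config(max_steps = 5L, mode = "branched", seed = seed))
  attr(space, "seed") <- seed
  space
}

#' Golden evaluation set: targets, records, and a replay map
#'
#' Samples `n` routes, serializes them to retro records, and keys every
#' target to its golden response text so a [replay_backend()] reproduces the
#' training-data self-consistency ceiling (all six benchmarks at 100%).
#'
#' @param space A `synth_space`.
#' @param n Number of evaluation targets.
#' @param config A [sampler_config()] (its seed fixes the set).
#' @return A list with `targets` (character), `records` (named list of
#'   `retro_record` keyed by target), and `replay_map` (named character of
#'   response texts keyed by target).
#' @export
golden_eval_set <- function(space, n, config = sampler_config()) {
  stopifnot(n >= 1L)
  corpus <- generate_corpus(space, n, config)
  # Later routes to the same target overwrite earlier ones; replay needs one
  # response per distinct target.
  keep <- !duplicated(corpus$target, fromLast = TRUE)
  list(
    targets = corpus$target,
    records = setNames(corpus$record[keep], corpus$target[keep]),
    replay_map = setNames(corpus$response[keep], corpus$target[keep])
  )
}
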