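test_that("predicted building blocks partition by library membership", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)
  parsed <- batch$parsed[[1]]
  cls <- classify_predicted_bbs(parsed, space$library)
  expect_length(cls$novel, 0L)
  expect_length(cls$unparsable, 0L)
  expect_setequal(cls$in_library, canonicalize_smiles(parsed$building_blocks))

  parsed$building_blocks <- c(parsed$building_blocks, "NC1CCOC1N", "C(")
  cls <- classify_predicted_bbs(parsed, space$library)
  expect_identical(cls$novel, canonicalize_smiles("NC1CCOC1N"))
  expect_identical(cls$unparsable, "C(")
})

test_that("nn_search equals a brute-force scan under both representations", {
  space <- toy_space_fixture()
  cfg_m <- search_config("morgan_tanimoto", k_neighbors = 3L)
  cfg_s <- search_config("smiles_ngram", k_neighbors = 3L)
  pool <- index_pool(space$index, 76L, 2L) # amine slot, a rich pool
  set.seed(7)
  queries <- c(sample(pool$smiles, 3), canonicalize_smiles("NCCc1ccco1"))
  for (q in queries) {
    got <- nn_search(q, 76L, 2L, space, cfg_m)
    oracle <- synthspace:::cs_tanimoto_oracle(rep(q, nrow(pool)), pool$smiles)
    ord <- order(-oracle, pool$smiles, method = "radix")
    expect_equal(got$similarity, oracle[ord][1:3], tolerance = 1e-12)
    expect_identical(got$smiles, pool$smiles[ord][1:3])

    got <- nn_search(q, 76L, 2L, space, cfg_s)
    oracle <- vapply(pool$smiles, function(p) oracle_trigram_jaccard(q, p),
                     numeric(1), USE.NAMES = FALSE)
    oracle[pool$smiles == q] <- 1
    ord <- order(-oracle, pool$smiles, method = "radix")
    expect_equal(got$similarity, oracle[ord][1:3], tolerance = 1e-12)
    expect_identical(got$smiles, pool$smiles[ord][1:3])
  }
  # a query present in the pool is always its own first neighbor
  self <- nn_search(pool$smiles[5], 76L, 2L, space, cfg_m)
  expect_identical(self$smiles[1], pool$smiles[5])
  expect_equal(self$similarity[1], 1)
  expect_error(nn_search("CN", 999L, 1L, space, cfg_m),
               class = "synthspace_empty_slot_pool")
})

test_that("forward template application enumerates and canonicalizes products", {
  amide <- toy_templates()[1, ]
  out <- apply_template_forward(amide, c("CC(=O)O", "CN"))
  expect_identical(out, canonicalize_smiles("CNC(C)=O"))
  expect_length(apply_template_forward(amide, c("CC", "CN")), 0L)
  # symmetric diacid: two equivalent sites collapse to one canonical product
  expect_length(apply_template_forward(amide, c("OC(=O)CCC(=O)O", "CN")), 1L)
  # distinct sites give distinct products
  expect_length(apply_template_forward(amide, c("CC(C(=O)O)CC(=O)O", "CN")), 2L)
  expect_error(apply_template_forward(amide, c("C(", "CN")),
               class = "synthspace_unparsable_smiles")
  expect_error(apply_template_forward(amide, "CC(=O)O"),
               class = "synthspace_arity_mismatch")
})

test_that("product selection is the string-similarity argmax", {
  prods <- apply_template_forward(toy_templates()[1, ], c("CC(C(=O)O)CC(=O)O", "CN"))
  expect_identical(select_product(prods, prods[2]), prods[2])
  expect_identical(select_product(prods[1], "CCCCC"), prods[1]) # singleton
  # exhaustive argmax oracle (a prediction outside the product set)
  pred <- "CNC(=O)CC(C)C(=O)OC"
  sims <- vapply(prods, function(p) {
    oracle_trigram_jaccard(canonicalize_smiles(pred), p)
  }, numeric(1))
  expect_identical(select_product(prods, pred),
                   prods[order(-sims, prods)][1])
  expect_error(select_product(character(), "C"),
               class = "synthspace_empty_product_set")
})

test_that("golden inferences reconstruct exactly with the full library", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)
  for (i in 1:6) {
    res <- reconstruct(batch$parsed[[i]], space)
    expect_true(res$exact_match)
    expect_equal(max(res$analogs$similarity), 1)
    expect_length(res$novel_bbs, 0L)
    for (rt in res$analogs$route) {
      expect_length(validate_route(rt, space$registry), 0L)
    }
  }
})

test_that("ablating a route's building block forces valid analogs", {
  space <- toy_space_fixture()
  g <- golden_fixture(20)
  batch <- golden_batch_fixture(20)
  forced <- 0L
  for (i in 1:6) {
    rec <- g$records[[batch$target[i]]]
    victim <- rec$building_blocks[1]
    res <- tryCatch(
      reconstruct(batch$parsed[[i]], remove_building_block(space, victim)),
      synthspace_reconstruction_impossible = function(e) NULL
    )
    if (is.null(res)) next
    forced <- forced + 1L
    expect_gt(nrow(res$analogs), 0L)
    for (rt in res$analogs$route) {
      expect_length(validate_route(rt, space$registry), 0L)
      expect_false(victim %in% rt$building_blocks)
    }
  }
  expect_gt(forced, 0L)
})

test_that("novel building blocks are flagged via the purchasability hook", {
  space <- toy_space_fixture()
  # a reaction built on an acid that is not in the library
  novel_acid <- canonicalize_smiles("OC(=O)C1(C)CC1")
  expect_false(novel_acid %in% space$library$smiles)
  amide <- space$registry[space$registry$name == "amide coupling", ]
  product <- apply_template_forward(amide, c(novel_acid, "CN"))[1]
  rec <- synthspace:::new_retro_record(
    product,
    list(list(template_smarts = amide$smarts,
              reactants = c(novel_acid, canonicalize_smiles("CN")),
              product = product)),
    c(novel_acid, canonicalize_smiles("CN"))
  )
  parsed <- parse_response(synthspace:::response_json(rec), source_smiles = product)

  res <- reconstruct(parsed, space)
  expect_identical(res$novel_bbs, novel_acid)
  expect_identical(res$novel_bb_purchasable, NA) # default: unverified
  expect_false(res$exact_match) # library substitutes only
  expect_true(all(res$analogs$uses_only_library_bbs))

  res <- reconstruct(parsed, space, search_config(
    allow_novel_bbs = TRUE,
    purchasability_hook = function(smiles) TRUE
  ))
  expect_identical(res$novel_bb_purchasable, TRUE)
  expect_true(res$exact_match) # the novel acid itself rebuilds the target
  exact_row <- res$analogs[res$analogs$smiles == res$target, ]
  expect_false(exact_row$uses_only_library_bbs)
})

test_that("a response whose only reaction is foreign cannot be reconstructed", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)
  parsed <- batch$parsed[[1]]
  parsed$reactions <- list(list(
    template_smarts = "[C:1][Br]>>[C:1]O",
    reactants = "CCBr", product = "CCO"
  ))
  expect_warning(
    expect_error(reconstruct(parsed, space),
                 class = "synthspace_reconstruction_impossible"),
    "unknown templates"
  )
})

test_that("larger k or beam never loses analogs", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)
  i <- which(vapply(batch$parsed, function(p) length(p$reactions) >= 2, logical(1)))[1]
  small <- reconstruct(batch$parsed[[i]], space,
                       search_config(k_neighbors = 1L, beam_width = 2L,
                                     max_analogs = 50L))
  big <- reconstruct(batch$parsed[[i]], space,
                     search_config(k_neighbors = 3L, beam_width = 10L,
                                   max_analogs = 50L))
  expect_gte(nrow(big$analogs), nrow(small$analogs))
  expect_identical(big$analogs$smiles, unique(big$analogs$smiles))
})

test_that("scaffold filtering and hit expansion retain only scaffold matches", {
  space <- toy_space_fixture()
  analogs <- tibble::tibble(smiles = canonicalize_smiles(
    c("c1ccccc1", "CCc1ccccc1", "CCCCC", "c1ccncc1")
  ))
  kept <- scaffold_constrained_filter(analogs, "c1ccccc1")
  expect_identical(kept$smiles, analogs$smiles[1:2])
  expect_equal(nrow(scaffold_constrained_filter(analogs[0, ], "c1ccccc1")), 0L)
  expect_error(scaffold_constrained_filter(analogs, "C(("),
               class = "synthspace_bad_pattern")

  batch <- golden_batch_fixture(20)
  i <- which(grepl("c1ccc", batch$target, fixed = TRUE))[1]
  res <- expand_hit(batch$parsed[[i]], space, scaffold = "c1ccccc1", n_analogs = 15L)
  expect_lte(nrow(res$analogs), 15L)
  if (nrow(res$analogs)) {
    hits <- synthspace:::cs_substruct("c1ccccc1", res$analogs$smiles)[, 1]
    expect_true(all(hits))
  }
})
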