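test_that("a golden replay batch is the 100% ceiling on all six metrics", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)
  rep <- benchmark_report(batch, space$registry)
  expect_equal(rep$metrics$percent, rep(100, 6))
  expect_equal(rep$metrics$numerator, rep$metrics$denominator)
  gl <- glance(rep)
  expect_equal(gl$valid_json, 100)
  expect_equal(nrow(tidy(rep)), 6L)
})

test_that("valid_json counts parse failures over all responses", {
  batch <- golden_batch_fixture(20)[1:10, ]
  batch$parsed[1:3] <- lapply(batch$response[1:3], function(t) {
    parse_response(paste0(t, " oops"))
  })
  batch$parse_ok[1:3] <- FALSE
  expect_equal(score_valid_json(batch), 0.7)
  # downstream denominators exclude the unscoreable responses
  rep <- benchmark_report(batch, toy_space_fixture()$registry)
  expect_equal(rep$metrics$denominator[rep$metrics$metric == "valid_json"], 10)
  expect_equal(rep$metrics$denominator[rep$metrics$metric == "bb_selection"], 7)
  expect_error(score_valid_json(batch[0, ]), class = "synthspace_empty_batch")
})

corrupt_one <- function(batch, i, fn) {
  obj <- jsonlite::parse_json(batch$response[i])
  obj <- fn(obj)
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  batch$response[i] <- txt
  batch$parsed[[i]] <- parse_response(txt, source_smiles = batch$target[i])
  batch$parse_ok[i] <- batch$parsed[[i]]$parse_ok
  batch
}

test_that("template memorization is exact string membership, not position", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)[1:10, ]
  expect_equal(score_template_memorization(batch, space$registry), 1)
  # single atom-token edit -> that reaction is a miss
  edited <- corrupt_one(batch, 1, function(obj) {
    obj$reactions[[1]]$template_smarts <-
      sub("\\[c:1\\]|\\[C:1\\]", "[N:1]", obj$reactions[[1]]$template_smarts)
    obj
  })
  n_rxn <- nrow(synthspace:::batch_reactions(batch))
  expect_equal(score_template_memorization(edited, space$registry),
               (n_rxn - 1) / n_rxn)
  # swapping registry-valid SMARTS between reactions keeps 100%
  two <- which(vapply(batch$parsed, function(p) length(p$reactions) >= 2, logical(1)))[1]
  swapped <- corrupt_one(batch, two, function(obj) {
    s <- obj$reactions[[1]]$template_smarts
    obj$reactions[[1]]$template_smarts <- obj$reactions[[2]]$template_smarts
    obj$reactions[[2]]$template_smarts <- s
    obj
  })
  expect_equal(score_template_memorization(swapped, space$registry), 1)
})

test_that("bb_selection demands exactly the non-product reactants", {
  batch <- golden_batch_fixture(20)[1:10, ]
  expect_equal(score_bb_selection(batch), 1)
  omitted <- corrupt_one(batch, 1, function(obj) {
    obj$building_blocks <- obj$building_blocks[-1]
    obj
  })
  expect_equal(score_bb_selection(omitted), 0.9)
  # listing an intermediate product fails too
  multi <- which(vapply(batch$parsed, function(p) length(p$reactions) >= 2, logical(1)))[1]
  padded <- corrupt_one(batch, multi, function(obj) {
    obj$building_blocks <- c(obj$building_blocks, obj$reactions[[2]]$product)
    obj
  })
  expect_equal(score_bb_selection(padded), 0.9)
})

test_that("valid_smiles counts every SMILES occurrence", {
  batch <- golden_batch_fixture(20)[1:10, ]
  n_all <- sum(vapply(batch$parsed, function(p) {
    length(unlist(lapply(p$reactions, `[[`, "reactants"))) +
      length(p$reactions) + length(p$building_blocks)
  }, numeric(1)))
  expect_equal(score_valid_smiles(batch), 1)
  broken <- corrupt_one(batch, 1, function(obj) {
    obj$reactions[[1]]$reactants[[1]] <- "C("
    obj
  })
  expect_equal(score_valid_smiles(broken), (n_all - 1) / n_all)
})

test_that("matched reactants use order-insensitive perfect matching", {
  space <- toy_space_fixture()
  reg <- space$registry
  mk_batch <- function(reactants) {
    rec <- synthspace:::new_retro_record(
      "CNC(C)=O",
      list(list(template_smarts = amide_smarts(), reactants = reactants,
                product = "CNC(C)=O")),
      reactants[!reactants %in% "CNC(C)=O"]
    )
    run_batch(replay_backend(setNames(
      list(synthspace:::response_json(rec)), "CNC(C)=O"
    )), "CNC(C)=O")
  }
  # swapped order still admits a perfect matching
  expect_equal(score_matched_reactants(mk_batch(c("CN", "CC(=O)O")), reg), 1)
  expect_equal(score_matched_reactants(mk_batch(c("CC(=O)O", "CN")), reg), 1)
  # ethane matches no slot: no perfect matching
  expect_equal(score_matched_reactants(mk_batch(c("CC", "CC(=O)O")), reg), 0)
  # good products tolerate an unused extra reactant, matching does not
  extra <- mk_batch(c("CC(=O)O", "CN", "CCCC"))
  expect_equal(score_matched_reactants(extra, reg), 0)
  expect_equal(score_good_products(extra, reg), 1)
})

test_that("good products require forward derivability up to canonicalization", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)[1:10, ]
  expect_equal(score_good_products(batch, space$registry), 1)
  n_rxn <- nrow(synthspace:::batch_reactions(batch))
  # product replaced by its own first reactant -> underivable
  bad <- corrupt_one(batch, 1, function(obj) {
    obj$reactions[[1]]$product <- obj$reactions[[1]]$reactants[[1]]
    obj
  })
  expect_equal(score_good_products(bad, space$registry), (n_rxn - 1) / n_rxn)
  # a non-canonical spelling of the true product still passes
  rec <- synthspace:::new_retro_record(
    "O=C(C)NC", # same amide as CNC(C)=O, written differently
    list(list(template_smarts = amide_smarts(),
              reactants = c("OC(C)=O", "NC"), product = "O=C(C)NC")),
    c("OC(C)=O", "NC")
  )
  odd <- run_batch(
    replay_backend(setNames(list(synthspace:::response_json(rec)), "O=C(C)NC")),
    "O=C(C)NC"
  )
  expect_equal(score_good_products(odd, space$registry), 1)
})

test_that("error injection never increases the corresponding metric", {
  space <- toy_space_fixture()
  batch <- golden_batch_fixture(20)[1:10, ]
  base <- benchmark_report(batch, space$registry)$metrics
  worse <- corrupt_one(batch, 2, function(obj) {
    obj$reactions[[1]]$product <- "C1CC1"
    obj
  })
  m <- benchmark_report(worse, space$registry)$metrics
  expect_lte(m$percent[m$metric == "good_products"],
             base$percent[base$metric == "good_products"])
  expect_true(all(m$numerator <= m$denominator))
})
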