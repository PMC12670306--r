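test_that("records list reactions in retro order with the building-block rule", {
  space <- toy_space_fixture()
  reg <- space$registry
  # Build a forced 2-step route by hand: amide coupling, then Suzuki on the
  # aryl bromide the acid carried.
  amide <- reg[reg$name == "amide coupling", ]
  suzuki <- reg[reg$name == "Suzuki coupling", ]
  acid <- canonicalize_smiles("OC(=O)c1ccc(Br)cc1")
  amine <- canonicalize_smiles("NCc1ccccc1")
  boronic <- canonicalize_smiles("OB(O)c1ccc(C)cc1")
  p1 <- apply_template_forward(amide, c(acid, amine))[1]
  p2 <- apply_template_forward(suzuki, c(p1, boronic))[1]
  route <- synthspace:::new_route(tibble::tibble(
    step = 1:2, template_id = c(amide$template_id, suzuki$template_id),
    reactants = list(c(acid, amine), c(p1, boronic)), product = c(p1, p2)
  ))
  rec <- route_to_record(route, reg)
  expect_identical(rec$input_smiles, p2)
  expect_identical(rec$reactions[[1]]$template_smarts, suzuki$smarts) # retro first
  expect_identical(rec$reactions[[2]]$template_smarts, amide$smarts)
  expect_setequal(rec$building_blocks, c(acid, amine, boronic))

  # one-step route: building blocks are exactly that step's reactants
  one <- sample_linear_route(amide_only_space(), sampler_config(seed = 3L))
  rec1 <- route_to_record(one, amide_only_space()$registry)
  expect_length(rec1$reactions, 1L)
  expect_setequal(rec1$building_blocks, rec1$reactions[[1]]$reactants)
})

test_that("record <-> route round-trips losslessly on sampled routes", {
  space <- toy_space_fixture()
  routes <- sample_routes(space, 20, sampler_config(mode = "mixed", seed = 53L))
  for (r in routes$route) {
    rec <- route_to_record(r, space$registry)
    back <- record_to_route(rec, space$registry)
    expect_identical(back$steps$template_id, r$steps$template_id)
    expect_identical(back$steps$reactants, r$steps$reactants)
    expect_identical(back$steps$product, r$steps$product)
    expect_identical(back$building_blocks, r$building_blocks)
    expect_identical(route_to_record(back, space$registry)$reactions, rec$reactions)
  }
})

test_that("shuffled but consistent reactions still topologically sort", {
  space <- toy_space_fixture()
  r <- sample_branched_route(space, sampler_config(mode = "branched", seed = 59L))
  rec <- route_to_record(r, space$registry)
  shuffled <- rec
  set.seed(1)
  shuffled$reactions <- sample(shuffled$reactions)
  back <- record_to_route(shuffled, space$registry)
  expect_length(validate_route(back, space$registry), 0L)
  expect_identical(back$target, r$target)
  expect_setequal(back$building_blocks, r$building_blocks)
})

test_that("records referencing foreign SMARTS are rejected", {
  space <- toy_space_fixture()
  r <- sample_linear_route(space, sampler_config(seed = 61L))
  rec <- route_to_record(r, space$registry)
  rec$reactions[[1]]$template_smarts <- "[C:1][Br]>>[C:1]O"
  expect_error(record_to_route(rec, space$registry),
               class = "synthspace_unknown_template")
})

test_that("corpus generation is byte-deterministic and schema-valid", {
  space <- toy_space_fixture()
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  c1 <- generate_corpus(space, 25, sampler_config(mode = "mixed", seed = 67L), path = p1)
  c2 <- generate_corpus(space, 25, sampler_config(mode = "mixed", seed = 67L), path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(nrow(c1), 25L)
  # every serialized response parses clean against the schema
  expect_true(all(vapply(c1$response, function(t) parse_response(t)$parse_ok, logical(1))))
  # manifest bookkeeping
  man <- attr(c1, "manifest")
  expect_equal(man$n, 25L)
  expect_equal(man$seed, 67L)
  expect_identical(man$schema, "retro-record/1")
  # reading the file back reproduces the responses
  back <- read_corpus(p1)
  expect_identical(back$response, c1$response)
  expect_identical(back$target, c1$target)
})

test_that("the drug-likeness filter resamples and fails honestly when it cannot", {
  space <- toy_space_fixture()
  filtered <- generate_corpus(space, 10, sampler_config(seed = 71L),
                              druglike_filter = TRUE)
  expect_true(all(synthspace:::cs_lipinski(filtered$target)))
  # a space whose every product violates the rule of five
  greasy <- synth_space(
    bb_library(c(
      "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC(=O)O", "CCCCCCCCCCCCCCCCCCCCCC(=O)O",
      "NCCCCCCCCCCCCCCCCCCCC", "NCCCCCCCCCCCCCCCCCC"
    )),
    template_registry(data.frame(template_id = 1L, name = "amide",
                                 smarts = amide_smarts()))
  )
  expect_error(
    generate_corpus(greasy, 2, sampler_config(seed = 73L), druglike_filter = TRUE),
    class = "synthspace_no_realizable_template"
  )
})
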