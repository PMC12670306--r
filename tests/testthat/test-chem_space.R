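test_that("canonicalization maps equivalent SMILES to one string and is idempotent", {
  out <- canonicalize_smiles(c("OCC", "CCO"))
  expect_identical(out[1], out[2])
  lib <- toy_space_fixture()$library$smiles
  expect_identical(canonicalize_smiles(lib), lib) # already canonical: fixed point
  expect_identical(canonicalize_smiles(canonicalize_smiles("N[C@@H](C)C(=O)O")),
                   canonicalize_smiles("N[C@@H](C)C(=O)O"))
  # stereochemistry is preserved
  expect_false(canonicalize_smiles("N[C@@H](C)C(=O)O") ==
                 canonicalize_smiles("N[C@H](C)C(=O)O"))
  expect_error(canonicalize_smiles("C("), class = "synthspace_unparsable_smiles")
  expect_identical(canonicalize_smiles("C(", strict = FALSE), NA_character_)
})

test_that("building-block loading collapses duplicates, skips bad lines, rejects salts", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# a comment", "CCO BB1", "OCC BB2", "CCN BB3"), path)
  lib <- load_building_blocks(path)
  expect_equal(nrow(lib), 2L) # ethanol written twice
  expect_setequal(lib$smiles, canonicalize_smiles(c("CCO", "CCN")))

  writeLines(c("CCO", "CCN", "CCC", "C("), path)
  lib <- load_building_blocks(path)
  expect_equal(nrow(lib), 3L)
  expect_equal(attr(lib, "load_report")$n_skipped_unparsable, 1L)

  writeLines(c("CCO.Cl x1", "CCN x2"), path)
  lib <- load_building_blocks(path)
  expect_equal(nrow(lib), 1L)
  expect_equal(attr(lib, "load_report")$n_skipped_multifragment, 1L)

  writeLines(character(), path)
  expect_error(load_building_blocks(path), class = "synthspace_empty_library")
  writeLines("C(", path)
  expect_error(load_building_blocks(path), class = "synthspace_empty_library")
})

test_that("library load is deterministic in content and order", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO a", "CCN b", "CC(=O)O c"), path)
  l1 <- load_building_blocks(path)
  l2 <- load_building_blocks(path)
  expect_identical(l1$smiles, l2$smiles)
  expect_identical(l1$bb_id, c("a", "b", "c"))
})

test_that("template registry validates SMARTS, arity, and id uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tsmarts", paste0("76\tamide coupling\t", amide_smarts())), path)
  reg <- load_templates(path)
  expect_s3_class(reg, "template_registry")
  expect_equal(reg$arity, 2L)
  expect_equal(reg$template_id, 76L)

  writeLines(c("id\tname\tsmarts", "1\tbad\t>>[C:1]O"), path)
  expect_error(load_templates(path), class = "synthspace_bad_template")

  writeLines(c(
    "id\tname\tsmarts",
    paste0("76\ta\t", amide_smarts()),
    paste0("76\tb\t", amide_smarts())
  ), path)
  expect_error(load_templates(path), class = "synthspace_duplicate_template_id")
})

test_that("match_slots reads compatibility as reactant-pattern substructure match", {
  reg <- toy_templates()
  amide <- reg[reg$name == "amide coupling", ]
  expect_equal(match_slots(amide, "CC(=O)O"), 1L) # acetic acid: acid slot
  expect_equal(match_slots(amide, "CN"), 2L) # methylamine: amine slot
  expect_equal(match_slots(amide, "CC"), integer()) # ethane: neither
  expect_error(match_slots(amide, "C("), class = "synthspace_unparsable_smiles")
})

test_that("compatibility index equals the brute-force pattern scan", {
  space <- toy_space_fixture()
  reg <- space$registry
  lib <- space$library
  # Independent oracle: split each reaction SMARTS into its reactant patterns
  # and run plain substructure matrices over the whole library.
  for (j in seq_len(nrow(reg))) {
    patterns <- strsplit(sub(">>.*$", "", reg$smarts[j]), ".", fixed = TRUE)[[1]]
    expect_length(patterns, reg$arity[j])
    hits <- synthspace:::cs_substruct(patterns, lib$smiles)
    for (s in seq_along(patterns)) {
      expected <- sort(lib$bb_id[hits[, s]])
      got <- sort(index_pool(space$index, reg$template_id[j], s)$bb_id)
      expect_identical(got, expected)
    }
  }
})

test_that("a constructed fixture yields the expected per-slot pool sizes", {
  registry <- template_registry(
    data.frame(template_id = 1L, name = "amide", smarts = amide_smarts())
  )
  library <- bb_library(c("CC(=O)O", "OC(=O)C1CC1", "CN", "CC"))
  idx <- build_compatibility_index(registry, library)
  expect_equal(nrow(index_pool(idx, 1L, 1L)), 2L) # two acids
  expect_equal(nrow(index_pool(idx, 1L, 2L)), 1L) # one amine
  # no matches at all -> empty index
  none <- build_compatibility_index(registry, bb_library(c("CC", "CCC")))
  expect_equal(nrow(none), 0L)
})

test_that("removing a building block ablates library and index consistently", {
  space <- toy_space_fixture()
  victim <- space$library$smiles[1]
  sp2 <- remove_building_block(space, victim)
  expect_equal(nrow(sp2$library), nrow(space$library) - 1L)
  expect_false(victim %in% sp2$index$smiles)
  expect_true(all(sp2$index$bb_id %in% sp2$library$bb_id))
})
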