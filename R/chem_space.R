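# Chemical-space definition: building-block libraries, reaction-template
# registries, and the (template, slot) -> building-block compatibility index.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the canonical isomeric form of the underlying toolkit
#' (RDKit). Every molecule-equality comparison in the package goes through this
#' one dialect, so "the same molecule written differently" always compares
#' equal. Canonicalization is idempotent and preserves stereochemistry.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), an unparsable SMILES raises an error of
#'   class `synthspace_unparsable_smiles`; if `FALSE`, it yields `NA`.
#' @return Character vector of canonical SMILES (with `NA` for invalid input
#'   when `strict = FALSE`).
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO")) # identical outputs
#' }
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (strict) cs_canon_strict(smiles) else cs_canon(smiles)
}

#' Build a building-block library
#'
#' A building block (BB) is a purchasable small molecule usable as a leaf
#' reactant of a synthesis route. The library is a tibble with columns
#' `bb_id`, `smiles` (canonical) and `source`. Duplicates (by canonical
#' SMILES) are collapsed, unparsable entries are skipped and counted, and
#' dot-disconnected (multi-fragment/salt) SMILES are rejected since templates
#' operate on single species. The load report is attached as attribute
#' `"load_report"`.
#'
#' @param smiles Character vector of SMILES.
#' @param bb_id Optional identifiers (recycled defaults `BB0001`, ...).
#' @param source One of `"train"`, `"test"`, `"external"`.
#' @return A `bb_library` tibble.
#' @export
bb_library <- function(smiles, bb_id = NULL, source = c("train", "test", "external")) {
  source <- match.arg(source)
  stopifnot(is.character(smiles))
  canon <- cs_canon(smiles)
  multi <- !is.na(canon) & grepl(".", canon, fixed = TRUE)
  bad <- is.na(canon) | multi
  report <- list(
    n_input = length(smiles),
    n_skipped_unparsable = sum(is.na(canon)),
    n_skipped_multifragment = sum(multi),
    skipped = smiles[bad]
  )
  canon <- canon[!bad]
  ids <- if (is.null(bb_id)) sprintf("BB%04d", seq_along(smiles)) else as.character(bb_id)
  ids <- ids[!bad]
  keep <- !duplicated(canon)
  report$n_duplicates <- sum(!keep)
  lib <- tibble(bb_id = ids[keep], smiles = canon[keep], source = source)
  if (nrow(lib) == 0L) {
    stop_synthspace("empty_library", "no valid building blocks after filtering")
  }
  if (anyDuplicated(lib$bb_id)) {
    stop_synthspace("duplicate_bb_id", "bb_id values must be unique")
  }
  attr(lib, "load_report") <- report
  class(lib) <- c("bb_library", class(lib))
  lib
}

#' Read a building-block library from a `.smi` file
#'
#' Expects one record per line, whitespace-separated `SMILES [id]`; `#` starts
#' a comment. See [bb_library()] for the filtering rules and load report.
#'
#' @param path Path to a `.smi` file.
#' @param source Provenance label, one of `"train"`, `"test"`, `"external"`.
#' @return A `bb_library` tibble.
#' @export
load_building_blocks <- function(path, source = c("train", "test", "external")) {
  source <- match.arg(source)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop_synthspace("empty_library", paste0("no records in ", path))
  }
  fields <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(fields, `[[`, character(1), 1L)
  ids <- vapply(fields, function(f) if (length(f) > 1L) f[[2]] else NA_character_, character(1))
  if (anyNA(ids)) ids <- sprintf("BB%04d", seq_along(smiles))
  bb_library(smiles, bb_id = ids, source = source)
}

#' Build a reaction-template registry
#'
#' A reaction template is a reaction SMARTS with one or more reactant patterns
#' (ordered slots) and exactly one product pattern; it is the unit of allowed
#' chemistry in the synthesizable space. Each SMARTS is validated with the
#' toolkit and `arity` (the number of reactant slots) is derived from it.
#'
#' @param templates A data frame with columns `template_id`, `name`, `smarts`
#'   (or `id`, `name`, `smarts`).
#' @param label Registry label, e.g. `"RXN1-mini"`.
#' @return A `template_registry` tibble with columns `template_id`, `name`,
#'   `smarts`, `arity`.
#' @export
template_registry <- function(templates, label = "registry") {
  df <- as_tibble(templates)
  if ("id" %in% names(df) && !"template_id" %in% names(df)) {
    df <- rename(df, template_id = "id")
  }
  stopifnot(all(c("template_id", "name", "smarts") %in% names(df)))
  if (nrow(df) == 0L) {
    stop_synthspace("empty_registry", "a template registry must be nonempty")
  }
  df$template_id <- as.integer(df$template_id)
  df$smarts <- trimws(df$smarts)
  if (anyDuplicated(df$template_id)) {
    dup <- df$template_id[duplicated(df$template_id)]
    stop_synthspace(
      "duplicate_template_id",
      paste0("duplicate template id(s): ", paste(unique(dup), collapse = ", "))
    )
  }
  info <- cs_rxn_info(df$smarts)
  bad <- !info$ok | info$n_products != 1L | info$n_reactants < 1L
  if (any(bad)) {
    stop_synthspace(
      "bad_template",
      paste0(
        "invalid reaction template(s): ",
        paste(df$template_id[bad], collapse = ", "),
        " (must parse and have >=1 reactant pattern and exactly 1 product pattern)"
      )
    )
  }
  df <- mutate(df, arity = info$n_reactants)
  df <- select(df, "template_id", "name", "smarts", "arity")
  attr(df, "label") <- label
  class(df) <- c("template_registry", class(df))
  df
}

#' Read a reaction-template registry from a TSV file
#'
#' Expects a UTF-8 TSV with header `id<TAB>name<TAB>smarts`.
#'
#' @param path Path to the TSV file.
#' @param label Registry label (defaults to the file name).
#' @return A `template_registry` tibble.
#' @export
load_templates <- function(path, label = basename(path)) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  template_registry(df, label = label)
}

registry_lookup <- function(registry, template_id) {
  i <- match(template_id, registry$template_id)
  if (anyNA(i)) {
    stop_synthspace(
      "unknown_template",
      paste0("unknown template id(s): ", paste(template_id[is.na(i)], collapse = ", "))
    )
  }
  registry[i, , drop = FALSE]
}

#' Reactant slots of a template matched by a molecule
#'
#' Reads the notion of a "compatible" building block as a plain
#' substructure match of the reactant pattern: slot `s` is returned iff the
#' molecule substructure-matches reactant pattern `s` of the template.
#'
#' @param template A one-row `template_registry` slice, or a reaction SMARTS
#'   string.
#' @param mol A single SMILES string.
#' @return Sorted integer vector of matching slot indices (1-based; possibly
#'   empty).
#' @export
match_slots <- function(template, mol) {
  smarts <- if (is.character(template)) template else template$smarts
  stopifnot(length(smarts) == 1L, is.character(mol), length(mol) == 1L)
  res <- cs_match_slots(smarts, mol)[[1]]
  if (identical(res, NA) || !is.list(res)) {
    stop_unparsable_smiles(mol)
  }
  sort(res[[1]])
}

#' Precompute the building-block compatibility index
#'
#' For every (template, reactant slot) pair, the set of library building
#' blocks whose molecule substructure-matches that slot's pattern. The index
#' is the backbone of both probabilistic route sampling (its pool sizes define
#' the template weights) and template-constrained nearest-neighbor search.
#'
#' @param registry A `template_registry`.
#' @param library A `bb_library`.
#' @return A `compat_index` tibble with columns `template_id`, `slot`, `bb_id`,
#'   `smiles`; slots with no compatible building block simply have no rows.
#' @export
build_compatibility_index <- function(registry, library) {
  stopifnot(nrow(registry) > 0L, nrow(library) > 0L)
  hits <- cs_match_slots(registry$smarts, library$smiles)
  rows <- list()
  for (i in seq_len(nrow(library))) {
    per_rxn <- hits[[i]]
    for (j in seq_len(nrow(registry))) {
      slots <- per_rxn[[j]]
      if (length(slots)) {
        rows[[length(rows) + 1L]] <- tibble(
          template_id = registry$template_id[j],
          slot = as.integer(slots),
          bb_id = library$bb_id[i],
          smiles = library$smiles[i]
        )
      }
    }
  }
  idx <- if (length(rows)) bind_rows(rows) else {
    tibble(template_id = integer(), slot = integer(),
           bb_id = character(), smiles = character())
  }
  idx <- arrange(idx, .data$template_id, .data$slot, .data$bb_id)
  class(idx) <- c("compat_index", class(idx))
  idx
}

#' Extract one slot's building-block pool from a compatibility index
#'
#' @param index A `compat_index`.
#' @param template_id,slot The template and reactant slot (1-based).
#' @return The index rows for that slot (possibly zero rows).
#' @export
index_pool <- function(index, template_id, slot) {
  index[index$template_id == template_id & index$slot == slot, , drop = FALSE]
}

#' Assemble a synthesizable chemical space
#'
#' Bundles a building-block library, a template registry and their
#' compatibility index into one object consumed by the samplers, the corpus
#' generator and the reconstruction search.
#'
#' @param library A `bb_library`.
#' @param registry A `template_registry`.
#' @param label Space label.
#' @return A `synth_space` list with elements `library`, `registry`, `index`,
#'   `label`.
#' @export
synth_space <- function(library, registry, label = "space") {
  structure(
    list(
      library = library,
      registry = registry,
      index = build_compatibility_index(registry, library),
      label = label
    ),
    class = "synth_space"
  )
}

#' Remove building blocks from a space
#'
#' Drops the given building blocks (by canonical SMILES or `bb_id`) from the
#' library and the compatibility index without recomputation — the standard
#' way to construct ablated spaces for forced-analog experiments.
#'
#' @param space A `synth_space`.
#' @param what Character vector of canonical SMILES or `bb_id` values.
#' @return The reduced `synth_space`.
#' @export
remove_building_block <- function(space, what) {
  drop_ids <- space$library$bb_id[
    space$library$bb_id %in% what | space$library$smiles %in% what
  ]
  space$library <- space$library[!space$library$bb_id %in% drop_ids, , drop = FALSE]
  space$index <- space$index[!space$index$bb_id %in% drop_ids, , drop = FALSE]
  space
}

#' @export
print.synth_space <- function(x, ...) {
  cat(
    sprintf(
      "<synth_space '%s': %d building blocks x %d templates, %d index entries>\n",
      x$label, nrow(x$library), nrow(x$registry), nrow(x$index)
    )
  )
  invisible(x)
}
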