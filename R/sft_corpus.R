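# Retrosynthesis training records: serialization of sampled routes into
# retro-ordered prompt/response pairs ("retro-record/1") and JSONL corpora.
#
# A record lists the route's reactions target-first (reverse topological
# order), expands template ids to their full SMARTS, and compiles building
# blocks by the non-product rule: reactants of the reactions section that are
# not the product of any reaction.

new_retro_record <- function(input_smiles, reactions, building_blocks) {
  structure(
    list(
      instruction = the_instruction,
      input_smiles = input_smiles,
      reactions = reactions,
      building_blocks = building_blocks
    ),
    class = "retro_record"
  )
}

#' @export
print.retro_record <- function(x, ...) {
  cat(sprintf(
    "<retro_record: %s, %d reaction(s), %d building block(s)>\n",
    x$input_smiles, length(x$reactions), length(x$building_blocks)
  ))
  invisible(x)
}

#' Convert a synthesis route to a retrosynthesis record
#'
#' Reverses the forward steps into retro order (the first listed reaction
#' produces the target), expands template ids to full reaction SMARTS, and
#' compiles `building_blocks` as the reactants never appearing as a product.
#' The mapping is lossless: [record_to_route()] inverts it.
#'
#' @param route A `synthesis_route`.
#' @param registry The `template_registry` the route was sampled from.
#' @return A `retro_record`.
#' @export
route_to_record <- function(route, registry) {
  v <- validate_route(route, registry, max_steps = max(nrow(route$steps), 5L))
  if (length(v)) {
    stop_synthspace("invalid_route", paste0("invalid route: ", paste(v, collapse = "; ")))
  }
  n <- nrow(route$steps)
  reactions <- lapply(rev(seq_len(n)), function(i) {
    trow <- registry_lookup(registry, route$steps$template_id[i])
    list(
      template_smarts = trow$smarts,
      reactants = route$steps$reactants[[i]],
      product = route$steps$product[i]
    )
  })
  new_retro_record(route$target, reactions, route$building_blocks)
}

# Forward (topological) ordering of a record's retro-listed reactions: a
# reaction can run once each of its reactants is a leaf or already produced.
# Among runnable reactions the latest in retro order goes first, which
# reproduces the sampler's forward order for its own records.
forward_order <- function(reactions) {
  products <- vapply(reactions, function(r) r$product, character(1))
  remaining <- seq_along(reactions)
  produced <- character()
  order_out <- integer()
  while (length(remaining)) {
    runnable <- remaining[vapply(remaining, function(i) {
      all(vapply(reactions[[i]]$reactants, function(r) {
        !(r %in% products[remaining]) || r %in% produced
      }, logical(1)))
    }, logical(1))]
    if (!length(runnable)) {
      stop_synthspace(
        "invalid_record",
        "reactions do not topologically sort (cyclic or missing intermediate)"
      )
    }
    nxt <- max(runnable)
    order_out <- c(order_out, nxt)
    produced <- c(produced, products[nxt])
    remaining <- setdiff(remaining, nxt)
  }
  order_out
}

#' Convert a retrosynthesis record back to a forward route
#'
#' Topologically sorts the record's reactions into forward order (so shuffled
#' but consistent reaction lists still convert), maps each reaction SMARTS
#' back to its registry template, and validates the resulting route.
#'
#' @param record A `retro_record` (or an equivalent parsed list with
#'   `reactions` and `building_blocks`).
#' @param registry A `template_registry`.
#' @return A `synthesis_route`.
#' @export
record_to_route <- function(record, registry) {
  reactions <- record$reactions
  if (!length(reactions)) {
    stop_synthspace("invalid_record", "record has no reactions")
  }
  tidx <- match(
    trimws(vapply(reactions, function(r) r$template_smarts, character(1))),
    registry$smarts
  )
  if (anyNA(tidx)) {
    stop_synthspace(
      "unknown_template",
      "record references reaction SMARTS absent from the registry"
    )
  }
  ord <- forward_order(reactions)
  steps <- tibble(
    step = seq_along(ord),
    template_id = registry$template_id[tidx[ord]],
    reactants = lapply(reactions[ord], function(r) {
      vapply(r$reactants, as.character, character(1), USE.NAMES = FALSE)
    }),
    product = vapply(reactions[ord], function(r) as.character(r$product), character(1))
  )
  route <- new_route(steps)
  v <- validate_route(route, registry, max_steps = max(nrow(steps), 5L))
  if (length(v)) {
    stop_synthspace("invalid_record", paste0("record is not a valid route: ",
                                             paste(v, collapse = "; ")))
  }
  route
}

# The response section exactly as an inference backend would emit it: a single
# JSON object with "reactions" and "building_blocks".
response_json <- function(record) {
  body <- list(
    reactions = lapply(record$reactions, function(r) {
      list(
        template_smarts = unbox(r$template_smarts),
        reactants = lapply(as.character(r$reactants), unbox),
        product = unbox(r$product)
      )
    }),
    building_blocks = lapply(as.character(record$building_blocks), unbox)
  )
  as.character(toJSON(body, auto_unbox = FALSE, digits = NA))
}

record_json <- function(record) {
  body <- list(
    schema = unbox(record_schema_version),
    instruction = unbox(record$instruction),
    input_smiles = unbox(record$input_smiles),
    reactions = lapply(record$reactions, function(r) {
      list(
        template_smarts = unbox(r$template_smarts),
        reactants = lapply(as.character(r$reactants), unbox),
        product = unbox(r$product)
      )
    }),
    building_blocks = lapply(as.character(record$building_blocks), unbox)
  )
  as.character(toJSON(body, auto_unbox = FALSE, digits = NA))
}

record_from_parsed_json <- function(x) {
  new_retro_record(
    input_smiles = as.character(x$input_smiles %||% NA_character_),
    reactions = lapply(x$reactions, function(r) {
      list(
        template_smarts = as.character(r$template_smarts),
        reactants = vapply(r$reactants, as.character, character(1), USE.NAMES = FALSE),
        product = as.character(r$product)
      )
    }),
    building_blocks = vapply(x$building_blocks, as.character, character(1), USE.NAMES = FALSE)
  )
}

#' Generate a retrosynthesis training corpus
#'
#' Samples `n` routes from the space, converts each to a retro-ordered record
#' and (optionally) writes a JSONL corpus plus a manifest. With
#' `druglike_filter = TRUE`, routes whose target fails the Lipinski
#' rule-of-five predicate are resampled (rejections are counted in the
#' manifest); the resample budget is `50 * n` draws.
#'
#' @param space A `synth_space`.
#' @param n Number of records.
#' @param config A [sampler_config()]; its `seed` makes the output
#'   deterministic (identical file bytes across runs).
#' @param path Optional JSONL output path; a manifest is written alongside as
#'   `<path>.manifest.json`.
#' @param druglike_filter Resample targets failing the rule-of-five predicate.
#' @return A tibble with columns `record_id`, `target`, `mode`, `n_steps`,
#'   `record` (list-column of `retro_record`) and `response` (the serialized
#'   response text); the manifest list is attached as attribute `"manifest"`.
#' @export
generate_corpus <- function(space, n, config = sampler_config(), path = NULL,
                            druglike_filter = FALSE) {
  stopifnot(n >= 1L)
  out <- with_seed(config$seed, {
    records <- vector("list", n)
    modes <- character(n)
    rejected <- 0L
    budget <- 50L * n
    i <- 0L
    while (i < n) {
      if (budget <= 0L) {
        stop_synthspace(
          "no_realizable_template",
          "resample budget exhausted before reaching the requested corpus size"
        )
      }
      budget <- budget - 1L
      mode <- if (config$mode == "mixed") {
        if (runif(1) < 0.5) "linear" else "branched"
      } else {
        config$mode
      }
      route <- if (mode == "linear") {
        sample_linear_impl(space, config$max_steps)
      } else {
        sample_branched_impl(space, config)
      }
      if (druglike_filter && !isTRUE(cs_lipinski(route$target))) {
        rejected <- rejected + 1L
        next
      }
      i <- i + 1L
      records[[i]] <- route_to_record(route, space$registry)
      modes[i] <- mode
    }
    list(records = records, modes = modes, rejected = rejected)
  })
  corpus <- tibble(
    record_id = seq_len(n),
    target = vapply(out$records, `[[`, character(1), "input_smiles"),
    mode = out$modes,
    n_steps = vapply(out$records, function(r) length(r$reactions), integer(1)),
    record = out$records,
    response = vapply(out$records, response_json, character(1))
  )
  manifest <- list(
    schema = record_schema_version,
    space_label = space$label,
    n = n,
    seed = config$seed,
    mode = config$mode,
    max_steps = config$max_steps,
    druglike_filter = druglike_filter,
    rejected = out$rejected
  )
  attr(corpus, "manifest") <- manifest
  if (!is.null(path)) {
    writeLines(vapply(out$records, record_json, character(1)), path)
    write_json(manifest, paste0(path, ".manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  }
  corpus
}

#' Read a JSONL corpus written by [generate_corpus()]
#'
#' @param path Path to the JSONL file.
#' @return A tibble with `record_id`, `target`, `record` and `response`
#'   columns (as in [generate_corpus()]).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- lapply(lines, function(l) record_from_parsed_json(parse_json(l)))
  tibble(
    record_id = seq_along(records),
    target = vapply(records, `[[`, character(1), "input_smiles"),
    n_steps = vapply(records, function(r) length(r$reactions), integer(1)),
    record = records,
    response = vapply(records, response_json, character(1))
  )
}
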