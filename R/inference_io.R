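# Inference-backend contract and the strict response parser.
#
# A backend is any R function (target_smiles, sampling_params) -> completion
# text. Two reference implementations are provided: a replay backend that
# returns stored golden responses, and a corrupting mock that injects
# configurable error classes for benchmark calibration. The parser enforces
# the "retro-record/1" response schema: a single JSON object with a
# "reactions" array and a "building_blocks" array; any deviation is recorded
# as data (never an R error), since parsability is itself a benchmark.

#' Sampling parameters for an inference backend
#'
#' Defaults follow the low-temperature setting used for reproducible
#' benchmarking (`T = 0.1`, `TopP = 0.1`).
#'
#' @param temperature Nonnegative real.
#' @param top_p Real in `(0, 1]`.
#' @return A `sampling_params` list.
#' @export
sampling_params <- function(temperature = 0.1, top_p = 0.1) {
  stopifnot(temperature >= 0, top_p > 0, top_p <= 1)
  structure(list(temperature = temperature, top_p = top_p), class = "sampling_params")
}

new_parsed_inference <- function(source_smiles, reactions = list(),
                                 building_blocks = character(),
                                 schema_errors = character()) {
  structure(
    list(
      source_smiles = source_smiles,
      reactions = reactions,
      building_blocks = building_blocks,
      parse_ok = length(schema_errors) == 0L,
      schema_errors = schema_errors
    ),
    class = "parsed_inference"
  )
}

#' @export
print.parsed_inference <- function(x, ...) {
  if (x$parse_ok) {
    cat(sprintf(
      "<parsed_inference: %d reaction(s), %d building block(s)>\n",
      length(x$reactions), length(x$building_blocks)
    ))
  } else {
    cat("<parsed_inference: parse failed>\n")
    cat(paste0("  - ", x$schema_errors, "\n"), sep = "")
  }
  invisible(x)
}

#' Strictly parse an inference response
#'
#' Parses `text` as a single JSON object against the response schema; leading
#' or trailing non-JSON text, missing or extra keys, and wrongly typed fields
#' all fail the parse. Failures never raise: they are returned in
#' `schema_errors`, with `parse_ok = FALSE`. SMILES/SMARTS strings are
#' retained unvalidated — chemical validity is the benchmarks' job.
#'
#' @param text A single character string (a backend completion).
#' @param source_smiles Optional target SMILES this response answers.
#' @return A `parsed_inference`.
#' @export
parse_response <- function(text, source_smiles = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    return(new_parsed_inference(source_smiles,
                                schema_errors = "response is not a single string"))
  }
  obj <- tryCatch(parse_json(text), error = function(e) e)
  if (inherits(obj, "error")) {
    msg <- conditionMessage(obj)
    kind <- if (grepl("trailing", msg)) "non-JSON suffix" else "invalid JSON"
    return(new_parsed_inference(source_smiles, schema_errors = paste0(kind, ": ", msg)))
  }
  errs <- character()
  if (!is.list(obj) || (length(obj) && is.null(names(obj)))) {
    return(new_parsed_inference(source_smiles, schema_errors = "top level is not a JSON object"))
  }
  extra <- setdiff(names(obj), c("reactions", "building_blocks"))
  if (length(extra)) {
    errs <- c(errs, paste0("unexpected key(s): ", paste(extra, collapse = ", ")))
  }
  for (key in c("reactions", "building_blocks")) {
    if (!key %in% names(obj)) {
      errs <- c(errs, paste0("missing key: ", key))
    }
  }
  reactions <- list()
  if ("reactions" %in% names(obj)) {
    rx <- obj$reactions
    if (!is.list(rx) || (length(rx) && !is.null(names(rx)))) {
      errs <- c(errs, "reactions must be an array")
    } else if (!length(rx)) {
      errs <- c(errs, "reactions is empty")
    } else {
      for (i in seq_along(rx)) {
        r <- rx[[i]]
        at <- sprintf("reactions[%d]", i)
        if (!is.list(r) || is.null(names(r))) {
          errs <- c(errs, paste0(at, " is not an object"))
          next
        }
        miss <- setdiff(c("template_smarts", "reactants", "product"), names(r))
        if (length(miss)) {
          errs <- c(errs, paste0(at, " missing key(s): ", paste(miss, collapse = ", ")))
          next
        }
        bad_extra <- setdiff(names(r), c("template_smarts", "reactants", "product"))
        if (length(bad_extra)) {
          errs <- c(errs, paste0(at, " unexpected key(s): ", paste(bad_extra, collapse = ", ")))
        }
        if (!is_scalar_string(r$template_smarts)) {
          errs <- c(errs, paste0(at, "$template_smarts must be a string"))
        }
        if (!is_scalar_string(r$product)) {
          errs <- c(errs, paste0(at, "$product must be a string"))
        }
        if (!is.list(r$reactants) || !length(r$reactants) ||
            !all(vapply(r$reactants, is_scalar_string, logical(1)))) {
          errs <- c(errs, paste0(at, "$reactants must be a nonempty array of strings"))
        }
        if (!length(errs)) {
          reactions[[length(reactions) + 1L]] <- list(
            template_smarts = as.character(r$template_smarts),
            reactants = vapply(r$reactants, as.character, character(1), USE.NAMES = FALSE),
            product = as.character(r$product)
          )
        }
      }
    }
  }
  building_blocks <- character()
  if ("building_blocks" %in% names(obj)) {
    bb <- obj$building_blocks
    if (!is.list(bb) || (length(bb) && !is.null(names(bb))) ||
        !all(vapply(bb, is_scalar_string, logical(1)))) {
      errs <- c(errs, "building_blocks must be an array of strings")
    } else {
      building_blocks <- vapply(bb, as.character, character(1), USE.NAMES = FALSE)
    }
  }
  if (length(errs)) {
    return(new_parsed_inference(source_smiles, schema_errors = errs))
  }
  new_parsed_inference(source_smiles, reactions = reactions,
                       building_blocks = building_blocks)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Replay backend
#'
#' A deterministic inference backend that answers each target with a stored
#' response (the golden-record replay used for self-consistency ceilings).
#'
#' @param replay_map Named character vector or list: target SMILES -> response
#'   text.
#' @return A backend function `(target, params) -> text`.
#' @export
replay_backend <- function(replay_map) {
  replay_map <- as.list(replay_map)
  function(target, params = sampling_params()) {
    res <- replay_map[[target]]
    if (is.null(res)) {
      stop_synthspace("backend_failure", paste0("no stored response for target: ", target))
    }
    res
  }
}

# Run `code` under this backend's private RNG stream, leaving the caller's
# RNG untouched.
private_rng <- function(seed) {
  state <- new.env(parent = emptyenv())
  with_seed(seed, state$seed <- get(".Random.seed", envir = globalenv()))
  function(code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state$seed, envir = globalenv())
    on.exit({
      state$seed <- get(".Random.seed", envir = globalenv())
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else {
        rm(".Random.seed", envir = globalenv())
      }
    })
    force(code)
  }
}

#' Corrupting mock backend
#'
#' Replays golden records while injecting three independent error classes at
#' configurable rates, for calibrating the benchmark metrics:
#' * `p_invalid_json` (per response): appends trailing prose so the strict
#'   JSON parse fails;
#' * `p_corrupt_product` (per reaction): replaces the product with a valid
#'   decoy molecule that the templates cannot produce (fails Good Products
#'   only);
#' * `p_corrupt_reactant` (per reaction): appends a valid decoy reactant that
#'   matches no reactant slot (fails Matched Reactants only, since Good
#'   Products allows extra reactants to go unused).
#'
#' @param records Named list: target SMILES -> `retro_record` (golden).
#' @param p_invalid_json,p_corrupt_product,p_corrupt_reactant Injection rates.
#' @param seed Seed of the backend's private corruption RNG stream.
#' @param product_decoys,reactant_decoy Decoy SMILES used for the injections.
#' @return A backend function `(target, params) -> text`.
#' @export
corrupting_backend <- function(records, p_invalid_json = 0, p_corrupt_product = 0,
                               p_corrupt_reactant = 0, seed = 1L,
                               product_decoys = c("C1CC1", "C1CCNCC1", "c1ccncc1"),
                               reactant_decoy = "CCCC") {
  records <- as.list(records)
  rng <- private_rng(seed)
  function(target, params = sampling_params()) {
    rec <- records[[target]]
    if (is.null(rec)) {
      stop_synthspace("backend_failure", paste0("no golden record for target: ", target))
    }
    rng({
      if (runif(1) < p_invalid_json) {
        return(paste0(response_json(rec), " Hope this synthesis helps!"))
      }
      rec$reactions <- lapply(rec$reactions, function(r) {
        if (runif(1) < p_corrupt_product) {
          r$product <- product_decoys[match(FALSE, product_decoys == r$product)]
        }
        if (runif(1) < p_corrupt_reactant) {
          r$reactants <- c(r$reactants, reactant_decoy)
        }
        r
      })
      response_json(rec)
    })
  }
}

#' Run a backend over a batch of targets
#'
#' Calls the backend once per target (order preserved) and strictly parses
#' each completion. Per-item backend failures are isolated: they yield a
#' `parse_ok = FALSE` row instead of aborting the batch.
#'
#' @param backend A backend function `(target, params) -> text`.
#' @param targets Character vector of target SMILES.
#' @param params A [sampling_params()].
#' @return A tibble with columns `target`, `response` (raw text, `NA` on
#'   backend failure), `parsed` (list of `parsed_inference`), `parse_ok`.
#' @export
run_batch <- function(backend, targets, params = sampling_params()) {
  stopifnot(is.function(backend), is.character(targets))
  rows <- lapply(targets, function(tg) {
    text <- tryCatch(backend(tg, params), error = function(e) e)
    if (inherits(text, "error")) {
      parsed <- new_parsed_inference(
        tg,
        schema_errors = paste0("backend failure: ", conditionMessage(text))
      )
      return(list(target = tg, response = NA_character_, parsed = parsed))
    }
    list(target = tg, response = text, parsed = parse_response(text, source_smiles = tg))
  })
  tibble(
    target = vapply(rows, `[[`, character(1), "target"),
    response = vapply(rows, `[[`, character(1), "response"),
    parsed = lapply(rows, `[[`, "parsed"),
    parse_ok = vapply(rows, function(r) r$parsed$parse_ok, logical(1))
  )
}
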