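# The six response-quality metrics over a batch of parsed inferences:
# Valid JSON, Template Memorization, BB Selection, Valid SMILES, Matched
# Reactants, Good Products. Valid JSON is scored over all responses; the five
# downstream metrics are scored over the parse-ok subset (an unparsable
# response is unscoreable for them).

canon_or_raw <- function(x) {
  if (!length(x)) {
    return(character())
  }
  cx <- cs_canon(x)
  ifelse(is.na(cx), x, cx)
}

ok_batch <- function(batch) {
  if (!is.data.frame(batch) || nrow(batch) == 0L) {
    stop_synthspace("empty_batch", "benchmark batch is empty")
  }
  ok <- batch[batch$parse_ok, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop_synthspace("empty_batch", "no parse-ok responses to score")
  }
  ok
}

# One row per predicted reaction over the parse-ok responses.
batch_reactions <- function(batch) {
  ok <- ok_batch(batch)
  rows <- list()
  for (i in seq_len(nrow(ok))) {
    rx <- ok$parsed[[i]]$reactions
    for (j in seq_along(rx)) {
      rows[[length(rows) + 1L]] <- tibble(
        response = i,
        template_smarts = rx[[j]]$template_smarts,
        reactants = list(rx[[j]]$reactants),
        product = rx[[j]]$product
      )
    }
  }
  bind_rows(rows)
}

permutations_of <- function(v) {
  if (length(v) <= 1L) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], p)
    }
  }
  out
}

# All injective maps slot -> reactant index (vectors of length `arity` with
# distinct entries drawn from 1..m).
slot_injections <- function(m, arity) {
  if (m < arity) {
    return(list())
  }
  subsets <- utils::combn(m, arity, simplify = FALSE)
  unlist(lapply(subsets, permutations_of), recursive = FALSE)
}

# Per-reaction chemistry checks shared by Matched Reactants and Good Products.
# For each reaction: is the template registry-known, do all reactants parse,
# does a perfect reactant/slot matching exist, and does some (injective) slot
# assignment forward-apply to the predicted product?
reaction_checks <- function(reactions, registry) {
  n <- nrow(reactions)
  tidx <- match(trimws(reactions$template_smarts), registry$smarts)
  matched <- logical(n)
  good <- logical(n)
  react_jobs <- list() # per reaction: list of candidate tuples
  for (i in seq_len(n)) {
    react_jobs[[i]] <- list()
    if (is.na(tidx[i])) next
    trow <- registry[tidx[i], ]
    reactants <- reactions$reactants[[i]]
    m <- length(reactants)
    slots <- cs_match_slots(trow$smarts, reactants)
    slots <- lapply(slots, function(s) if (is.list(s)) s[[1]] else integer())
    all_parse <- all(!vapply(
      cs_canon(reactants), is.na, logical(1)
    ))
    # Matched Reactants: perfect matching (every reactant used, every slot
    # filled), so the counts must agree.
    if (all_parse && m == trow$arity) {
      for (p in permutations_of(seq_len(m))) {
        if (all(vapply(seq_len(m), function(s) s %in% slots[[p[s]]], logical(1)))) {
          matched[i] <- TRUE
          break
        }
      }
    }
    # Good Products: some injective slot assignment whose forward application
    # yields the predicted product; extra reactants may go unused.
    if (!is.na(cs_canon(reactions$product[i]))) {
      for (a in slot_injections(m, trow$arity)) {
        if (all(vapply(seq_len(trow$arity), function(s) s %in% slots[[a[s]]], logical(1)))) {
          react_jobs[[i]] <- c(react_jobs[[i]], list(reactants[a]))
        }
      }
    }
  }
  # Forward applications batched per template SMARTS.
  flat <- tibble(
    rxn = rep(seq_len(n), lengths(react_jobs)),
    tuple = unlist(react_jobs, recursive = FALSE)
  )
  if (nrow(flat)) {
    flat$smarts <- registry$smarts[tidx[flat$rxn]]
    for (sm in unique(flat$smarts)) {
      sel <- which(flat$smarts == sm)
      prods <- cs_react(sm, flat$tuple[sel])
      for (k in seq_along(sel)) {
        i <- flat$rxn[sel[k]]
        p <- prods[[k]]
        if (!identical(p, NA) && cs_canon(reactions$product[i]) %in% p) {
          good[i] <- TRUE
        }
      }
    }
  }
  tibble(
    template_known = !is.na(tidx),
    matched_reactants = matched,
    good_product = good
  )
}

#' Benchmark: fraction of responses that parse as valid JSON
#'
#' @param batch A [run_batch()] tibble.
#' @return Fraction in `[0, 1]`.
#' @export
score_valid_json <- function(batch) {
  if (!is.data.frame(batch) || nrow(batch) == 0L) {
    stop_synthspace("empty_batch", "benchmark batch is empty")
  }
  mean(batch$parse_ok)
}

#' Benchmark: fraction of predicted reactions using a registry template verbatim
#'
#' A reaction counts as memorized iff its `template_smarts`, after whitespace
#' trimming, exactly equals one of the registry SMARTS strings (string
#' equality, not SMARTS-graph equivalence: the criterion is memorization).
#'
#' @inheritParams score_valid_json
#' @param registry A `template_registry`.
#' @return Fraction in `[0, 1]`.
#' @export
score_template_memorization <- function(batch, registry) {
  rx <- batch_reactions(batch)
  mean(trimws(rx$template_smarts) %in% registry$smarts)
}

#' Benchmark: fraction of responses whose building-block list is exactly right
#'
#' A response passes iff its `building_blocks`, as a canonical-SMILES set,
#' equals the set of reactants in its reactions section that appear as no
#' reaction's product.
#'
#' @inheritParams score_valid_json
#' @return Fraction in `[0, 1]`.
#' @export
score_bb_selection <- function(batch) {
  ok <- ok_batch(batch)
  passes <- vapply(seq_len(nrow(ok)), function(i) {
    parsed <- ok$parsed[[i]]
    reactants <- unlist(lapply(parsed$reactions, `[[`, "reactants"), use.names = FALSE)
    products <- vapply(parsed$reactions, `[[`, character(1), "product")
    reactants <- canon_or_raw(reactants)
    products <- canon_or_raw(products)
    expected <- unique(reactants[!reactants %in% products])
    setequal(canon_or_raw(parsed$building_blocks), expected)
  }, logical(1))
  mean(passes)
}

#' Benchmark: fraction of valid SMILES among all SMILES strings in responses
#'
#' The denominator counts every reactant, product and building-block string
#' (per occurrence) over the parse-ok responses.
#'
#' @inheritParams score_valid_json
#' @return Fraction in `[0, 1]`.
#' @export
score_valid_smiles <- function(batch) {
  ok <- ok_batch(batch)
  all_smiles <- unlist(lapply(seq_len(nrow(ok)), function(i) {
    parsed <- ok$parsed[[i]]
    c(
      unlist(lapply(parsed$reactions, `[[`, "reactants"), use.names = FALSE),
      vapply(parsed$reactions, `[[`, character(1), "product"),
      parsed$building_blocks
    )
  }), use.names = FALSE)
  mean(cs_valid(all_smiles))
}

#' Benchmark: fraction of reactions whose reactants fit the template slots
#'
#' A reaction passes iff its template is registry-known, all its reactants
#' parse, and a perfect assignment of reactants to reactant slots exists
#' (order-insensitive bipartite matching; each reactant must
#' substructure-match its assigned slot pattern).
#'
#' @inheritParams score_template_memorization
#' @return Fraction in `[0, 1]`.
#' @export
score_matched_reactants <- function(batch, registry) {
  rx <- batch_reactions(batch)
  mean(reaction_checks(rx, registry)$matched_reactants)
}

#' Benchmark: fraction of reactions whose product is derivable
#'
#' A reaction passes iff applying its template forward to some slot
#' assignment of its reactants yields a product whose canonical SMILES equals
#' the predicted product's canonical SMILES.
#'
#' @inheritParams score_template_memorization
#' @return Fraction in `[0, 1]`.
#' @export
score_good_products <- function(batch, registry) {
  rx <- batch_reactions(batch)
  mean(reaction_checks(rx, registry)$good_product)
}

#' Compute the full six-metric benchmark report
#'
#' @inheritParams score_template_memorization
#' @return A `benchmark_report` object; `tidy()` gives one row per metric
#'   (percent, numerator, denominator), `glance()` one wide row.
#' @export
benchmark_report <- function(batch, registry) {
  if (!is.data.frame(batch) || nrow(batch) == 0L) {
    stop_synthspace("empty_batch", "benchmark batch is empty")
  }
  n_resp <- nrow(batch)
  n_ok <- sum(batch$parse_ok)
  if (n_ok == 0L) {
    stop_synthspace("empty_batch", "no parse-ok responses to score")
  }
  rx <- batch_reactions(batch)
  checks <- reaction_checks(rx, registry)
  n_rxn <- nrow(rx)
  all_smiles_n <- sum(vapply(which(batch$parse_ok), function(i) {
    parsed <- batch$parsed[[i]]
    length(unlist(lapply(parsed$reactions, `[[`, "reactants"))) +
      length(parsed$reactions) + length(parsed$building_blocks)
  }, numeric(1)))
  metrics <- tibble(
    metric = c(
      "valid_json", "template_memorization", "bb_selection",
      "valid_smiles", "matched_reactants", "good_products"
    ),
    numerator = c(
      sum(batch$parse_ok),
      sum(trimws(rx$template_smarts) %in% registry$smarts),
      round(score_bb_selection(batch) * n_ok),
      round(score_valid_smiles(batch) * all_smiles_n),
      sum(checks$matched_reactants),
      sum(checks$good_product)
    ),
    denominator = c(n_resp, n_rxn, n_ok, all_smiles_n, n_rxn, n_rxn)
  )
  metrics$percent <- 100 * metrics$numerator / metrics$denominator
  structure(
    list(metrics = metrics, n_responses = n_resp, n_parse_ok = n_ok,
         registry_label = attr(registry, "label") %||% "registry"),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report: %d responses (%d parse-ok), registry '%s'>\n",
    x$n_responses, x$n_parse_ok, x$registry_label
  ))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf(
      "  %-22s %6.2f%%  (%d/%d)\n",
      m$metric[i], m$percent[i], m$numerator[i], m$denominator[i]
    ))
  }
  invisible(x)
}
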