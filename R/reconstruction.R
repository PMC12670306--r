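# Reconstruction of targets / synthesizable analogs from a parsed inference:
# replay the predicted retro reactions forward, substituting every predicted
# building block by its nearest library neighbors constrained to the predicted
# template slot, beam-searching over candidate combinations, and ranking the
# resulting molecules by similarity to the target. Every emitted analog
# carries an executable route whose products come from actual forward template
# application — synthesizability by construction.

#' Reconstruction search configuration
#'
#' @param representation Molecular representation for the constrained
#'   nearest-neighbor search and beam scoring: `"morgan_tanimoto"` (Tanimoto
#'   over hashed Morgan fingerprints) or `"smiles_ngram"`
#'   (character-trigram Jaccard over canonical SMILES).
#' @param k_neighbors Neighbors kept per predicted building block (default 2,
#'   the "top two most similar BBs" choice).
#' @param beam_width Beam width over candidate combinations during forward
#'   replay.
#' @param max_analogs Maximum analogs returned (default 10).
#' @param allow_novel_bbs If `TRUE`, a parseable predicted building block
#'   absent from the library is also kept as its own candidate (marked
#'   non-library), mirroring reconstruction with novel building blocks; the
#'   default `FALSE` restricts candidates to the library.
#' @param purchasability_hook Optional function `(smiles) -> logical` used to
#'   flag novel predicted building blocks as purchasable from other suppliers.
#'   The default `NULL` performs no lookup and marks every novel building
#'   block as unverified (`NA`).
#' @param fp An [fp_config()] used for Morgan similarities.
#' @return A `search_config` list.
#' @export
search_config <- function(representation = c("morgan_tanimoto", "smiles_ngram"),
                          k_neighbors = 2L, beam_width = 8L, max_analogs = 10L,
                          allow_novel_bbs = FALSE, purchasability_hook = NULL,
                          fp = fp_config()) {
  representation <- match.arg(representation)
  stopifnot(k_neighbors >= 1L, beam_width >= 1L, max_analogs >= 1L,
            is.null(purchasability_hook) || is.function(purchasability_hook))
  structure(
    list(
      representation = representation,
      k_neighbors = as.integer(k_neighbors),
      beam_width = as.integer(beam_width),
      max_analogs = as.integer(max_analogs),
      allow_novel_bbs = isTRUE(allow_novel_bbs),
      purchasability_hook = purchasability_hook,
      fp = fp
    ),
    class = "search_config"
  )
}

trigram_set <- function(s) {
  n <- nchar(s)
  if (n < 3L) {
    return(s)
  }
  unique(substring(s, seq_len(n - 2L), seq(3L, n)))
}

# Character-trigram Jaccard similarity of one string against many.
string_similarity <- function(query, pool) {
  q <- trigram_set(query)
  vapply(pool, function(p) jaccard_sets(q, trigram_set(p)), numeric(1),
         USE.NAMES = FALSE)
}

# Similarity of candidate molecules to a (possibly unparsable) query under
# the configured representation. `pool` must be canonical SMILES.
rep_similarity <- function(query, pool, config) {
  qc <- cs_canon(query)
  if (config$representation == "morgan_tanimoto" && !is.na(qc)) {
    qb <- cs_morgan(qc, config$fp$radius, config$fp$n_bits)[[1]]
    pb <- cs_morgan(pool, config$fp$radius, config$fp$n_bits)
    vapply(seq_along(pool), function(i) {
      if (identical(pool[i], qc)) 1 else jaccard_sets(qb, pb[[i]])
    }, numeric(1))
  } else {
    # smiles_ngram representation, or unparsable query under either.
    ref <- if (is.na(qc)) query else qc
    sims <- string_similarity(ref, pool)
    if (!is.na(qc)) sims[pool == qc] <- 1
    sims
  }
}

#' Template-constrained nearest-neighbor search for a building block
#'
#' Ranks the library building blocks compatible with reactant slot `slot` of
#' template `template_id` (the compatibility-index pool — the effective
#' search space) by similarity to the query, returning the top `k_neighbors`.
#' Ties are broken by canonical-SMILES lexicographic order. A query that is
#' itself in the pool ranks first with similarity 1.
#'
#' @param query A predicted building-block SMILES.
#' @param template_id,slot The predicted template and reactant slot
#'   constraining the pool.
#' @param space A `synth_space`.
#' @param config A [search_config()].
#' @return A tibble `bb_id`, `smiles`, `similarity`, sorted descending.
#' @export
nn_search <- function(query, template_id, slot, space, config = search_config()) {
  pool <- index_pool(space$index, template_id, slot)
  if (nrow(pool) == 0L) {
    stop_synthspace(
      "empty_slot_pool",
      sprintf("no compatible building blocks for template %s slot %s", template_id, slot)
    )
  }
  sims <- rep_similarity(query, pool$smiles, config)
  ord <- order(-sims, pool$smiles, method = "radix")
  top <- head(ord, config$k_neighbors)
  tibble(bb_id = pool$bb_id[top], smiles = pool$smiles[top], similarity = sims[top])
}

#' Forward application of a reaction template
#'
#' Applies the template's bond rewrite to the ordered reactants and returns
#' all distinct canonical products over symmetry-equivalent reactive sites
#' (sorted). The set is empty when some reactant fails to match its slot.
#'
#' @param template A one-row `template_registry` slice or a reaction SMARTS
#'   string.
#' @param reactants Character vector of reactant SMILES in slot order.
#' @return Character vector of canonical product SMILES (possibly empty).
#' @export
apply_template_forward <- function(template, reactants) {
  smarts <- if (is.character(template)) template else template$smarts
  stopifnot(length(smarts) == 1L)
  info <- cs_rxn_info(smarts)
  if (!info$ok) {
    stop_synthspace("bad_template", paste0("invalid reaction SMARTS: ", smarts))
  }
  if (length(reactants) != info$n_reactants) {
    stop_synthspace(
      "arity_mismatch",
      sprintf("expected %d reactants, got %d", info$n_reactants, length(reactants))
    )
  }
  cs_canon_strict(reactants)
  prods <- cs_react(smarts, list(reactants))[[1]]
  if (identical(prods, NA)) {
    stop_unparsable_smiles(reactants)
  }
  prods
}

#' Select the realized product closest to the predicted one
#'
#' When a template application yields several products, the one most similar
#' to the predicted product by character-trigram Jaccard on canonical SMILES
#' is kept; ties break lexicographically.
#'
#' @param products Nonempty character vector of candidate product SMILES.
#' @param predicted_product The predicted product SMILES (canonicalized when
#'   parseable).
#' @return A single SMILES from `products`.
#' @export
select_product <- function(products, predicted_product) {
  if (!length(products)) {
    stop_synthspace("empty_product_set", "no products to select from")
  }
  pc <- cs_canon(predicted_product)
  ref <- if (is.na(pc)) predicted_product else pc
  if (ref %in% products) {
    # the predicted product itself always wins (similarity 1, tie-proof)
    return(ref)
  }
  sims <- string_similarity(ref, products)
  products[order(-sims, products, method = "radix")][1]
}

#' Partition predicted building blocks by library membership
#'
#' @param parsed A `parsed_inference` with `parse_ok = TRUE`.
#' @param library A `bb_library`.
#' @return A list with character vectors `in_library`, `novel` (both
#'   canonical SMILES) and `unparsable` (raw strings).
#' @export
classify_predicted_bbs <- function(parsed, library) {
  stopifnot(isTRUE(parsed$parse_ok))
  bbs <- unique(parsed$building_blocks)
  canon <- cs_canon(bbs)
  unparsable <- bbs[is.na(canon)]
  canon <- unique(canon[!is.na(canon)])
  inlib <- canon %in% library$smiles
  list(
    in_library = canon[inlib],
    novel = canon[!inlib],
    unparsable = unparsable
  )
}

# Candidate realizations of one predicted building block in one slot:
# nn_search pool neighbors, plus (optionally) the novel predicted BB itself.
bb_candidates <- function(query_norm, template_id, slot, space, config) {
  cand <- tryCatch(
    nn_search(query_norm, template_id, slot, space, config),
    synthspace_empty_slot_pool = function(e) NULL
  )
  if (is.null(cand)) {
    return(NULL)
  }
  cand$in_library <- TRUE
  qc <- cs_canon(query_norm)
  if (config$allow_novel_bbs && !is.na(qc) && !(qc %in% space$library$smiles)) {
    cand <- bind_rows(
      tibble(bb_id = NA_character_, smiles = qc, similarity = 1, in_library = FALSE),
      cand
    )
  }
  cand
}

#' Reconstruct a target or synthesizable analogs from a parsed inference
#'
#' Orders the predicted reactions forward, then replays them: predicted
#' intermediates are carried through the beam, predicted building blocks are
#' substituted by their template/slot-constrained nearest library neighbors
#' (a predicted building block present in the library is always its own
#' rank-1 candidate, so exact reconstruction dominates analog generation),
#' slot assignment follows the same order-insensitive matching as the
#' Matched-Reactants benchmark, each candidate tuple is forward-applied, and
#' of multiple products the one closest to the predicted product by string
#' similarity is kept. Beam states are scored by the similarity of the
#' running intermediate to the predicted intermediate. Final molecules are
#' deduplicated, ranked by Morgan-Tanimoto similarity to the target, and
#' returned with their executable routes.
#'
#' @param parsed A `parsed_inference` with `parse_ok = TRUE`; reactions whose
#'   template is not in the registry are dropped with a warning.
#' @param space A `synth_space`.
#' @param config A [search_config()].
#' @return A `reconstruction_result`: list with `target`, `exact_match`,
#'   `analogs` (tibble `smiles`, `similarity`, `uses_only_library_bbs`,
#'   `route` list-column), `novel_bbs`, `unparsable_bbs`.
#' @export
reconstruct <- function(parsed, space, config = search_config()) {
  if (!isTRUE(parsed$parse_ok)) {
    stop_synthspace("invalid_record", "cannot reconstruct from a failed parse")
  }
  reg <- space$registry
  reactions <- parsed$reactions
  known <- !is.na(match(trimws(vapply(reactions, `[[`, character(1), "template_smarts")),
                        reg$smarts))
  if (any(!known)) {
    warn(sprintf("dropping %d reaction(s) with unknown templates", sum(!known)))
    reactions <- reactions[known]
  }
  if (!length(reactions)) {
    stop_synthspace("reconstruction_impossible", "no registry-known reactions to replay")
  }
  ord <- tryCatch(forward_order(reactions), synthspace_error = function(e) NULL)
  if (is.null(ord)) {
    stop_synthspace("reconstruction_impossible",
                    "predicted reactions do not form a consistent route")
  }
  reactions <- reactions[ord]
  tidx <- match(trimws(vapply(reactions, `[[`, character(1), "template_smarts")),
                reg$smarts)
  pred_products <- canon_or_raw(vapply(reactions, `[[`, character(1), "product"))
  target_norm <- if (is_scalar_string(parsed$source_smiles) && !is.na(parsed$source_smiles)) {
    canon_or_raw(parsed$source_smiles)
  } else {
    pred_products[length(pred_products)]
  }

  states <- list(list(steps = list(), made = list(), score = 1, all_lib = TRUE))
  for (si in seq_along(reactions)) {
    r <- reactions[[si]]
    trow <- reg[tidx[si], ]
    m <- length(r$reactants)
    if (m != trow$arity) {
      states <- list()
      break
    }
    norm_reactants <- canon_or_raw(r$reactants)
    is_int <- norm_reactants %in% pred_products[seq_len(si - 1L)]
    # Slot compatibility of the *predicted* reactants; an unparsable predicted
    # building block may sit in any slot (its library substitutes decide).
    slot_sets <- lapply(seq_len(m), function(ri) {
      if (is_int[ri]) {
        s <- cs_match_slots(trow$smarts, norm_reactants[ri])[[1]]
        if (is.list(s)) s[[1]] else integer()
      } else if (is.na(cs_canon(norm_reactants[ri]))) {
        seq_len(trow$arity)
      } else {
        s <- cs_match_slots(trow$smarts, norm_reactants[ri])[[1]]
        if (is.list(s)) s[[1]] else integer()
      }
    })
    assignments <- keep(permutations_of(seq_len(m)), function(p) {
      all(vapply(seq_len(m), function(s) s %in% slot_sets[[p[s]]], logical(1)))
    })
    # Candidate realizations per (assignment slot, reactant).
    jobs <- list() # each: list(state_i, tuple, bb_sim, all_lib)
    for (st_i in seq_along(states)) {
      state <- states[[st_i]]
      for (p in assignments) {
        cand_per_slot <- vector("list", trow$arity)
        feasible <- TRUE
        for (s in seq_len(trow$arity)) {
          ri <- p[s]
          if (is_int[ri]) {
            realized <- state$made[[norm_reactants[ri]]]
            if (is.null(realized)) {
              feasible <- FALSE
              break
            }
            cand_per_slot[[s]] <- tibble(smiles = realized, similarity = 1,
                                         in_library = TRUE)
          } else {
            cand <- bb_candidates(norm_reactants[ri], trow$template_id, s, space, config)
            if (is.null(cand)) {
              feasible <- FALSE
              break
            }
            cand_per_slot[[s]] <- cand
          }
        }
        if (!feasible) next
        grid <- do.call(expand.grid, lapply(cand_per_slot, function(x) seq_len(nrow(x))))
        for (g in seq_len(nrow(grid))) {
          idx <- as.integer(unlist(grid[g, ]))
          tuple <- vapply(seq_len(trow$arity),
                          function(s) cand_per_slot[[s]]$smiles[idx[s]], character(1))
          all_lib <- state$all_lib &&
            all(vapply(seq_len(trow$arity),
                       function(s) cand_per_slot[[s]]$in_library[idx[s]], logical(1)))
          jobs[[length(jobs) + 1L]] <- list(state_i = st_i, tuple = tuple,
                                            all_lib = all_lib)
        }
      }
    }
    if (!length(jobs)) {
      states <- list()
      break
    }
    # Deduplicate identical (state, tuple) jobs, then react in one batch.
    sig <- vapply(jobs, function(j) paste(j$state_i, paste(j$tuple, collapse = "|")),
                  character(1))
    jobs <- jobs[!duplicated(sig)]
    prods <- cs_react(trow$smarts, lapply(jobs, `[[`, "tuple"))
    new_states <- list()
    seen <- character()
    for (k in seq_along(jobs)) {
      pk <- prods[[k]]
      if (identical(pk, NA) || !length(pk)) next
      state <- states[[jobs[[k]]$state_i]]
      # A tuple with several symmetry- or regio-distinct products forks the
      # beam: each product is scored against the predicted intermediate, so
      # the exact path (similarity 1) can never be lost to a greedy pick.
      # Rank the fork by string similarity to the predicted product
      # (select_product order) so ties resolve the same way everywhere.
      pk <- pk[order(-string_similarity(canon_or_raw(r$product), pk), pk,
                     method = "radix")]
      scores <- rep_similarity(pred_products[si], pk, config)
      for (pi in seq_along(pk)) {
        ns <- state
        ns$steps[[length(ns$steps) + 1L]] <- list(
          template_id = trow$template_id, reactants = jobs[[k]]$tuple,
          product = pk[pi]
        )
        ns$made[[pred_products[si]]] <- pk[pi]
        ns$score <- state$score * scores[pi]
        ns$all_lib <- jobs[[k]]$all_lib
        key <- paste(vapply(ns$steps, function(s) {
          paste(s$template_id, paste(s$reactants, collapse = ","), s$product)
        }, character(1)), collapse = ";")
        if (key %in% seen) next
        seen <- c(seen, key)
        new_states[[length(new_states) + 1L]] <- ns
      }
    }
    if (!length(new_states)) {
      states <- list()
      break
    }
    ord_ns <- order(-vapply(new_states, `[[`, numeric(1), "score"))
    states <- new_states[head(ord_ns, config$beam_width)]
  }

  if (!length(states)) {
    stop_synthspace("reconstruction_impossible",
                    "no predicted reaction step could be realized from the library")
  }

  bbs <- classify_predicted_bbs(parsed, space$library)
  finals <- map(states, function(state) {
    steps <- tibble(
      step = seq_along(state$steps),
      template_id = vapply(state$steps, `[[`, integer(1), "template_id"),
      reactants = lapply(state$steps, `[[`, "reactants"),
      product = vapply(state$steps, `[[`, character(1), "product")
    )
    route <- new_route(steps)
    list(smiles = route$target, route = route, all_lib = state$all_lib)
  })
  smiles <- vapply(finals, `[[`, character(1), "smiles")
  sim_cfg <- list(representation = "morgan_tanimoto", fp = config$fp)
  sims <- rep_similarity(target_norm, smiles, sim_cfg)
  keep_i <- order(-sims, smiles, method = "radix")
  keep_i <- keep_i[!duplicated(smiles[keep_i])]
  keep_i <- head(keep_i, config$max_analogs)
  analogs <- tibble(
    smiles = smiles[keep_i],
    similarity = sims[keep_i],
    uses_only_library_bbs = vapply(finals[keep_i], `[[`, logical(1), "all_lib"),
    route = lapply(finals[keep_i], `[[`, "route")
  )
  purchasable <- if (length(bbs$novel) == 0L) {
    logical()
  } else if (is.null(config$purchasability_hook)) {
    rep(NA, length(bbs$novel)) # no supplier lookup: unverified
  } else {
    vapply(bbs$novel, function(s) isTRUE(config$purchasability_hook(s)), logical(1),
           USE.NAMES = FALSE)
  }
  structure(
    list(
      target = target_norm,
      exact_match = any(analogs$smiles == target_norm),
      analogs = analogs,
      novel_bbs = bbs$novel,
      novel_bb_purchasable = purchasable,
      unparsable_bbs = bbs$unparsable
    ),
    class = "reconstruction_result"
  )
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_result: target %s, exact_match=%s, %d analog(s)>\n",
    x$target, x$exact_match, nrow(x$analogs)
  ))
  invisible(x)
}

#' @export
tidy.reconstruction_result <- function(x, ...) {
  mutate(x$analogs, target = x$target, exact_match = .data$smiles == x$target,
         .before = 1L)
}

#' @export
glance.reconstruction_result <- function(x, ...) {
  tibble(
    target = x$target,
    exact_match = x$exact_match,
    n_analogs = nrow(x$analogs),
    best_similarity = if (nrow(x$analogs)) max(x$analogs$similarity) else NA_real_,
    n_novel_bbs = length(x$novel_bbs)
  )
}

#' Reconstruct every parse-ok response of a batch
#'
#' @param batch A [run_batch()] tibble.
#' @param space A `synth_space`.
#' @param config A [search_config()].
#' @return A tibble: `target`, `status` (`"ok"`, `"parse_failed"`,
#'   `"impossible"`), `exact_match`, `n_analogs`, `best_similarity`, `result`
#'   (list-column of `reconstruction_result` or `NULL`).
#' @export
reconstruct_batch <- function(batch, space, config = search_config()) {
  rows <- lapply(seq_len(nrow(batch)), function(i) {
    if (!batch$parse_ok[i]) {
      return(list(status = "parse_failed", result = NULL))
    }
    res <- tryCatch(
      reconstruct(batch$parsed[[i]], space, config),
      synthspace_reconstruction_impossible = function(e) NULL
    )
    if (is.null(res)) {
      list(status = "impossible", result = NULL)
    } else {
      list(status = "ok", result = res)
    }
  })
  tibble(
    target = batch$target,
    status = vapply(rows, `[[`, character(1), "status"),
    exact_match = vapply(rows, function(r) {
      if (is.null(r$result)) FALSE else r$result$exact_match
    }, logical(1)),
    n_analogs = vapply(rows, function(r) {
      if (is.null(r$result)) 0L else nrow(r$result$analogs)
    }, integer(1)),
    best_similarity = vapply(rows, function(r) {
      if (is.null(r$result) || !nrow(r$result$analogs)) {
        NA_real_
      } else {
        max(r$result$analogs$similarity)
      }
    }, numeric(1)),
    result = lapply(rows, `[[`, "result")
  )
}

#' Keep only analogs retaining a scaffold
#'
#' Filters an analog tibble to molecules substructure-matching the scaffold
#' pattern (SMARTS or SMILES), preserving order — the scaffold-constrained
#' filter used for local hit expansion.
#'
#' @param analogs A tibble with a `smiles` column (e.g. `result$analogs`).
#' @param scaffold A substructure pattern.
#' @return The filtered tibble.
#' @export
scaffold_constrained_filter <- function(analogs, scaffold) {
  stopifnot(is.data.frame(analogs), "smiles" %in% names(analogs))
  if (!nrow(analogs)) {
    return(analogs)
  }
  hit <- cs_substruct(scaffold, analogs$smiles)[, 1]
  analogs[!is.na(hit) & hit, , drop = FALSE]
}

#' Scaffold-constrained hit expansion
#'
#' Generates up to `n_analogs` synthesizable analogs of a hit molecule from
#' its predicted (or golden) retrosynthesis and keeps those that retain the
#' given scaffold — the local hit-expansion workflow (default 50 analogs
#' before filtering).
#'
#' @param parsed A `parsed_inference` for the hit molecule.
#' @param space A `synth_space`.
#' @param scaffold Substructure pattern the analogs must retain.
#' @param n_analogs Analog budget before filtering (default 50).
#' @param config Optional [search_config()]; by default the search is widened
#'   (`k_neighbors = 4`, `beam_width = max(50, n_analogs)`) so the budget can
#'   be filled.
#' @return A `reconstruction_result` whose `analogs` are scaffold-filtered.
#' @export
expand_hit <- function(parsed, space, scaffold, n_analogs = 50L, config = NULL) {
  if (is.null(config)) {
    config <- search_config(k_neighbors = 4L,
                            beam_width = max(50L, n_analogs),
                            max_analogs = n_analogs)
  } else {
    config$max_analogs <- as.integer(n_analogs)
  }
  res <- reconstruct(parsed, space, config)
  res$analogs <- scaffold_constrained_filter(res$analogs, scaffold)
  res
}
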