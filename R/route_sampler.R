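# Probabilistic enumeration of synthesis routes from a synthesizable space.
#
# A route is grown forward: an initial template is drawn with probability
# proportional to its number of realizable reactant tuples, its slots are
# filled with uniformly drawn compatible building blocks, and the resulting
# intermediate is then iteratively matched against the registry to recruit
# further templates and building blocks, until nothing matches or the step cap
# is reached. Branched mode grows two sub-trees and merges their intermediates
# in a single template application.

#' Sampler configuration
#'
#' @param max_steps Maximum number of reaction steps per route (default 5,
#'   the cap used for the synthesizable space definition).
#' @param mode `"linear"`, `"branched"`, or `"mixed"` (each route drawn
#'   linear/branched with equal probability).
#' @param seed Optional integer; when given, sampling functions use it via a
#'   private RNG scope (the caller's RNG state is untouched).
#' @param branch_attempts Retry budget for finding a feasible merge in
#'   branched mode.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(max_steps = 5L, mode = c("linear", "branched", "mixed"),
                           seed = NULL, branch_attempts = 50L) {
  mode <- match.arg(mode)
  stopifnot(max_steps >= 1L, branch_attempts >= 1L)
  structure(
    list(
      max_steps = as.integer(max_steps), mode = mode, seed = seed,
      branch_attempts = as.integer(branch_attempts)
    ),
    class = "sampler_config"
  )
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

sample1 <- function(x) x[[sample.int(length(x), 1L)]]

new_route <- function(steps) {
  products <- steps$product
  reactants <- unlist(steps$reactants, use.names = FALSE)
  structure(
    list(
      steps = steps,
      building_blocks = sort(unique(reactants[!reactants %in% products])),
      target = products[[length(products)]]
    ),
    class = "synthesis_route"
  )
}

#' @export
print.synthesis_route <- function(x, ...) {
  cat(sprintf("<synthesis_route: %d step(s) -> %s>\n", nrow(x$steps), x$target))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf(
      "  %d. RXN %d: %s >> %s\n", i, x$steps$template_id[i],
      paste(x$steps$reactants[[i]], collapse = " + "), x$steps$product[i]
    ))
  }
  invisible(x)
}

#' Initial-template selection weights
#'
#' The weight of template `t` is the number of realizable reactant tuples,
#' i.e. the product over its slots of the compatibility-pool sizes. Templates
#' with any empty slot get weight zero, so they can never start a route.
#'
#' @param index A `compat_index`.
#' @param registry A `template_registry`.
#' @return Numeric vector of weights aligned with `registry` rows.
#' @export
template_weights <- function(index, registry) {
  counts <- count(as_tibble(index), .data$template_id, .data$slot)
  vapply(seq_len(nrow(registry)), function(i) {
    tid <- registry$template_id[i]
    n <- counts$n[match(
      paste(tid, seq_len(registry$arity[i])),
      paste(counts$template_id, counts$slot)
    )]
    if (anyNA(n)) 0 else prod(n)
  }, numeric(1))
}

#' Draw the initial template of a route
#'
#' Draws a template id with probability proportional to [template_weights()].
#'
#' @inheritParams template_weights
#' @return A single `template_id`.
#' @export
select_initial_template <- function(index, registry) {
  w <- template_weights(index, registry)
  if (all(w == 0)) {
    stop_synthspace("no_realizable_template", "no template has all slots populated")
  }
  registry$template_id[sample.int(nrow(registry), 1L, prob = w)]
}

# Templates the current intermediate can feed: it matches >=1 slot and every
# other slot has a nonempty pool. Returns list of (template row index,
# matched slots).
next_step_options <- function(space, intermediate) {
  reg <- space$registry
  counts <- count(as_tibble(space$index), .data$template_id, .data$slot)
  per_rxn <- cs_match_slots(reg$smarts, intermediate)[[1]]
  opts <- list()
  for (j in seq_len(nrow(reg))) {
    ms <- per_rxn[[j]]
    if (!length(ms)) next
    others <- setdiff(seq_len(reg$arity[j]), ms)
    pool_n <- counts$n[match(
      paste(reg$template_id[j], seq_len(reg$arity[j])),
      paste(counts$template_id, counts$slot)
    )]
    feasible <- ms[vapply(ms, function(s) {
      rest <- setdiff(seq_len(reg$arity[j]), s)
      !length(rest) || !anyNA(pool_n[rest])
    }, logical(1))]
    if (length(feasible)) {
      opts[[length(opts) + 1L]] <- list(j = j, slots = feasible)
    }
  }
  opts
}

fill_slots <- function(space, trow, fixed = list()) {
  # fixed: named list slot -> smiles; remaining slots drawn uniformly from pools
  tuple <- character(trow$arity)
  for (s in seq_len(trow$arity)) {
    key <- as.character(s)
    if (!is.null(fixed[[key]])) {
      tuple[s] <- fixed[[key]]
    } else {
      pool <- index_pool(space$index, trow$template_id, s)
      if (nrow(pool) == 0L) {
        return(NULL)
      }
      tuple[s] <- sample1(pool$smiles)
    }
  }
  tuple
}

sample_step <- function(space, trow, fixed = list(), tries = 5L) {
  for (k in seq_len(tries)) {
    tuple <- fill_slots(space, trow, fixed)
    if (is.null(tuple)) {
      return(NULL)
    }
    prods <- cs_react(trow$smarts, list(tuple))[[1]]
    if (!identical(prods, NA) && length(prods)) {
      return(list(reactants = tuple, product = sample1(prods)))
    }
  }
  NULL
}

sample_linear_impl <- function(space, max_steps) {
  reg <- space$registry
  w <- template_weights(space$index, reg)
  if (all(w == 0)) {
    stop_synthspace("no_realizable_template", "no template has all slots populated")
  }
  first <- NULL
  for (k in seq_len(20L)) {
    j <- sample.int(nrow(reg), 1L, prob = w)
    first <- sample_step(space, reg[j, ])
    if (!is.null(first)) break
  }
  if (is.null(first)) {
    stop_synthspace("no_realizable_template", "no initial template application succeeded")
  }
  steps <- tibble(
    step = 1L, template_id = reg$template_id[j],
    reactants = list(first$reactants), product = first$product
  )
  intermediate <- first$product
  while (nrow(steps) < max_steps) {
    opts <- next_step_options(space, intermediate)
    if (!length(opts)) break
    done <- FALSE
    for (o in sample(opts)) {
      trow <- reg[o$j, ]
      slot <- sample1(o$slots)
      st <- sample_step(space, trow, fixed = setNames(list(intermediate), as.character(slot)))
      if (!is.null(st)) {
        steps <- bind_rows(steps, tibble(
          step = nrow(steps) + 1L, template_id = trow$template_id,
          reactants = list(st$reactants), product = st$product
        ))
        intermediate <- st$product
        done <- TRUE
        break
      }
    }
    if (!done) break
  }
  new_route(steps)
}

#' Sample a linear synthesis route
#'
#' Grows a route forward from a weighted initial template draw; each
#' subsequent step consumes the current intermediate in one matching slot and
#' recruits library building blocks for the others. Growth stops when no
#' template matches the intermediate or `max_steps` is reached.
#'
#' @param space A `synth_space`.
#' @param config A [sampler_config()].
#' @return A `synthesis_route`.
#' @export
sample_linear_route <- function(space, config = sampler_config()) {
  with_seed(config$seed, sample_linear_impl(space, config$max_steps))
}

sample_branched_impl <- function(space, config) {
  reg <- space$registry
  max_steps <- config$max_steps
  if (max_steps < 3L) {
    stop_synthspace(
      "branch_unrealizable",
      "branched routes need max_steps >= 3 (two sub-trees plus a merge)"
    )
  }
  counts <- count(as_tibble(space$index), .data$template_id, .data$slot)
  for (attempt in seq_len(config$branch_attempts)) {
    s_a <- sample.int(max_steps - 2L, 1L)
    s_b <- sample.int(max_steps - 1L - s_a, 1L)
    r_a <- sample_linear_impl(space, s_a)
    r_b <- sample_linear_impl(space, s_b)
    m_a <- r_a$target
    m_b <- r_b$target
    hits <- cs_match_slots(reg$smarts, c(m_a, m_b))
    merges <- list()
    for (j in seq_len(nrow(reg))) {
      sa <- hits[[1]][[j]]
      sb <- hits[[2]][[j]]
      if (!length(sa) || !length(sb)) next
      pool_n <- counts$n[match(
        paste(reg$template_id[j], seq_len(reg$arity[j])),
        paste(counts$template_id, counts$slot)
      )]
      for (i in sa) {
        for (k in setdiff(sb, i)) {
          rest <- setdiff(seq_len(reg$arity[j]), c(i, k))
          if (!length(rest) || !anyNA(pool_n[rest])) {
            merges[[length(merges) + 1L]] <- list(j = j, i = i, k = k)
          }
        }
      }
    }
    if (!length(merges)) next
    for (m in sample(merges)) {
      trow <- reg[m$j, ]
      fixed <- setNames(list(m_a, m_b), as.character(c(m$i, m$k)))
      st <- sample_step(space, trow, fixed = fixed)
      if (is.null(st)) next
      steps_b <- r_b$steps
      steps_b$step <- steps_b$step + nrow(r_a$steps)
      merge_step <- tibble(
        step = nrow(r_a$steps) + nrow(steps_b) + 1L,
        template_id = trow$template_id,
        reactants = list(st$reactants), product = st$product
      )
      return(new_route(bind_rows(r_a$steps, steps_b, merge_step)))
    }
  }
  stop_synthspace(
    "branch_unrealizable",
    sprintf("no feasible branched route in %d attempts", config$branch_attempts)
  )
}

#' Sample a branched synthesis route
#'
#' Grows two independent sub-trees and merges their intermediates as reactants
#' of a single template application, so the returned route always contains at
#' least one step with two non-building-block reactants. Retries up to
#' `config$branch_attempts` times before failing with
#' `synthspace_branch_unrealizable`.
#'
#' @inheritParams sample_linear_route
#' @return A `synthesis_route`.
#' @export
sample_branched_route <- function(space, config = sampler_config(mode = "branched")) {
  with_seed(config$seed, sample_branched_impl(space, config))
}

#' Sample many routes into a tibble
#'
#' @inheritParams sample_linear_route
#' @param n Number of routes.
#' @return A tibble with columns `route_id`, `mode`, `target`, `n_steps`, and
#'   a `route` list-column of `synthesis_route` objects.
#' @export
sample_routes <- function(space, n, config = sampler_config()) {
  stopifnot(n >= 1L)
  with_seed(config$seed, {
    modes <- switch(config$mode,
      linear = rep("linear", n),
      branched = rep("branched", n),
      mixed = ifelse(runif(n) < 0.5, "linear", "branched")
    )
    routes <- lapply(modes, function(m) {
      if (m == "linear") {
        sample_linear_impl(space, config$max_steps)
      } else {
        sample_branched_impl(space, config)
      }
    })
    tibble(
      route_id = seq_len(n),
      mode = modes,
      target = vapply(routes, `[[`, character(1), "target"),
      n_steps = vapply(routes, function(r) nrow(r$steps), integer(1)),
      route = routes
    )
  })
}

#' Check a route against the space invariants
#'
#' Returns a character vector of violations (empty when the route is valid):
#' step count within `[1, max_steps]`, known templates, reactant count equal
#' to template arity, every product reproducible by forward application of its
#' template to its reactants, every reactant either a leaf building block or
#' the product of an earlier step, target equal to the final product, and the
#' `building_blocks` field equal to the set of leaf reactants.
#'
#' @param route A `synthesis_route`.
#' @param registry A `template_registry`.
#' @param max_steps Step cap to enforce (default 5).
#' @return Character vector of violation messages.
#' @export
validate_route <- function(route, registry, max_steps = 5L) {
  v <- character()
  steps <- route$steps
  n <- nrow(steps)
  if (n < 1L || n > max_steps) {
    v <- c(v, sprintf("step count: %d not in [1, %d]", n, max_steps))
  }
  products <- steps$product
  for (i in seq_len(n)) {
    tid <- steps$template_id[i]
    ti <- match(tid, registry$template_id)
    if (is.na(ti)) {
      v <- c(v, sprintf("step %d: unknown template id %s", i, tid))
      next
    }
    reactants <- steps$reactants[[i]]
    if (length(reactants) != registry$arity[ti]) {
      v <- c(v, sprintf("step %d: reactant count != template arity", i))
      next
    }
    if (anyNA(cs_canon(c(reactants, products[i])))) {
      v <- c(v, sprintf("step %d: unparsable SMILES", i))
      next
    }
    prods <- cs_react(registry$smarts[ti], list(reactants))[[1]]
    if (identical(prods, NA) || !(cs_canon(products[i]) %in% prods)) {
      v <- c(v, sprintf("step %d: product not derivable", i))
    }
    for (r in reactants) {
      if (r %in% products && !(r %in% products[seq_len(i - 1L)])) {
        v <- c(v, sprintf("step %d: reactant '%s' produced by a later step", i, r))
      }
    }
  }
  if (n >= 1L && !identical(route$target, products[n])) {
    v <- c(v, "target != final product")
  }
  reactants_all <- unlist(steps$reactants, use.names = FALSE)
  leaves <- sort(unique(reactants_all[!reactants_all %in% products]))
  if (!setequal(route$building_blocks, leaves)) {
    v <- c(v, "building_blocks != leaf reactants")
  }
  v
}

#' Does a route contain a convergent (branched) step?
#'
#' A route is branched iff at least one step consumes two or more
#' intermediates (reactants that are products of earlier steps) — the
#' defining predicate of the branched test sets.
#'
#' @param route A `synthesis_route`.
#' @return `TRUE` or `FALSE`.
#' @export
route_is_branched <- function(route) {
  products <- route$steps$product
  any(vapply(seq_len(nrow(route$steps)), function(i) {
    sum(route$steps$reactants[[i]] %in% products[seq_len(i - 1L)]) >= 2L
  }, logical(1)))
}

# JSON-friendly forward-order representation (used for routes.jsonl and
# golden fixtures).
route_to_list <- function(route) {
  list(
    steps = lapply(seq_len(nrow(route$steps)), function(i) {
      list(
        template_id = route$steps$template_id[i],
        reactants = as.list(route$steps$reactants[[i]]),
        product = route$steps$product[i]
      )
    }),
    building_blocks = as.list(route$building_blocks),
    target = route$target
  )
}

route_from_list <- function(x) {
  steps <- tibble(
    step = seq_along(x$steps),
    template_id = vapply(x$steps, function(s) as.integer(s$template_id), integer(1)),
    reactants = lapply(x$steps, function(s) {
      vapply(s$reactants, as.character, character(1))
    }),
    product = vapply(x$steps, function(s) as.character(s$product), character(1))
  )
  new_route(steps)
}
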