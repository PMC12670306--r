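# Mid-level vectorised chemistry wrappers over the worker, with memoisation.
# Invalid molecules are reported as NA sentinels (never NULL, so they cache).

SEP1 <- "\x1f"
SEP2 <- "\x1e"

null_na <- function(x, na) if (is.null(x)) na else x

cs_canon <- function(smiles) {
  if (!length(smiles)) {
    return(character())
  }
  stopifnot(is.character(smiles))
  keys <- paste0("canon", SEP1, smiles)
  got <- cached_vapply(keys, as.list(smiles), function(items) {
    ans <- chem_request("canon", list(smiles = items))
    lapply(ans$r, null_na, na = NA_character_)
  })
  vapply(got, identity, character(1))
}

# Canonicalize, erroring on any unparsable input.
cs_canon_strict <- function(smiles) {
  out <- cs_canon(smiles)
  if (anyNA(out)) {
    stop_unparsable_smiles(smiles[is.na(out)])
  }
  out
}

cs_valid <- function(smiles) !is.na(cs_canon(smiles))

# For each molecule, the 1-based reactant-slot indices of each reaction SMARTS
# it substructure-matches. Returns list[mol][rxn] = integer().
cs_match_slots <- function(rxns, smiles) {
  if (!length(smiles)) {
    return(list())
  }
  rxn_key <- paste(rxns, collapse = SEP2)
  keys <- paste0("slots", SEP1, rxn_key, SEP1, smiles)
  got <- cached_vapply(keys, as.list(smiles), function(items) {
    ans <- chem_request("match_slots", list(rxns = as.list(rxns), smiles = items))
    lapply(ans$r, function(row) {
      if (is.null(row)) {
        return(NA)
      }
      lapply(row, function(slots) vapply(slots, as.integer, integer(1)) + 1L)
    })
  })
  got
}

# Forward application: one reaction SMARTS, a list of ordered reactant tuples.
# Returns a list of character vectors of canonical products (sorted, distinct);
# NA for tuples containing an unparsable reactant.
cs_react <- function(smarts, tuples) {
  if (!length(tuples)) {
    return(list())
  }
  keys <- vapply(
    tuples,
    function(tp) paste0("react", SEP1, smarts, SEP1, paste(tp, collapse = SEP2)),
    character(1)
  )
  cached_vapply(keys, tuples, function(items) {
    ans <- chem_request("react", list(
      smarts = smarts,
      tuples = lapply(items, as.list)
    ))
    lapply(ans$r, function(x) {
      if (!isTRUE(x$ok)) {
        return(NA)
      }
      vapply(x$products, identity, character(1), USE.NAMES = FALSE)
    })
  })
}

cs_rxn_info <- function(smarts) {
  ans <- chem_request("rxn_info", list(smarts = as.list(smarts)))
  tibble(
    smarts = smarts,
    ok = vapply(ans$r, function(x) isTRUE(x$ok), logical(1)),
    n_reactants = vapply(ans$r, function(x) as.integer(x$n_reactants %||% NA), integer(1)),
    n_products = vapply(ans$r, function(x) as.integer(x$n_products %||% NA), integer(1))
  )
}

# Logical matrix [smiles x patterns]; NA rows for unparsable molecules.
cs_substruct <- function(patterns, smiles) {
  ans <- tryCatch(
    chem_request("substruct", list(patterns = as.list(patterns), smiles = as.list(smiles))),
    synthspace_worker_op = function(e) {
      if (grepl("bad pattern", conditionMessage(e), fixed = TRUE)) {
        stop_synthspace("bad_pattern", conditionMessage(e))
      }
      stop(e)
    }
  )
  rows <- lapply(ans$r, function(row) {
    if (is.null(row)) {
      rep(NA, length(patterns))
    } else {
      vapply(row, isTRUE, logical(1))
    }
  })
  matrix(unlist(rows), ncol = length(patterns), byrow = TRUE,
         dimnames = list(NULL, NULL))
}

# Morgan fingerprint on-bit indices (0-based), memoised; NA for invalid input.
cs_morgan <- function(smiles, radius = 2L, n_bits = 4096L) {
  if (!length(smiles)) {
    return(list())
  }
  keys <- paste0("morgan", SEP1, radius, SEP1, n_bits, SEP1, smiles)
  cached_vapply(keys, as.list(smiles), function(items) {
    ans <- chem_request("morgan", list(smiles = items, radius = radius, n_bits = n_bits))
    lapply(ans$r, function(x) {
      if (is.null(x)) NA else vapply(x, as.integer, integer(1))
    })
  })
}

cs_gobbi <- function(smiles) {
  if (!length(smiles)) {
    return(list())
  }
  keys <- paste0("gobbi", SEP1, smiles)
  cached_vapply(keys, as.list(smiles), function(items) {
    ans <- chem_request("gobbi", list(smiles = items))
    lapply(ans$r, function(x) {
      if (is.null(x)) NA else vapply(x, as.integer, integer(1))
    })
  })
}

cs_murcko <- function(smiles) {
  if (!length(smiles)) {
    return(character())
  }
  keys <- paste0("murcko", SEP1, smiles)
  got <- cached_vapply(keys, as.list(smiles), function(items) {
    ans <- chem_request("murcko", list(smiles = items))
    lapply(ans$r, null_na, na = NA_character_)
  })
  vapply(got, identity, character(1))
}

cs_lipinski <- function(smiles) {
  if (!length(smiles)) {
    return(logical())
  }
  keys <- paste0("ro5", SEP1, smiles)
  got <- cached_vapply(keys, as.list(smiles), function(items) {
    ans <- chem_request("lipinski", list(smiles = items))
    lapply(ans$r, null_na, na = NA)
  })
  vapply(got, function(x) as.logical(x), logical(1))
}

# RDKit's own Tanimoto; kept separate from the R-side bit-set implementation
# so tests can compare the two routes.
cs_tanimoto_oracle <- function(a, b, radius = 2L, n_bits = 4096L) {
  ans <- chem_request("tanimoto", list(
    a = as.list(a), b = as.list(b), radius = radius, n_bits = n_bits
  ))
  vapply(ans$r, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1))
}
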