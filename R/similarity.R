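# Molecular similarity scorers used for analog ranking and reporting:
# Tanimoto over hashed Morgan fingerprints (default 4096 bits, radius 2),
# over Morgan fingerprints of Murcko scaffolds, and over Gobbi 2D
# pharmacophore fingerprints. The Tanimoto ratio |A∩B|/|A∪B| is computed in R
# from the fingerprints' on-bit sets; RDKit's own Tanimoto is kept only as an
# independent oracle for tests.

#' Fingerprint configuration
#'
#' @param n_bits Bit width of the hashed fingerprint (power of two; default
#'   4096, the width used for analog similarity reporting).
#' @param radius Morgan radius (default 2, the community default for
#'   ECFP4-like fingerprints).
#' @param flavor `"morgan"` (whole molecule), `"murcko_morgan"` (Morgan
#'   fingerprint of the Murcko scaffold), or `"pharmacophore_2d"` (Gobbi 2D
#'   pharmacophore fingerprint; `n_bits`/`radius` are ignored).
#' @return An `fp_config` list.
#' @export
fp_config <- function(n_bits = 4096L, radius = 2L,
                      flavor = c("morgan", "murcko_morgan", "pharmacophore_2d")) {
  flavor <- match.arg(flavor)
  n_bits <- as.integer(n_bits)
  radius <- as.integer(radius)
  stopifnot(n_bits >= 2L, bitwAnd(n_bits, n_bits - 1L) == 0L, radius >= 1L)
  structure(list(n_bits = n_bits, radius = radius, flavor = flavor),
            class = "fp_config")
}

fp_bits <- function(smiles, cfg) {
  switch(cfg$flavor,
    morgan = cs_morgan(smiles, radius = cfg$radius, n_bits = cfg$n_bits),
    murcko_morgan = {
      scaf <- cs_murcko(smiles)
      # Acyclic molecules have an empty scaffold: compare them whole.
      use <- ifelse(is.na(scaf) | !nzchar(scaf), smiles, scaf)
      cs_morgan(use, radius = cfg$radius, n_bits = cfg$n_bits)
    },
    pharmacophore_2d = cs_gobbi(smiles)
  )
}

jaccard_sets <- function(a, b) {
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  if (nu == 0L) 0 else ni / nu
}

#' Tanimoto similarity between molecules
#'
#' `tanimoto(a, b)` is `|A∩B| / |A∪B|` over the on-bit sets of the configured
#' fingerprints; it is symmetric, lies in `[0, 1]`, and equals exactly 1 for
#' identical canonical molecules (this identity shortcut also covers
#' molecules whose fingerprints are empty). Vectorized over pairs (inputs are
#' recycled).
#'
#' @param a,b SMILES character vectors (recycled to a common length).
#' @param cfg An [fp_config()].
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
tanimoto <- function(a, b, cfg = fp_config()) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  ca <- cs_canon(a)
  cb <- cs_canon(b)
  if (anyNA(ca)) stop_unparsable_smiles(a[is.na(ca)])
  if (anyNA(cb)) stop_unparsable_smiles(b[is.na(cb)])
  fa <- fp_bits(ca, cfg)
  fb <- fp_bits(cb, cfg)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (identical(ca[i], cb[i])) 1 else jaccard_sets(fa[[i]], fb[[i]])
  }
  out
}

#' Murcko-scaffold similarity
#'
#' Tanimoto similarity of Morgan fingerprints computed on the molecules'
#' Murcko scaffolds (ring systems plus linkers, side chains removed). An
#' acyclic molecule has an empty scaffold and is compared as the whole
#' molecule, so an acyclic pair scores exactly its plain [tanimoto()].
#'
#' @inheritParams tanimoto
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
scaffold_similarity <- function(a, b, cfg = fp_config()) {
  cfg$flavor <- "murcko_morgan"
  tanimoto(a, b, cfg)
}

#' Per-target best-analog similarity report
#'
#' For each target, the similarity of its best analog (exact reconstructions
#' count as 1); the summary means follow the reporting convention of counting
#' fully reconstructed targets with a score of 1, with an
#' `mean_similarity_excl_exact` variant that leaves them out. Targets with no
#' analogs are excluded from the means and reflected in `coverage`.
#'
#' @param targets Character vector of target SMILES.
#' @param results List of `reconstruction_result` objects aligned with
#'   `targets`.
#' @return A tibble (one row per target: `target`, `exact_match`, `n_analogs`,
#'   `best_similarity`); the summary list (means, coverage) is attached as
#'   attribute `"summary"` and available via `glance()`.
#' @export
batch_similarity_report <- function(targets, results) {
  if (length(targets) != length(results)) {
    stop_synthspace("length_mismatch", "targets and results must have equal length")
  }
  rows <- tibble(
    target = targets,
    exact_match = vapply(results, function(r) isTRUE(r$exact_match), logical(1)),
    n_analogs = vapply(results, function(r) nrow(r$analogs), integer(1)),
    best_similarity = vapply(results, function(r) {
      if (isTRUE(r$exact_match)) {
        1
      } else if (nrow(r$analogs)) {
        max(r$analogs$similarity)
      } else {
        NA_real_
      }
    }, numeric(1))
  )
  covered <- !is.na(rows$best_similarity)
  summary <- list(
    n_targets = length(targets),
    coverage = mean(covered),
    n_exact = sum(rows$exact_match),
    mean_similarity = if (any(covered)) mean(rows$best_similarity[covered]) else NA_real_,
    mean_similarity_excl_exact = {
      keep <- covered & !rows$exact_match
      if (any(keep)) mean(rows$best_similarity[keep]) else NA_real_
    }
  )
  attr(rows, "summary") <- summary
  class(rows) <- c("similarity_report", class(rows))
  rows
}

#' @export
glance.similarity_report <- function(x, ...) {
  as_tibble(attr(x, "summary"))
}
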