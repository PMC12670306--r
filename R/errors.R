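# Condition helpers: every package error carries class
# c("synthspace_<class>", "synthspace_error", "error"), so callers and tests
# can catch precise failure modes.

stop_synthspace <- function(class, message, ...) {
  abort(message, class = c(paste0("synthspace_", class), "synthspace_error"), ...)
}

stop_unparsable_smiles <- function(smiles) {
  stop_synthspace(
    "unparsable_smiles",
    paste0("unparsable SMILES: ", paste(utils::head(smiles, 5L), collapse = ", "))
  )
}
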