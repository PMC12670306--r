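# Persistent RDKit worker -----------------------------------------------------
#
# All chemistry primitives are served by a long-lived Python subprocess running
# inst/python/chem_worker.py (RDKit). Communication is one JSON object per line
# in each direction. The worker is started lazily on first use and shared by
# the whole session; results are memoised on the R side so repeated queries
# (canonical forms, slot matches, fingerprints) never cross the pipe twice.

.engine <- new.env(parent = emptyenv())

engine_python <- function() {
  p <- getOption("synthspace.python", "")
  if (!nzchar(p)) p <- Sys.getenv("SYNTHSPACE_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) {
    stop_synthspace(
      "no_python",
      "No python interpreter found; set options(synthspace.python=) or SYNTHSPACE_PYTHON."
    )
  }
  unname(p)
}

engine_script <- function() {
  path <- system.file("python", "chem_worker.py", package = "synthspace")
  if (!nzchar(path)) {
    stop_synthspace("internal", "chem_worker.py not found in the installed package.")
  }
  path
}

engine_proc <- function() {
  px <- .engine$proc
  if (!is.null(px) && px$is_alive()) {
    return(px)
  }
  px <- processx::process$new(
    engine_python(), c("-u", engine_script()),
    stdin = "|", stdout = "|", stderr = "|"
  )
  .engine$proc <- px
  .engine$buf <- ""
  ans <- engine_transact(px, list(op = "ping"), timeout_s = 180)
  if (!isTRUE(ans$ok)) {
    stop_synthspace("worker", "chemistry worker failed its startup handshake")
  }
  .engine$rdkit_version <- ans$rdkit
  px
}

engine_transact <- function(px, req, timeout_s = 600) {
  line <- toJSON(req, auto_unbox = TRUE, null = "null", digits = NA)
  px$write_input(paste0(line, "\n"))
  deadline <- Sys.time() + timeout_s
  repeat {
    nl <- regexpr("\n", .engine$buf, fixed = TRUE)
    if (nl > 0L) break
    px$poll_io(1000L)
    chunk <- px$read_output()
    if (nzchar(chunk)) {
      .engine$buf <- paste0(.engine$buf, chunk)
    } else if (!px$is_alive()) {
      err <- paste(px$read_all_error_lines(), collapse = "\n")
      .engine$proc <- NULL
      stop_synthspace("worker", paste0("chemistry worker exited unexpectedly:\n", err))
    } else if (Sys.time() > deadline) {
      stop_synthspace("worker", "chemistry worker timed out")
    }
  }
  line <- substr(.engine$buf, 1L, nl - 1L)
  .engine$buf <- substr(.engine$buf, nl + 1L, nchar(.engine$buf))
  ans <- parse_json(line)
  if (!is.null(ans$error)) {
    stop_synthspace("worker_op", paste0("chemistry worker error: ", ans$error))
  }
  ans
}

chem_request <- function(op, args = NULL, timeout_s = 600) {
  engine_transact(engine_proc(), list(op = op, args = args), timeout_s = timeout_s)
}

#' Stop the background chemistry worker
#'
#' The RDKit worker process is started lazily on first use and normally lives
#' for the whole R session. `chem_engine_stop()` terminates it (it restarts
#' automatically when next needed) and clears the memoisation caches.
#'
#' @return Invisibly, `TRUE`.
#' @export
chem_engine_stop <- function() {
  if (!is.null(.engine$proc)) {
    try(.engine$proc$kill(), silent = TRUE)
    .engine$proc <- NULL
  }
  .engine$cache <- new.env(hash = TRUE, parent = emptyenv())
  invisible(TRUE)
}

engine_cache <- function() {
  if (is.null(.engine$cache)) {
    .engine$cache <- new.env(hash = TRUE, parent = emptyenv())
  }
  .engine$cache
}

# Memoised vector transaction: `keys` must align with `items`; `fetch(items)`
# is called on the uncached subset and must return a list aligned with it.
cached_vapply <- function(keys, items, fetch) {
  cache <- engine_cache()
  out <- vector("list", length(keys))
  hit <- logical(length(keys))
  for (i in seq_along(keys)) {
    v <- cache[[keys[[i]]]]
    if (!is.null(v)) {
      out[[i]] <- v
      hit[i] <- TRUE
    }
  }
  miss <- which(!hit)
  if (length(miss)) {
    first <- !duplicated(keys[miss])
    ask <- miss[first]
    got <- fetch(items[ask])
    for (j in seq_along(ask)) {
      cache[[keys[[ask[j]]]]] <- got[[j]]
    }
    for (i in miss) out[[i]] <- cache[[keys[[i]]]]
  }
  out
}
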