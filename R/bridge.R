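# Python/RDKit bridge.
#
# Ligand parsing, seeded distance-geometry embedding (ETKDGv3) and
# Wildman-Crippen per-atom logP contributions are delegated to RDKit via
# the bundled script inst/python/ligand_bridge.py.  Results are cached per
# (structure, format, seed, attachment pattern) within the session, so
# repeated particle builds re-use one embedding per ligand.

.bridge_cache <- new.env(parent = emptyenv())

vgnp_python <- function() {
  py <- getOption("vgnp.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    vgnp_abort(paste0(
      "No `python` interpreter found on the PATH. Ligand parsing needs ",
      "Python with rdkit; point options(vgnp.python = ...) at one."),
      "vgnp_bridge_error")
  }
  py
}

bridge_key <- function(req) {
  paste(req$structure, req$format, req$seed, req$attachment_smarts,
        sep = "\r")
}

# Run the bridge for a list of requests (each a list with ligand_id,
# structure, format, seed, attachment_smarts).  Returns a list of results
# in request order; raises classed conditions on per-ligand failures.
run_ligand_bridge <- function(requests) {
  keys <- vapply(requests, bridge_key, character(1))
  cached <- vapply(keys, function(k) !is.null(.bridge_cache[[k]]), logical(1))
  todo <- which(!cached)

  if (length(todo) > 0) {
    script <- system.file("python", "ligand_bridge.py", package = "vgnp")
    if (!nzchar(script)) {
      vgnp_abort("bundled ligand_bridge.py not found; reinstall vgnp",
                 "vgnp_bridge_error")
    }
    infile <- tempfile(fileext = ".json")
    outfile <- tempfile(fileext = ".json")
    on.exit(unlink(c(infile, outfile)), add = TRUE)
    jsonlite::write_json(lapply(requests[todo], function(r) r),
                         infile, auto_unbox = TRUE, digits = NA,
                         null = "null")
    err <- system2(vgnp_python(), c(shQuote(script), shQuote(infile),
                                    shQuote(outfile)),
                   stdout = TRUE, stderr = TRUE)
    status <- attr(err, "status")
    if (!is.null(status) && status != 0 || !file.exists(outfile)) {
      vgnp_abort(paste0("ligand bridge failed (is rdkit importable from ",
                        "python?):\n", paste(err, collapse = "\n")),
                 "vgnp_bridge_error")
    }
    results <- jsonlite::read_json(outfile, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE,
                                   simplifyMatrix = FALSE)
    for (i in seq_along(todo)) {
      .bridge_cache[[keys[todo[i]]]] <- results[[i]]
    }
  }

  lapply(keys, function(k) .bridge_cache[[k]])
}

# Drop all cached embeddings (mainly for tests).
clear_ligand_cache <- function() {
  rm(list = ls(.bridge_cache), envir = .bridge_cache)
  invisible(NULL)
}
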