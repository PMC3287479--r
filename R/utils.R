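#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers can distinguish pipeline stages.
stop2 <- function(..., class = "pleiomine_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of an R object, used to stamp output files for provenance.
# tools::md5sum only hashes files, so serialize to a temp file first.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

# Header comment written at the top of every pipeline output file.
provenance_header <- function(config, seed) {
  sprintf("# pleiomine config_hash=%s seed=%s", config_hash(config),
          as.character(seed %||% "NA"))
}
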