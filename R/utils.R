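# Internal helpers shared across modules.

# Strip Ensembl-style ".N" version suffixes; GENCODE versions drift between
# releases so identifiers are joined version-free everywhere.
strip_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

# Stage-count logging goes through here so it can be silenced with
# suppressMessages() or options(lncoex.quiet = TRUE).
log_info <- function(...) {
  if (!isTRUE(getOption("lncoex.quiet", FALSE))) {
    inform(paste0(...))
  }
  invisible(NULL)
}

check_file_exists <- function(path, what = "file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("%s not found: '%s'", what, as.character(path)[1]))
  }
  invisible(path)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}
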