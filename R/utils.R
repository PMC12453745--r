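# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. Mersenne-Twister state is platform-stable, which the seeded
# generators rely on for bit-identical output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}

feba_file <- function(...) {
  path <- system.file("extdata", ..., package = "feba", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) the file may sit under inst/
    path <- system.file("inst", "extdata", ..., package = "feba",
                        mustWork = TRUE)
  }
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_feba <- function(...) stop(sprintf(...), call. = FALSE)

is_binary_labels <- function(y) {
  is.numeric(y) && all(y %in% c(0, 1))
}

# Deterministic order of a numeric vector, descending, ties broken by lower
# index. Used wherever the pipeline must break importance ties reproducibly.
order_desc_stable <- function(x) order(-x, seq_along(x))

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# md5 of a serialized object via base tools (provenance stamps).
hash_config <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                                           force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}
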