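# internal helpers

# Run code with a local RNG seed, leaving the caller's RNG state untouched.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Polynomial rolling hash of a character vector, as an 8-digit hex string.
# Used only for provenance stamps on written artifacts.
.content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967296
  sprintf("%08x", h)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
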