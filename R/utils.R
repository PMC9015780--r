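## Internal helpers: seeded RNG hygiene and config hashing.

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG
## stream. All user-facing sampling goes through this so every operation is
## a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

## Deterministically derive a child seed from a parent seed and a string tag
## (e.g. a patient id), keeping the result in [0, 2^31 - 2]. Cheap FNV-1a
## style fold; collisions are harmless (streams just share a seed).
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

## Polynomial rolling hash over a canonical JSON rendering; used to stamp
## outputs with a config fingerprint so artifacts are traceable to their
## parameters. Not cryptographic -- a provenance checksum only.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
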