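# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-cell substream: hash a string key against a master seed.
# Kept below 2^31 - 1 so the result is a valid integer seed.
seed_stream <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- master %% 2147483647
  for (cc in utf8ToInt(as.character(key))) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}

stop_config <- function(...) {
  stop(structure(class = c("ppirel_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Raised when an activation-thresholded seed mask retains no voxels; mirrors
# the exclusion of a subject whose seed shows no suprathreshold activation.
stop_seed_empty <- function(...) {
  stop(structure(class = c("ppirel_seed_empty", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
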