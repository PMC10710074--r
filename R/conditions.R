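# Classed conditions so callers (and the command-line wrapper) can
# distinguish configuration problems from data problems.

stop_invalid <- function(msg) {
  stop(structure(
    class = c("emdiag_invalid_parameter", "emdiag_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_config <- function(msg) {
  stop(structure(
    class = c("emdiag_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_data <- function(msg) {
  stop(structure(
    class = c("emdiag_data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `expr` with a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded generators do not disturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("`seed` must be a single finite integer.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Small stable hash (FNV-1a over the deparsed object) used in provenance
# blocks; not cryptographic, just a reproducible fingerprint.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
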