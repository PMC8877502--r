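# Internal helpers shared across modules.

# Run `code` under a fixed RNG state, restoring the caller's state on exit.
# Keeps simulation functions pure in (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_config <- function(msg, ...) abort(msg, class = "ticdiff_config_error", ...)
stop_format <- function(msg, ...) abort(msg, class = "ticdiff_format_error", ...)
stop_design <- function(msg, ...) abort(msg, class = "ticdiff_design_error", ...)
stop_stat <- function(msg, ...) abort(msg, class = "ticdiff_stat_error", ...)

# Short deterministic fingerprint of an R object, used in output headers.
config_hash <- function(x) substr(rlang::hash(x), 1, 16)
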