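# Structured conditions so callers (and the CLI) can map failures to exit codes.

retilab_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "retilab_error"), call = call))
}

input_error <- function(msg) retilab_error(msg, "retilab_input_error")
config_error <- function(msg) retilab_error(msg, "retilab_config_error")
generation_error <- function(msg) retilab_error(msg, "retilab_generation_error")
scoring_error <- function(msg) retilab_error(msg, "retilab_scoring_error")

# Evaluate an expression with a private, restorable RNG stream.  All seeded
# operations in the package funnel through this so user RNG state is never
# disturbed and identical seeds give identical results.
with_seed <- function(seed, expr) {
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
    })
    set.seed(as.integer(seed))
  }
  expr
}
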