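# internal helpers

# evaluate `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    })
    set.seed(as.integer(seed))
  }
  expr
}

# counter-based derivation of per-replicate seeds from a master seed, so any
# replicate (or scenario) is reproducible independently of execution order
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2147483647 + 48271 * as.double(counter)) %% 2147483646 + 1)
}

z_quantile <- function(alpha_one_sided) stats::qnorm(1 - alpha_one_sided)

`%||%` <- function(a, b) if (is.null(a)) b else a
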