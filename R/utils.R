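# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators do not perturb the
# session RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# log10(1 + 10^z), a smooth positive ramp used to turn log-concentrations
# into a nonnegative chemical burden; computed stably for large |z|.
softplus10 <- function(z) {
  out <- ifelse(z > 30, z, log10(1 + 10^z))
  out
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 0

# upper-triangle (excluding diagonal) of a square matrix as a vector
upper_tri_vec <- function(m) m[upper.tri(m)]
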