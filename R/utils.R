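# Seed plumbing shared by the generator, the model harness and the pipeline.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme used to fan one master seed out to per-stage
#' and per-item seeds (cohort members, training repeats, partitionings).
#' Children are decorrelated by a multiplicative hash and kept within the
#' 32-bit signed-integer range R requires of `set.seed()`.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer counter (stage or item number).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  x <- (m * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(x %/% 1 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
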