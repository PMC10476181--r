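## Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed and context indices
#'
#' Deterministic integer hash (linear-congruential mixing, modulus 2^31 - 1)
#' so that each (trial, cycle, replica) propagation gets an independent,
#' reproducible noise stream from a single campaign seed.
#'
#' @param master integer master seed.
#' @param ... further integer context components (trial, cycle, replica, ...).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  m <- 2147483647
  h <- 104729
  for (p in as.numeric(parts)) {
    ## double-precision arithmetic stays exact below 2^53
    h <- (h * 48271 + (p %% m) * 16807 + 12345) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

## Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Standard atomic masses (u) for the elements occurring in protein heavy
## atoms plus hydrogen; used for centre-of-mass computations.
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971
)

atomic_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- ATOMIC_MASSES[el]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

stopifnot_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) stop(sprintf("'%s' must be a finite number %s %g", name,
                        if (strict) ">" else ">=", min), call. = FALSE)
  invisible(x)
}
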