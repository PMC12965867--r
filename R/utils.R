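#' @keywords internal
#' @importFrom stats setNames
"_PACKAGE"

# Deterministic child-seed derivation (Lehmer step). Keeps every derived seed
# in [1, 2^31 - 2] so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(k %% 64 + 1)) s <- (s * 48271) %% m
  as.integer((s + k) %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
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

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
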