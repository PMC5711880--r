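# Internal helpers shared across modules.

GW_LEVELS <- c(14L, 18L, 22L)
TARGET_LEVELS <- c("eye", "mouth", "wall")
HAND_LEVELS <- c("right", "left")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + 104729 * offset) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0) || any(x >= 1)) {
    stopf("`%s` must lie strictly in (0, 1)", name)
  }
  invisible(x)
}
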