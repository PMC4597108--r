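## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in genomics
#' reports conventionally round half up. Used by [percent()] and the
#' synthetic-data generator's count rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up (half away from zero for negatives).
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so library code never perturbs the
## user's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Counter-based derived seed: independent of iteration order, stays below
## 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(master, counter) {
  as.integer((as.double(master %% 97561L) * 20011 + as.double(counter) * 9973 +
                104729) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Apportion n among length(p) classes so counts sum to n (largest-remainder).
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
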