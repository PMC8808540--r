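## internal helpers shared across modules

#' Evaluate an expression under a temporary RNG state
#'
#' Sets a fixed seed (Mersenne-Twister / Inversion / Rejection so results
#' are identical across platforms and R versions >= 3.6), evaluates `expr`,
#' then restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

## deterministic small integer hash of a string, for deriving per-sample
## seeds; stays well below 2^31
str_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 1999993L
  as.integer(h)
}

derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "|")
  as.integer((as.numeric(seed) * 48611 + str_hash(parts)) %% 2147483587)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

## running mean over a centered window of `k` elements (k odd not required);
## edges use the partial window
running_mean <- function(x, k) {
  n <- length(x)
  if (k >= n) return(rep(mean(x), n))
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
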