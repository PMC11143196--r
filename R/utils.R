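# internal helpers: seeding, error classes, small numerics

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' package functions are deterministic without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and arbitrary stream labels
#'
#' Mixes the parent seed with string/numeric tokens (stage name, ROI index)
#' through a Lehmer-style recurrence; result is always a valid 32-bit seed.
#' @noRd
derive_seed <- function(seed, ...) {
  toks <- c(as.numeric(seed), unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else as.numeric(x)
  })))
  s <- 11
  for (t in toks) s <- (s * 48271 + abs(t) + 1) %% 2147483587
  as.integer(s)
}

# error conditions: config errors (CLI exit 2) vs data errors (CLI exit 3)
spl_config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("spl_config_error", "spl_error")))
}

spl_data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("spl_data_error", "spl_error")))
}

# population SD (denominator n), the convention used for abundance Z-scores
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
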