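# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Abort with a classed condition so callers/tests can distinguish error kinds.
stop_nutrimpact <- function(msg, class) {
  stop(structure(
    class = c(class, "nutrimpact_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_probability <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_nutrimpact(
      sprintf("%s must be a proportion in [0, 1], got: %s",
              what, paste(format(x), collapse = ", ")),
      "nutrimpact_domain_error"
    )
  }
  invisible(x)
}

assert_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_nutrimpact(sprintf("%s must be a single number", what),
                    "nutrimpact_domain_error")
  }
  invisible(x)
}

# Deterministic 32-bit stream seed from (seed, purpose tag, index), so each
# generator draws from its own reproducible stream and adding a generator
# never perturbs existing fixtures.
stream_seed <- function(seed, tag, index = 0L) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + as.double(index)) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.
with_stream_seed <- function(seed, expr) {
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

# Standard normal quantile used for all 95% intervals (matches review
# software convention; not a t quantile).
Z95 <- 1.959964
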