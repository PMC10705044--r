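# Internal helpers: seeded RNG scoping and input validation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps package functions from clobbering
# the user's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministically derive a child seed from a master seed and integer tags.
# Plain integer arithmetic mod a prime < 2^31 so seeds stay valid R integers
# and per-(sample, trial) streams are order-independent.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  p <- 2147483629  # largest prime < 2^31
  x <- as.numeric(seed) %% p
  for (t in tags) {
    x <- (x * 48271 + as.numeric(t) + 1) %% p
  }
  as.integer(x)
}

stop_config <- function(...) {
  stop(structure(
    class = c("granulefate_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_config(name, " must be > ", lower)
  }
  if (!strict_lower && x < lower) {
    stop_config(name, " must be >= ", lower)
  }
  if (x > upper) stop_config(name, " must be <= ", upper)
  invisible(x)
}
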