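# internal helpers shared across modules

abort2 <- function(message, class) {
  stop(structure(
    class = c(class, "blse_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
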