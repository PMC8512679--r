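# Set the RNG seed for the duration of the calling frame, restoring the
# previous global RNG state on exit, so generator functions are pure
# functions of their seed without clobbering the caller's stream.
local_rng_seed <- function(seed, env = parent.frame()) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  cleanup <- if (is.null(old)) {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  } else {
    function() assign(".Random.seed", old, envir = globalenv())
  }
  do.call(base::on.exit, list(substitute(cleanup(), list(cleanup = cleanup)),
                              add = TRUE), envir = env)
  invisible(seed)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# kept below 2^31 - 1.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483563
  as.integer(h + 1)
}

# first-derivative operator matrix matching differentiate(): central
# differences inside, one-sided first-order at the ends
diff_matrix <- function(n, fs) {
  h <- 1 / fs
  D <- matrix(0, n, n)
  D[1, 1:2] <- c(-1, 1) / h
  D[n, (n - 1):n] <- c(-1, 1) / h
  for (i in 2:(n - 1)) D[i, c(i - 1, i + 1)] <- c(-1, 1) / (2 * h)
  D
}

# smootherstep ramp (zero first and second derivative at both ends)
smootherstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (x * (x * 6 - 15) + 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
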