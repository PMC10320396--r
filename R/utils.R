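# internal numeric helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp for a matrix
row_logsumexp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic child seeds from one master seed (counter scheme);
# kept below 2^31 so they are valid R integer seeds
child_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + counter * 2654435761) %% 2147483647)
}

# run code with a private RNG stream, restoring the caller's stream after
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)
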