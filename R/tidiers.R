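#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concordance fit into one row per association pattern
#'
#' @param x A `pattern_fit`.
#' @param ... Unused.
#' @return Tibble `pattern, weight` plus one logical column per study.
#' @export
tidy.pattern_fit <- function(x, ...) {
  out <- tibble::tibble(pattern = pattern_labels(x$patterns), weight = x$pi)
  for (j in seq_along(x$studies))
    out[[x$studies[j]]] <- x$patterns[, j] == 1L
  out
}

#' One-row summary of a concordance fit
#'
#' @param x A `pattern_fit`.
#' @param ... Unused.
#' @return Tibble with genes, studies, null weight, log-likelihood,
#'   iteration count and convergence flag.
#' @export
glance.pattern_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_studies = length(x$studies),
    pi_null = x$pi[1],
    logLik = x$loglik[length(x$loglik)],
    iterations = x$iterations,
    converged = x$converged
  )
}
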