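#' Transform p-values to chi-square-scale statistics
#'
#' `t = -2 ln p`, so that null (uniform) p-values give t distributed as a
#' 2-df chi-square. This is the statistic scale on which the concordance
#' mixture model operates.
#'
#' @param P Numeric vector or matrix of p-values in (0, 1].
#' @return Object of the same shape with `t >= 0`.
#' @export
transform_pvalues <- function(P) {
  if (any(!is.finite(P)) || any(P <= 0 | P > 1))
    stop_format("transform_pvalues: p-values must lie in (0, 1]")
  -2 * log(P)
}

# all 2^J binary association patterns, K x J; row 1 is the all-null pattern
pattern_matrix <- function(J) {
  K <- 2L^J
  Q <- matrix(0L, K, J)
  for (j in seq_len(J)) Q[, j] <- bitwAnd(seq_len(K) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  storage.mode(Q) <- "integer"
  colnames(Q) <- paste0("study", seq_len(J))
  Q
}

pattern_labels <- function(Q) apply(Q, 1L, paste, collapse = "")

#' Fit one study's null/alternative mixture densities
#'
#' The null density of `t = -2 ln p` is the 2-df chi-square. The alternative
#' is a scaled 2-df chi-square whose scale is estimated from the upper tail:
#' `a = max(1 + 1e-6, mean of the ceiling(alt_prop * G) largest statistics / 2)`
#' — a moment estimate under the working assumption that roughly an
#' `alt_prop` fraction of statistics come from the alternative.
#'
#' @param t_column Numeric vector of G statistics for one study.
#' @param alt_prop Prior alternative proportion in (0, 0.5).
#' @return List with the scale `a` and `n_tail` (tail size used).
#' @export
fit_study_mixture <- function(t_column, alt_prop = 1e-3) {
  stopifnot(alt_prop > 0, alt_prop < 0.5)
  G <- length(t_column)
  n_tail <- ceiling(alt_prop * G)
  if (n_tail < 5)
    warning("fewer than 5 tail statistics available for the alternative scale; ",
            "estimate will be noisy", call. = FALSE)
  a <- max(1 + 1e-6, mean(sort(t_column, decreasing = TRUE)[seq_len(n_tail)]) / 2)
  list(a = a, n_tail = n_tail)
}

# log density of t under the null (chi^2_2) and scaled-chi^2_2 alternative
log_dnull <- function(t) -t / 2 - log(2)
log_dalt <- function(t, a) -t / (2 * a) - log(2 * a)

#' EM for the 2^J pattern weights
#'
#' E-step: `posterior_ik` proportional to `pi_k * prod_j f_j^{(q_kj)}(t_ij)`
#' with `f^(1)` the scaled-chi-square alternative and `f^(0)` the chi-square
#' null, computed in log space. M-step: `pi_k = mean_i posterior_ik`.
#' Initialization puts 0.9 on the all-null pattern and spreads the rest
#' uniformly. The observed-data log-likelihood is non-decreasing across
#' iterations; convergence is `max |delta pi| < tol`.
#'
#' @param T G x J matrix of statistics (from [transform_pvalues()]).
#' @param a Per-study alternative scales (length J), from
#'   [fit_study_mixture()].
#' @param tol Convergence tolerance on the pattern weights.
#' @param max_iter Iteration cap (warns and flags on non-convergence).
#' @param init Optional starting weights (length 2^J, summing to 1).
#' @return List: `pi` (length 2^J), `posterior` (G x K, consistent with the
#'   returned `pi`), `loglik` (trace), `iterations`, `converged`,
#'   `patterns` (K x J).
#' @export
em_pattern_weights <- function(T, a, tol = 1e-6, max_iter = 1000L, init = NULL) {
  T <- as.matrix(T)
  J <- ncol(T)
  if (J > 8) stop_format("em_pattern_weights: at most 8 studies (2^J patterns)")
  stopifnot(length(a) == J)
  Q <- pattern_matrix(J)
  K <- nrow(Q)
  lf0 <- log_dnull(T)
  lf1 <- vapply(seq_len(J), function(j) log_dalt(T[, j], a[j]), numeric(nrow(T)))
  D <- lf1 - lf0                      # G x J log density ratios
  L <- D %*% t(Q)                     # G x K pattern log-likelihood offsets
  base <- rowSums(lf0)                # per-gene constant
  pi_k <- init %||% c(0.9, rep(0.1 / (K - 1), K - 1))
  stopifnot(length(pi_k) == K, abs(sum(pi_k) - 1) < 1e-8)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post <- NULL
  repeat {
    iter <- iter + 1L
    M <- sweep(L, 2L, log(pi_k), `+`)
    mx <- apply(M, 1L, max)
    E <- exp(M - mx)
    rs <- rowSums(E)
    loglik <- c(loglik, sum(mx + log(rs)) + sum(base))
    post <- E / rs
    pi_new <- colMeans(post)
    delta <- max(abs(pi_new - pi_k))
    pi_k <- pi_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) {
      warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)
      break
    }
  }
  # refresh the E-step so the returned posterior matches the returned weights
  M <- sweep(L, 2L, log(pi_k), `+`)
  mx <- apply(M, 1L, max)
  E <- exp(M - mx)
  post <- E / rowSums(E)
  list(pi = pi_k, posterior = post, loglik = loglik,
       iterations = iter, converged = converged, patterns = Q)
}

#' Per-gene, per-study marginal association posteriors
#'
#' `PP_ij` is the posterior mass on patterns with a 1 in study j.
#'
#' @param fit A `pattern_fit` (or the list from [em_pattern_weights()]).
#' @param pp_threshold Posterior-probability call threshold (default 0.95).
#' @return List: `PP` (G x J matrix) and `significant` (tibble of
#'   gene/study pairs with `PP > pp_threshold`).
#' @export
pattern_posteriors <- function(fit, pp_threshold = 0.95) {
  PP <- pmin(pmax(fit$posterior %*% fit$patterns, 0), 1)
  genes <- fit$genes %||% seq_len(nrow(PP))
  studies <- fit$studies %||% colnames(fit$patterns)
  dimnames(PP) <- list(NULL, studies)
  hits <- which(PP > pp_threshold, arr.ind = TRUE)
  significant <- tibble::tibble(
    gene = genes[hits[, 1L]],
    study = studies[hits[, 2L]],
    PP = PP[hits]
  )
  list(PP = PP, significant = dplyr::arrange(significant, .data$gene, .data$study))
}

#' Fit the multi-study concordance model
#'
#' Joint analysis of J studies' gene-level p-values: each study contributes
#' a two-group mixture (chi-square null, scaled-chi-square alternative with
#' prior alternative proportion `alt_props`), and genes are assigned
#' posteriors over all 2^J binary association patterns by EM. Conditional on
#' the pattern, studies are treated as independent.
#'
#' @param P Gene x study matrix (or data frame) of p-values in (0, 1], with
#'   genes in `rownames` or supplied via `genes`.
#' @param genes,studies Optional gene and study labels.
#' @param alt_props Prior alternative proportion per study (scalar recycled,
#'   default 1e-3).
#' @param tol,max_iter EM controls.
#' @return Object of class `pattern_fit`: pattern weights `pi`, per-study
#'   alternative scales `a`, `posterior` (G x 2^J), marginal posteriors `PP`
#'   (G x J), the log-likelihood trace and labels.
#' @export
fit_concordance <- function(P, genes = NULL, studies = NULL, alt_props = 1e-3,
                            tol = 1e-6, max_iter = 1000L) {
  P <- as.matrix(P)
  genes <- genes %||% rownames(P) %||% paste0("gene", seq_len(nrow(P)))
  studies <- studies %||% colnames(P) %||% paste0("study", seq_len(ncol(P)))
  if (ncol(P) < 1) stop_format("fit_concordance: need at least one study")
  if (anyNA(P)) stop_format("fit_concordance: P must have no missing entries")
  if (nrow(P) < 100)
    warning("fewer than 100 genes; mixture density estimation is unreliable",
            call. = FALSE)
  alt_props <- rep_len(alt_props, ncol(P))
  T <- transform_pvalues(P)
  mix <- lapply(seq_len(ncol(P)), function(j) fit_study_mixture(T[, j], alt_props[j]))
  a <- vapply(mix, `[[`, numeric(1), "a")
  em <- em_pattern_weights(T, a, tol = tol, max_iter = max_iter)
  colnames(em$patterns) <- studies
  fit <- structure(list(
    genes = genes, studies = studies, alt_props = alt_props, a = a,
    pi = em$pi, patterns = em$patterns, posterior = em$posterior,
    loglik = em$loglik, iterations = em$iterations, converged = em$converged
  ), class = "pattern_fit")
  pp <- pattern_posteriors(fit)
  fit$PP <- pp$PP
  fit
}

#' @export
print.pattern_fit <- function(x, ...) {
  cat(sprintf("<pattern_fit> %d genes x %d studies; %d patterns; %s after %d EM iterations\n",
              length(x$genes), length(x$studies), length(x$pi),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  all-null weight pi_0 = %.4f; alternative scales: %s\n",
              x$pi[1], paste(sprintf("%.2f", x$a), collapse = ", ")))
  invisible(x)
}

#' Genes called associated at a posterior-probability threshold
#'
#' @param fit A `pattern_fit`.
#' @param pp_threshold Call threshold (default 0.95).
#' @return Tibble `gene, study, PP`.
#' @export
significant_concordance <- function(fit, pp_threshold = 0.95) {
  pattern_posteriors(fit, pp_threshold)$significant
}

#' Sensitivity sweep over the prior alternative proportion
#'
#' Refits the concordance model on a grid of `alt_props` values and counts
#' PP-threshold calls; larger priors typically admit more calls.
#'
#' @inheritParams fit_concordance
#' @param grid Values of `alt_props` to sweep.
#' @param pp_threshold Call threshold.
#' @return Tibble `alt_props, n_significant, pi_null`.
#' @export
sweep_alt_props <- function(P, grid = c(1e-4, 1e-3, 1e-2), genes = NULL,
                            studies = NULL, pp_threshold = 0.95, tol = 1e-6,
                            max_iter = 1000L) {
  rows <- lapply(grid, function(ap) {
    fit <- fit_concordance(P, genes = genes, studies = studies, alt_props = ap,
                           tol = tol, max_iter = max_iter)
    tibble::tibble(alt_props = ap,
                   n_significant = nrow(significant_concordance(fit, pp_threshold)),
                   pi_null = fit$pi[1])
  })
  dplyr::bind_rows(rows)
}
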