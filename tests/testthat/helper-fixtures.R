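# shared fixture builders and independent oracles

# hand-built aligned region: effects and LD specified directly
make_region <- function(b_zx, se_zx, b_zy, se_zy, ld = NULL, pos = NULL,
                        p_zx = NULL) {
  m <- length(b_zx)
  z <- b_zx / se_zx
  structure(list(
    probe = tibble::tibble(probe_id = "p1", gene = "G1", chrom = "1",
                           probe_pos = 1000000L, paradigm = "expression"),
    snps = tibble::tibble(
      snp = paste0("rs", seq_len(m)), pos = pos %||% (seq_len(m) * 1000L),
      a1 = "A", a2 = "G",
      b_zx = b_zx, se_zx = se_zx,
      p_zx = p_zx %||% (2 * stats::pnorm(-abs(z))),
      b_zy = b_zy, se_zy = se_zy,
      p_zy = 2 * stats::pnorm(-abs(b_zy / se_zy)),
      freq_xqtl = 0.3, freq_gwas = 0.3, freq_ref = 0.3),
    ld = ld %||% diag(m),
    counts = c(kept = m)
  ), class = "aligned_region")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent re-derivation of the HEIDI difference covariance (test oracle)
oracle_heidi_cov <- function(region, top, snp_set) {
  idx <- c(top, snp_set)
  s <- region$snps[idx, ]
  R <- region$ld[idx, idx, drop = FALSE]
  n <- length(idx)
  b <- s$b_zy / s$b_zx
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- R[i, j] * (s$se_zy[i] * s$se_zy[j] +
                            b[i] * b[j] * s$se_zx[i] * s$se_zx[j]) /
      (s$b_zx[i] * s$b_zx[j])
  }
  m <- n - 1L
  Cd <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    Cd[i, j] <- V[i + 1, j + 1] - V[i + 1, 1] - V[j + 1, 1] + V[1, 1]
  }
  list(d = b[-1] - b[1], Cd = Cd)
}

# exhaustive-enumeration hypergeometric upper tail (small N oracle)
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K]
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# hand-rolled Benjamini-Hochberg step-up (oracle for bh_fdr)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}
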