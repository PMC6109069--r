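# Independent free-energy oracle: unbinned MBAR-style estimator.
#
# Deliberately a different algorithm from the package's binned histogram
# WHAM: the self-consistency runs over individual samples, and the density
# is assembled from per-sample weights afterwards.  Used only as a
# cross-check.
mbar_pmf_oracle <- function(windows, temperature_K = 310, edges,
                            tol = 1e-9, max_iter = 3000L) {
  kT <- 0.0083144621 * temperature_K
  z <- unlist(lapply(windows, function(w) w$samples))
  N <- vapply(windows, function(w) length(w$samples), numeric(1))
  U <- vapply(windows, function(w) {
    0.5 * w$force_constant * (z - w$center)^2 / kT
  }, numeric(length(z)))                       # reduced bias, N_tot x K
  expU <- exp(-U)
  f <- numeric(length(windows))                # reduced free energies
  for (it in seq_len(max_iter)) {
    d <- as.vector(exp(sweep(-U, 2L, f, `+`)) %*% N)
    f_new <- -log(colSums(expU / d))
    f_new <- f_new - f_new[1L]
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  d <- as.vector(exp(sweep(-U, 2L, f, `+`)) %*% N)
  w_n <- 1 / d
  idx <- findInterval(z, edges, rightmost.closed = TRUE, all.inside = TRUE)
  P <- vapply(seq_len(length(edges) - 1L),
              function(b) sum(w_n[idx == b]), numeric(1))
  P <- P / sum(P)
  ifelse(P > 0, -kT * log(P), NA_real_)
}
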