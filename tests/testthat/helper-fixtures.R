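# Small in-code fixtures shared across the suite.

# A minimal frame: one glutamate (two carboxylate oxygens 0.22 nm apart,
# centroid at `at`) plus `n_shell` shell atoms placed on a circle of radius
# `shell_r` around the centroid.
toy_residue_frame <- function(residue = "E343", at = c(0, 0, 0),
                              n_shell = 20L, shell_r = 0.5) {
  rows <- data.frame(
    atom = paste0(residue, "_O", 1:2),
    residue = residue, role = "carboxyl_O",
    x = at[1] + c(0.11, -0.11), y = at[2], z = at[3],
    stringsAsFactors = FALSE
  )
  if (n_shell > 0L) {
    th <- 2 * pi * seq_len(n_shell) / n_shell
    rows <- rbind(rows, data.frame(
      atom = paste0("SH", seq_len(n_shell)), residue = NA_character_,
      role = "shell",
      x = at[1] + shell_r * cos(th), y = at[2] + shell_r * sin(th),
      z = at[3], stringsAsFactors = FALSE
    ))
  }
  rows
}

add_atom <- function(frame, atom, role, pos, residue = NA_character_) {
  rbind(frame, data.frame(atom = atom, residue = residue, role = role,
                          x = pos[1], y = pos[2], z = pos[3],
                          stringsAsFactors = FALSE))
}

# Repeat a static frame over a time grid to make a trajectory table.
as_trajectory <- function(frame, times) {
  do.call(rbind, lapply(times, function(t) {
    fr <- frame
    fr$time_ns <- t
    fr
  }))
}

# Hand-built correlation_matrix object (for filter/ranking tests where the
# matrix itself is the input, not the series).
fake_corr_matrix <- function(r, state, means = NULL, replicate = 1L,
                             n = 100L) {
  res <- rownames(r)
  if (is.null(means)) means <- stats::setNames(rep(4.5, length(res)), res)
  out <- list(residues = res, r = r, n = n, window = c(t_start = 150,
                                                       t_end = 250),
              means = means, ci_lo = NULL, ci_hi = NULL, level = NULL,
              state = state, replicate = as.integer(replicate))
  class(out) <- "correlation_matrix"
  out
}

# Symmetric random correlation-like matrix over the pocket (entries in
# [-1, 1], unit diagonal); not necessarily PSD, which the filter tests do
# not require.
random_r_matrix <- function(pocket = hka_pocket()) {
  p <- length(pocket)
  r <- matrix(0, p, p, dimnames = list(pocket, pocket))
  vals <- stats::runif(p * (p - 1) / 2, -1, 1)
  r[upper.tri(r)] <- vals
  r <- r + t(r)
  diag(r) <- 1
  r
}

write_pka_csv <- function(path, times, values, residues = hka_pocket()) {
  header <- paste(c("time_ns", residues), collapse = ",")
  rows <- vapply(seq_along(times), function(i) {
    paste(c(times[i], values[i, ]), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}
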