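# Windowed Pearson correlation of pKa time series.
#
# The per-trajectory statistic of the analysis: pairwise Pearson r over the
# trailing window of each pKa series (by default the last 100 ns, i.e.
# n = 100 samples at 1 ns), with Fisher-z confidence intervals for the
# strongest pairs.  Strong negative r between a protonated/deprotonated pair
# is the downstream signal of proton-transfer propensity.

#' Pearson correlation coefficient of two series
#'
#' Direct evaluation of
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`
#' over the supplied samples. `NA` pairs (e.g. predictor failures) are
#' dropped pairwise; the number dropped is reported via `attr(, "n_dropped")`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Pearson r in `[-1, 1]`, with attributes `n` (pairs used) and
#'   `n_dropped`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx * dx)
  sy <- sum(dy * dy)
  if (sx == 0 || sy == 0) {
    stop("undefined correlation: zero variance in a series", call. = FALSE)
  }
  r <- sum(dx * dy) / sqrt(sx * sy)
  r <- min(1, max(-1, r))  # guard rounding at |r| = 1
  structure(r, n = n, n_dropped = n_dropped)
}

#' Fisher-z confidence interval for a Pearson coefficient
#'
#' Two-sided interval `tanh(atanh(r) +/- z_crit / sqrt(n - 3))`.
#'
#' @param r Sample correlation with `|r| < 1`.
#' @param n Number of samples (>= 4).
#' @param level Confidence level (default 0.99, as used for the strongest
#'   pairs in the correlation matrices).
#' @return Numeric `c(lo, hi)` with `lo < r < hi`.
#' @export
confidence_interval <- function(r, n, level = 0.99) {
  if (abs(r) >= 1) {
    stop("degenerate interval: |r| = 1 has zero Fisher-z variance",
         call. = FALSE)
  }
  if (n < 4L) stop("need n >= 4 for a Fisher-z interval", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  c(lo = tanh(z - zc * se), hi = tanh(z + zc * se))
}

#' Pairwise correlation matrix over the trailing window
#'
#' Restricts the series to its trailing `window_ns` (the sums *and* the
#' means of the Pearson formula both use only the windowed samples) and
#' computes all residue-pair coefficients. If `window_ns` is not a multiple
#' of the sampling interval the sample count is floored, with a message.
#'
#' @param series A [pka_series()].
#' @param window_ns Length of the trailing window in ns (default 100).
#' @param level Confidence level for the per-pair Fisher-z intervals; `NULL`
#'   skips them.
#' @return Object of class `correlation_matrix`: residues, symmetric `r`
#'   with unit diagonal, sample count `n`, window `(t_start, t_end)`,
#'   windowed residue means, optional `ci_lo`/`ci_hi`, state and replicate.
#' @export
correlation_matrix <- function(series, window_ns = 100, level = 0.99) {
  stopifnot(inherits(series, "pka_series"))
  total <- length(series$times)
  n_win <- as.integer(floor(window_ns / series$interval_ns + 1e-9))
  if (abs(n_win * series$interval_ns - window_ns) > 1e-9) {
    message("window ", window_ns, " ns floored to ", n_win,
            " samples at ", series$interval_ns, " ns")
  }
  if (n_win > total) {
    stop("window error: ", window_ns, " ns window exceeds series length of ",
         total * series$interval_ns, " ns", call. = FALSE)
  }
  if (n_win < 3L) stop("window too short for correlation", call. = FALSE)
  idx <- seq(total - n_win + 1L, total)
  v <- series$values[idx, , drop = FALSE]
  p <- length(series$residues)
  r <- diag(1, p)
  ci_lo <- ci_hi <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      rij <- pearson_r(v[, i], v[, j])
      r[i, j] <- r[j, i] <- as.numeric(rij)
      if (!is.null(level) && abs(rij) < 1) {
        ci <- confidence_interval(as.numeric(rij), attr(rij, "n"), level)
        ci_lo[i, j] <- ci_lo[j, i] <- ci[["lo"]]
        ci_hi[i, j] <- ci_hi[j, i] <- ci[["hi"]]
      }
    }
  }
  dimnames(r) <- dimnames(ci_lo) <- dimnames(ci_hi) <-
    list(series$residues, series$residues)
  out <- list(
    residues = series$residues, r = r, n = n_win,
    window = c(t_start = series$times[idx[1L]],
               t_end = series$times[idx[n_win]]),
    means = colMeans(v, na.rm = TRUE),
    ci_lo = if (is.null(level)) NULL else ci_lo,
    ci_hi = if (is.null(level)) NULL else ci_hi,
    level = level, state = series$state, replicate = series$replicate
  )
  class(out) <- "correlation_matrix"
  out
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  lab <- if (!is.null(x$state)) state_label(x$state) else "?"
  cat("correlation_matrix (state ", lab, ", replicate ", x$replicate,
      "): n = ", x$n, ", window ", x$window[["t_start"]], "-",
      x$window[["t_end"]], " ns\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Strongest correlated residue pairs
#'
#' Ranks the off-diagonal pairs by descending `|r|`; ties are broken by
#' canonical pocket order of the pair, so rankings are stable across runs.
#'
#' @param matrix A `correlation_matrix`.
#' @param k Number of pairs to return (default 3, matching the number of
#'   pairs annotated with intervals on the matrix figures). If `k` exceeds
#'   the number of pairs the full list is returned with a warning.
#' @return Data frame with `res_i`, `res_j`, `r`, `ci_lo`, `ci_hi`.
#' @export
top_k_pairs <- function(matrix, k = 3L) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  p <- length(matrix$residues)
  ij <- which(upper.tri(matrix$r), arr.ind = TRUE)
  pairs <- data.frame(
    res_i = matrix$residues[ij[, 1L]],
    res_j = matrix$residues[ij[, 2L]],
    r = matrix$r[ij],
    ci_lo = if (is.null(matrix$ci_lo)) NA_real_ else matrix$ci_lo[ij],
    ci_hi = if (is.null(matrix$ci_hi)) NA_real_ else matrix$ci_hi[ij],
    stringsAsFactors = FALSE
  )
  ord <- order(-abs(pairs$r), ij[, 1L], ij[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  if (k > nrow(pairs)) {
    warning("k = ", k, " exceeds the ", nrow(pairs),
            " available pairs; returning all")
    k <- nrow(pairs)
  }
  rownames(pairs) <- NULL
  pairs[seq_len(k), , drop = FALSE]
}

#' Export a correlation matrix
#'
#' Writes the residue-by-residue `r` matrix as CSV and, alongside it, a JSON
#' sidecar with the sample count, window, confidence level and per-pair
#' intervals.
#'
#' @param matrix A `correlation_matrix`.
#' @param path CSV output path; the JSON sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
export_correlation_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  utils::write.csv(round(matrix$r, 10), path, row.names = TRUE)
  meta <- list(
    residues = matrix$residues, n = matrix$n,
    window_ns = as.list(matrix$window), level = matrix$level,
    state = if (!is.null(matrix$state)) state_label(matrix$state) else NULL,
    replicate = matrix$replicate,
    ci_lo = matrix$ci_lo, ci_hi = matrix$ci_hi
  )
  jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a correlation heat map
#'
#' Red-to-green heat map of the coefficient matrix (red = -1, green = +1),
#' the colour convention of the per-trajectory matrix figures.
#'
#' @param matrix A `correlation_matrix`.
#' @param file Optional PNG path; `NULL` draws on the current device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_correlation_matrix <- function(matrix, file = NULL) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 600)
    on.exit(grDevices::dev.off())
  }
  p <- length(matrix$residues)
  pal <- grDevices::colorRampPalette(c("red", "white", "green"))(101)
  graphics::image(seq_len(p), seq_len(p), t(matrix$r[p:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(p), labels = matrix$residues, las = 2)
  graphics::axis(2, at = seq_len(p), labels = rev(matrix$residues), las = 2)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    graphics::text(j, p - i + 1, sprintf("%.2f", matrix$r[i, j]), cex = 0.8)
  }
  invisible(file)
}
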