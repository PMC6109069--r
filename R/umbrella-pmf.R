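# Umbrella-sampling window planning and WHAM free-energy profiles.
#
# Windows restrain the K+ ion along the z reaction coordinate (distance
# from the reference carbonyl carbon, in nm) with harmonic biases; the
# standard layout is 47 windows spanning 0.20-2.50 nm at 0.05 nm spacing
# with force constant 5000 kJ/mol/nm^2 at 310 K.  The weighted histogram
# analysis method (WHAM) self-consistently unbiases the window histograms
# into a single potential of mean force; errors come from a block
# bootstrap over the (autocorrelated) window time series.

#' Boltzmann constant in kJ/mol/K
#' @export
KB_KJMOL <- 0.0083144621

#' Thermal energy at a temperature
#'
#' @param temperature_K Temperature in K (default 310).
#' @return `k_B T` in kJ/mol (~2.577 kJ/mol at 310 K).
#' @export
kT_kJmol <- function(temperature_K = 310) KB_KJMOL * temperature_K

#' Generate equidistant umbrella window centers
#'
#' Centers `z_min, z_min + spacing, ..., z_max` inclusive, with a
#' floating-point-safe count. The span must be commensurate with the
#' spacing to within 1e-9 nm.
#'
#' @param z_min,z_max Span of the reaction coordinate in nm.
#' @param spacing Window spacing in nm.
#' @return Numeric vector of window centers.
#' @export
#' @examples
#' length(generate_windows(0.20, 2.50, 0.05))  # 47
generate_windows <- function(z_min = 0.20, z_max = 2.50, spacing = 0.05) {
  if (z_max <= z_min) stop("z_max must exceed z_min", call. = FALSE)
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  n <- round((z_max - z_min) / spacing) + 1
  if (abs(z_min + (n - 1) * spacing - z_max) > 1e-9) {
    stop("layout error: span ", z_max - z_min,
         " nm is not a multiple of spacing ", spacing, " nm", call. = FALSE)
  }
  z_min + spacing * (seq_len(n) - 1)
}

#' Select starting frames for each window from a pull trace
#'
#' For each window center, the index of the pull-trajectory frame whose
#' reaction-coordinate value is closest; ties resolve to the earliest
#' frame.
#'
#' @param pull_trace Numeric vector of per-frame reaction-coordinate values
#'   (time order).
#' @param centers Window centers; each must lie within the range of the
#'   trace.
#' @return Integer vector of frame indices, one per center.
#' @export
select_initial_frames <- function(pull_trace, centers) {
  rng <- range(pull_trace)
  out <- sapply(centers, function(ctr) {
    if (ctr < rng[1L] - 1e-12 || ctr > rng[2L] + 1e-12) {
      stop("coverage error: window center ", ctr,
           " nm outside pull-trace range [", rng[1L], ", ", rng[2L], "]",
           call. = FALSE)
    }
    which.min(abs(pull_trace - ctr))  # which.min takes the earliest tie
  })
  as.integer(out)
}

#' Construct an umbrella window
#'
#' @param center Restraint center in nm.
#' @param samples Reaction-coordinate time series (nm) after discarding
#'   equilibration.
#' @param force_constant Harmonic force constant in kJ/mol/nm^2 (default
#'   5000).
#' @param equil_discard_ns Equilibration time already discarded (metadata).
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, samples, force_constant = 5000,
                            equil_discard_ns = 10) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L || !all(is.finite(samples))) {
    stop("window samples must be non-empty and finite", call. = FALSE)
  }
  if (force_constant < 0) stop("force_constant must be >= 0", call. = FALSE)
  w <- list(center = center, samples = samples,
            force_constant = force_constant,
            equil_discard_ns = equil_discard_ns)
  class(w) <- "umbrella_window"
  w
}

#' Read one window sample file
#'
#' Two whitespace- or comma-separated columns, `time_ps z_nm`, the common
#' pull-output layout; lines starting with `#` or `@` are skipped.
#'
#' @param path File path.
#' @param center,force_constant Window metadata.
#' @param equil_discard_ns Initial time span to drop, in ns.
#' @return An [umbrella_window()].
#' @export
read_window_samples <- function(path, center, force_constant = 5000,
                                equil_discard_ns = 0) {
  lines <- readLines(path)
  lines <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  t_ps <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  z <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(t_ps) || anyNA(z)) {
    stop("parse error in window file '", path, "'", call. = FALSE)
  }
  keep <- t_ps >= equil_discard_ns * 1000
  umbrella_window(center, z[keep], force_constant, equil_discard_ns)
}

# Histogram counts of all windows on a common grid; also the bias matrix.
wham_setup <- function(windows, n_bins, range_z = NULL) {
  z_all <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range_z)) range_z <- range(z_all)
  edges <- seq(range_z[1L], range_z[2L], length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  counts <- vapply(windows, function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  bias <- vapply(windows, function(w) {
    0.5 * w$force_constant * (centers - w$center)^2
  }, numeric(n_bins))
  list(edges = edges, centers = centers, counts = counts, bias = bias)
}

check_overlap <- function(windows, setup) {
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  counts <- setup$counts[, ord, drop = FALSE]
  centers <- vapply(windows, `[[`, numeric(1), "center")[ord]
  overlap <- numeric(length(ord) - 1L)
  for (i in seq_len(length(ord) - 1L)) {
    both <- counts[, i] > 0L & counts[, i + 1L] > 0L
    overlap[i] <- sum(pmin(counts[both, i] / sum(counts[, i]),
                           counts[both, i + 1L] / sum(counts[, i + 1L])))
    if (!any(both)) {
      stop("stitching error: no histogram overlap between windows at ",
           centers[i], " nm and ", centers[i + 1L], " nm", call. = FALSE)
    }
  }
  overlap
}

#' WHAM estimate of the potential of mean force
#'
#' Standard 1-D weighted histogram analysis: iterates the window free-energy
#' constants `f_i` and the unbiased bin probabilities to self-consistency
#' (`max |delta f_i| < tol` in units of `k_B T`), then returns
#' `G(z) = -k_B T ln P(z)` on `n_bins` equal-width bins spanning the sampled
#' range. The profile is unshifted (defined up to a constant); see
#' [align_pmf()]. Adjacent-window histogram overlap is checked and reported
#' in the result.
#'
#' @param windows List of [umbrella_window()] objects (>= 1). With a single
#'   unbiased window (force constant 0) WHAM degenerates to direct
#'   Boltzmann inversion of the histogram.
#' @param temperature_K Temperature (default 310 K).
#' @param n_bins Number of bins (default 200).
#' @param tol Convergence tolerance on the window constants, in `k_B T`.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param f_init Optional warm-start window constants (kJ/mol).
#' @return Object of class `pmf_profile`: `z` (bin centers, nm), `G_kJmol`
#'   (`NA` on unsampled bins), `G_kT`, `err_kJmol` (`NA` until
#'   [bootstrap_pmf()]), `temperature_K`, `n_bins`, window constants `f`,
#'   iteration count, `overlap` (adjacent-window shared histogram
#'   fraction), `anchor` (`NULL` until aligned).
#' @export
wham <- function(windows, temperature_K = 310, n_bins = 200, tol = 1e-7,
                 max_iter = 100000L, f_init = NULL) {
  if (length(windows) == 0L) stop("no windows supplied", call. = FALSE)
  lapply(windows, function(w) stopifnot(inherits(w, "umbrella_window")))
  kT <- kT_kJmol(temperature_K)
  setup <- wham_setup(windows, n_bins)
  overlap <- if (length(windows) >= 2L) check_overlap(windows, setup) else
    numeric(0)
  N <- vapply(windows, function(w) length(w$samples), numeric(1))
  M <- rowSums(setup$counts)
  B <- exp(-setup$bias / kT)              # n_bins x n_windows
  f <- if (is.null(f_init)) numeric(length(windows)) else f_init
  ef <- exp(f / kT)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.vector(B %*% (N * ef))
    P <- ifelse(denom > 0, M / denom, 0)
    P <- P / sum(P)
    Z <- as.vector(crossprod(B, P))       # per-window partition integrals
    f_new <- -kT * log(Z)
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    ef <- exp(f / kT)
    if (delta < tol * kT) break
    if (iter >= max_iter) {
      stop("convergence error: WHAM residual ", format(delta / kT),
           " kT after ", max_iter, " iterations", call. = FALSE)
    }
  }
  G <- ifelse(P > 0, -kT * log(P), NA_real_)
  out <- list(z = setup$centers, G_kJmol = G, G_kT = G / kT,
              err_kJmol = rep(NA_real_, n_bins),
              temperature_K = temperature_K, n_bins = n_bins, f = f,
              iterations = iter, overlap = overlap, anchor = NULL,
              edges = setup$edges)
  class(out) <- "pmf_profile"
  out
}

#' @export
print.pmf_profile <- function(x, digits = 2, ...) {
  kT <- kT_kJmol(x$temperature_K)
  rng <- range(x$G_kJmol, na.rm = TRUE)
  cat("pmf_profile:", x$n_bins, "bins over [",
      round(min(x$z), 3), ",", round(max(x$z), 3), "] nm @",
      x$temperature_K, "K\n")
  cat("  G range:", round(diff(rng), digits), "kJ/mol (",
      round(diff(rng) / kT, digits), "kT );",
      if (is.null(x$anchor)) "unanchored" else
        paste0("zeroed over [", x$anchor[1L], ", ", x$anchor[2L], "] nm"),
      "\n")
  invisible(x)
}

# Moving-block bootstrap resample of one window's series.
block_resample <- function(x, block_length) {
  n <- length(x)
  L <- max(1L, min(block_length, n))
  n_blocks <- ceiling(n / L)
  starts <- sample.int(n - L + 1L, n_blocks, replace = TRUE)
  idx <- as.vector(outer(0:(L - 1L), starts, `+`))
  x[idx[seq_len(n)]]
}

#' Block-bootstrap errors for a WHAM profile
#'
#' Resamples each window's time series with a moving-block bootstrap (the
#' samples are autocorrelated, so i.i.d. resampling would understate the
#' error), recomputes WHAM per replicate (warm-started from the full-data
#' solution), and returns the per-bin standard deviation after removing
#' each replicate's arbitrary additive constant against the full profile.
#' Deterministic for a fixed seed.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed Integer RNG seed.
#' @param block_length Block length in samples (default 50).
#' @param temperature_K,n_bins,tol,max_iter Passed to [wham()].
#' @return A `pmf_profile` (the full-data profile) with `err_kJmol` filled
#'   in.
#' @export
bootstrap_pmf <- function(windows, n_boot = 200L, seed = 1L,
                          block_length = 50L, temperature_K = 310,
                          n_bins = 200, tol = 1e-7, max_iter = 100000L) {
  if (n_boot < 2L) stop("config error: n_boot must be >= 2", call. = FALSE)
  full <- wham(windows, temperature_K, n_bins, tol, max_iter)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  boots <- matrix(NA_real_, nrow = n_bins, ncol = n_boot)
  for (b in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      umbrella_window(w$center, block_resample(w$samples, block_length),
                      w$force_constant, w$equil_discard_ns)
    })
    pb <- wham_on_grid(wb, full$edges, temperature_K, tol, max_iter,
                       f_init = full$f)
    ok <- is.finite(pb) & is.finite(full$G_kJmol)
    boots[, b] <- pb - mean(pb[ok] - full$G_kJmol[ok])
  }
  full$err_kJmol <- apply(boots, 1L, stats::sd, na.rm = TRUE)
  full$n_boot <- n_boot
  full$block_length <- block_length
  full
}

# WHAM on a fixed bin grid (so bootstrap replicates share bins); returns G.
wham_on_grid <- function(windows, edges, temperature_K, tol, max_iter,
                         f_init = NULL) {
  kT <- kT_kJmol(temperature_K)
  n_bins <- length(edges) - 1L
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  counts <- vapply(windows, function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  bias <- vapply(windows, function(w) {
    0.5 * w$force_constant * (centers - w$center)^2
  }, numeric(n_bins))
  N <- vapply(windows, function(w) length(w$samples), numeric(1))
  M <- rowSums(counts)
  B <- exp(-bias / kT)
  f <- if (is.null(f_init)) numeric(length(windows)) else f_init
  ef <- exp(f / kT)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.vector(B %*% (N * ef))
    P <- ifelse(denom > 0, M / denom, 0)
    P <- P / sum(P)
    f_new <- -kT * log(as.vector(crossprod(B, P)))
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    ef <- exp(f / kT)
    if (delta < tol * kT || iter >= max_iter) break
  }
  ifelse(P > 0, -kT * log(P), NA_real_)
}

#' Anchor a profile to zero in the bulk region
#'
#' Subtracts the mean free energy over `bulk_region` so the unbound plateau
#' defines the zero of the profile.
#'
#' @param profile A `pmf_profile`.
#' @param bulk_region Numeric `c(z_lo, z_hi)` in nm; must contain sampled
#'   bins.
#' @return The shifted profile with `anchor` recorded.
#' @export
align_pmf <- function(profile, bulk_region = c(2.0, 2.5)) {
  stopifnot(inherits(profile, "pmf_profile"))
  sel <- profile$z >= bulk_region[1L] & profile$z <= bulk_region[2L] &
    is.finite(profile$G_kJmol)
  if (!any(sel)) {
    stop("range error: bulk region [", bulk_region[1L], ", ",
         bulk_region[2L], "] nm contains no sampled bins", call. = FALSE)
  }
  shift <- mean(profile$G_kJmol[sel])
  profile$G_kJmol <- profile$G_kJmol - shift
  profile$G_kT <- profile$G_kJmol / kT_kJmol(profile$temperature_K)
  profile$anchor <- bulk_region
  profile
}

#' Binding free energy from an anchored profile
#'
#' `Delta G_bind = min G` over the binding region, relative to the bulk zero
#' set by [align_pmf()].
#'
#' @param profile An anchored `pmf_profile`.
#' @param binding_region Numeric `c(z_lo, z_hi)` in nm; default everything
#'   below the bulk anchor.
#' @return List with `dG_kJmol`, `dG_kT`, and `z_min` (location of the
#'   minimum).
#' @export
binding_free_energy <- function(profile, binding_region = NULL) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (is.null(profile$anchor)) {
    stop("profile must be aligned to a bulk zero first (align_pmf)",
         call. = FALSE)
  }
  if (is.null(binding_region)) {
    binding_region <- c(min(profile$z), profile$anchor[1L])
  }
  sel <- profile$z >= binding_region[1L] & profile$z <= binding_region[2L] &
    is.finite(profile$G_kJmol)
  if (!any(sel)) stop("binding region contains no sampled bins",
                      call. = FALSE)
  i <- which(sel)[which.min(profile$G_kJmol[sel])]
  list(dG_kJmol = profile$G_kJmol[i],
       dG_kT = profile$G_kT[i],
       z_min = profile$z[i])
}

#' Export a PMF profile
#'
#' CSV with columns `z_nm, G_kJmol, G_kT, err_kJmol`.
#'
#' @param profile A `pmf_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_pmf <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  utils::write.csv(data.frame(z_nm = profile$z, G_kJmol = profile$G_kJmol,
                              G_kT = profile$G_kT,
                              err_kJmol = profile$err_kJmol),
                   path, row.names = FALSE)
  invisible(path)
}
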