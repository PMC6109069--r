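# Synthetic inputs with the statistical structure the analysis assumes.
#
# No trajectory data are deposited for this system, so every pipeline stage
# is exercised on generated stand-ins: correlated Gaussian AR(1) pKa series
# (with optional planted strongly anti-correlated pairs and change points),
# stochastic ion binding/unbinding over a five-carboxylate pocket geometry,
# and umbrella windows Boltzmann-sampled from a known 1-D potential under
# harmonic biases.  The generators are the ground truth ("oracle") against
# which the analysis modules are validated; they make no claim to force-field
# realism.

#' Synthetic ensemble specification
#'
#' Defaults reproduce the study design the analysis targets: 20 protonation
#' states (2 or 3 protons) x 3 replicates = 60 trajectories of 250 frames at
#' 1 ns; umbrella layout of 47 windows over 0.20-2.50 nm at 0.05 nm spacing
#' with k = 5000 kJ/mol/nm^2 at 310 K.
#'
#' @param seed Base seed; every derived stream is a deterministic function
#'   of it.
#' @param pocket Pocket residues.
#' @param states List of `protonation_state` (default the 20-state
#'   ensemble).
#' @param replicates Replicates per state (default 3).
#' @param n_frames Frames per trajectory (default 250).
#' @param interval_ns Sampling interval (default 1 ns).
#' @param pka_mean,pka_sd Named per-residue stationary means/sds of the pKa
#'   series (defaults: class model values, sd 1).
#' @param ar_tau_ns AR(1) autocorrelation time of the series (default 5 ns).
#' @param motifs Planted anti-correlation motifs: list of
#'   `list(pair = c(donor, acceptor), rho = -0.923, states = <labels>)`;
#'   applied in all replicates of the listed states.
#' @param change_point Optional `list(pair =, time_ns =, delta =)`: swap the
#'   two residues' means at `time_ns` (regime switch).
#' @param binding Ion-binding kinetics: per-slot on/off rates per ns chosen
#'   so the two- and three-proton groups approach the target endpoint means
#'   (defaults 1.87 and 1.10 bound K+), plus site propensities.
#' @param potential Function `U(z)` in kJ/mol for the umbrella generator
#'   (default [pmf_test_potential()]).
#' @param umbrella List: `z_min`, `z_max`, `spacing`, `force_constant`,
#'   `temperature_K`, `n_samples` per window, `tau` (autocorrelation, in
#'   samples).
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       pocket = hka_pocket(),
                       states = default_ensemble_states(pocket),
                       replicates = 3L,
                       n_frames = 250L,
                       interval_ns = 1,
                       pka_mean = NULL,
                       pka_sd = NULL,
                       ar_tau_ns = 5,
                       motifs = list(),
                       change_point = NULL,
                       binding = list(target_mean = c(two_proton = 1.87,
                                                      three_proton = 1.10),
                                      k_off = 0.01),
                       potential = pmf_test_potential,
                       umbrella = list(z_min = 0.20, z_max = 2.50,
                                       spacing = 0.05, force_constant = 5000,
                                       temperature_K = 310,
                                       n_samples = 40000L, tau = 5)) {
  if (is.null(pka_mean)) {
    pka_mean <- stats::setNames(
      ifelse(residue_class(pocket) == "aspartate", 3.8, 4.5), pocket)
  }
  if (is.null(pka_sd)) pka_sd <- stats::setNames(rep(1, length(pocket)),
                                                 pocket)
  spec <- list(seed = as.integer(seed), pocket = pocket, states = states,
               replicates = as.integer(replicates),
               n_frames = as.integer(n_frames), interval_ns = interval_ns,
               pka_mean = pka_mean, pka_sd = pka_sd, ar_tau_ns = ar_tau_ns,
               motifs = motifs, change_point = change_point,
               binding = binding, potential = potential,
               umbrella = umbrella)
  class(spec) <- "synth_spec"
  spec
}

# Target correlation matrix for one state: identity plus planted motifs.
target_correlation <- function(spec, state) {
  p <- length(spec$pocket)
  R <- diag(1, p)
  dimnames(R) <- list(spec$pocket, spec$pocket)
  for (m in spec$motifs) {
    if (!is.null(m$states) && !(state_label(state) %in% m$states)) next
    i <- match(m$pair[1L], spec$pocket)
    j <- match(m$pair[2L], spec$pocket)
    if (is.na(i) || is.na(j)) stop("motif pair not in pocket", call. = FALSE)
    R[i, j] <- R[j, i] <- m$rho
  }
  R
}

#' Generate one synthetic pKa series
#'
#' Stationary Gaussian AR(1) whose stationary correlation across residues is
#' the state's target matrix (identity plus planted motif entries): the
#' innovation covariance is `(1 - phi^2) * L L'` with `L` the Cholesky
#' factor of the target, `phi = exp(-interval / tau)`. A non-positive-
#' definite target is a spec error. Optional change point swaps the two
#' named residues' means at the stated time.
#'
#' @param spec A [synth_spec()].
#' @param state `protonation_state` the series is tagged with.
#' @param replicate Replicate index (enters the derived seed).
#' @return A [pka_series()].
#' @export
gen_pka_series <- function(spec, state, replicate = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  R <- target_correlation(spec, state)
  L <- tryCatch(chol(R), error = function(e)
    stop("spec error: target correlation matrix is not positive definite",
         call. = FALSE))
  p <- length(spec$pocket)
  n <- spec$n_frames
  phi <- exp(-spec$interval_ns / spec$ar_tau_ns)
  sd <- spec$pka_sd[spec$pocket]
  mu <- matrix(spec$pka_mean[spec$pocket], nrow = n, ncol = p, byrow = TRUE)
  if (!is.null(spec$change_point)) {
    # regime switch: first residue runs high / second low before time_ns,
    # swapped afterwards
    cp <- spec$change_point
    i <- match(cp$pair[1L], spec$pocket)
    j <- match(cp$pair[2L], spec$pocket)
    after <- seq_len(n) * spec$interval_ns > cp$time_ns
    mu[, i] <- mu[, i] + ifelse(after, -cp$delta, cp$delta)
    mu[, j] <- mu[, j] + ifelse(after, cp$delta, -cp$delta)
  }
  st_idx <- match(state_label(state),
                  vapply(spec$states, state_label, character(1)))
  if (is.na(st_idx)) st_idx <- 0L
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(mix_seed(spec$seed, st_idx + 1L, replicate))
  z <- matrix(stats::rnorm(n * p), n, p) %*% L  # rows: iid N(0, R)
  x <- matrix(0, n, p)
  x[1L, ] <- z[1L, ]
  s <- sqrt(1 - phi^2)
  for (t in seq(2L, n)) x[t, ] <- phi * x[t - 1L, ] + s * z[t, ]
  vals <- mu + sweep(x, 2L, sd, `*`)
  times <- seq_len(n) * spec$interval_ns
  pka_series(times, vals, spec$pocket, interval_ns = spec$interval_ns,
             state = state, replicate = replicate)
}

#' Generate the full synthetic pKa ensemble
#'
#' One [gen_pka_series()] per (state, replicate); with the default 20
#' states x 3 replicates this is the 60-trajectory ensemble.
#'
#' @param spec A [synth_spec()].
#' @return List of `pka_series`, ordered state-major.
#' @export
gen_pka_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  out <- list()
  for (s in spec$states) {
    for (r in seq_len(spec$replicates)) {
      out[[length(out) + 1L]] <- gen_pka_series(spec, s, r)
    }
  }
  out
}

#' Toy binding-pocket geometry template
#'
#' Reproducible coordinates (nm) for the five carboxylate pairs, the K791
#' amine nitrogen, a site-III locus between the aspartates, and a shell of
#' burial atoms. E795 and E820 are placed proximal (minimum O-O distance
#' below 0.6 nm) by default; `scale` expands all inter-residue distances.
#'
#' @param scale Multiplier on all coordinates (default 1).
#' @param n_shell Number of shell atoms for burial estimation.
#' @return A pocket frame data frame (no `time_ns` column); site loci are
#'   attached as attributes `site_I_II` and `site_III`.
#' @export
gen_pocket_structure <- function(scale = 1, n_shell = 24L) {
  # carboxylate O pairs around two lobes: Glu cluster (site I/II side) and
  # Asp cluster (site III side); O-O within a residue 0.22 nm apart
  base <- list(
    E343 = c(0.00, 0.45, 0.00),
    E795 = c(0.40, 0.15, 0.00),
    E820 = c(0.40, -0.25, 0.05),
    D824 = c(-0.15, -0.45, 0.35),
    D942 = c(0.20, -0.55, 0.45)
  )
  rows <- list()
  for (res in names(base)) {
    ctr <- base[[res]] * scale
    for (k in 1:2) {
      off <- if (k == 1) c(0.11, 0, 0) else c(-0.11, 0, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        atom = paste0(res, "_O", k), residue = res, role = "carboxyl_O",
        x = ctr[1] + off[1], y = ctr[2] + off[2], z = ctr[3] + off[3],
        stringsAsFactors = FALSE)
    }
  }
  amine <- c(0.65, -0.05, 0.15) * scale
  rows[[length(rows) + 1L]] <- data.frame(
    atom = "K791_NZ", residue = NA_character_, role = "amine_N",
    x = amine[1], y = amine[2], z = amine[3], stringsAsFactors = FALSE)
  # deterministic shell: points on a sphere of radius 0.7*scale around the
  # pocket centroid (golden-angle spiral)
  ctr_all <- colMeans(do.call(rbind, base)) * scale
  gi <- seq_len(n_shell)
  th <- 2.39996323 * gi
  zz <- 1 - 2 * (gi - 0.5) / n_shell
  rr <- sqrt(pmax(0, 1 - zz^2))
  shell <- data.frame(
    atom = paste0("SH", gi), residue = NA_character_, role = "shell",
    x = ctr_all[1] + 0.7 * scale * rr * cos(th),
    y = ctr_all[2] + 0.7 * scale * rr * sin(th),
    z = ctr_all[3] + 0.7 * scale * zz, stringsAsFactors = FALSE)
  frame <- rbind(do.call(rbind, rows), shell)
  attr(frame, "site_I_II") <- colMeans(rbind(base$E343, base$E795,
                                             base$E820)) * scale
  attr(frame, "site_III") <- colMeans(rbind(base$D824, base$D942)) * scale
  attr(frame, "bulk") <- c(0, 0, 3) * scale
  frame
}

# Slot occupancy probability so the stationary mean matches the group target.
slot_p_bound <- function(target_mean, n_slots) {
  min(0.999, max(0, target_mean / n_slots))
}

#' Generate a synthetic ion-binding trajectory
#'
#' Ions jump in discrete time (one step per frame) between bulk and binding
#' slots. Two site I/II slots are always present; in states where both
#' aspartates are deprotonated the second slot sits at the site-III locus
#' (deep coordination becomes available). Per-slot on/off rates are chosen
#' so the stationary occupancy matches the group endpoint target in
#' expectation. Bound ions are placed 0.27 nm from the slot's coordinating
#' oxygens; bulk ions 3 nm away. `deterministic` skips the kinetics and
#' pins one ion in site I/II and one at site III from t = 0.
#'
#' @param spec A [synth_spec()].
#' @param state `protonation_state` of the trajectory.
#' @param replicate Replicate index (enters the derived seed).
#' @param deterministic Logical; fixed two-ion placement for construction
#'   tests.
#' @return Trajectory data frame (pocket-frame columns plus `time_ns`).
#' @export
gen_ion_trajectory <- function(spec, state, replicate = 1L,
                               deterministic = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  template <- gen_pocket_structure()
  n <- spec$n_frames
  times <- seq_len(n) * spec$interval_ns - spec$interval_ns
  n_prot <- length(state$protonated)
  both_asp_free <- !any(c("D824", "D942") %in% state$protonated)
  # slot positions: sit 0.27 nm above the midpoint of two coordinating O's
  slot_pos <- function(res_pair) {
    oo <- template[!is.na(template$residue) &
                     template$residue %in% res_pair &
                     template$role == "carboxyl_O", c("x", "y", "z")]
    ctr <- colMeans(oo)
    ctr + c(0, 0, 0.12)
  }
  slots <- list(slot_pos(c("E343", "E795")))
  slots[[2L]] <- if (both_asp_free || deterministic)
    slot_pos(c("D824", "D942")) else slot_pos(c("E795", "E820"))
  bulk <- attr(template, "bulk")
  k_off <- spec$binding$k_off
  group <- if (n_prot == 2L) "two_proton" else "three_proton"
  target <- spec$binding$target_mean[[group]]
  p_eq <- slot_p_bound(target, length(slots))
  k_on <- k_off * p_eq / (1 - p_eq)
  st_idx <- match(state_label(state),
                  vapply(spec$states, state_label, character(1)))
  if (is.na(st_idx)) st_idx <- 0L
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(mix_seed(spec$seed, 1000L + st_idx, replicate))
  p_on <- 1 - exp(-k_on * spec$interval_ns)
  p_off <- 1 - exp(-k_off * spec$interval_ns)
  occ <- if (deterministic) rep(TRUE, length(slots)) else
    stats::runif(length(slots)) < p_eq  # start from stationary occupancy
  frames <- vector("list", n)
  for (t in seq_len(n)) {
    if (!deterministic) {
      flip_on <- stats::runif(length(slots)) < p_on
      flip_off <- stats::runif(length(slots)) < p_off
      occ <- ifelse(occ, !flip_off, flip_on)
    }
    ions <- do.call(rbind, lapply(seq_along(slots), function(s) {
      pos <- if (occ[s]) slots[[s]] else
        bulk + c(0.3 * s, 0, 0)  # parked in bulk, well separated
      data.frame(atom = paste0("K_", s), residue = NA_character_,
                 role = "ion", x = pos[1], y = pos[2], z = pos[3],
                 stringsAsFactors = FALSE)
    }))
    fr <- rbind(template, ions)
    fr$time_ns <- times[t]
    frames[[t]] <- fr
  }
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}

#' Default analytic test potential for the umbrella generator
#'
#' A binding well at 0.45 nm plus a barrier at 1.0 nm, flat (zero) in bulk:
#' `U(z) = -depth * exp(-(z - 0.45)^2 / (2 * 0.12^2))
#'        + barrier * exp(-(z - 1.0)^2 / (2 * 0.10^2))`, in kJ/mol.
#'
#' @param z Reaction coordinate (nm).
#' @param depth_kJmol Well depth (default 12 kJ/mol, ~4.7 kT at 310 K).
#' @param barrier_kJmol Barrier height (default 6 kJ/mol).
#' @return `U(z)` in kJ/mol.
#' @export
pmf_test_potential <- function(z, depth_kJmol = 12, barrier_kJmol = 6) {
  -depth_kJmol * exp(-(z - 0.45)^2 / (2 * 0.12^2)) +
    barrier_kJmol * exp(-(z - 1.00)^2 / (2 * 0.10^2))
}

#' Boltzmann-sample one umbrella window
#'
#' Draws from `p(z) proportional to exp(-beta * (U(z) + k/2 (z - c)^2))` by
#' inverse-CDF on a fine grid (10^4 points), then imposes a stated
#' autocorrelation via a Gaussian-copula AR(1) reshuffle: ranks follow an
#' AR(1) process with lag-1 coefficient `exp(-1/tau)`, so the marginal
#' distribution is exact and the series is autocorrelated like real window
#' output.
#'
#' @param center Window center (nm).
#' @param potential Function `U(z)` in kJ/mol.
#' @param force_constant Bias force constant (kJ/mol/nm^2).
#' @param temperature_K Temperature.
#' @param n_samples Samples to draw.
#' @param tau Autocorrelation time in samples (0 = independent draws).
#' @param seed Integer seed.
#' @param grid_points Inverse-CDF grid resolution.
#' @return An [umbrella_window()].
#' @export
gen_umbrella_window <- function(center, potential = pmf_test_potential,
                                force_constant = 5000, temperature_K = 310,
                                n_samples = 2000L, tau = 5, seed = 1L,
                                grid_points = 10000L) {
  kT <- kT_kJmol(temperature_K)
  half_width <- 6 * sqrt(kT / max(force_constant, 1e-6))
  # widen until the biased density is negligible at the grid edges (an
  # external potential can tilt the minimum away from the window center)
  for (try in 1:8) {
    zg <- seq(center - half_width, center + half_width,
              length.out = grid_points)
    u <- potential(zg) + 0.5 * force_constant * (zg - center)^2
    w <- exp(-(u - min(u)) / kT)
    if (!all(is.finite(w)) || sum(w) <= 0) {
      stop("spec error: unnormalizable window density at center ", center,
           call. = FALSE)
    }
    if (max(w[1L], w[grid_points]) < 1e-10 * max(w)) break
    half_width <- half_width * 2
  }
  cdf <- cumsum(w) / sum(w)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  if (tau > 0) {
    phi <- exp(-1 / tau)
    eps <- c(stats::rnorm(1),
             stats::rnorm(n_samples - 1L, sd = sqrt(1 - phi^2)))
    g <- as.numeric(stats::filter(eps, phi, method = "recursive"))
    uu <- stats::pnorm(g)
  } else {
    uu <- stats::runif(n_samples)
  }
  idx <- findInterval(uu, cdf) + 1L
  idx[idx > grid_points] <- grid_points
  umbrella_window(center, zg[idx], force_constant, equil_discard_ns = 0)
}

#' Generate the full set of umbrella windows
#'
#' One [gen_umbrella_window()] per center of the layout in
#' `spec$umbrella`, with per-window derived seeds.
#'
#' @param spec A [synth_spec()].
#' @return List of `umbrella_window` objects (47 with the default layout).
#' @export
gen_umbrella_samples <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  u <- spec$umbrella
  centers <- generate_windows(u$z_min, u$z_max, u$spacing)
  lapply(seq_along(centers), function(i) {
    gen_umbrella_window(centers[i], spec$potential, u$force_constant,
                        u$temperature_K, u$n_samples, u$tau,
                        seed = mix_seed(spec$seed, 2000L + i))
  })
}
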