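test_that("generators are bit-reproducible given (seed, spec)", {
  spec <- synth_spec(seed = 5, states = default_ensemble_states()[1:2],
                     replicates = 2, n_frames = 60)
  s1 <- gen_pka_series(spec, spec$states[[1]], 2)
  s2 <- gen_pka_series(spec, spec$states[[1]], 2)
  expect_identical(s1$values, s2$values)
  s3 <- gen_pka_series(synth_spec(seed = 6,
                                  states = spec$states,
                                  replicates = 2, n_frames = 60),
                       spec$states[[1]], 2)
  expect_false(identical(s1$values, s3$values))
  # replicate streams differ
  expect_false(identical(s1$values,
                         gen_pka_series(spec, spec$states[[1]], 1)$values))
  # generation does not disturb the session RNG state
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(gen_pka_series(spec, spec$states[[1]], 1))
  expect_identical(rnorm(1), before)
})

test_that("identity target yields null-level pairwise correlations", {
  spec <- synth_spec(seed = 8, ar_tau_ns = 0.2, n_frames = 250)
  frac_small <- mean(vapply(1:40, function(i) {
    s <- gen_pka_series(spec, spec$states[[(i %% 20) + 1]], i)
    cm <- correlation_matrix(s, window_ns = 100)
    all(abs(cm$r[upper.tri(cm$r)]) < 0.3)
  }, logical(1)))
  expect_gte(frac_small, 0.95)
})

test_that("planted pair correlation is recovered on average", {
  spec <- synth_spec(seed = 13,
                     motifs = list(list(pair = c("E795", "E820"),
                                        rho = -0.923, states = NULL)))
  st <- parse_state_label("E795+D824+D942+")
  rs <- vapply(1:40, function(r) {
    cm <- correlation_matrix(gen_pka_series(spec, st, r), window_ns = 100)
    cm$r["E795", "E820"]
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.923)), 0.05)
})

test_that("motifs apply only to their listed states", {
  spec <- synth_spec(seed = 17,
                     motifs = list(list(pair = c("E795", "E820"),
                                        rho = -0.9,
                                        states = "E795+D824+D942+")))
  on_state <- correlation_matrix(gen_pka_series(
    spec, parse_state_label("E795+D824+D942+"), 1))
  off_state <- correlation_matrix(gen_pka_series(
    spec, parse_state_label("E343+D824+D942+"), 1))
  expect_lt(on_state$r["E795", "E820"], -0.6)
  expect_gt(off_state$r["E795", "E820"], -0.5)
})

test_that("non-PSD targets are rejected as spec errors", {
  spec <- synth_spec(seed = 1,
                     motifs = list(list(pair = c("E343", "E795"),
                                        rho = -0.99, states = NULL),
                                   list(pair = c("E343", "E820"),
                                        rho = -0.99, states = NULL),
                                   list(pair = c("E795", "E820"),
                                        rho = -0.99, states = NULL)))
  expect_error(gen_pka_series(spec, parse_state_label("E343+E795+"), 1),
               "positive definite")
})

test_that("change-point mode swaps the pair means at the stated time", {
  spec <- synth_spec(seed = 21, n_frames = 250,
                     change_point = list(pair = c("E795", "E820"),
                                         time_ns = 150, delta = 1.5))
  s <- gen_pka_series(spec, parse_state_label("E795+D824+D942+"), 1)
  before <- s$times <= 150
  expect_gt(mean(s$values[before, "E795"]), mean(s$values[!before, "E795"]))
  expect_lt(mean(s$values[before, "E820"]), mean(s$values[!before, "E820"]))
})

test_that("pocket template has the documented proximity structure", {
  fr <- gen_pocket_structure()
  expect_silent(validate_pocket_frame(fr))
  min_oo <- function(frame, a, b) {
    oa <- frame[!is.na(frame$residue) & frame$residue == a, c("x", "y", "z")]
    ob <- frame[!is.na(frame$residue) & frame$residue == b, c("x", "y", "z")]
    min(sqrt(outer(seq_len(nrow(oa)), seq_len(nrow(ob)), function(i, j) {
      (oa$x[i] - ob$x[j])^2 + (oa$y[i] - ob$y[j])^2 + (oa$z[i] - ob$z[j])^2
    })))
  }
  expect_lt(min_oo(fr, "E795", "E820"), 0.6)
  # tripled template: all pairs beyond the default proximity cutoff
  fr3 <- gen_pocket_structure(scale = 3)
  pocket <- hka_pocket()
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gt(min_oo(fr3, pocket[i], pocket[j]), 0.6)
  }
  # template drives the stand-in estimator deterministically
  expect_identical(estimate_pka_frame(fr, "E343"),
                   estimate_pka_frame(fr, "E343"))
})

test_that("ion kinetics respect rates and deterministic placement", {
  spec0 <- synth_spec(seed = 3, n_frames = 50,
                      binding = list(target_mean = c(two_proton = 0,
                                                     three_proton = 0),
                                     k_off = 0.01))
  st <- parse_state_label("E343+E795+")
  traj <- gen_ion_trajectory(spec0, st, 1)
  tr <- binding_trace(traj, state = st, replicate = 1)
  expect_identical(nrow(tr$records), 0L)  # binding rate 0: never bound

  # deterministic mode reproduces the two-site configuration
  spec <- synth_spec(seed = 3, n_frames = 10)
  trj <- gen_ion_trajectory(spec, parse_state_label("E343+D824+"), 1,
                            deterministic = TRUE)
  bt <- binding_trace(trj, state = parse_state_label("E343+D824+"),
                      replicate = 1)
  last <- bt$records[bt$records$time_ns == max(bt$records$time_ns), ]
  expect_setequal(last$site, c("site_I_II", "site_III"))
  expect_identical(unname(bt$first_binding_ns), c(0, 0))
})

test_that("calibrated ensemble endpoint means track the group targets", {
  spec <- synth_spec(seed = 41, n_frames = 100)
  traces <- list()
  for (s in spec$states) {
    for (r in seq_len(spec$replicates)) {
      traces[[length(traces) + 1L]] <- binding_trace(
        gen_ion_trajectory(spec, s, r), state = s, replicate = r)
    }
  }
  os <- occupancy_summary(traces)
  # binomial-expectation oracle: mean of 30 trajectories, 2 slots at
  # p = target/2 -> SE = sqrt(2 p (1-p) / 30) ~ 0.065; allow 3 SE
  expect_lt(abs(os$group_means[["two_proton"]] - 1.87), 0.20)
  expect_lt(abs(os$group_means[["three_proton"]] - 1.10), 0.27)
})

test_that("umbrella window samples match the Gaussian closed forms", {
  kT <- kT_kJmol(310)
  k <- 5000
  # U = 0: mean ~ center, variance ~ kT/k
  w <- gen_umbrella_window(0.8, potential = function(z) rep(0, length(z)),
                           force_constant = k, n_samples = 20000, tau = 0,
                           seed = 9)
  expect_lt(abs(mean(w$samples) - 0.8), 3 * sqrt(kT / k) / sqrt(20000) * 5)
  expect_lt(abs(var(w$samples) / (kT / k) - 1), 0.05)

  # harmonic U: completing the square gives mean k*c/(k+a), var kT/(k+a)
  a <- 2000
  U <- function(z) 0.5 * a * z^2
  w2 <- gen_umbrella_window(0.8, potential = U, force_constant = k,
                            n_samples = 20000, tau = 0, seed = 10)
  expect_lt(abs(mean(w2$samples) - k * 0.8 / (k + a)), 0.002)
  expect_lt(abs(var(w2$samples) / (kT / (k + a)) - 1), 0.05)

  # autocorrelated mode keeps the marginal but correlates neighbours
  w3 <- gen_umbrella_window(0.8, potential = U, force_constant = k,
                            n_samples = 20000, tau = 10, seed = 11)
  expect_lt(abs(mean(w3$samples) - k * 0.8 / (k + a)), 0.005)
  r1 <- cor(w3$samples[-1], w3$samples[-length(w3$samples)])
  expect_gt(r1, 0.8)
})

test_that("generated windows feed WHAM back to the input potential", {
  spec <- synth_spec(seed = 2,
                     umbrella = list(z_min = 0.20, z_max = 2.50,
                                     spacing = 0.05, force_constant = 5000,
                                     temperature_K = 310,
                                     n_samples = 3000L, tau = 0))
  wins <- gen_umbrella_samples(spec)
  expect_length(wins, 47L)
  prof <- align_pmf(wham(wins, n_bins = 150), c(2.0, 2.5))
  U <- pmf_test_potential(prof$z)
  U <- U - mean(U[prof$z >= 2.0 & prof$z <= 2.5])
  sel <- prof$z >= 0.25 & prof$z <= 2.45 & is.finite(prof$G_kJmol)
  expect_lt(max(abs(prof$G_kJmol[sel] - U[sel])) / kT_kJmol(310), 0.5)
})
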