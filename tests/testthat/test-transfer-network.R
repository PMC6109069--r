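pocket <- hka_pocket()

# matrix with one strong negative pair, everything else mild
one_pair_matrix <- function(pair, r_val, state, means = NULL) {
  r <- diag(1, 5)
  dimnames(r) <- list(pocket, pocket)
  r[pair[1], pair[2]] <- r[pair[2], pair[1]] <- r_val
  fake_corr_matrix(r, state, means = means)
}

test_that("candidate pairs require exactly one protonated member", {
  st <- parse_state_label("E795+D824+D942+")  # E795 protonated, E820 not
  cm <- one_pair_matrix(c("E795", "E820"), -0.923, st,
                        means = c(E343 = 4.5, E795 = 3.9, E820 = 5.1,
                                  D824 = 3.8, D942 = 3.8))
  got <- candidate_pairs(cm)
  expect_identical(nrow(got), 1L)
  expect_identical(got$donor, "E795")
  expect_identical(got$acceptor, "E820")
  expect_equal(got$r, -0.923)
  expect_true(got$low_to_high)  # donor mean 3.9 < acceptor mean 5.1

  # both protonated: excluded however strong the anti-correlation
  st2 <- parse_state_label("E795+E820+")
  expect_identical(nrow(candidate_pairs(one_pair_matrix(
    c("E795", "E820"), -0.9, st2))), 0L)
  # both deprotonated: likewise
  st3 <- parse_state_label("D824+D942+")
  expect_identical(nrow(candidate_pairs(one_pair_matrix(
    c("E795", "E820"), -0.9, st3))), 0L)
  # nothing below threshold: empty
  expect_identical(nrow(candidate_pairs(one_pair_matrix(
    c("E795", "E820"), -0.4, st))), 0L)
  # threshold is strict
  expect_identical(nrow(candidate_pairs(one_pair_matrix(
    c("E795", "E820"), -0.5, st))), 0L)
})

test_that("candidate pairs match the exhaustive filter oracle", {
  set.seed(21)
  states <- default_ensemble_states()
  for (i in 1:25) {
    r <- random_r_matrix()
    st <- states[[sample(20, 1)]]
    cm <- fake_corr_matrix(r, st)
    got <- candidate_pairs(cm, threshold = -0.5)
    # oracle: brute force over all C(5,2) unordered pairs
    want <- 0L
    for (a in 1:4) for (b in (a + 1):5) {
      pa <- pocket[a] %in% st$protonated
      pb <- pocket[b] %in% st$protonated
      if (xor(pa, pb) && r[a, b] < -0.5) {
        want <- want + 1L
        donor <- if (pa) pocket[a] else pocket[b]
        expect_true(donor %in% got$donor)
        row <- got[got$donor == donor &
                     got$acceptor == setdiff(pocket[c(a, b)], donor), ]
        expect_equal(row$r, r[a, b])
      }
    }
    expect_identical(nrow(got), want)
    # every donor protonated, every acceptor not
    expect_true(all(got$donor %in% st$protonated))
    expect_false(any(got$acceptor %in% st$protonated))
  }
})

test_that("threshold extremes decompose the filter", {
  set.seed(22)
  states <- default_ensemble_states()
  for (i in 1:10) {
    cm <- fake_corr_matrix(random_r_matrix(), states[[sample(20, 1)]])
    expect_identical(nrow(candidate_pairs(cm, threshold = -1.0)), 0L)
    all_pairs <- candidate_pairs(cm, threshold = +1.0)
    np <- length(cm$state$protonated)
    expect_identical(nrow(all_pairs), np * (5L - np))
  }
})

test_that("proximity filter keeps close pairs and annotates distances", {
  st <- parse_state_label("E795+D824+D942+")
  pairs <- data.frame(donor = "E795", acceptor = "E820", r = -0.9,
                      low_to_high = TRUE, state = st$label, replicate = 1L,
                      stringsAsFactors = FALSE)
  close <- rbind(toy_residue_frame("E795", at = c(0, 0, 0), n_shell = 0),
                 toy_residue_frame("E820", at = c(0.35 + 0.22, 0, 0),
                                   n_shell = 0))
  kept <- proximity_filter(pairs, as_trajectory(close, 0:4), cutoff_nm = 0.6)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$mean_min_oo_nm, 0.35, tolerance = 1e-12)

  far <- rbind(toy_residue_frame("E795", at = c(0, 0, 0), n_shell = 0),
               toy_residue_frame("E820", at = c(1.5 + 0.22, 0, 0),
                                 n_shell = 0))
  expect_identical(nrow(proximity_filter(pairs, as_trajectory(far, 0:4),
                                         cutoff_nm = 0.6)), 0L)

  # fluctuating geometry: decision matches a frame-loop mean-of-minima
  set.seed(3)
  seps <- runif(8, 0.3, 0.9)
  traj <- do.call(rbind, lapply(seq_along(seps), function(i) {
    fr <- rbind(toy_residue_frame("E795", at = c(0, 0, 0), n_shell = 0),
                toy_residue_frame("E820", at = c(seps[i] + 0.22, 0, 0),
                                  n_shell = 0))
    fr$time_ns <- i
    fr
  }))
  out <- proximity_filter(pairs, traj, cutoff_nm = mean(seps) + 0.01)
  expect_identical(nrow(out), 1L)
  expect_equal(out$mean_min_oo_nm, mean(seps), tolerance = 1e-12)
  expect_identical(nrow(proximity_filter(pairs, traj,
                                         cutoff_nm = mean(seps) - 0.01)), 0L)

  expect_error(proximity_filter(pairs, as_trajectory(
    toy_residue_frame("E795", n_shell = 0), 0:2), cutoff_nm = 0.6),
    "structural-data")
})

# the published instance table of the 60-trajectory ensemble
table1_pairs <- function() {
  spec <- list(c("E795", "E820", 5), c("E820", "E795", 5),
               c("E820", "E343", 4), c("E343", "E820", 2),
               c("D824", "E795", 2), c("E820", "D824", 1),
               c("D942", "E795", 1), c("D942", "D824", 1))
  do.call(rbind, lapply(seq_along(spec), function(i) {
    k <- as.integer(spec[[i]][3])
    data.frame(donor = spec[[i]][1], acceptor = spec[[i]][2], r = -0.7,
               low_to_high = TRUE,
               state = paste0("S", i, "_", seq_len(k)),  # distinct trajs
               replicate = 1L, stringsAsFactors = FALSE)
  }))
}

test_that("aggregation reproduces the instance-table counts and ranking", {
  net <- aggregate_network(table1_pairs())
  edge_count <- function(d, a) {
    net$edges$instances[net$edges$donor == d & net$edges$acceptor == a]
  }
  expect_identical(edge_count("E795", "E820"), 5L)
  expect_identical(edge_count("E820", "E795"), 5L)
  expect_identical(edge_count("E820", "E343"), 4L)
  expect_identical(edge_count("E343", "E820"), 2L)
  expect_identical(edge_count("D824", "E795"), 2L)
  expect_identical(edge_count("E820", "D824"), 1L)
  expect_identical(edge_count("D942", "E795"), 1L)
  expect_identical(edge_count("D942", "D824"), 1L)
  # conservation: counts sum to the accepted tuples
  expect_identical(sum(net$edges$instances), nrow(table1_pairs()))
  # likelihood ranking: E795<->E820 above the single-instance D942 -> E795
  ranked <- rank_transfer_likelihood(net)$edges
  pos <- function(d, a) which(ranked$donor == d & ranked$acceptor == a)
  expect_lt(pos("E795", "E820"), pos("D942", "E795"))
  expect_lt(pos("E820", "E795"), pos("D942", "E795"))
})

test_that("aggregation counts trajectories once and dedupes", {
  single <- data.frame(donor = "E795", acceptor = "E820", r = -0.8,
                       low_to_high = TRUE, state = "E795+D824+",
                       replicate = 1L, stringsAsFactors = FALSE)
  net <- aggregate_network(single)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$instances, 1L)
  expect_warning(net2 <- aggregate_network(rbind(single, single)),
                 "deduplicated")
  expect_identical(net2$edges$instances, 1L)
})

test_that("rankings of random counts equal a sort oracle", {
  set.seed(33)
  for (i in 1:10) {
    n_edge <- sample(3:8, 1)
    combos <- expand.grid(d = pocket, a = pocket,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$d != combos$a, ]
    pick <- combos[sample(nrow(combos), n_edge), ]
    counts <- sample(1:6, n_edge, replace = TRUE)
    pairs <- do.call(rbind, lapply(seq_len(n_edge), function(e) {
      data.frame(donor = pick$d[e], acceptor = pick$a[e], r = -0.8,
                 low_to_high = TRUE,
                 state = paste0("T", e, "_", seq_len(counts[e])),
                 replicate = 1L, stringsAsFactors = FALSE)
    }))
    net <- aggregate_network(pairs)
    expect_identical(net$edges$instances, sort(counts, decreasing = TRUE))
  }
})

test_that("network exports round-trip and unknown formats error", {
  net <- aggregate_network(table1_pairs())
  jsonf <- withr::local_tempfile(fileext = ".json")
  dotf <- withr::local_tempfile(fileext = ".dot")
  csvf <- withr::local_tempfile(fileext = ".csv")
  export_network(net, jsonf, "json")
  export_network(net, dotf, "dot")
  export_network(net, csvf, "csv")
  j <- jsonlite::read_json(jsonf, simplifyVector = TRUE)
  expect_identical(j$nodes, pocket)
  expect_identical(nrow(j$edges), 8L)
  dot <- readLines(dotf)
  expect_true(any(grepl("\"E795\" -> \"E820\" \\[weight=5", dot)))
  back <- utils::read.csv(csvf, stringsAsFactors = FALSE)
  expect_identical(back$instances, net$edges$instances)
  expect_error(export_network(net, jsonf, "gexf"), "unknown export format")

  # empty network still exports and ranks
  r_id <- diag(1, 5)
  dimnames(r_id) <- list(pocket, pocket)
  empty <- aggregate_network(candidate_pairs(
    fake_corr_matrix(r_id, parse_state_label("E343+E795+"))))
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(rank_transfer_likelihood(empty)$edges), 0L)
})

test_that("depth annotation reports access-point distances", {
  net <- aggregate_network(table1_pairs())
  frames <- as_trajectory(gen_pocket_structure(), 0:2)
  rk <- rank_transfer_likelihood(net, frames = frames,
                                 access_point = c(0, 0, 3))
  expect_length(rk$depth_nm, 5L)
  # the aspartates sit higher in z here, i.e. closer to this access point
  expect_true(all(rk$depth_nm[c("D824", "D942")] <
                    max(rk$depth_nm[c("E343", "E795")])))
})
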