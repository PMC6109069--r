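# Spontaneous K+ binding: detection, site classification, occupancy.
#
# An ion counts as bound when enough pocket carboxylate oxygens coordinate
# it (>= min_coord oxygens within cutoff_nm; defaults 2 and 0.35 nm, the
# typical K+-O coordination distance).  Sites I and II cannot be separated
# in the trajectories, so bound ions are classified as site I/II versus the
# deeper site III, the latter defined by majority coordination from the two
# aspartates D824/D942.

#' Detect bound K+ ions in one frame
#'
#' @param frame Pocket frame (see [validate_pocket_frame()]).
#' @param cutoff_nm Coordination distance cutoff (default 0.35 nm).
#' @param min_coord Minimum number of coordinating pocket oxygens for an ion
#'   to count as bound (default 2).
#' @return Data frame with one row per bound ion: `ion` (atom label),
#'   `n_coord`, `site`, and `residues` (list column: coordinating residue
#'   multiset). Zero rows when no ion is bound; a frame without K+ atoms is
#'   not an error.
#' @export
detect_bound_ions <- function(frame, cutoff_nm = 0.35, min_coord = 2L) {
  validate_pocket_frame(frame)
  ions <- frame[frame$role == "ion", , drop = FALSE]
  oxy <- frame[frame$role == "carboxyl_O" & !is.na(frame$residue), ,
               drop = FALSE]
  empty <- data.frame(ion = character(), n_coord = integer(),
                      site = character(), stringsAsFactors = FALSE)
  empty$residues <- list()
  if (nrow(ions) == 0L || nrow(oxy) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(ions))) {
    d <- sqrt((oxy$x - ions$x[i])^2 + (oxy$y - ions$y[i])^2 +
                (oxy$z - ions$z[i])^2)
    near <- d <= cutoff_nm
    if (sum(near) >= min_coord) {
      coord <- oxy$residue[near]
      rows[[length(rows) + 1L]] <- list(ion = ions$atom[i],
                                        n_coord = sum(near),
                                        site = classify_site(coord),
                                        residues = coord)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    ion = vapply(rows, `[[`, character(1), "ion"),
    n_coord = vapply(rows, `[[`, integer(1), "n_coord"),
    site = vapply(rows, `[[`, character(1), "site"),
    stringsAsFactors = FALSE
  )
  out$residues <- lapply(rows, `[[`, "residues")
  out
}

#' Classify a coordination multiset into a binding site
#'
#' `"site_III"` when a strict majority of the coordinating oxygens belong to
#' the aspartates D824/D942 (the deeper locus), `"site_I_II"` otherwise.
#' An exact tie is classified as site I/II and flagged via
#' `attr(, "tie")`. Pure function of the multiset: frame-independent.
#'
#' @param residues Non-empty character vector (multiset) of coordinating
#'   residue names, one entry per coordinating oxygen.
#' @param site_iii_residues Residues defining site III.
#' @return `"site_I_II"` or `"site_III"`.
#' @export
#' @examples
#' classify_site(c("E343", "E795"))           # site_I_II
#' classify_site(c("D824", "D942", "D942"))   # site_III
classify_site <- function(residues, site_iii_residues = c("D824", "D942")) {
  if (length(residues) == 0L) {
    stop("empty coordination set: classify_site requires a bound ion",
         call. = FALSE)
  }
  n_iii <- sum(residues %in% site_iii_residues)
  n_other <- length(residues) - n_iii
  if (n_iii > n_other) return("site_III")
  structure("site_I_II", tie = n_iii == n_other && n_iii > 0L)
}

#' Per-frame binding trace of a trajectory
#'
#' Applies [detect_bound_ions()] to every frame and records, per ion, the
#' first time it is found bound. An ion already bound in the first frame
#' (i.e. bound since equilibration) gets first binding time 0.
#'
#' @param frames Trajectory table (pocket-frame columns plus `time_ns`),
#'   time-ordered.
#' @param cutoff_nm,min_coord Binding criterion, as in
#'   [detect_bound_ions()].
#' @param state Optional `protonation_state` tag.
#' @param replicate Replicate tag.
#' @return Object of class `binding_trace`: `records` (long data frame of
#'   time_ns, ion, site, n_coord), `first_binding_ns` (named per-ion),
#'   `times`, `state`, `replicate`.
#' @export
binding_trace <- function(frames, cutoff_nm = 0.35, min_coord = 2L,
                          state = NULL, replicate = NA_integer_) {
  if (!"time_ns" %in% names(frames)) {
    stop("frames must carry a time_ns column", call. = FALSE)
  }
  times <- unique(frames$time_ns)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("input error: frames are not in increasing time order",
         call. = FALSE)
  }
  recs <- list()
  first <- c()
  for (t in times) {
    fr <- frames[frames$time_ns == t, , drop = FALSE]
    b <- detect_bound_ions(fr, cutoff_nm, min_coord)
    if (nrow(b) > 0L) {
      recs[[length(recs) + 1L]] <- data.frame(
        time_ns = t, ion = b$ion, site = b$site, n_coord = b$n_coord,
        stringsAsFactors = FALSE
      )
      new <- setdiff(b$ion, names(first))
      if (length(new) > 0L) {
        first[new] <- if (t == times[1L]) 0 else as.numeric(t)
      }
    }
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(time_ns = numeric(), ion = character(), site = character(),
               n_coord = integer(), stringsAsFactors = FALSE)
  out <- list(records = records, first_binding_ns = first, times = times,
              state = state, replicate = replicate)
  class(out) <- "binding_trace"
  out
}

#' @export
print.binding_trace <- function(x, ...) {
  cat("binding_trace:", length(x$times), "frames,",
      length(x$first_binding_ns), "ion(s) ever bound\n")
  if (length(x$first_binding_ns) > 0L) {
    cat("  first binding (ns):",
        paste(names(x$first_binding_ns), x$first_binding_ns, sep = "@",
              collapse = " "), "\n")
  }
  invisible(x)
}

end_counts <- function(trace) {
  t_end <- trace$times[length(trace$times)]
  last <- trace$records[trace$records$time_ns == t_end, , drop = FALSE]
  c(site_I_II = sum(last$site == "site_I_II"),
    site_III = sum(last$site == "site_III"))
}

#' Ensemble occupancy summary
#'
#' Per state and site: mean and standard error (n-1 denominator, over the
#' replicates) of the number of ions bound at the end of each trajectory —
#' occupancy is counted at the final frame, matching how the ensemble bar
#' summaries are built; time-averaged occupancy is reported alongside for
#' diagnostics. Grand means over the two-proton and three-proton state
#' groups are attached.
#'
#' @param traces List of `binding_trace` objects covering the ensemble; each
#'   must carry its `state`.
#' @return Object of class `occupancy_summary`: `per_state` data frame
#'   (state, n_protons, site, mean, se, n_replicates, mean_time_avg),
#'   `group_means` (named: mean total bound for 2- and 3-proton groups),
#'   `per_trajectory` end counts.
#' @export
occupancy_summary <- function(traces) {
  if (length(traces) == 0L) stop("config error: no traces supplied",
                                 call. = FALSE)
  rows <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "binding_trace"))
    if (is.null(tr$state)) stop("trace lacks its protonation state",
                                call. = FALSE)
    ec <- end_counts(tr)
    rec <- tr$records
    tavg <- if (nrow(rec) > 0L) {
      c(site_I_II = sum(rec$site == "site_I_II") / length(tr$times),
        site_III = sum(rec$site == "site_III") / length(tr$times))
    } else c(site_I_II = 0, site_III = 0)
    data.frame(state = state_label(tr$state),
               n_protons = length(tr$state$protonated),
               replicate = tr$replicate,
               site_I_II = ec[["site_I_II"]], site_III = ec[["site_III"]],
               tavg_I_II = tavg[["site_I_II"]], tavg_III = tavg[["site_III"]],
               stringsAsFactors = FALSE)
  })
  per_traj <- do.call(rbind, rows)
  states <- unique(per_traj$state)
  per_state <- do.call(rbind, lapply(states, function(s) {
    sub <- per_traj[per_traj$state == s, , drop = FALSE]
    n <- nrow(sub)
    se <- function(v) if (n > 1L) stats::sd(v) / sqrt(n) else 0
    data.frame(
      state = s, n_protons = sub$n_protons[1L],
      site = c("site_I_II", "site_III"),
      mean = c(mean(sub$site_I_II), mean(sub$site_III)),
      se = c(se(sub$site_I_II), se(sub$site_III)),
      n_replicates = n,
      mean_time_avg = c(mean(sub$tavg_I_II), mean(sub$tavg_III)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_state) <- NULL
  total <- per_traj$site_I_II + per_traj$site_III
  group_means <- c(
    two_proton = mean(total[per_traj$n_protons == 2L]),
    three_proton = mean(total[per_traj$n_protons == 3L])
  )
  out <- list(per_state = per_state, group_means = group_means,
              per_trajectory = per_traj)
  class(out) <- "occupancy_summary"
  out
}

#' @export
print.occupancy_summary <- function(x, digits = 3, ...) {
  cat("occupancy_summary over", nrow(x$per_trajectory), "trajectories\n")
  gm <- round(x$group_means, digits)
  cat("  group mean bound K+ at trajectory end: 2-proton =",
      gm[["two_proton"]], ", 3-proton =", gm[["three_proton"]], "\n")
  invisible(x)
}

#' Write the occupancy summary table
#'
#' CSV mirroring the per-state bar summary: state label, site, mean, SE.
#'
#' @param summary An `occupancy_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_occupancy_summary <- function(summary, path) {
  stopifnot(inherits(summary, "occupancy_summary"))
  utils::write.csv(summary$per_state, path, row.names = FALSE)
  invisible(path)
}

#' Occupancy versus protonated-glutamate count
#'
#' Within a proton-count group (default the three-proton states), the
#' correlation between each state's number of protonated glutamates and its
#' mean total bound K+ at trajectory end; the aspartate analogue is
#' computed the same way (expected near zero). More protonated glutamates
#' mimic lower luminal pH, so a negative coefficient supports the transport
#' stoichiometry-variation hypothesis.
#'
#' @param summary An `occupancy_summary`.
#' @param n_protons Which proton-count group to analyse (default 3).
#' @return List with `r_glutamate`, `r_aspartate` and the per-state table
#'   used.
#' @export
stoichiometry_correlation <- function(summary, n_protons = 3L) {
  stopifnot(inherits(summary, "occupancy_summary"))
  ps <- summary$per_state[summary$per_state$n_protons == n_protons, ,
                          drop = FALSE]
  states <- unique(ps$state)
  if (length(states) < 3L) {
    stop("need at least 3 states in the group", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(states, function(s) {
    prot <- parse_state_label(s)$protonated
    data.frame(
      state = s,
      n_glu = sum(residue_class(prot) == "glutamate"),
      n_asp = sum(residue_class(prot) == "aspartate"),
      mean_bound = sum(ps$mean[ps$state == s]),
      stringsAsFactors = FALSE
    )
  }))
  list(
    r_glutamate = as.numeric(pearson_r(tab$n_glu, tab$mean_bound)),
    r_aspartate = as.numeric(pearson_r(tab$n_asp, tab$mean_bound)),
    table = tab
  )
}

#' Export a binding trace
#'
#' Long CSV: `time_ns, ion, bound, site, coordinating_residues` (the
#' multiset joined with `;`). Frames where an ion is unbound are implicit.
#'
#' @param trace A `binding_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_binding_trace <- function(trace, path) {
  stopifnot(inherits(trace, "binding_trace"))
  rec <- trace$records
  rec$bound <- TRUE
  utils::write.csv(rec[, c("time_ns", "ion", "bound", "site", "n_coord")],
                   path, row.names = FALSE)
  invisible(path)
}
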