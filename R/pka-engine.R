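# Per-frame pKa series for the pocket carboxylates.
#
# Production use ingests tables written by an external empirical pKa
# predictor run on trajectory snapshots (one row per frame, one column per
# residue).  For end-to-end runs on synthetic structures the module also
# provides a deliberately simple electrostatic stand-in estimator: a model
# pKa per residue class plus a burial term and pairwise Coulomb-like shifts
# from nearby charged groups, computed from heavy-atom geometry only.

# ---- pocket frames ---------------------------------------------------------

#' Validate a pocket frame table
#'
#' A pocket frame is the minimal structural view of the binding pocket at one
#' time point: a data frame with columns `atom` (unique atom label),
#' `residue` (residue name, or `NA` for ions/shell atoms), `role` (one of
#' `"carboxyl_O"`, `"amine_N"`, `"ion"`, `"shell"`) and coordinates `x`,
#' `y`, `z` in nm. Trajectories are the same table with an extra `time_ns`
#' column.
#'
#' @param frame Data frame to validate.
#' @return The frame, invisibly; errors describe the first violation.
#' @export
validate_pocket_frame <- function(frame) {
  need <- c("atom", "residue", "role", "x", "y", "z")
  miss <- setdiff(need, names(frame))
  if (length(miss) > 0L) {
    stop("pocket frame lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok_roles <- c("carboxyl_O", "amine_N", "ion", "shell")
  if (!all(frame$role %in% ok_roles)) {
    stop("unknown atom role(s): ",
         paste(unique(setdiff(frame$role, ok_roles)), collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in pocket frame",
                                 call. = FALSE)
  invisible(frame)
}

frame_at_time <- function(frames, t, tol = 1e-9) {
  sel <- abs(frames$time_ns - t) < tol
  if (!any(sel)) stop("no frame at requested time ", t, " ns", call. = FALSE)
  frames[sel, , drop = FALSE]
}

# Centroid of a residue's carboxylate oxygens within one frame.
residue_centroid <- function(frame, residue) {
  sel <- !is.na(frame$residue) & frame$residue == residue &
    frame$role == "carboxyl_O"
  if (!any(sel)) {
    stop("residue ", residue, " has no carboxylate oxygens in frame",
         call. = FALSE)
  }
  colMeans(frame[sel, c("x", "y", "z"), drop = FALSE])
}

# ---- PkaSeries container ---------------------------------------------------

#' Construct a pKa time series
#'
#' Container for per-residue pKa values sampled at a fixed interval along one
#' trajectory. `NA` cells (predictor failures) are tolerated up to 10% per
#' residue; downstream correlation drops them pairwise.
#'
#' @param times Strictly increasing frame times in ns.
#' @param values Numeric matrix, `length(times)` rows by `length(residues)`
#'   columns.
#' @param residues Residue names for the columns.
#' @param interval_ns Sampling interval (default 1 ns); consecutive times
#'   must match it within tolerance.
#' @param state Optional `protonation_state` the trajectory was run in.
#' @param replicate Integer replicate index.
#' @return Object of class `pka_series`.
#' @export
pka_series <- function(times, values, residues, interval_ns = 1,
                       state = NULL, replicate = NA_integer_) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (length(times) != nrow(values)) {
    stop("times and values row count differ", call. = FALSE)
  }
  if (length(residues) != ncol(values)) {
    stop("residues and values column count differ", call. = FALSE)
  }
  if (length(times) >= 2L) {
    d <- diff(times)
    if (any(d <= 0)) stop("frame times must be strictly increasing",
                          call. = FALSE)
    if (any(abs(d - interval_ns) > 1e-6 * max(1, interval_ns))) {
      stop("frame spacing inconsistent with interval_ns = ", interval_ns,
           call. = FALSE)
    }
  }
  n_missing <- colSums(is.na(values))
  frac <- n_missing / max(1L, nrow(values))
  if (any(frac > 0.10)) {
    stop("more than 10% missing pKa values for residue(s): ",
         paste(residues[frac > 0.10], collapse = ", "), call. = FALSE)
  }
  colnames(values) <- residues
  s <- list(times = times, values = values, residues = as.character(residues),
            interval_ns = interval_ns, state = state,
            replicate = as.integer(replicate), n_missing = n_missing)
  class(s) <- "pka_series"
  s
}

#' @export
print.pka_series <- function(x, ...) {
  cat("pka_series:", nrow(x$values), "frames x", length(x$residues),
      "residues @", x$interval_ns, "ns\n")
  if (!is.null(x$state)) cat("  state:", state_label(x$state),
                             " replicate:", x$replicate, "\n")
  invisible(x)
}

#' Read a per-frame pKa table
#'
#' Reads the columnar predictor-output format: CSV with header
#' `time_ns,E343,E795,E820,D824,D942` (UTF-8, `.` decimal), one row per
#' frame. Rows are sorted by time; duplicate times and non-numeric cells are
#' rejected with informative errors.
#'
#' @param path File path.
#' @param state Optional `protonation_state` tag.
#' @param replicate Replicate index tag.
#' @param pocket Residue columns required to be present.
#' @return A [pka_series()].
#' @export
load_pka_table <- function(path, state = NULL, replicate = NA_integer_,
                           pocket = hka_pocket()) {
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("schema error reading '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L) stop("schema error: '", path, "' has no data rows",
                            call. = FALSE)
  need <- c("time_ns", pocket)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         " in '", path, "'", call. = FALSE)
  }
  num <- function(col, what) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "NA" & is.na(out))
    if (length(bad) > 0L) {
      stop("parse error: non-numeric ", what, " value '", v[bad[1L]],
           "' at data row ", bad[1L], " of '", path, "'", call. = FALSE)
    }
    out
  }
  t <- num("time_ns", "time")
  if (anyNA(t)) stop("parse error: missing time values in '", path, "'",
                     call. = FALSE)
  if (anyDuplicated(t)) {
    stop("duplicate frame times in '", path, "'", call. = FALSE)
  }
  vals <- vapply(pocket, function(r) num(r, paste0("pKa (", r, ")")),
                 numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(NULL, pocket))
  o <- order(t)
  interval <- if (length(t) >= 2L) stats::median(diff(t[o])) else 1
  pka_series(t[o], vals[o, , drop = FALSE], pocket, interval_ns = interval,
             state = state, replicate = replicate)
}

#' Write a pKa table
#'
#' Inverse of [load_pka_table()]; values are written with full double
#' precision so that a load/write round trip is bit-exact.
#'
#' @param series A `pka_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pka_table <- function(series, path) {
  stopifnot(inherits(series, "pka_series"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  header <- paste(c("time_ns", series$residues), collapse = ",")
  rows <- vapply(seq_along(series$times), function(i) {
    paste(c(fmt(series$times[i]), fmt(series$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---- stand-in estimator ----------------------------------------------------

#' Parameters of the stand-in pKa estimator
#'
#' The stand-in is not a reimplementation of any published predictor; it is
#' the simplest geometry-only model whose output has the dependence structure
#' the downstream correlation analysis assumes: a class model pKa, a burial
#' shift proportional to the heavy-atom count around the carboxylate, and
#' `+/- w_c / d` Coulomb-like shifts from charged neighbours (positive
#' charges lower the pKa, negative raise it). Hydrogen positions are never
#' used.
#'
#' @param model_pka Named model pKa per residue class.
#' @param r_b Burial shell radius in nm.
#' @param r_c Charge-interaction cutoff in nm.
#' @param w_c Charge-shift weight in pKa units x nm.
#' @param w_b Burial weight in pKa units per heavy atom.
#' @param n_ref Reference heavy-atom count (burial shift is zero at this
#'   count).
#' @param max_b Upper clamp of the burial shift in pKa units.
#' @param state Optional `protonation_state`: protonated carboxylates are
#'   treated as neutral, deprotonated ones as -1 charges.
#' @return List of parameters.
#' @export
standin_params <- function(model_pka = c(aspartate = 3.80, glutamate = 4.50),
                           r_b = 0.9, r_c = 1.2, w_c = 2.4, w_b = 0.02,
                           n_ref = 20L, max_b = 2.0, state = NULL) {
  list(model_pka = model_pka, r_b = r_b, r_c = r_c, w_c = w_c, w_b = w_b,
       n_ref = as.integer(n_ref), max_b = max_b, state = state)
}

#' Estimate the pKa of one residue in one frame
#'
#' `pKa = model_pKa(class) + burial_shift + sum_j charge_shift(d_j)` with
#' `burial_shift = clamp(w_b * (N_heavy(r_b) - n_ref), 0, max_b)` and
#' `charge_shift = -q_j * w_c / d_j` for every charged group `j` within
#' `r_c` of the residue's carboxylate-oxygen centroid. Charged groups are
#' K+ ions and amine nitrogens (+1) and deprotonated carboxylates of the
#' other pocket residues (-1). Depends on interatomic distances only, hence
#' invariant under rigid motions of the frame.
#'
#' @param frame A pocket frame (see [validate_pocket_frame()]).
#' @param residue Residue name present in the frame.
#' @param params A [standin_params()] list.
#' @return Estimated pKa (numeric scalar).
#' @export
estimate_pka_frame <- function(frame, residue, params = standin_params()) {
  validate_pocket_frame(frame)
  if (!any(!is.na(frame$residue) & frame$residue == residue)) {
    stop("residue ", residue, " absent from frame", call. = FALSE)
  }
  cls <- residue_class(residue)
  if (!cls %in% names(params$model_pka)) {
    stop("no model pKa for residue class '", cls, "'", call. = FALSE)
  }
  ctr <- residue_centroid(frame, residue)

  own <- !is.na(frame$residue) & frame$residue == residue
  other <- frame[!own, , drop = FALSE]
  d_all <- sqrt((other$x - ctr[1])^2 + (other$y - ctr[2])^2 +
                  (other$z - ctr[3])^2)

  n_heavy <- sum(d_all <= params$r_b)
  burial <- min(max(params$w_b * (n_heavy - params$n_ref), 0), params$max_b)

  protonated <- if (!is.null(params$state)) params$state$protonated else
    character()
  shift <- 0
  # positive point charges: every K+ ion and amine nitrogen
  pos <- other$role %in% c("ion", "amine_N")
  if (any(pos)) {
    d <- d_all[pos]
    shift <- shift - sum(params$w_c / d[d <= params$r_c & d > 0])
  }
  # negative charges: deprotonated carboxylates of the other residues,
  # located at their oxygen centroids
  others <- setdiff(unique(other$residue[other$role == "carboxyl_O" &
                                           !is.na(other$residue)]),
                    protonated)
  for (rj in others) {
    cj <- residue_centroid(frame, rj)
    d <- sqrt(sum((cj - ctr)^2))
    if (d > 0 && d <= params$r_c) shift <- shift + params$w_c / d
  }
  unname(params$model_pka[[cls]] + burial + shift)
}

#' Compute a pKa series from trajectory frames
#'
#' Applies [estimate_pka_frame()] at each sampled time on the requested
#' interval grid. Deterministic for fixed inputs.
#'
#' @param frames Trajectory table: pocket-frame columns plus `time_ns`.
#' @param residues Residues to estimate (default the canonical pocket).
#' @param interval_ns Sampling interval; must not be finer than the frame
#'   spacing.
#' @param params A [standin_params()] list.
#' @param state,replicate Tags stored on the result.
#' @return A [pka_series()].
#' @export
compute_pka_series <- function(frames, residues = hka_pocket(),
                               interval_ns = 1, params = standin_params(),
                               state = NULL, replicate = NA_integer_) {
  if (!"time_ns" %in% names(frames)) {
    stop("frames must carry a time_ns column", call. = FALSE)
  }
  times <- sort(unique(frames$time_ns))
  if (length(times) >= 2L) {
    spacing <- min(diff(times))
    if (interval_ns < spacing - 1e-9) {
      stop("resolution error: requested interval ", interval_ns,
           " ns is finer than frame spacing ", spacing, " ns", call. = FALSE)
    }
  }
  grid <- seq(times[1L],
              times[1L] + floor((times[length(times)] - times[1L]) /
                                  interval_ns) * interval_ns,
              by = interval_ns)
  vals <- matrix(NA_real_, nrow = length(grid), ncol = length(residues),
                 dimnames = list(NULL, residues))
  for (i in seq_along(grid)) {
    fr <- frame_at_time(frames, grid[i], tol = 1e-6)
    for (j in seq_along(residues)) {
      vals[i, j] <- estimate_pka_frame(fr, residues[j], params)
    }
  }
  pka_series(grid, vals, residues, interval_ns = interval_ns,
             state = state, replicate = replicate)
}

#' Extract a single pocket frame from a PDB file
#'
#' Convenience adapter for single-snapshot input: maps carboxylate oxygens
#' (OE1/OE2 of Glu, OD1/OD2 of Asp), lysine NZ amines, K+ ions and all other
#' heavy atoms within `shell_nm` of the pocket centroid onto the internal
#' pocket-frame columns.
#'
#' @param path PDB file path.
#' @param pocket Pocket residue names (`"E343"` style).
#' @param shell_nm Radius of the heavy-atom shell retained for burial
#'   estimation.
#' @return A pocket frame data frame (coordinates in nm).
#' @export
pocket_frame_from_pdb <- function(path, pocket = hka_pocket(),
                                  shell_nm = 1.2) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("pocket_frame_from_pdb requires the 'bio3d' package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  resno <- as.integer(sub("^[A-Z]", "", pocket))
  lab <- paste0(substr(a$resid, 1L, 1L), a$resno)  # e.g. G343 for GLU343
  lab <- ifelse(a$resid == "GLU", paste0("E", a$resno),
                ifelse(a$resid == "ASP", paste0("D", a$resno), lab))
  is_pocket <- lab %in% pocket & a$resno %in% resno
  carbox <- is_pocket & a$elety %in% c("OE1", "OE2", "OD1", "OD2")
  amine <- a$resid == "LYS" & a$elety == "NZ"
  ion <- a$resid %in% c("K", "POT") | a$elety %in% c("K", "K+")
  xyz <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  ctr <- colMeans(xyz[carbox, , drop = FALSE])
  d <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  heavy <- !grepl("^H", a$elety) & !carbox & !amine & !ion & d <= shell_nm
  keep <- carbox | amine | ion | heavy
  data.frame(
    atom = paste0(a$elety[keep], "_", a$resno[keep]),
    residue = ifelse(carbox[keep], lab[keep], NA_character_),
    role = ifelse(carbox[keep], "carboxyl_O",
                  ifelse(amine[keep], "amine_N",
                         ifelse(ion[keep], "ion", "shell"))),
    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
    stringsAsFactors = FALSE
  )
}
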