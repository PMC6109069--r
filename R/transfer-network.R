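# Directed proton-transfer network from ensemble correlation matrices.
#
# Physical screening criteria, applied per trajectory: (1) exactly one of
# the pair is protonated (a transfer needs a donor and a vacancy); (2) the
# pair's pKa series are strongly anti-correlated (r below a negative
# threshold, default -0.5); (3) the residues are spatially proximal;
# (4) depth from the luminal K+ access pathway, reported as an annotation.
# Edges are directed donor (protonated) -> acceptor (deprotonated) and
# weighted by the number of trajectories in which the pair passes.

#' Candidate donor/acceptor pairs from one correlation matrix
#'
#' Selects residue pairs whose coefficient is strictly below `threshold` and
#' of which exactly one member is protonated in the trajectory's state; the
#' protonated member becomes the donor. Pairs with both or neither member
#' protonated are excluded regardless of how negative their r is. Each pair
#' carries a `low_to_high` consistency flag: `TRUE` when the donor also has
#' the lower windowed mean pKa (transfer from low pKa to high pKa);
#' inconsistent pairs are flagged, never dropped.
#'
#' @param matrix A [correlation_matrix()] carrying its `protonation_state`.
#' @param threshold Correlation threshold (default -0.5; strict `<`).
#' @return Data frame with columns `donor`, `acceptor`, `r`, `low_to_high`,
#'   `state`, `replicate` (possibly zero rows).
#' @export
candidate_pairs <- function(matrix, threshold = -0.5) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  if (is.null(matrix$state)) {
    stop("correlation matrix carries no protonation state", call. = FALSE)
  }
  res <- matrix$residues
  prot <- matrix$state$protonated
  out <- list()
  for (i in seq_len(length(res) - 1L)) {
    for (j in seq(i + 1L, length(res))) {
      pi <- res[i] %in% prot
      pj <- res[j] %in% prot
      if (xor(pi, pj) && matrix$r[i, j] < threshold) {
        donor <- if (pi) res[i] else res[j]
        acceptor <- if (pi) res[j] else res[i]
        out[[length(out) + 1L]] <- data.frame(
          donor = donor, acceptor = acceptor, r = matrix$r[i, j],
          low_to_high = matrix$means[[donor]] < matrix$means[[acceptor]],
          state = state_label(matrix$state), replicate = matrix$replicate,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor = character(), acceptor = character(),
                      r = numeric(), low_to_high = logical(),
                      state = character(), replicate = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Filter candidate pairs by spatial proximity
#'
#' A transfer is implausible between distant residues: keeps pairs whose
#' time-averaged minimum carboxylate oxygen-oxygen distance over the
#' trajectory frames is at most `cutoff_nm`, annotating each retained pair
#' with that distance (`mean_min_oo_nm`).
#'
#' @param pairs Data frame from [candidate_pairs()].
#' @param frames Trajectory table (pocket-frame columns plus `time_ns`).
#' @param cutoff_nm Distance cutoff (default 0.6 nm, carboxylate
#'   hydrogen-bond/water-bridge reach).
#' @return The filtered, annotated pair data frame.
#' @export
proximity_filter <- function(pairs, frames, cutoff_nm = 0.6) {
  if (nrow(pairs) == 0L) {
    pairs$mean_min_oo_nm <- numeric(0)
    return(pairs)
  }
  times <- unique(frames$time_ns)
  dist_pair <- function(a, b) {
    per_frame <- vapply(times, function(t) {
      fr <- frames[frames$time_ns == t, , drop = FALSE]
      oa <- fr[!is.na(fr$residue) & fr$residue == a &
                 fr$role == "carboxyl_O", c("x", "y", "z"), drop = FALSE]
      ob <- fr[!is.na(fr$residue) & fr$residue == b &
                 fr$role == "carboxyl_O", c("x", "y", "z"), drop = FALSE]
      if (nrow(oa) == 0L || nrow(ob) == 0L) {
        stop("structural-data error: carboxylate oxygens of ", a, " or ", b,
             " missing from frames", call. = FALSE)
      }
      d2 <- outer(seq_len(nrow(oa)), seq_len(nrow(ob)), function(i, j) {
        (oa$x[i] - ob$x[j])^2 + (oa$y[i] - ob$y[j])^2 + (oa$z[i] - ob$z[j])^2
      })
      sqrt(min(d2))
    }, numeric(1))
    mean(per_frame)
  }
  pairs$mean_min_oo_nm <- mapply(dist_pair, pairs$donor, pairs$acceptor)
  pairs[pairs$mean_min_oo_nm <= cutoff_nm, , drop = FALSE]
}

#' Aggregate accepted pairs into a transfer network
#'
#' One directed edge per (donor, acceptor); `instances` counts the distinct
#' (state, replicate) trajectories contributing the pair — the unit of the
#' instance table is the trajectory, not the frame. Duplicate
#' (state, replicate, donor, acceptor) rows are deduplicated with a warning.
#' Edges are sorted by descending count, then canonical pocket order.
#'
#' @param pairs Row-bound accepted pairs from the whole ensemble.
#' @param pocket Canonical residue order for the node set and tie-breaks.
#' @return Object of class `transfer_network`: `nodes`, `edges` data frame
#'   (`donor`, `acceptor`, `instances`), and `contributing` (per-edge list
#'   of state/replicate data frames).
#' @export
aggregate_network <- function(pairs, pocket = hka_pocket()) {
  need <- c("donor", "acceptor", "state", "replicate")
  stopifnot(all(need %in% names(pairs)))
  key <- paste(pairs$state, pairs$replicate, pairs$donor, pairs$acceptor,
               sep = "|")
  if (anyDuplicated(key)) {
    warning("duplicate (state, replicate, donor, acceptor) entries ",
            "deduplicated: ", sum(duplicated(key)))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  if (any(pairs$donor == pairs$acceptor)) {
    stop("self-edges are not allowed in a transfer network", call. = FALSE)
  }
  ekey <- paste(pairs$donor, pairs$acceptor, sep = "->")
  counts <- table(ekey)
  uniq <- !duplicated(ekey)
  edges <- data.frame(
    donor = pairs$donor[uniq], acceptor = pairs$acceptor[uniq],
    instances = as.integer(counts[ekey[uniq]]),
    stringsAsFactors = FALSE
  )
  di <- match(edges$donor, pocket)
  ai <- match(edges$acceptor, pocket)
  ord <- order(-edges$instances, di, ai)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  contributing <- lapply(paste(edges$donor, edges$acceptor, sep = "->"),
                         function(k) {
                           sel <- ekey == k
                           data.frame(state = pairs$state[sel],
                                      replicate = pairs$replicate[sel],
                                      stringsAsFactors = FALSE)
                         })
  net <- list(nodes = pocket, edges = edges, contributing = contributing)
  class(net) <- "transfer_network"
  net
}

#' @export
print.transfer_network <- function(x, ...) {
  cat("transfer_network:", length(x$nodes), "residues,",
      nrow(x$edges), "directed edges\n")
  if (nrow(x$edges) > 0L) {
    print(transform(x$edges,
                    edge = paste0(donor, "+ -> ", acceptor))[, c("edge",
                                                                 "instances")])
  }
  invisible(x)
}

#' Rank edges by transfer likelihood
#'
#' Edges ordered by instance count (the ensemble frequency of strong
#' anti-correlation is read as transfer likelihood). Optionally annotates
#' each residue with its depth from a luminal access point — the distance of
#' the residue's carboxylate centroid from `access_point` averaged over
#' `frames` — supporting the release-to-bulk criterion; depth is reported,
#' never used as an automatic filter.
#'
#' @param network A `transfer_network`.
#' @param frames Optional trajectory table for depth annotation.
#' @param access_point Optional numeric `c(x, y, z)` of the luminal K+
#'   access point in nm.
#' @return List with `edges` (ranked data frame, rank column added) and
#'   `depth_nm` (named residue depths, or `NULL`).
#' @export
rank_transfer_likelihood <- function(network, frames = NULL,
                                     access_point = NULL) {
  stopifnot(inherits(network, "transfer_network"))
  edges <- network$edges
  edges$rank <- seq_len(nrow(edges))
  depth <- NULL
  if (!is.null(frames) && !is.null(access_point)) {
    stopifnot(length(access_point) == 3L)
    times <- unique(frames$time_ns)
    depth <- vapply(network$nodes, function(res) {
      mean(vapply(times, function(t) {
        ctr <- residue_centroid(frames[frames$time_ns == t, , drop = FALSE],
                                res)
        sqrt(sum((ctr - access_point)^2))
      }, numeric(1)))
    }, numeric(1))
  }
  list(edges = edges, depth_nm = depth)
}

as_igraph <- function(network) {
  stopifnot(inherits(network, "transfer_network"))
  if (nrow(network$edges) == 0L) {
    return(igraph::make_empty_graph(n = length(network$nodes)))
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = data.frame(
                                       name = network$nodes))
  igraph::E(g)$weight <- network$edges$instances
  g
}

#' Export a transfer network
#'
#' `"json"` writes nodes, directed edges with counts and the contributing
#' (state, replicate) list; `"dot"` writes Graphviz DOT with edge weights
#' equal to the counts; `"csv"` writes the donor/acceptor/instances table.
#'
#' @param network A `transfer_network`.
#' @param path Output path.
#' @param format One of `"json"`, `"dot"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("json", "dot", "csv")) {
  stopifnot(inherits(network, "transfer_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown export format",
                                              call. = FALSE))
  if (format == "json") {
    jsonlite::write_json(
      list(nodes = network$nodes,
           edges = cbind(network$edges,
                         contributing = I(lapply(network$contributing,
                                                 identity)))),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  } else if (format == "csv") {
    utils::write.csv(network$edges, path, row.names = FALSE)
  } else {
    lines <- c("digraph transfer_network {")
    for (n in network$nodes) lines <- c(lines, sprintf("  \"%s\";", n))
    if (nrow(network$edges) > 0L) {
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [weight=%d, label=%d, penwidth=%d];",
        network$edges$donor, network$edges$acceptor,
        network$edges$instances, network$edges$instances,
        network$edges$instances))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}
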