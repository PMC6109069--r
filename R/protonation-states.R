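# Protonation microstates of the cation-binding pocket.
#
# The luminal-open E2P binding pocket of the gastric proton pump carries five
# titratable carboxylates (E343, E795, E820, D824, D942).  A classical MD run
# fixes which of them are protonated; each such fixed assignment is one
# "protonation state" and the ensemble of simulations is one trajectory set
# per state.

#' Canonical binding-pocket residues
#'
#' Returns the five titratable carboxylate residues of the H+,K+-ATPase
#' cation-binding pocket in canonical order. All state labels produced by the
#' package use this order, so labels are stable join keys across modules.
#'
#' @return Character vector of residue names, e.g. `"E343"`.
#' @export
#' @examples
#' hka_pocket()
hka_pocket <- function() {
  c("E343", "E795", "E820", "D824", "D942")
}

#' Residue class from a residue name
#'
#' Residue names combine a one-letter residue type and a sequence number
#' (`"E343"`, `"D824"`). The letter determines the titratable class.
#'
#' @param name Character vector of residue names.
#' @return Character vector: `"glutamate"`, `"aspartate"` or `"other"`.
#' @export
residue_class <- function(name) {
  stopifnot(is.character(name))
  first <- substr(name, 1L, 1L)
  ifelse(first == "E", "glutamate", ifelse(first == "D", "aspartate", "other"))
}

validate_pocket <- function(pocket) {
  if (!is.character(pocket) || length(pocket) == 0L) {
    stop("pocket must be a non-empty character vector of residue names",
         call. = FALSE)
  }
  if (anyDuplicated(pocket)) {
    stop("pocket residue names must be unique", call. = FALSE)
  }
  if (!all(grepl("^[A-Z][0-9]+$", pocket))) {
    stop("residue names must look like 'E343' (letter + sequence number)",
         call. = FALSE)
  }
  invisible(pocket)
}

#' Construct a protonation state
#'
#' A protonation state records which pocket residues carry a proton. The
#' canonical label is the `'+'`-suffixed concatenation of the protonated
#' residues in pocket order, e.g. `"E343+E795+"`; the empty set has label
#' `""`.
#'
#' @param protonated Character vector of protonated residue names (a subset
#'   of `pocket`; order irrelevant).
#' @param pocket Ordered character vector of the pocket residues.
#' @return An object of class `protonation_state` with elements `protonated`,
#'   `pocket` and `label`.
#' @seealso [parse_state_label()], [enumerate_states()]
#' @export
#' @examples
#' protonation_state(c("D824", "E820"))$label
protonation_state <- function(protonated = character(), pocket = hka_pocket()) {
  validate_pocket(pocket)
  protonated <- unique(as.character(protonated))
  bad <- setdiff(protonated, pocket)
  if (length(bad) > 0L) {
    stop("protonated residues not in pocket: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  protonated <- pocket[pocket %in% protonated]  # canonical pocket order
  s <- list(
    protonated = protonated,
    pocket = pocket,
    label = state_label_chr(protonated)
  )
  class(s) <- "protonation_state"
  s
}

state_label_chr <- function(protonated) {
  if (length(protonated) == 0L) return("")
  paste0(paste0(protonated, "+"), collapse = "")
}

#' Canonical label of a protonation state
#'
#' @param state A `protonation_state`.
#' @return The canonical label string.
#' @export
state_label <- function(state) {
  stopifnot(inherits(state, "protonation_state"))
  state$label
}

#' Parse a protonation-state label
#'
#' Inverse of [state_label()]: `parse_state_label(state_label(s), s$pocket)`
#' recovers `s` for every state.
#'
#' @param label Label string such as `"E795+D824+D942+"`; `""` is the fully
#'   deprotonated state.
#' @param pocket Ordered pocket residues.
#' @return A `protonation_state`.
#' @export
#' @examples
#' parse_state_label("E795+D824+D942+")$protonated
parse_state_label <- function(label, pocket = hka_pocket()) {
  stopifnot(is.character(label), length(label) == 1L)
  validate_pocket(pocket)
  if (nchar(label) == 0L) return(protonation_state(character(), pocket))
  if (!grepl("\\+$", label)) {
    stop("malformed state label (tokens must end in '+'): ", label,
         call. = FALSE)
  }
  tokens <- strsplit(label, "+", fixed = TRUE)[[1L]]
  bad <- setdiff(tokens, pocket)
  if (length(bad) > 0L) {
    stop("unknown residue token(s) in label '", label, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tokens)) {
    stop("duplicate residue token in label: ", label, call. = FALSE)
  }
  protonation_state(tokens, pocket)
}

#' @export
print.protonation_state <- function(x, ...) {
  lab <- if (nchar(x$label)) x$label else "(fully deprotonated)"
  cat("protonation_state:", lab, "\n")
  cat("  pocket:", paste(x$pocket, collapse = " "), "\n")
  invisible(x)
}

#' @export
format.protonation_state <- function(x, ...) x$label

#' Enumerate protonation states with given proton counts
#'
#' Returns every subset of the pocket whose size is in `proton_counts`, as
#' `protonation_state` objects in deterministic lexicographic order of their
#' labels. With the five-residue pocket and counts `{2, 3}` this yields the
#' 20 microstates of the standard simulation ensemble; counts `{2}` alone
#' give the 10 two-proton states.
#'
#' @param pocket Ordered pocket residues.
#' @param proton_counts Integer vector of allowed numbers of protonated
#'   residues; every value must lie in `[0, length(pocket)]`.
#' @return List of `protonation_state` objects.
#' @export
#' @examples
#' length(enumerate_states(proton_counts = c(2, 3)))  # 20
enumerate_states <- function(pocket = hka_pocket(), proton_counts = c(2L, 3L)) {
  validate_pocket(pocket)
  proton_counts <- sort(unique(as.integer(proton_counts)))
  n <- length(pocket)
  if (any(is.na(proton_counts)) || any(proton_counts < 0L) ||
      any(proton_counts > n)) {
    stop("proton_counts must lie in [0, ", n, "]", call. = FALSE)
  }
  states <- list()
  for (k in proton_counts) {
    subs <- if (k == 0L) list(character()) else
      utils::combn(pocket, k, simplify = FALSE)
    states <- c(states, lapply(subs, protonation_state, pocket = pocket))
  }
  labels <- vapply(states, state_label, character(1))
  states[order(labels, method = "radix")]
}

#' Default simulation ensemble states
#'
#' The 20 microstates with two or three protonated residues. One- , four- and
#' five-proton states are enumerable via [enumerate_states()] but excluded
#' here: with a single proton the pocket carries too much net negative charge
#' for stable conformations, and with four or five protons K+ binding is
#' unlikely.
#'
#' @param pocket Ordered pocket residues.
#' @return List of 20 `protonation_state` objects.
#' @export
default_ensemble_states <- function(pocket = hka_pocket()) {
  enumerate_states(pocket, c(2L, 3L))
}

#' Write an ensemble manifest
#'
#' Serializes the ensemble design (states, replicate count, per-replicate
#' seeds) to JSON. Seeds are derived deterministically from `seed` so a
#' manifest fully reproduces an ensemble.
#'
#' @param states List of `protonation_state` objects.
#' @param path Output file path.
#' @param replicates Replicates per state (default 3).
#' @param seed Integer base seed.
#' @return The manifest (a list), invisibly.
#' @export
write_ensemble_manifest <- function(states, path, replicates = 3L, seed = 1L) {
  stopifnot(length(states) > 0L, replicates >= 1L)
  labels <- vapply(states, state_label, character(1))
  entries <- lapply(seq_along(states), function(i) {
    list(
      label = labels[[i]],
      protonated = states[[i]]$protonated,
      replicates = as.integer(replicates),
      seeds = vapply(seq_len(replicates), function(r) mix_seed(seed, i, r),
                     integer(1))
    )
  })
  manifest <- list(
    pocket = states[[1L]]$pocket,
    n_states = length(states),
    replicates_per_state = as.integer(replicates),
    base_seed = as.integer(seed),
    states = entries
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read an ensemble manifest
#'
#' @param path Manifest JSON path written by [write_ensemble_manifest()].
#' @return List with `pocket`, `states` (list of `protonation_state`),
#'   `replicates_per_state`, `base_seed` and per-state `seeds`.
#' @export
read_ensemble_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  pocket <- as.character(m$pocket)
  states <- lapply(m$states$label, parse_state_label, pocket = pocket)
  list(
    pocket = pocket,
    states = states,
    replicates_per_state = as.integer(m$replicates_per_state),
    base_seed = as.integer(m$base_seed),
    seeds = m$states$seeds
  )
}

# Deterministic 32-bit-safe seed mixing for derived streams.
mix_seed <- function(seed, i, j = 0L) {
  s <- (as.double(seed) * 2654435.0 + as.double(i) * 97561.0 +
          as.double(j) * 7919.0 + 12345.0) %% 2147483647
  as.integer(s)
}
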