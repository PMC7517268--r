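# IIT 3.0 calculator for binary networks of up to ~6 nodes.
#
# All user-facing functions take a full-system TPM plus a collective state
# and (optionally) a subsystem.  Nodes outside the subsystem are treated
# as background conditions frozen at their current state.  State indexing
# is little-endian throughout (see `state_to_bits()`).

MAX_IIT_NODES <- 6L

# Normalise `state` to a full-system bit vector.  A length-n 0/1 vector is
# taken as bits (node 1 first); a scalar is taken as the state integer.
as_state_bits <- function(state, n) {
  if (length(state) == n && n > 1L && all(state %in% c(0, 1))) {
    as.integer(state)
  } else if (length(state) == 1L) {
    state_to_bits(state, n)
  } else {
    stop("state must be a state integer or a length-", n, " bit vector")
  }
}

check_subsystem <- function(subsystem, n) {
  subsystem <- sort(as.integer(subsystem))
  stopifnot(length(subsystem) >= 1, all(subsystem >= 1), all(subsystem <= n),
            !anyDuplicated(subsystem))
  if (n > MAX_IIT_NODES) {
    stop("IIT calculations are limited to ", MAX_IIT_NODES, " nodes")
  }
  subsystem
}

#' Earth mover's distance between two distributions
#'
#' Exact optimal-transport cost between two probability distributions over
#' the same state space.  The default ground metric between binary purview
#' states is the Hamming distance; any symmetric non-negative matrix with a
#' zero diagonal can be supplied instead.
#'
#' @param p,q numeric probability vectors of equal length, each summing to
#'   1 (within `1e-9`).
#' @param ground_metric square matrix of pairwise state distances, or
#'   `NULL` for the Hamming distance between the little-endian binary
#'   states `0:(length(p)-1)` (which requires `length(p)` to be a power of
#'   two).
#' @return the optimal transport cost (non-negative scalar; 0 iff `p == q`
#'   up to tolerance).
#' @examples
#' emd(c(1, 0, 0, 0), c(0, 1, 0, 0))  # move mass 1 across Hamming dist 1
#' @export
emd <- function(p, q, ground_metric = NULL) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("p and q must be normalised distributions (sum to 1 within 1e-9)")
  }
  if (any(p < -1e-12) || any(q < -1e-12)) stop("negative probabilities")
  if (is.null(ground_metric)) {
    n_bits <- round(log2(length(p)))
    if (2^n_bits != length(p)) {
      stop("default Hamming metric needs a power-of-two state space")
    }
    return(cpp_hamming_emd(p, q))
  }
  ground_metric <- as.matrix(ground_metric)
  if (!isTRUE(all.equal(ground_metric, t(ground_metric))) ||
      any(diag(ground_metric) != 0) || any(ground_metric < 0)) {
    stop("ground_metric must be symmetric, non-negative, with zero diagonal")
  }
  cpp_transport(p, q, ground_metric)
}

repertoire <- function(purview, distribution, defined = TRUE) {
  structure(list(purview = purview, distribution = distribution,
                 defined = defined),
            class = "phi_repertoire")
}

#' @export
print.phi_repertoire <- function(x, ...) {
  cat("Repertoire over nodes {", paste(x$purview, collapse = ","), "}",
      if (!x$defined) " (undefined)", "\n", sep = "")
  print(x$distribution)
  invisible(x)
}

#' Effect repertoire of a mechanism over a purview
#'
#' Distribution over the next states of the purview when the mechanism
#' nodes are clamped to their current state and all other inputs are
#' replaced by independent maximum-entropy noise.  Purview nodes are
#' treated independently (the TPM is state-by-node, i.e. conditionally
#' independent).  An empty mechanism gives the unconstrained repertoire.
#'
#' @param tpm full-system [phi_tpm()].
#' @param state collective state: integer or full-system bit vector.
#' @param mechanism integer node indices (1-based); may be `integer(0)`.
#' @param purview non-empty integer node indices (1-based).
#' @param subsystem nodes forming the system under analysis; others are
#'   frozen background.  Default: all nodes.
#' @return a `phi_repertoire`: the purview and a probability vector over
#'   its `2^|purview|` states (little-endian in purview order).
#' @export
effect_repertoire <- function(tpm, state, mechanism, purview,
                              subsystem = seq_len(n_nodes(tpm))) {
  ctx <- iit_context(tpm, state, subsystem)
  rep_from_ctx(ctx, mechanism, purview, direction = "effect")
}

#' Cause repertoire of a mechanism over a purview
#'
#' Bayesian inversion of the forward dynamics under a uniform prior on
#' past states, marginalised onto the purview; per-mechanism-node
#' inversions are combined multiplicatively and renormalised (IIT 3.0
#' convention).  If the mechanism state is unreachable from every past
#' state the repertoire is flagged undefined and the mechanism contributes
#' `phi_cause = 0`.
#'
#' @inheritParams effect_repertoire
#' @return a `phi_repertoire`; check its `defined` flag.
#' @export
cause_repertoire <- function(tpm, state, mechanism, purview,
                             subsystem = seq_len(n_nodes(tpm))) {
  ctx <- iit_context(tpm, state, subsystem)
  rep_from_ctx(ctx, mechanism, purview, direction = "cause")
}

# Conditioned analysis context: subsystem TPM + subsystem-local state.
# `local` maps full-system node indices to 1..k within the subsystem.
iit_context <- function(tpm, state, subsystem) {
  tpm <- as_phi_tpm(tpm)
  n <- n_nodes(tpm)
  subsystem <- check_subsystem(subsystem, n)
  bits <- as_state_bits(state, n)
  sub_tpm <- condition_tpm(tpm, subsystem, bits)
  local <- match(seq_len(n), subsystem)
  list(tpm = sub_tpm, state = bits[subsystem], subsystem = subsystem,
       local = local, full_state = bits)
}

to_local <- function(ctx, nodes) {
  out <- ctx$local[as.integer(nodes)]
  if (anyNA(out)) stop("nodes must lie within the subsystem")
  sort(out)
}

rep_from_ctx <- function(ctx, mechanism, purview, direction) {
  purview_l <- to_local(ctx, purview)
  if (length(purview_l) == 0) stop("purview must be non-empty")
  mech_l <- if (length(mechanism)) to_local(ctx, mechanism) else integer(0)
  if (direction == "effect") {
    d <- cpp_effect_repertoire(unclass(ctx$tpm), ctx$state, mech_l - 1L,
                               purview_l - 1L)
    repertoire(ctx$subsystem[purview_l], d, TRUE)
  } else {
    r <- cpp_cause_repertoire(unclass(ctx$tpm), ctx$state, mech_l - 1L,
                              purview_l - 1L)
    repertoire(ctx$subsystem[purview_l], r$distribution, r$defined)
  }
}

#' Integrated information of a single mechanism-purview pair
#'
#' Minimum over all mechanism-level bipartitions of the earth mover's
#' distance between the unpartitioned repertoire and the product of the
#' part repertoires.  Partitions split the (mechanism, purview) pair into
#' two non-degenerate parts following the IIT 3.0 convention; the
#' minimising partition is returned.
#'
#' @inheritParams effect_repertoire
#' @param direction `"cause"` or `"effect"`.
#' @return list with `phi` (non-negative; 0 if the cause repertoire is
#'   undefined) and `partition` (the minimising partition as node-index
#'   lists, or `NULL`).
#' @export
small_phi <- function(tpm, state, mechanism, purview,
                      direction = c("effect", "cause"),
                      subsystem = seq_len(n_nodes(tpm))) {
  direction <- match.arg(direction)
  if (length(mechanism) == 0) stop("mechanism must be non-empty")
  if (length(purview) == 0) stop("purview must be non-empty")
  ctx <- iit_context(tpm, state, subsystem)
  mech_l <- to_local(ctx, mechanism)
  purv_l <- to_local(ctx, purview)
  r <- cpp_small_phi(unclass(ctx$tpm), ctx$state, mech_l - 1L, purv_l - 1L,
                     direction == "effect")
  if (length(r$partition) == 0) r$partition <- NULL
  if (!is.null(r$partition)) {
    r$partition <- lapply(r$partition, function(idx) ctx$subsystem[idx + 1L])
  }
  r
}

#' Compute the concept of a mechanism
#'
#' Maximises small phi over all candidate purviews for the cause and
#' effect directions separately (ties: largest purview, then the
#' lexicographically smallest).  A concept exists iff
#' `min(phi_cause, phi_effect) > 0`.
#'
#' @inheritParams effect_repertoire
#' @return a `phi_concept` (mechanism, purviews, repertoires,
#'   `phi = min(phi_cause, phi_effect)`), or `NULL` if the mechanism
#'   specifies no concept.
#' @export
compute_concept <- function(tpm, state, mechanism,
                            subsystem = seq_len(n_nodes(tpm))) {
  if (length(mechanism) == 0) stop("mechanism must be non-empty")
  ctx <- iit_context(tpm, state, subsystem)
  mech_l <- to_local(ctx, mechanism)
  cp <- cpp_concept(unclass(ctx$tpm), ctx$state, mech_l - 1L)
  if (!cp$exists) return(NULL)
  concept_from_cpp(cp, ctx)
}

concept_from_cpp <- function(cp, ctx) {
  structure(list(
    mechanism = ctx$subsystem[cp$mechanism + 1L],
    state = ctx$state[cp$mechanism + 1L],
    phi = cp$phi, phi_cause = cp$phi_cause, phi_effect = cp$phi_effect,
    cause_purview = ctx$subsystem[cp$cause_purview + 1L],
    effect_purview = ctx$subsystem[cp$effect_purview + 1L],
    cause_rep = repertoire(ctx$subsystem[cp$cause_purview + 1L], cp$cause_rep),
    effect_rep = repertoire(ctx$subsystem[cp$effect_purview + 1L],
                            cp$effect_rep)),
    class = "phi_concept")
}

#' @export
print.phi_concept <- function(x, ...) {
  cat(sprintf("Concept {%s}=%s  phi=%.6g (cause %.6g over {%s}, effect %.6g over {%s})\n",
              paste(x$mechanism, collapse = ","),
              paste(x$state, collapse = ""),
              x$phi, x$phi_cause, paste(x$cause_purview, collapse = ","),
              x$phi_effect, paste(x$effect_purview, collapse = ",")))
  invisible(x)
}

#' Conceptual structure (constellation of concepts) of a subsystem
#'
#' Iterates [compute_concept()] over every non-empty mechanism in the
#' power set of the subsystem and collects the concepts.
#'
#' @inheritParams effect_repertoire
#' @return a `phi_structure`: list of `phi_concept`s plus the subsystem
#'   and state.
#' @export
conceptual_structure <- function(tpm, state,
                                 subsystem = seq_len(n_nodes(tpm))) {
  ctx <- iit_context(tpm, state, subsystem)
  raw <- cpp_constellation(unclass(ctx$tpm), ctx$state)
  concepts <- lapply(raw, concept_from_cpp, ctx = ctx)
  structure(list(concepts = concepts, subsystem = ctx$subsystem,
                 state = ctx$full_state),
            class = "phi_structure")
}

#' @export
print.phi_structure <- function(x, ...) {
  cat("Conceptual structure over {", paste(x$subsystem, collapse = ","),
      "}: ", length(x$concepts), " concept(s), sum phi = ",
      format(sum(vapply(x$concepts, `[[`, numeric(1), "phi"))), "\n", sep = "")
  for (cpt in x$concepts) print(cpt)
  invisible(x)
}

# ---- conceptual-structure (extended EMD) distance ------------------------

# Expand a concept's repertoires over the full subsystem state space.
# Cause side: joint with the uniform distribution over non-purview nodes.
# Effect side: product with the unconstrained effect repertoire of the
# concept's own (possibly cut) system.
expand_concept <- function(cp, k, local_of, q_uncon) {
  list(cause = expand_cause(cp$cause_rep$distribution,
                            local_of(cp$cause_purview), k),
       effect = expand_effect(cp$effect_rep$distribution,
                              local_of(cp$effect_purview), k, q_uncon),
       phi = cp$phi)
}

expand_cause <- function(dist, purview_l, k) {
  bits <- all_state_bits(k)
  z <- as.vector(bits[, purview_l, drop = FALSE] %*% 2^(seq_along(purview_l) - 1L))
  dist[z + 1L] / 2^(k - length(purview_l))
}

expand_effect <- function(dist, purview_l, k, q_uncon) {
  bits <- all_state_bits(k)
  z <- as.vector(bits[, purview_l, drop = FALSE] %*% 2^(seq_along(purview_l) - 1L))
  out <- dist[z + 1L]
  for (j in setdiff(seq_len(k), purview_l)) {
    out <- out * ifelse(bits[, j] == 1L, q_uncon[j], 1 - q_uncon[j])
  }
  out
}

# Distance between two constellations (lists of expanded concepts) with a
# shared null concept; phi-weighted transport in concept space where the
# ground distance between concepts is the sum of their cause- and
# effect-repertoire EMDs over the full-system state space.
constellation_distance <- function(exp1, exp2, null_concept, k) {
  n1 <- length(exp1); n2 <- length(exp2)
  if (n1 == 0 && n2 == 0) return(0)
  bind <- function(lst, field) {
    vapply(c(lst, list(null_concept)), `[[`, numeric(2^k), field)
  }
  cpp_constellation_distance(
    bind(exp1, "cause"), bind(exp1, "effect"),
    vapply(exp1, `[[`, numeric(1), "phi"),
    bind(exp2, "cause"), bind(exp2, "effect"),
    vapply(exp2, `[[`, numeric(1), "phi"))
}

# Unconstrained per-node ON probabilities (inputs fully noised).
unconstrained_on <- function(sub_tpm) colMeans(unclass(sub_tpm))

#' Integrated conceptual information (big Phi) of a subsystem
#'
#' Phi is the minimum, over the evaluated unidirectional system cuts, of
#' the extended earth mover's distance between the intact conceptual
#' structure and the structure of the cut system.  The `cut_one`
#' approximation evaluates, for each node, the two cuts that sever the
#' node's incoming or outgoing edges (2N cuts); `exhaustive` evaluates
#' every unidirectional bipartition.  Cut edges are replaced by
#' independent maximum-entropy noise.
#'
#' @inheritParams effect_repertoire
#' @param cut_scheme `"cut_one"` (default, as used throughout the
#'   pipeline) or `"exhaustive"`.
#' @return a `phi_result`: `big_phi`, the minimising `mip_cut`
#'   (`from`/`to` node sets), the intact conceptual structure, the
#'   subsystem, and the distances of every evaluated cut.
#' @export
big_phi <- function(tpm, state, subsystem = seq_len(n_nodes(tpm)),
                    cut_scheme = c("cut_one", "exhaustive")) {
  cut_scheme <- match.arg(cut_scheme)
  tpm <- as_phi_tpm(tpm)
  subsystem <- check_subsystem(subsystem, n_nodes(tpm))
  if (length(subsystem) < 2) {
    stop("big_phi needs a subsystem of at least 2 nodes")
  }
  ctx <- iit_context(tpm, state, subsystem)
  k <- length(subsystem)
  local_of <- function(nodes) match(sort(as.integer(nodes)), subsystem)
  structure_full <- conceptual_structure(tpm, state, subsystem)
  cuts <- system_cuts(k, cut_scheme)
  cuts_global <- lapply(cuts, function(cut) {
    list(from = subsystem[cut$from], to = subsystem[cut$to])
  })

  if (length(structure_full$concepts) == 0) {
    return(phi_result(state = ctx$full_state, big_phi = 0,
                      mip_cut = cuts_global[[1]],
                      structure = structure_full, subsystem = subsystem,
                      cut_distances = rep(0, length(cuts))))
  }

  q_full <- unconstrained_on(ctx$tpm)
  exp_full <- lapply(structure_full$concepts, expand_concept, k = k,
                     local_of = local_of, q_uncon = q_full)
  null_concept <- list(cause = rep(1 / 2^k, 2^k),
                       effect = expand_effect(1, integer(0), k, q_full),
                       phi = 0)

  distances <- vapply(cuts, function(cut) {
    cut_tpm <- apply_cut(ctx$tpm, cut$from, cut$to)
    raw <- cpp_constellation(unclass(cut_tpm), ctx$state)
    q_cut <- unconstrained_on(cut_tpm)
    exp_cut <- lapply(raw, function(cp) {
      list(cause = expand_cause(cp$cause_rep, cp$cause_purview + 1L, k),
           effect = expand_effect(cp$effect_rep, cp$effect_purview + 1L, k,
                                  q_cut),
           phi = cp$phi)
    })
    constellation_distance(exp_full, exp_cut, null_concept, k)
  }, numeric(1))

  phi <- min(distances)
  if (phi < 1e-10) phi <- 0
  mip_idx <- which(distances <= phi + 1e-10)[1]
  phi_result(state = ctx$full_state, big_phi = phi,
             mip_cut = cuts_global[[mip_idx]], structure = structure_full,
             subsystem = subsystem, cut_distances = distances)
}

phi_result <- function(state, big_phi, mip_cut, structure, subsystem,
                       cut_distances) {
  structure(list(state = state, big_phi = big_phi, mip_cut = mip_cut,
                 structure = structure, subsystem = subsystem,
                 cut_distances = cut_distances),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("Phi = %.6g  state=%s  subsystem={%s}  MIP cut {%s} -/-> {%s}\n",
              x$big_phi, paste(x$state, collapse = ""),
              paste(x$subsystem, collapse = ","),
              paste(x$mip_cut$from, collapse = ","),
              paste(x$mip_cut$to, collapse = ",")))
  cat("  concepts:", length(x$structure$concepts), "\n")
  invisible(x)
}

#' Main complex of a network in a state
#'
#' Evaluates [big_phi()] over every node subset of size >= 2 and returns
#' the subset with maximal Phi.  Ties are resolved in favour of the
#' largest subset, then the lexicographically smallest.
#'
#' @inheritParams big_phi
#' @return list with `subsystem` and the corresponding `phi_result`.
#' @export
main_complex <- function(tpm, state, cut_scheme = c("cut_one", "exhaustive")) {
  cut_scheme <- match.arg(cut_scheme)
  tpm <- as_phi_tpm(tpm)
  n <- n_nodes(tpm)
  if (n < 2) stop("main_complex needs at least 2 nodes")
  candidates <- list()
  for (size in 2:n) {
    cmb <- combn(n, size)
    for (i in seq_len(ncol(cmb))) {
      candidates[[length(candidates) + 1L]] <- cmb[, i]
    }
  }
  best <- NULL
  for (sub in candidates) {
    res <- big_phi(tpm, state, sub, cut_scheme)
    if (is.null(best)) { best <- res; next }
    d <- res$big_phi - best$big_phi
    if (d > 1e-10) {
      best <- res
    } else if (abs(d) <= 1e-10 && subset_beats(sub, best$subsystem)) {
      best <- res
    }
  }
  list(subsystem = best$subsystem, result = best)
}

# Tie rule: larger subset wins; equal size -> lexicographically smaller.
subset_beats <- function(a, b) {
  if (length(a) != length(b)) return(length(a) > length(b))
  cmp <- a - b
  nz <- which(cmp != 0)
  if (length(nz) == 0) return(FALSE)
  cmp[nz[1]] < 0
}

#' JSON serialisation of a Phi result
#'
#' @param x a `phi_result`.
#' @param path optional file to write to.
#' @return JSON string (invisibly if `path` given).
#' @export
phi_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "phi_result"))
  obj <- list(
    state = paste(x$state, collapse = ""),
    big_phi = x$big_phi,
    subsystem = x$subsystem,
    mip_cut = list(from = x$mip_cut$from, to = x$mip_cut$to,
                   direction = "from -/-> to"),
    concepts = lapply(x$structure$concepts, function(cp) {
      list(mechanism = cp$mechanism, phi = cp$phi,
           phi_cause = cp$phi_cause, phi_effect = cp$phi_effect,
           cause_purview = cp$cause_purview,
           effect_purview = cp$effect_purview)
    }))
  out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
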