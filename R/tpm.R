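# State-by-node transition probability matrices.
#
# A `phi_tpm` is a (2^N x N) matrix: entry (r, i) is the probability that
# node i is ON at the next step given that the previous collective state
# was r - 1 (little-endian integer encoding; node 1 = least significant
# bit).  Under the conditional-independence assumption the full-state
# transition probability is the product over nodes of these entries.

#' Construct a state-by-node TPM
#'
#' @param probabilities numeric matrix with `2^N` rows and `N` columns;
#'   entry `(r, i)` is `P(node i ON at t | previous state r - 1)`.  Row
#'   order is little-endian: row `r` encodes the previous collective state
#'   `r - 1` with node 1 as the least significant bit.
#' @return an object of class `phi_tpm`.
#' @examples
#' copy2 <- phi_tpm(matrix(c(0, 0, 1, 1,   # node 1 next-ON iff node 2 ON
#'                           0, 1, 0, 1),  # node 2 next-ON iff node 1 ON
#'                         ncol = 2))
#' @export
phi_tpm <- function(probabilities) {
  probabilities <- as.matrix(probabilities)
  n <- ncol(probabilities)
  if (nrow(probabilities) != 2^n) {
    stop("a state-by-node TPM needs 2^N rows for N columns, got ",
         nrow(probabilities), " x ", n)
  }
  if (anyNA(probabilities) || any(probabilities < 0) || any(probabilities > 1)) {
    stop("TPM entries must be probabilities in [0, 1]")
  }
  storage.mode(probabilities) <- "double"
  dimnames(probabilities) <- list(
    apply(all_state_bits(n), 1, paste0, collapse = ""),
    paste0("node", seq_len(n)))
  structure(probabilities, class = c("phi_tpm", "matrix"))
}

#' @export
print.phi_tpm <- function(x, ...) {
  cat("State-by-node TPM:", n_nodes(x), "nodes,",
      nrow(x), "previous states (little-endian rows)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Number of nodes of a TPM
#' @param tpm a [phi_tpm()].
#' @return integer node count.
#' @export
n_nodes <- function(tpm) ncol(tpm)

as_phi_tpm <- function(tpm) {
  if (inherits(tpm, "phi_tpm")) tpm else phi_tpm(tpm)
}

#' Read / write a TPM in the plain-text exchange format
#'
#' The format is a whitespace-separated matrix of `2^N` rows by `N`
#' columns preceded by a single comment header naming `N` and the row
#' convention, e.g. `# schoolphi tpm n=3 rows=little-endian`.
#'
#' @param path file path.
#' @return `read_tpm()` returns a [phi_tpm()]; `write_tpm()` returns
#'   `path` invisibly.
#' @export
read_tpm <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#.*tpm.*n=\\d+", header)) {
    stop("not a schoolphi TPM file (missing header): ", path)
  }
  n <- as.integer(sub(".*n=(\\d+).*", "\\1", header))
  m <- as.matrix(read.table(path, skip = 1L, header = FALSE))
  if (ncol(m) != n) stop("TPM file header says n=", n, " but found ",
                         ncol(m), " columns")
  phi_tpm(m)
}

#' @rdname read_tpm
#' @param tpm a [phi_tpm()].
#' @export
write_tpm <- function(tpm, path) {
  tpm <- as_phi_tpm(tpm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schoolphi tpm n=%d rows=little-endian", n_nodes(tpm)),
             con)
  utils::write.table(unclass(tpm), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- conditioning and cuts ----------------------------------------------

# Restrict a TPM to `subsystem`, freezing the remaining nodes as background
# conditions clamped to their current state (IIT 3.0 convention).  `state`
# is the full-system bit vector.  Returns a (2^k x k) phi_tpm over the
# subsystem nodes in ascending order.
condition_tpm <- function(tpm, subsystem, state) {
  tpm <- as_phi_tpm(tpm)
  n <- n_nodes(tpm)
  subsystem <- sort(as.integer(subsystem))
  stopifnot(all(subsystem >= 1), all(subsystem <= n), !anyDuplicated(subsystem))
  k <- length(subsystem)
  if (k == n) return(tpm)
  background <- setdiff(seq_len(n), subsystem)
  sub_bits <- all_state_bits(k)
  full_states <- integer(2^k)
  for (z in seq_len(2^k)) {
    bits <- integer(n)
    bits[subsystem] <- sub_bits[z, ]
    bits[background] <- state[background]
    full_states[z] <- bits_to_state(bits)
  }
  phi_tpm(unclass(tpm)[full_states + 1L, subsystem, drop = FALSE])
}

# Apply a unidirectional system cut: connections from `from` into `to` are
# replaced by independent maximum-entropy noise.  Concretely, for each node
# j in `to`, its conditional ON-probability is averaged over the states of
# the `from` nodes (inputs from `from` no longer constrain j).  Nodes are
# 1-based indices into the (sub)system the TPM describes.
apply_cut <- function(tpm, from, to) {
  tpm <- as_phi_tpm(tpm)
  k <- n_nodes(tpm)
  from <- sort(as.integer(from)); to <- sort(as.integer(to))
  stopifnot(length(from) > 0, length(to) > 0,
            length(intersect(from, to)) == 0,
            setequal(c(from, to), seq_len(k)))
  states <- 0:(2^k - 1L)
  keep_mask <- sum(2^(setdiff(seq_len(k), from) - 1L))
  grp <- bitwAnd(states, keep_mask)
  out <- unclass(tpm)
  for (j in to) {
    means <- tapply(out[, j], grp, mean)
    out[, j] <- means[as.character(grp)]
  }
  phi_tpm(out)
}

# Unidirectional cuts evaluated by each scheme, in the deterministic order
# used for tie-breaking (per node: edges *into* the node first, then edges
# out of it; exhaustive cuts by ascending from-part mask).
system_cuts <- function(k, cut_scheme = c("cut_one", "exhaustive")) {
  cut_scheme <- match.arg(cut_scheme)
  nodes <- seq_len(k)
  cuts <- list()
  if (cut_scheme == "cut_one") {
    for (v in nodes) {
      cuts[[length(cuts) + 1L]] <- list(from = setdiff(nodes, v), to = v)
      cuts[[length(cuts) + 1L]] <- list(from = v, to = setdiff(nodes, v))
    }
  } else {
    for (mask in 1:(2^k - 2L)) {
      from <- nodes[bitwAnd(bitwShiftR(mask, nodes - 1L), 1L) == 1L]
      cuts[[length(cuts) + 1L]] <- list(from = from, to = setdiff(nodes, from))
    }
  }
  unique(cuts)
}
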