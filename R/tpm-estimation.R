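# Estimating a state-by-node TPM from a collective-state sequence, and
# simulating sequences from a given TPM.

seq_to_states <- function(seq) {
  m <- unclass(seq)
  as.integer(m %*% 2^(seq_len(ncol(m)) - 1L))
}

#' Transition counts of a collective-state sequence
#'
#' @param seq a `state_seq` (or plain 0/1 matrix, one row per step).
#' @return list with `n_on` (`2^N x N` matrix: times each node was ON at
#'   `t+1` given the previous state) and `n_total` (occurrences of each
#'   previous state followed by another observation).
#' @export
transition_counts <- function(seq) {
  m <- unclass(as.matrix(seq))
  if (nrow(m) < 2) stop("need at least 2 observations to count transitions")
  n <- ncol(m)
  prev <- as.integer(m[-nrow(m), , drop = FALSE] %*% 2^(seq_len(n) - 1L))
  nxt <- m[-1, , drop = FALSE]
  n_on <- matrix(0, 2^n, n)
  for (j in seq_len(n)) {
    s <- tapply(nxt[, j], factor(prev, levels = 0:(2^n - 1L)), sum)
    n_on[, j] <- ifelse(is.na(s), 0, s)
  }
  n_total <- as.vector(table(factor(prev, levels = 0:(2^n - 1L))))
  list(n_on = n_on, n_total = n_total)
}

#' Estimate a state-by-node TPM from a state sequence
#'
#' Maximum-likelihood per-node ON frequencies conditional on the previous
#' collective state, under the conditional-independence assumption.
#' Previous states never observed are filled with maximum-entropy rows
#' (0.5 per node) by default, consistent with the maximum-entropy input
#' convention of the IIT machinery; `fill = "laplace"` instead applies
#' add-one smoothing to every row.
#'
#' @param seq a `state_seq` or 0/1 matrix (rows = time).
#' @param fill `"maxent"` (default) or `"laplace"`.
#' @return a [phi_tpm()] with a `counts` attribute (see
#'   [transition_counts()]).
#' @export
estimate_tpm <- function(seq, fill = c("maxent", "laplace")) {
  fill <- match.arg(fill)
  cnt <- transition_counts(seq)
  n <- ncol(cnt$n_on)
  if (fill == "laplace") {
    p <- (cnt$n_on + 1) / (cnt$n_total + 2)
  } else {
    p <- cnt$n_on / ifelse(cnt$n_total == 0, 1, cnt$n_total)
    p[cnt$n_total == 0, ] <- 0.5
  }
  out <- phi_tpm(p)
  attr(out, "counts") <- cnt
  out
}

#' Simulate a collective-state sequence from a TPM
#'
#' Samples a Markov chain in which each node is drawn independently from
#' its conditional ON-probability given the previous collective state.
#'
#' @param tpm a [phi_tpm()].
#' @param length number of steps to generate.
#' @param seed integer seed (the caller's RNG state is preserved).
#' @param init initial collective state (integer, default drawn uniformly).
#' @return a `state_seq` (synthetic: `dt_frames = 1`).
#' @export
simulate_sequence <- function(tpm, length, seed, init = NULL) {
  tpm <- as_phi_tpm(tpm)
  n <- n_nodes(tpm)
  stopifnot(length >= 1)
  p <- unclass(tpm)
  states <- with_seed(seed, {
    u <- matrix(runif(length * n), length, n)
    out <- matrix(0L, length, n)
    s <- if (is.null(init)) sample(0:(2^n - 1L), 1) else as.integer(init)
    out[1, ] <- state_to_bits(s, n)
    if (length > 1) for (t in 2:length) {
      prev <- as.integer(sum(out[t - 1L, ] * 2^(seq_len(n) - 1L)))
      out[t, ] <- as.integer(u[t, ] < p[prev + 1L, ])
    }
    out
  })
  new_state_seq(states, NULL, 1L, 1, "simulated", seq_len(length), 0L,
                list(seed = seed))
}

#' State occupancy distribution of a sequence
#'
#' @param seq a `state_seq` or 0/1 matrix.
#' @return named numeric vector of relative frequencies over all `2^N`
#'   collective states (little-endian state labels); sums to 1.
#' @export
state_occupancy <- function(seq) {
  m <- unclass(as.matrix(seq))
  if (nrow(m) == 0) stop("empty sequence")
  n <- ncol(m)
  s <- as.integer(m %*% 2^(seq_len(n) - 1L))
  tab <- table(factor(s, levels = 0:(2^n - 1L)))
  out <- as.vector(tab) / nrow(m)
  names(out) <- apply(all_state_bits(n), 1, paste0, collapse = "")
  out
}
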