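#' @useDynLib schoolphi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm var cor setNames aggregate
#' @importFrom utils read.csv write.csv head combn modifyList
NULL

# ---- state indexing helpers (little-endian: node 1 is the LSB) ----------

#' Convert a state integer to its bit vector
#'
#' States are encoded little-endian: node 1 of the network is the least
#' significant bit of the collective-state integer.  This convention is
#' used everywhere in the package (TPM row order, state labels, simulated
#' sequences).
#'
#' @param state integer in `0:(2^n_nodes - 1)`.
#' @param n_nodes number of nodes.
#' @return integer vector of 0/1 bits, element `i` being the state of
#'   node `i`.
#' @examples
#' state_to_bits(5, 3)  # c(1, 0, 1)
#' @export
state_to_bits <- function(state, n_nodes) {
  stopifnot(length(state) == 1L, state >= 0, state < 2^n_nodes)
  bitwAnd(bitwShiftR(as.integer(state), 0:(n_nodes - 1L)), 1L)
}

#' Convert a bit vector to its state integer
#'
#' @param bits integer vector of 0/1, node 1 first (little-endian).
#' @return integer state index in `0:(2^length(bits) - 1)`.
#' @examples
#' bits_to_state(c(1, 0, 1))  # 5
#' @export
bits_to_state <- function(bits) {
  stopifnot(all(bits %in% c(0L, 1L)))
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

# Bits of all states 0..2^n-1 as a (2^n x n) matrix (row r = state r-1).
all_state_bits <- function(n_nodes) {
  states <- 0:(2^n_nodes - 1L)
  vapply(seq_len(n_nodes), function(i) bitwAnd(bitwShiftR(states, i - 1L), 1L),
         integer(length(states)))
}

# Hamming ground-distance matrix between the 2^n states of n bits.
hamming_matrix <- local({
  cache <- list()
  function(n_bits) {
    key <- as.character(n_bits)
    if (is.null(cache[[key]])) {
      states <- 0:(2^n_bits - 1L)
      x <- outer(states, states, bitwXor)
      d <- matrix(0, length(states), length(states))
      for (i in seq_len(n_bits)) {
        d <- d + bitwAnd(bitwShiftR(x, i - 1L), 1L)
      }
      cache[[key]] <<- d
    }
    cache[[key]]
  }
})

# ---- geometry helpers ----------------------------------------------------

# Angle in [0, pi] between rows of two 2-column matrices (or vectors).
# Returns NA where either vector has (near-)zero length.
vector_angle <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  dot <- rowSums(a * b)
  crs <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  na <- sqrt(rowSums(a^2)) < 1e-12 | sqrt(rowSums(b^2)) < 1e-12
  ang <- atan2(abs(crs), dot)
  ang[na] <- NA_real_
  ang
}

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
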