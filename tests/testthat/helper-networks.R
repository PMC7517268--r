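# Small reference networks used across the unit tests.

# 2-node copy: each node next-ON iff the other is currently ON.
copy2_tpm <- function() {
  phi_tpm(matrix(c(0, 0, 1, 1,   # node 1 reads node 2
                   0, 1, 0, 1),  # node 2 reads node 1
                 ncol = 2))
}

# Two causally independent fully-noisy nodes.
noise2_tpm <- function() phi_tpm(matrix(0.5, 4, 2))

# Feed-forward pair: node 1 has no inputs (constant 0.5 column), node 2
# copies node 1.
feedforward2_tpm <- function() {
  phi_tpm(matrix(c(0.5, 0.5, 0.5, 0.5,
                   0, 1, 0, 1), ncol = 2))
}

# Copy pair plus an isolated noisy third node.
copy_pair_plus_noise_tpm <- function() {
  # nodes 1,2 copy each other ignoring node 3; node 3 fully noisy
  bits <- expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1)
  phi_tpm(cbind(bits$b2, bits$b1, 0.5))
}

# 3-node majority-style network: each node next-ON with probability 0.9
# when at least one of the *other* nodes is ON, else 0.1.
majority3_tpm <- function() {
  bits <- expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1)
  p <- function(other1, other2) ifelse(other1 + other2 >= 1, 0.9, 0.1)
  phi_tpm(cbind(p(bits$b2, bits$b3), p(bits$b1, bits$b3), p(bits$b1, bits$b2)))
}
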