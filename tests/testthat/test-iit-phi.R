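# Mechanism-level integrated information: small phi, concepts, and
# conceptual structures, against exhaustive-enumeration oracles.

test_that("small phi is zero for causally disconnected pairs", {
  nn <- noise2_tpm()
  expect_equal(small_phi(nn, c(1, 1), 1, 2, "effect")$phi, 0)
  expect_equal(small_phi(nn, c(1, 1), 1, 2, "cause")$phi, 0)
})

test_that("small phi on the copy network matches exhaustive brute force", {
  tpm <- copy2_tpm()
  P <- unclass(tpm)
  for (d in c("effect", "cause")) {
    got <- small_phi(tpm, c(1, 1), 1, 2, d)$phi
    expect_equal(got, or_small_phi(P, c(1, 1), 1, 2, d), tolerance = 1e-10)
  }
  # undefined cause repertoire -> phi 0, no partition
  un <- phi_tpm(matrix(c(0.5, 0.5, 0.5, 0.5, 1, 1, 1, 1), ncol = 2))
  r <- small_phi(un, c(0, 0), 2, 1, "cause")
  expect_equal(r$phi, 0)
  expect_null(r$partition)
})

test_that("small phi matches the oracle on random multi-node pairs", {
  set.seed(31)
  for (rep_i in 1:4) {
    tpm <- random_markov_tpm(3, seed = 900 + rep_i)
    P <- unclass(tpm)
    state <- state_to_bits(sample(0:7, 1), 3)
    mech <- sort(sample(1:3, 2))
    purv <- sort(sample(1:3, 2))
    for (d in c("effect", "cause")) {
      expect_equal(small_phi(tpm, state, mech, purv, d)$phi,
                   or_small_phi(P, state, mech, purv, d),
                   tolerance = 1e-8,
                   label = sprintf("rep %d dir %s", rep_i, d))
    }
  }
})

test_that("concepts: copy network specifies them, noise does not", {
  tpm <- copy2_tpm()
  cp <- compute_concept(tpm, c(1, 1), 1)
  expect_s3_class(cp, "phi_concept")
  expect_gt(cp$phi, 0)
  expect_equal(cp$phi, min(cp$phi_cause, cp$phi_effect))
  # mechanism with no effect information -> no concept
  expect_null(compute_concept(noise2_tpm(), c(1, 1), 1))
  # unreachable mechanism state -> no concept
  un <- phi_tpm(matrix(c(0.5, 0.5, 0.5, 0.5, 1, 1, 1, 1), ncol = 2))
  expect_null(compute_concept(un, c(0, 0), 2))
})

test_that("concept purview choice matches the oracle tie rules", {
  set.seed(41)
  for (rep_i in 1:3) {
    tpm <- random_markov_tpm(3, seed = 1300 + rep_i)
    P <- unclass(tpm)
    state <- state_to_bits(sample(0:7, 1), 3)
    for (msize in 1:2) {
      mech <- sort(sample(1:3, msize))
      oc <- or_concept(P, state, mech)
      pc <- compute_concept(tpm, state, mech)
      if (oc$phi == 0) {
        expect_null(pc)
      } else {
        expect_equal(pc$phi, oc$phi, tolerance = 1e-8)
        expect_equal(pc$cause_purview, oc$cause_purview)
        expect_equal(pc$effect_purview, oc$effect_purview)
      }
    }
  }
})

test_that("conceptual structures enumerate the power set correctly", {
  # independent noisy nodes: empty structure
  cs <- conceptual_structure(noise2_tpm(), c(0, 0))
  expect_length(cs$concepts, 0)
  # copy network at (1,1): all three mechanisms are evaluated; the joint
  # mechanism factorises exactly (cross-partition reproduces both
  # repertoires), so only the single-node mechanisms specify concepts
  cs2 <- conceptual_structure(copy2_tpm(), c(1, 1))
  expect_length(cs2$concepts, 2)
  mechs <- lapply(cs2$concepts, `[[`, "mechanism")
  expect_setequal(vapply(mechs, paste, character(1), collapse = ","),
                  c("1", "2"))
  expect_equal(or_concept(unclass(copy2_tpm()), c(1, 1), c(1, 2))$phi, 0)
  # single-node subsystem without self-loops specifies nothing
  cs3 <- conceptual_structure(copy2_tpm(), c(1, 1), subsystem = 1)
  expect_length(cs3$concepts, 0)
})

test_that("identical inputs give bit-identical outputs", {
  tpm <- random_markov_tpm(3, seed = 77)
  a <- conceptual_structure(tpm, 5)
  b <- conceptual_structure(tpm, 5)
  expect_identical(a, b)
  r1 <- big_phi(tpm, 5)
  r2 <- big_phi(tpm, 5)
  expect_identical(r1$big_phi, r2$big_phi)
  expect_identical(r1$cut_distances, r2$cut_distances)
})
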