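# Independent brute-force IIT evaluator, written in plain R with its own
# enumeration code.  It shares nothing with the production path except
# the generic transport solver (cpp_transport), which is itself validated
# against frozen LP-oracle values in test-emd.R.  Everything else --
# repertoires, partition enumeration, purview scans, cuts, conceptual
# structure comparison -- is re-derived here by direct enumeration.

cpp_transport <- schoolphi:::cpp_transport

or_bits <- function(s, n) as.integer(intToBits(s))[seq_len(n)]
or_state <- function(bits) sum(bits * 2^(seq_along(bits) - 1))

or_hamming <- function(n_bits) {
  s <- 0:(2^n_bits - 1)
  outer(s, s, function(i, j) {
    mapply(function(a, b) sum(or_bits(bitwXor(a, b), n_bits)), i, j)
  })
}

or_emd <- function(p, q, D) cpp_transport(p, q, D)

# Effect repertoire: per purview node, explicit enumeration of the noised
# inputs; joint = product of marginals.
or_effect_rep <- function(P, mech, mstate, purview) {
  k <- ncol(P)
  marg <- vapply(purview, function(j) {
    tot <- 0; cnt <- 0
    for (r in 0:(2^k - 1)) {
      b <- or_bits(r, k)
      if (length(mech) && any(b[mech] != mstate)) next
      tot <- tot + P[r + 1, j]; cnt <- cnt + 1
    }
    tot / cnt
  }, numeric(1))
  nz <- 2^length(purview)
  vapply(0:(nz - 1), function(z) {
    zb <- or_bits(z, length(purview))
    prod(ifelse(zb == 1, marg, 1 - marg))
  }, numeric(1))
}

# Cause repertoire: per mechanism node Bayesian inversion under a uniform
# prior, combined multiplicatively; NULL when undefined.
or_cause_rep <- function(P, mech, mstate, purview) {
  k <- ncol(P)
  nz <- 2^length(purview)
  if (!length(mech)) return(rep(1 / nz, nz))
  acc <- rep(1, nz)
  for (a in seq_along(mech)) {
    ci <- rep(0, nz)
    for (r in 0:(2^k - 1)) {
      b <- or_bits(r, k)
      w <- if (mstate[a] == 1) P[r + 1, mech[a]] else 1 - P[r + 1, mech[a]]
      z <- or_state(b[purview])
      ci[z + 1] <- ci[z + 1] + w
    }
    acc <- acc * ci
  }
  s <- sum(acc)
  if (s <= 0) return(NULL)
  acc / s
}

or_rep <- function(P, mech, mstate, purview, direction) {
  if (direction == "effect") or_effect_rep(P, mech, mstate, purview)
  else or_cause_rep(P, mech, mstate, purview)
}

# Assemble a partitioned distribution over `purview` from two part
# distributions over disjoint pieces.
or_combine <- function(purview, v1, r1, v2, r2) {
  nz <- 2^length(purview)
  vapply(0:(nz - 1), function(z) {
    zb <- or_bits(z, length(purview))
    val <- 1
    if (length(v1)) val <- val * r1[or_state(zb[match(v1, purview)]) + 1]
    if (length(v2)) val <- val * r2[or_state(zb[match(v2, purview)]) + 1]
    val
  }, numeric(1))
}

subsets_of <- function(x) {
  out <- list(integer(0))
  for (e in x) out <- c(out, lapply(out, function(s) c(s, e)))
  out
}

# Minimum over all admissible (mechanism, purview) bipartitions; every
# unordered pair is visited (twice -- harmless for the minimum).
or_small_phi <- function(P, state, mech, purview, direction) {
  mstate <- state[mech]
  unpart <- or_rep(P, mech, mstate, purview, direction)
  if (is.null(unpart)) return(0)
  D <- or_hamming(length(purview))
  best <- Inf
  for (m1 in subsets_of(mech)) {
    m2 <- setdiff(mech, m1)
    for (v1 in subsets_of(purview)) {
      v2 <- setdiff(purview, v1)
      if (length(m1) == 0 && length(v1) == 0) next
      if (length(m2) == 0 && length(v2) == 0) next
      r1 <- if (length(v1)) or_rep(P, m1, state[m1], v1, direction)
      r2 <- if (length(v2)) or_rep(P, m2, state[m2], v2, direction)
      if ((length(v1) && is.null(r1)) || (length(v2) && is.null(r2))) next
      part <- or_combine(purview, v1, r1, v2, r2)
      best <- min(best, or_emd(unpart, part, D))
    }
  }
  if (best < 1e-10) 0 else best
}

# phi^max over purviews for one direction, with the package's tie rules
# (largest purview, then lexicographically smallest node list).
or_max_purview <- function(P, state, mech, direction) {
  k <- ncol(P)
  best <- NULL
  for (pv in subsets_of(seq_len(k))) {
    if (!length(pv)) next
    phi <- or_small_phi(P, state, mech, pv, direction)
    take <- is.null(best) || phi > best$phi + 1e-10 ||
      (abs(phi - best$phi) <= 1e-10 &&
         (length(pv) > length(best$purview) ||
            (length(pv) == length(best$purview) &&
               or_lex_less(pv, best$purview))))
    if (take) best <- list(phi = phi, purview = pv)
  }
  best$rep <- or_rep(P, mech, state[mech], best$purview, direction)
  best
}

or_lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  FALSE
}

or_concept <- function(P, state, mech) {
  ca <- or_max_purview(P, state, mech, "cause")
  ef <- or_max_purview(P, state, mech, "effect")
  phi <- min(ca$phi, ef$phi)
  list(mechanism = mech, phi = if (phi < 1e-10) 0 else phi,
       phi_cause = ca$phi, phi_effect = ef$phi,
       cause_purview = ca$purview, effect_purview = ef$purview,
       cause_rep = ca$rep, effect_rep = ef$rep)
}

or_constellation <- function(P, state) {
  k <- ncol(P)
  out <- list()
  for (mech in subsets_of(seq_len(k))) {
    if (!length(mech)) next
    cp <- or_concept(P, state, mech)
    if (cp$phi > 1e-10) out[[length(out) + 1]] <- cp
  }
  out
}

or_cut_tpm <- function(P, from, to) {
  k <- ncol(P)
  out <- P
  for (j in to) {
    for (r in 0:(2^k - 1)) {
      b <- or_bits(r, k)
      rows <- which(vapply(0:(2^k - 1), function(r2) {
        b2 <- or_bits(r2, k)
        all(b2[-from] == b[-from])
      }, logical(1)))
      out[r + 1, j] <- mean(P[rows, j])
    }
  }
  out
}

or_expand_cause <- function(dist, purview, k) {
  vapply(0:(2^k - 1), function(s) {
    b <- or_bits(s, k)
    dist[or_state(b[purview]) + 1] / 2^(k - length(purview))
  }, numeric(1))
}

or_expand_effect <- function(dist, purview, k, q) {
  vapply(0:(2^k - 1), function(s) {
    b <- or_bits(s, k)
    base <- if (length(purview)) dist[or_state(b[purview]) + 1] else 1
    rest <- setdiff(seq_len(k), purview)
    base * prod(ifelse(b[rest] == 1, q[rest], 1 - q[rest]))
  }, numeric(1))
}

or_constellation_distance <- function(con1, con2, P_uncut, P_cut1, P_cut2) {
  k <- ncol(P_uncut)
  Dfull <- or_hamming(k)
  expand_all <- function(con, P_sys) {
    q <- colMeans(P_sys)
    lapply(con, function(cp) list(
      cause = or_expand_cause(cp$cause_rep, cp$cause_purview, k),
      effect = or_expand_effect(cp$effect_rep, cp$effect_purview, k, q),
      phi = cp$phi))
  }
  e1 <- expand_all(con1, P_cut1)
  e2 <- expand_all(con2, P_cut2)
  q0 <- colMeans(P_uncut)
  null_c <- list(cause = rep(1 / 2^k, 2^k),
                 effect = or_expand_effect(NULL, integer(0), k, q0), phi = 0)
  a1 <- c(e1, list(null_c)); a2 <- c(e2, list(null_c))
  cost <- matrix(0, length(a1), length(a2))
  for (i in seq_along(a1)) {
    for (j in seq_along(a2)) {
      if (i == length(a1) && j == length(a2)) next
      cost[i, j] <- or_emd(a1[[i]]$cause, a2[[j]]$cause, Dfull) +
        or_emd(a1[[i]]$effect, a2[[j]]$effect, Dfull)
    }
  }
  sup <- c(vapply(e1, `[[`, numeric(1), "phi"),
           sum(vapply(e2, `[[`, numeric(1), "phi")))
  dem <- c(vapply(e2, `[[`, numeric(1), "phi"),
           sum(vapply(e1, `[[`, numeric(1), "phi")))
  cpp_transport(sup, dem, cost)
}

# Unidirectional bipartitions (every from-part), or the cut-one subset.
or_cuts <- function(k, scheme = "cut_one") {
  nodes <- seq_len(k)
  if (scheme == "cut_one") {
    cuts <- list()
    for (v in nodes) {
      cuts <- c(cuts, list(list(from = setdiff(nodes, v), to = v),
                           list(from = v, to = setdiff(nodes, v))))
    }
    cuts
  } else {
    lapply(1:(2^k - 2), function(mask) {
      from <- nodes[or_bits(mask, k)[nodes] == 1]
      list(from = from, to = setdiff(nodes, from))
    })
  }
}

or_big_phi <- function(P, state, scheme = "cut_one") {
  con <- or_constellation(P, state)
  cuts <- unique(or_cuts(ncol(P), scheme))
  if (!length(con)) {
    return(list(big_phi = 0, mip_cut = cuts[[1]],
                distances = rep(0, length(cuts)), constellation = con))
  }
  distances <- vapply(cuts, function(cut) {
    Pc <- or_cut_tpm(P, cut$from, cut$to)
    or_constellation_distance(con, or_constellation(Pc, state), P, P, Pc)
  }, numeric(1))
  phi <- min(distances)
  if (phi < 1e-10) phi <- 0
  list(big_phi = phi, mip_cut = cuts[[which(distances <= phi + 1e-10)[1]]],
       distances = distances, constellation = con)
}
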