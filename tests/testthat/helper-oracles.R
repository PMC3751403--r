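# Independent oracles: exhaustive enumeration for Mk2, a plain-R
# fixed-step RK4 integrator for the SSE ordinary differential
# equations, and small tree builders.  These deliberately share no
# code with the package internals they check.

# random non-ultrametric tree for Mk (branch lengths ~ U(0, scale))
rand_mk_tree <- function(n, scale = 5) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length * scale
  tr
}

# random ultrametric tree of depth `depth` (coalescent shape)
rand_ultra_tree <- function(n, depth = 20) {
  tr <- ape::rcoal(n)
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr
}

mk2_pmat_oracle <- function(t, q01, q10) {
  s <- q01 + q10
  if (s == 0) return(diag(2))
  pi0 <- q10 / s; pi1 <- q01 / s
  e <- exp(-s * t)
  rbind(c(pi0 + pi1 * e, pi1 * (1 - e)),
        c(pi0 * (1 - e), pi1 + pi0 * e))
}

# joint probability of one full assignment of states to all nodes
mk2_enum_joint <- function(tree, node_state, q01, q10, root_prior) {
  root <- ape::Ntip(tree) + 1L
  p <- root_prior[node_state[root] + 1L]
  for (e in seq_len(nrow(tree$edge))) {
    P <- mk2_pmat_oracle(tree$edge.length[e], q01, q10)
    p <- p * P[node_state[tree$edge[e, 1]] + 1L,
               node_state[tree$edge[e, 2]] + 1L]
  }
  p
}

# sum over all internal-state combinations
mk2_enum_loglik <- function(tree, states, q01, q10,
                            root_prior = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.null(root_prior)) {
    s <- q01 + q10
    root_prior <- if (s == 0) c(0.5, 0.5) else c(q10, q01) / s
  }
  m <- tree$Nnode
  st <- integer(ntip + m)
  st[seq_len(ntip)] <- as.integer(states[tree$tip.label])
  total <- 0
  for (combo in 0:(2^m - 1)) {
    st[ntip + seq_len(m)] <- bitwAnd(combo %/% 2^(seq_len(m) - 1), 1L)
    total <- total + mk2_enum_joint(tree, st, q01, q10, root_prior)
  }
  log(total)
}

# marginal probability that `node` is in state 0, by renormalised
# enumeration
mk2_enum_marginal0 <- function(tree, states, q01, q10, node,
                               root_prior = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.null(root_prior)) {
    s <- q01 + q10
    root_prior <- if (s == 0) c(0.5, 0.5) else c(q10, q01) / s
  }
  m <- tree$Nnode
  st <- integer(ntip + m)
  st[seq_len(ntip)] <- as.integer(states[tree$tip.label])
  tot <- 0; tot0 <- 0
  for (combo in 0:(2^m - 1)) {
    st[ntip + seq_len(m)] <- bitwAnd(combo %/% 2^(seq_len(m) - 1), 1L)
    p <- mk2_enum_joint(tree, st, q01, q10, root_prior)
    tot <- tot + p
    if (st[node] == 0L) tot0 <- tot0 + p
  }
  tot0 / tot
}

# plain-R fixed-step RK4 for the BiSSE / GeoSSE E-D systems
sse_rhs_oracle <- function(y, pars, family) {
  if (family == "bisse") {
    la <- pars[1:2]; mu <- pars[3:4]; q <- pars[5:6]
    E <- y[1:2]; D <- y[3:4]
    c(mu[1] - (mu[1] + la[1] + q[1]) * E[1] + la[1] * E[1]^2 + q[1] * E[2],
      mu[2] - (mu[2] + la[2] + q[2]) * E[2] + la[2] * E[2]^2 + q[2] * E[1],
      -(mu[1] + la[1] + q[1]) * D[1] + q[1] * D[2] + 2 * la[1] * E[1] * D[1],
      -(mu[2] + la[2] + q[2]) * D[2] + q[2] * D[1] + 2 * la[2] * E[2] * D[2])
  } else {
    sA <- pars[1]; sB <- pars[2]; sAB <- pars[3]
    xA <- pars[4]; xB <- pars[5]; dA <- pars[6]; dB <- pars[7]
    EA <- y[1]; EB <- y[2]; EAB <- y[3]
    DA <- y[4]; DB <- y[5]; DAB <- y[6]
    c(xA - (sA + dA + xA) * EA + dA * EAB + sA * EA^2,
      xB - (sB + dB + xB) * EB + dB * EAB + sB * EB^2,
      -(sA + sB + sAB + xA + xB) * EAB + xA * EB + xB * EA +
        sA * EA * EAB + sB * EB * EAB + sAB * EA * EB,
      -(sA + dA + xA) * DA + dA * DAB + 2 * sA * EA * DA,
      -(sB + dB + xB) * DB + dB * DAB + 2 * sB * EB * DB,
      -(sA + sB + sAB + xA + xB) * DAB + xA * DB + xB * DA +
        sA * (EA * DAB + EAB * DA) + sB * (EB * DAB + EAB * DB) +
        sAB * (EA * DB + EB * DA))
  }
}

rk4_integrate <- function(y, len, pars, family, dt = 1e-4) {
  nstep <- ceiling(len / dt)
  h <- len / nstep
  for (i in seq_len(nstep)) {
    k1 <- sse_rhs_oracle(y, pars, family)
    k2 <- sse_rhs_oracle(y + h / 2 * k1, pars, family)
    k3 <- sse_rhs_oracle(y + h / 2 * k2, pars, family)
    k4 <- sse_rhs_oracle(y + h * k3, pars, family)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# full GeoSSE likelihood on a cherry via RK4, root weighted by
# observed D
rk4_geosse_cherry <- function(t_a, t_b, state_a, state_b, pars, f,
                              dt = 1e-4) {
  lev <- c("A", "B", "AB")
  tip_y <- function(st) {
    y <- c(1 - f, rep(0, 3))
    y[3 + match(st, lev)] <- f[match(st, lev)]
    y
  }
  ya <- rk4_integrate(tip_y(state_a), t_a, pars, "geosse", dt)
  yb <- rk4_integrate(tip_y(state_b), t_b, pars, "geosse", dt)
  Dl <- ya[4:6]; Dr <- yb[4:6]
  sA <- pars[1]; sB <- pars[2]; sAB <- pars[3]
  D <- c(sA * Dl[1] * Dr[1],
         sB * Dl[2] * Dr[2],
         0.5 * (sA * (Dl[1] * Dr[3] + Dl[3] * Dr[1]) +
                sB * (Dl[2] * Dr[3] + Dl[3] * Dr[2]) +
                sAB * (Dl[1] * Dr[2] + Dl[2] * Dr[1])))
  log(sum(D^2) / sum(D))
}

# deterministic tree with all speciation events squeezed near the
# root: strong early burst, so gamma should be very negative
burst_tree <- function(n = 32, depth = 20, eps = 0.01) {
  tr <- rand_ultra_tree(n, depth = 1)
  bt <- ape::branching.times(tr)
  # compress node ages into (depth - eps, depth), preserving order
  ranks <- rank(bt, ties.method = "first")
  new_age <- depth - eps * (length(ranks) - ranks) / length(ranks)
  names(new_age) <- names(bt)
  scale_node_ages(tr, new_age)
}

# rebuild edge lengths from a named vector of internal-node ages
scale_node_ages <- function(tr, new_age) {
  ntip <- ape::Ntip(tr)
  age <- c(rep(0, ntip), new_age[as.character(ntip + seq_len(tr$Nnode))])
  tr$edge.length <- age[tr$edge[, 1]] - age[tr$edge[, 2]]
  tr
}
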