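## Two-state continuous-time Markov (Mk2) model: pruning likelihood,
## ML rate estimation, and marginal ancestral-state reconstruction.
## Transition probabilities are closed-form, not matrix exponentials:
## with s = q01 + q10 and stationary frequencies pi = (q10, q01)/s,
##   P00(t) = pi0 + pi1 exp(-s t),  P01(t) = pi1 (1 - exp(-s t)), etc.
## s = 0 is the identity (limit expression, no epsilon clamping).

mk2_pmat <- function(t, q01, q10) {
  s <- q01 + q10
  if (s == 0) return(diag(2))
  p0 <- q10 / s
  p1 <- q01 / s
  e <- exp(-s * t)
  # filled column-wise: rows are source states, columns target states
  matrix(c(p0 + p1 * e, p0 * (1 - e),
           p1 * (1 - e), p1 + p0 * e), 2, 2)
}

mk2_stationary <- function(q01, q10) {
  s <- q01 + q10
  if (s == 0) c(0.5, 0.5) else c(q10, q01) / s
}

## validate and coerce tip states to a named 0/1 integer vector in
## tree tip order
mk2_tip_states <- function(tree, states) {
  if (is.data.frame(states))
    states <- setNames(states[[2]], as.character(states[[1]]))
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("missing tip state(s) for: ", paste(miss, collapse = ", "))
  st <- as.integer(as.character(states[tree$tip.label]))
  if (any(is.na(st)) || any(!st %in% 0:1))
    stop("tip states must be 0 or 1")
  setNames(st, tree$tip.label)
}

## postorder pruning pass; returns per-node normalised partial
## likelihoods (rows sum to at most 2, renormalised) and the total
## log normalisation
mk2_prune <- function(tree, st, q01, q10) {
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(0, n_all, 2)
  L[cbind(seq_len(ntip), st + 1L)] <- 1
  lq <- 0
  nch <- integer(n_all)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- mk2_pmat(tr$edge.length[e], q01, q10)
    up <- as.vector(P %*% L[ch, ])
    if (nch[par] == 0L) L[par, ] <- up else L[par, ] <- L[par, ] * up
    nch[par] <- nch[par] + 1L
    if (nch[par] > 2L)
      stop("non-binary node encountered (node ", par, ")")
    if (nch[par] == 2L) {
      sc <- sum(L[par, ])
      if (sc <= 0 || !is.finite(sc)) stop("numerical failure in pruning")
      L[par, ] <- L[par, ] / sc
      lq <- lq + log(sc)
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  list(L = L, lq = lq, root = root, tr = tr)
}

mk2_root_weights <- function(Lroot, q01, q10,
                             root = c("stationary", "equal", "obs", "given"),
                             root_p = NULL) {
  root <- match.arg(root)
  switch(root,
         stationary = mk2_stationary(q01, q10),
         equal = c(0.5, 0.5),
         obs = Lroot / sum(Lroot),
         given = {
           stopifnot(length(root_p) == 2, abs(sum(root_p) - 1) < 1e-8)
           root_p
         })
}

#' Mk2 log-likelihood
#'
#' Log-likelihood of binary tip states on a dated tree under the
#' two-state Markov model with forward rate `q01` (0 to 1) and
#' backward rate `q10` (events/Myr), computed by Felsenstein pruning.
#'
#' @param tree A binary `phylo` tree.
#' @param states Tip states: named 0/1 vector (names are tip labels)
#'   or a data frame `species,state`.
#' @param q01,q10 Non-negative transition rates (events/Myr).
#' @param root Root-state weighting: `"stationary"` (default;
#'   frequencies `(q10, q01)/(q01+q10)`), `"equal"`, `"obs"`
#'   (weights proportional to the root partial likelihoods), or
#'   `"given"` (supply `root_p`).
#' @param root_p Root-state probabilities when `root = "given"`.
#' @return The log-likelihood (finite scalar).
#' @export
mk2_loglik <- function(tree, states, q01, q10,
                       root = c("stationary", "equal", "obs", "given"),
                       root_p = NULL) {
  stopifnot(q01 >= 0, q10 >= 0, is.finite(q01), is.finite(q10))
  st <- mk2_tip_states(tree, states)
  pr <- mk2_prune(tree, st, q01, q10)
  w <- mk2_root_weights(pr$L[pr$root, ], q01, q10, root, root_p)
  log(sum(w * pr$L[pr$root, ])) + pr$lq
}

#' Fit the Mk2 model by maximum likelihood
#'
#' Maximises [mk2_loglik()] over `(q01, q10)` in log-rate space with
#' five deterministic starting points spanning 1e-4 to 1 events/Myr.
#' Boundary estimates (a rate driven to the lower bound) indicate the
#' data contain no evidence of that transition.
#'
#' @inheritParams mk2_loglik
#' @param lower,upper Internal optimisation bounds on each rate.
#' @return An object of class `mk2_fit` with elements `par`
#'   (named `q01`, `q10`), `loglik`, `k` (= 2), `AIC`, `converged`,
#'   and `root`.
#' @export
fit_mk2 <- function(tree, states,
                    root = c("stationary", "equal", "obs", "given"),
                    root_p = NULL, lower = 1e-9, upper = 100) {
  root <- match.arg(root)
  st <- mk2_tip_states(tree, states)
  nll <- function(lp) {
    ll <- tryCatch(mk2_loglik(tree, st, exp(lp[1]), exp(lp[2]),
                              root = root, root_p = root_p),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- log(10^seq(-4, 0, length.out = 5))
  best <- NULL
  for (s in starts) {
    op <- suppressWarnings(
      nlminb(c(s, s), nll, lower = log(lower), upper = log(upper),
             control = list(rel.tol = 1e-10)))
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  if (!is.finite(best$objective) || best$objective >= 1e10)
    stop("Mk2 optimisation failed from all starts; best objective = ",
         best$objective)
  par <- setNames(exp(best$par), c("q01", "q10"))
  ll <- -best$objective
  structure(list(par = par, loglik = ll, k = 2L, AIC = 2 * 2 - 2 * ll,
                 converged = best$convergence == 0, root = root,
                 n_tips = ape::Ntip(tree)),
            class = "mk2_fit")
}

#' @export
print.mk2_fit <- function(x, ...) {
  cat("Mk2 maximum-likelihood fit (", x$n_tips, " tips, root: ",
      x$root, ")\n", sep = "")
  cat(sprintf("  q01 = %.6g  q10 = %.6g  (events/Myr)\n",
              x$par["q01"], x$par["q10"]))
  cat(sprintf("  logLik = %.4f  AIC = %.4f  converged: %s\n",
              x$loglik, x$AIC, x$converged))
  invisible(x)
}

#' @export
coef.mk2_fit <- function(object, ...) object$par

#' @export
logLik.mk2_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Marginal ancestral-state probabilities under Mk2
#'
#' Combines the postorder (subtree) and preorder (rest-of-tree) passes
#' to give, for every node, the marginal probability of each state
#' given all tip data.  Rows sum to one; tips with known states get
#' probability 1 on the observed state.
#'
#' @inheritParams mk2_loglik
#' @param params An `mk2_fit` object, or a numeric vector
#'   `c(q01, q10)`.
#' @return Data frame `node` (ape node index), `age` (Myr before
#'   present), `P0`, `P1`, for all tips and internal nodes.  The crown
#'   (root) node row is flagged in the `is_root` column.
#' @export
marginal_asr <- function(tree, states, params,
                         root = c("stationary", "equal", "obs", "given"),
                         root_p = NULL) {
  root <- match.arg(root)
  if (inherits(params, "mk2_fit")) params <- params$par
  q01 <- params[[1]]; q10 <- params[[2]]
  st <- mk2_tip_states(tree, states)
  pr <- mk2_prune(tree, st, q01, q10)
  L <- pr$L; tr <- pr$tr
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  w <- mk2_root_weights(L[pr$root, ], q01, q10, root, root_p)

  ## preorder pass: G[v, ] = likelihood of data outside v's subtree
  ## as a function of v's state (times root prior), normalised
  G <- matrix(0, n_all, 2)
  G[pr$root, ] <- w
  edges <- tr$edge
  ## sibling lookup: for each edge, the parent's other child
  for (e in rev(seq_len(nrow(edges)))) {   # preorder
    par <- edges[e, 1]; ch <- edges[e, 2]
    sibs <- edges[edges[, 1] == par, 2]
    sib <- sibs[sibs != ch]
    ## message from parent down: (G[par] * prod over siblings of their
    ## upward messages), propagated through this branch
    msg <- G[par, ]
    for (s2 in sib) {
      es <- which(edges[, 2] == s2)
      Ps <- mk2_pmat(tr$edge.length[es], q01, q10)
      msg <- msg * as.vector(Ps %*% L[s2, ])
    }
    P <- mk2_pmat(tr$edge.length[e], q01, q10)
    G[ch, ] <- as.vector(t(P) %*% msg)
    sc <- sum(G[ch, ])
    if (sc <= 0 || !is.finite(sc)) stop("numerical failure in ASR pass")
    G[ch, ] <- G[ch, ] / sc
  }
  post <- G * L
  post <- post / rowSums(post)
  ages <- max(node_depths(tree)[seq_len(ntip)]) - node_depths(tree)
  data.frame(node = seq_len(n_all), age = ages,
             P0 = post[, 1], P1 = post[, 2],
             is_root = seq_len(n_all) == pr$root)
}

#' Read tip states from CSV
#'
#' @param path CSV with columns `species,state`.
#' @return Named vector of states keyed by species.
#' @export
read_tip_states <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "state") %in% names(d)))
    stop("tip-state CSV must have columns species,state")
  setNames(d$state, d$species)
}
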