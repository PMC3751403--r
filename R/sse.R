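## BiSSE and GeoSSE state-dependent diversification models.
##
## Likelihoods integrate the E/D system branch-by-branch (compiled
## adaptive Runge-Kutta, see src/sse_ode.cpp), combine daughters at
## nodes with the model's cladogenetic rule, and weight root states by
## the root D values themselves ("obs", the observed-data weighting)
## unless told otherwise.  Incomplete sampling enters through the tip
## initial conditions D_i = f_i * 1[state = i], E_i = 1 - f_i.

BISSE_PARS <- c("lambda0", "lambda1", "mu0", "mu1", "m01", "m10")
GEOSSE_PARS <- c("sA", "sB", "sAB", "xA", "xB", "dA", "dB")

sse_par_names <- function(family)
  if (family == "bisse") BISSE_PARS else GEOSSE_PARS

## validate tree + states, returning the pieces the C++ core needs
sse_prepare <- function(tree, states, family, rel_tol = 1e-4) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree))
    stop("SSE likelihoods require a fully binary tree")
  chk <- check_ultrametric(tree, rel_tol = rel_tol)
  if (!chk$ultrametric)
    stop("SSE likelihoods require an ultrametric (dated) tree")
  if (is.data.frame(states))
    states <- setNames(states[[2]], as.character(states[[1]]))
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("missing tip state(s) for: ", paste(miss, collapse = ", "))
  lev <- if (family == "bisse") c("0", "1") else c("A", "B", "AB")
  st <- as.character(states[tree$tip.label])
  if (any(!st %in% lev))
    stop("tip states must be in {", paste(lev, collapse = ", "), "}")
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, edge_length = tr$edge.length,
       ntip = ape::Ntip(tree),
       tip_state = match(st, lev) - 1L, levels = lev,
       root_age = chk$root_age)
}

sse_root_code <- function(root) match(root, c("obs", "flat", "given")) - 1L

## raw likelihood: returns -Inf on numerical failure (used in fitting)
sse_ll_raw <- function(prep, pars, family, f, root, root_p,
                       cond_surv, atol, rtol) {
  nstate <- length(prep$levels)
  if (is.null(root_p)) root_p <- rep(1 / nstate, nstate)
  res <- .sse_loglik_cpp(prep$edge, prep$edge_length, prep$ntip,
                         prep$tip_state, as.numeric(pars),
                         if (family == "bisse") 0L else 1L,
                         as.numeric(f), sse_root_code(root),
                         as.numeric(root_p), cond_surv, atol, rtol)
  if (!isTRUE(res$ok)) return(-Inf)
  structure(res$loglik, root_D = res$root_D, root_E = res$root_E)
}

check_f <- function(f, nstate) {
  if (length(f) == 1) f <- rep(f, nstate)
  stopifnot(length(f) == nstate, all(f > 0), all(f <= 1))
  f
}

#' BiSSE log-likelihood
#'
#' Likelihood of binary tip states and tree shape under the
#' binary-state speciation-extinction model with parameters
#' `(lambda0, lambda1, mu0, mu1, m01, m10)` (events/lineage/Myr),
#' corrected for incomplete sampling by per-state sampling fractions.
#'
#' @param tree Binary ultrametric `phylo` tree (branch lengths in Myr).
#' @param states Named vector of tip states in `{0, 1}`.
#' @param pars Numeric vector of the six rates, in the order
#'   `lambda0, lambda1, mu0, mu1, m01, m10` (names optional).
#' @param f Sampling fractions, one per state (scalar recycled).
#' @param root Root-state weighting: `"obs"` (default, weights
#'   proportional to the root D values), `"flat"`, or `"given"` with
#'   `root_p`.
#' @param root_p Root-state probabilities when `root = "given"`.
#' @param cond_surv Condition on survival of the two crown lineages.
#' @param atol,rtol Absolute/relative ODE tolerances.
#' @return Log-likelihood, with the root `D` and `E` vectors attached
#'   as attributes.
#' @export
bisse_loglik <- function(tree, states, pars, f = 1,
                         root = c("obs", "flat", "given"), root_p = NULL,
                         cond_surv = FALSE, atol = 1e-10, rtol = 1e-8) {
  root <- match.arg(root)
  pars <- order_pars(pars, BISSE_PARS)
  stopifnot(all(pars >= 0), all(is.finite(pars)))
  prep <- sse_prepare(tree, states, "bisse")
  f <- check_f(f, 2)
  ll <- sse_ll_raw(prep, pars, "bisse", f, root, root_p, cond_surv,
                   atol, rtol)
  if (!is.finite(ll))
    stop("ODE integration failed (non-finite likelihood)")
  ll
}

#' GeoSSE log-likelihood
#'
#' Likelihood under the geographic-state speciation-extinction model
#' with states A, B and AB (widespread) and parameters
#' `(sA, sB, sAB, xA, xB, dA, dB)`: within-region speciation `sA`/`sB`,
#' between-region speciation `sAB` (an AB lineage splits into A and B
#' daughters), extinction/region loss `xA`/`xB`, and range expansion
#' `dA` (A to AB) and `dB` (B to AB).
#'
#' @inheritParams bisse_loglik
#' @param states Named vector of tip states in `{A, B, AB}`.
#' @param pars The seven rates in the order
#'   `sA, sB, sAB, xA, xB, dA, dB`.
#' @param require_all_states If `TRUE` (default), error unless every
#'   one of the three states is occupied by at least one tip, the
#'   model's stated applicability condition.
#' @return Log-likelihood with root attributes as in [bisse_loglik()].
#' @export
geosse_loglik <- function(tree, states, pars, f = 1,
                          root = c("obs", "flat", "given"), root_p = NULL,
                          cond_surv = FALSE, require_all_states = TRUE,
                          atol = 1e-10, rtol = 1e-8) {
  root <- match.arg(root)
  pars <- order_pars(pars, GEOSSE_PARS)
  stopifnot(all(pars >= 0), all(is.finite(pars)))
  prep <- sse_prepare(tree, states, "geosse")
  if (require_all_states && length(unique(prep$tip_state)) < 3L)
    stop("GeoSSE requires that all three geographic states ",
         "(region A, region B, and both) be occupied by at least one tip")
  f <- check_f(f, 3)
  ll <- sse_ll_raw(prep, pars, "geosse", f, root, root_p, cond_surv,
                   atol, rtol)
  if (!is.finite(ll))
    stop("ODE integration failed (non-finite likelihood)")
  ll
}

order_pars <- function(pars, nm) {
  if (!is.null(names(pars)) && all(nm %in% names(pars))) pars <- pars[nm]
  stopifnot(length(pars) == length(nm))
  setNames(as.numeric(pars), nm)
}

#' Define a constrained SSE model
#'
#' A model specification names the family and a set of equality
#' constraints (groups of parameters tied to a common value); the
#' free-parameter count `k` follows from the constraints.
#'
#' @param family `"bisse"` or `"geosse"`.
#' @param name Model label (e.g. `"equal_rates"`).
#' @param constraints List of character vectors; the parameters in
#'   each vector are constrained equal.
#' @return Object of class `sse_model_spec` with elements `family`,
#'   `name`, `constraints`, `free` (names of free parameters), `k`,
#'   and `expand(free_values)` mapping free to full parameters.
#' @export
sse_model_spec <- function(family = c("bisse", "geosse"), name,
                           constraints = list()) {
  family <- match.arg(family)
  nm <- sse_par_names(family)
  group <- seq_along(nm)
  names(group) <- nm
  for (con in constraints) {
    stopifnot(all(con %in% nm), length(con) >= 2)
    group[con] <- group[con[1]]
  }
  reps <- !duplicated(group)
  free <- nm[reps]
  idx <- match(group, group[reps])   # full par i <- free par idx[i]
  expand <- function(free_values) setNames(free_values[idx], nm)
  structure(list(family = family, name = name, constraints = constraints,
                 free = free, k = length(free), expand = expand),
            class = "sse_model_spec")
}

#' @export
print.sse_model_spec <- function(x, ...) {
  cat(sprintf("%s model '%s': k = %d free parameters (%s)\n",
              toupper(x$family), x$name, x$k,
              paste(x$free, collapse = ", ")))
  invisible(x)
}

#' The four BiSSE models of the hotspot comparison
#'
#' Full (k = 6); equal-rates (speciation, extinction and both
#' migration rates tied, k = 3); equal-speciation (speciation and
#' migration tied, extinction free, k = 4); equal-extinction
#' (extinction and migration tied, speciation free, k = 4).
#'
#' @return Named list of `sse_model_spec` objects.
#' @export
bisse_models <- function() {
  list(
    full = sse_model_spec("bisse", "full"),
    equal_rates = sse_model_spec("bisse", "equal_rates",
      list(c("lambda0", "lambda1"), c("mu0", "mu1"), c("m01", "m10"))),
    equal_speciation = sse_model_spec("bisse", "equal_speciation",
      list(c("lambda0", "lambda1"), c("m01", "m10"))),
    equal_extinction = sse_model_spec("bisse", "equal_extinction",
      list(c("mu0", "mu1"), c("m01", "m10"))))
}

#' The five GeoSSE models of the within-hotspot comparison
#'
#' Full (k = 7); equal-rates (`sA = sB`, `xA = xB`, `dA = dB`, k = 4);
#' equal-speciation (`sA = sB` only, k = 6); equal-extinction
#' (`xA = xB`, k = 6); equal-migration (`dA = dB`, k = 6).  The
#' between-region speciation rate `sAB` is left free in all of them
#' (the minimal reading of the model names).
#'
#' @return Named list of `sse_model_spec` objects.
#' @export
geosse_models <- function() {
  list(
    full = sse_model_spec("geosse", "full"),
    equal_rates = sse_model_spec("geosse", "equal_rates",
      list(c("sA", "sB"), c("xA", "xB"), c("dA", "dB"))),
    equal_speciation = sse_model_spec("geosse", "equal_speciation",
      list(c("sA", "sB"))),
    equal_extinction = sse_model_spec("geosse", "equal_extinction",
      list(c("xA", "xB"))),
    equal_migration = sse_model_spec("geosse", "equal_migration",
      list(c("dA", "dB"))))
}

## deterministic multi-starts: a Yule-moment / Mk2 heuristic plus
## scaled and flat variants, all in natural-rate space
sse_starts <- function(prep, tree, states, family) {
  lam_hat <- max(log(prep$ntip / 2) / prep$root_age, 1e-3)
  if (family == "bisse") {
    m_hat <- tryCatch({
      fm <- fit_mk2(tree, states)
      pmin(pmax(mean(fm$par), 1e-4), 2)
    }, error = function(e) 0.01)
    h <- c(lambda0 = lam_hat, lambda1 = lam_hat, mu0 = lam_hat / 5,
           mu1 = lam_hat / 5, m01 = m_hat, m10 = m_hat)
  } else {
    h <- c(sA = lam_hat, sB = lam_hat, sAB = lam_hat / 2,
           xA = lam_hat / 5, xB = lam_hat / 5,
           dA = lam_hat / 10, dB = lam_hat / 10)
  }
  list(h, h * 0.2, h * 5,
       setNames(rep(0.05, length(h)), names(h)),
       setNames(rep(0.3, length(h)), names(h)))
}

#' Fit an SSE model by maximum likelihood
#'
#' Maximises the BiSSE or GeoSSE likelihood over the free parameters
#' of a model specification, in log-rate space with deterministic
#' multi-starts.  Rates are bounded internally to `[1e-8, 10]`
#' events/Myr; estimates below `1e-6` are reported as 0 (boundary
#' hits, flagged but not rejected — extinction rates on real data
#' frequently fit at zero).
#'
#' @inheritParams bisse_loglik
#' @param states Tip states matching `spec$family`.
#' @param spec An [sse_model_spec()].
#' @param starts Optional list of full-length named start vectors;
#'   default: five deterministic starts including a Yule-moment / Mk2
#'   heuristic.
#' @return Object of class `sse_fit`: `spec`, `par` (full parameter
#'   vector, boundary rates reported as 0), `par_raw`, `free_par`,
#'   `loglik`, `k`, `AIC = 2k - 2 logLik`, `converged`,
#'   `boundary` (logical vector), `n_tips`.
#' @export
fit_sse <- function(tree, states, spec, f = 1,
                    root = c("obs", "flat", "given"), root_p = NULL,
                    cond_surv = FALSE, starts = NULL,
                    atol = 1e-10, rtol = 1e-8) {
  root <- match.arg(root)
  stopifnot(inherits(spec, "sse_model_spec"))
  family <- spec$family
  prep <- sse_prepare(tree, states, family)
  if (family == "geosse" && length(unique(prep$tip_state)) < 3L)
    stop("GeoSSE requires that all three geographic states ",
         "(region A, region B, and both) be occupied by at least one tip")
  f <- check_f(f, length(prep$levels))

  nll <- function(lp) {
    ll <- sse_ll_raw(prep, spec$expand(exp(lp)), family, f, root, root_p,
                     cond_surv, atol, rtol)
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (is.null(starts)) starts <- sse_starts(prep, tree, states, family)
  lo <- log(1e-8); hi <- log(10)
  best <- NULL; any_conv <- FALSE
  for (s in starts) {
    s_free <- pmin(pmax(s[spec$free], exp(lo)), exp(hi))
    op <- suppressWarnings(
      nlminb(log(s_free), nll, lower = lo, upper = hi,
             control = list(rel.tol = 1e-10, iter.max = 500,
                            eval.max = 2000)))
    if (op$convergence == 0 && op$objective < 1e9) any_conv <- TRUE
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  if (best$objective >= 1e9)
    stop("SSE optimisation failed from all starts (model '", spec$name,
         "'); best objective = ", best$objective)
  free_par <- setNames(exp(best$par), spec$free)
  par_raw <- spec$expand(free_par)
  boundary <- par_raw < 1e-6
  par <- ifelse(boundary, 0, par_raw)
  ll <- -best$objective
  structure(list(spec = spec, par = par, par_raw = par_raw,
                 free_par = free_par, loglik = ll, k = spec$k,
                 AIC = 2 * spec$k - 2 * ll, converged = any_conv,
                 boundary = boundary, n_tips = prep$ntip,
                 f = f, root = root, cond_surv = cond_surv,
                 fingerprint = sse_fingerprint(prep)),
            class = "sse_fit")
}

sse_fingerprint <- function(prep) {
  c(ntip = prep$ntip, tlen = sum(prep$edge_length),
    states = sum(prep$tip_state * seq_along(prep$tip_state)))
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf("%s fit, model '%s' (%d tips)\n",
              toupper(x$spec$family), x$spec$name, x$n_tips))
  print(round(x$par, 6))
  cat(sprintf("  logLik = %.4f  k = %d  AIC = %.4f  converged: %s\n",
              x$loglik, x$k, x$AIC, x$converged))
  if (any(x$boundary))
    cat("  boundary (reported 0):",
        paste(names(x$par)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.sse_fit <- function(object, ...) object$par

#' @export
logLik.sse_fit <- function(object, ...)
  structure(object$loglik, df = object$k, class = "logLik")

#' Fit the four-model BiSSE ladder
#'
#' Fits full, equal-rates, equal-speciation and equal-extinction BiSSE
#' models (k = 6, 3, 4, 4) to the same data and compares them by AIC.
#'
#' @inheritParams fit_sse
#' @return Object of class `sse_ladder`: named list `fits` plus a
#'   `comparison` table from [compare_models()].
#' @export
bisse_ladder <- function(tree, states, f = 1, ...) {
  fits <- lapply(bisse_models(), function(sp)
    fit_sse(tree, states, sp, f = f, ...))
  structure(list(fits = fits, comparison = compare_models(fits)),
            class = "sse_ladder")
}

#' Fit the five-model GeoSSE ladder
#'
#' Fits full, equal-rates, equal-speciation, equal-extinction and
#' equal-migration GeoSSE models (k = 7, 4, 6, 6, 6) and compares
#' them by AIC.
#'
#' @inheritParams fit_sse
#' @return An `sse_ladder` object.
#' @export
geosse_ladder <- function(tree, states, f = 1, ...) {
  fits <- lapply(geosse_models(), function(sp)
    fit_sse(tree, states, sp, f = f, ...))
  structure(list(fits = fits, comparison = compare_models(fits)),
            class = "sse_ladder")
}

#' @export
print.sse_ladder <- function(x, ...) {
  cat("SSE model ladder\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' Tabulates `AIC = 2k - 2 logLik` and the AIC difference of each
#' model from the minimum-AIC model, flagging differences above the
#' conventional "substantial" threshold of 2.  All fits must come from
#' the same data.
#'
#' @param fits List of `sse_fit` objects (>= 1).
#' @param threshold Delta-AIC flagged as substantial (default 2).
#' @return Data frame `model, k, loglik, AIC, dAIC, substantial`.
#' @export
compare_models <- function(fits, threshold = 2) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "sse_fit")))
  fp <- vapply(fits, function(f) f$fingerprint, numeric(3))
  if (length(fits) > 1 &&
      any(apply(fp, 1, function(v) max(v) - min(v)) > 1e-6))
    stop("fits come from different data; cannot compare AICs")
  aic <- vapply(fits, function(f) f$AIC, 0)
  out <- data.frame(
    model = vapply(fits, function(f) f$spec$name, ""),
    k = as.integer(vapply(fits, function(f) as.numeric(f$k), 0)),
    loglik = vapply(fits, function(f) f$loglik, 0),
    AIC = aic, dAIC = aic - min(aic))
  out$substantial <- out$dAIC > threshold
  rownames(out) <- NULL
  out
}
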