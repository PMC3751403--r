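## Replication of any analysis over a posterior sample of dated trees,
## with deterministic per-tree seeding and aggregation into medians,
## percentile intervals and model-preference proportions.

## per-analysis adapters: tree -> list(quantities = named numeric,
##                                     aic = named numeric or NULL,
##                                     k = named integer or NULL)
replication_adapters <- function() {
  list(
    gamma = function(tree, opts) {
      g <- gamma_stat(tree, tail = opts$tail %||% "two.sided")
      list(quantities = c(gamma = g$gamma, p_value = g$p_value,
                          significant = as.numeric(g$p_value < 0.05)))
    },
    ltt = function(tree, opts) {
      cv <- ltt_curve(tree)
      t_rel <- max(cv$age) - cv$age
      sl <- unname(coef(lm(log(cv$n_lineages) ~ t_rel))[2])
      list(quantities = c(root_age = max(cv$age),
                          n_tips = max(cv$n_lineages),
                          log_ltt_slope = sl))
    },
    age_richness = function(tree, opts) {
      cl <- clades_at_depth(tree, k = opts$depth_k %||% 6)
      fit <- age_richness_regression(cl)
      list(quantities = c(slope = fit$slope, intercept = fit$intercept,
                          r = fit$r, n_clades = fit$n))
    },
    mk2_asr = function(tree, opts) {
      fit <- fit_mk2(tree, opts$states, root = opts$mk2_root %||%
                       "stationary")
      asr <- marginal_asr(tree, opts$states, fit,
                          root = opts$mk2_root %||% "stationary")
      crown <- asr[asr$is_root, ]
      list(quantities = c(q01 = unname(fit$par["q01"]),
                          q10 = unname(fit$par["q10"]),
                          loglik = fit$loglik,
                          crown_P0 = crown$P0, crown_P1 = crown$P1))
    },
    bisse_ladder = function(tree, opts) {
      lad <- bisse_ladder(tree, opts$states, f = opts$f %||% 1)
      full <- lad$fits$full$par
      raw <- lad$fits$full$par_raw   # bounded away from 0
      list(quantities = c(full,
             net_div0 = unname(full["lambda0"] - full["mu0"]),
             net_div1 = unname(full["lambda1"] - full["mu1"]),
             lambda_ratio = unname(raw["lambda1"] / raw["lambda0"])),
           aic = vapply(lad$fits, function(x) x$AIC, 0),
           k = vapply(lad$fits, function(x) x$k, 0L))
    },
    geosse_ladder = function(tree, opts) {
      lad <- geosse_ladder(tree, opts$states, f = opts$f %||% 1)
      full <- lad$fits$full$par
      list(quantities = c(full,
             net_divA = unname(full["sA"] - full["xA"]),
             net_divB = unname(full["sB"] - full["xB"])),
           aic = vapply(lad$fits, function(x) x$AIC, 0),
           k = vapply(lad$fits, function(x) x$k, 0L))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replicate an analysis over a posterior sample of trees
#'
#' Runs one named analysis independently on every tree of a posterior
#' sample, with per-tree random seeds derived deterministically from
#' the master seed (so the whole replication is reproducible
#' bit-for-bit).  Per-tree failures are recorded, not fatal, unless
#' they exceed half the sample.
#'
#' If `species_map` is given, each tree is first pruned to one
#' randomly chosen tip per species (a fresh draw per tree, as when
#' posterior trees carry multiple subspecies).
#'
#' @param trees A `multiPhylo` posterior sample.
#' @param analysis One of `"gamma"`, `"ltt"`, `"age_richness"`,
#'   `"mk2_asr"`, `"bisse_ladder"`, `"geosse_ladder"`.
#' @param states Tip states keyed by species (required for `mk2_asr`
#'   and the ladders).
#' @param f Sampling fractions for the ladders.
#' @param species_map Optional tip-label to species map for per-tree
#'   pruning.
#' @param seed Master seed (integer).
#' @param ... Further analysis options (`depth_k`, `tail`,
#'   `mk2_root`).
#' @return Object of class `replication_result`: `analysis`,
#'   `n_trees`, `quantities` (trees x quantity matrix), `aic`
#'   (trees x model matrix or `NULL`), `model_k`, `failed` (logical),
#'   `errors` (messages for failed trees), `seed`.
#' @export
replicate_analysis <- function(trees, analysis, states = NULL, f = 1,
                               species_map = NULL, seed = 1, ...) {
  trees <- as_posterior(trees)
  adapters <- replication_adapters()
  if (!analysis %in% names(adapters))
    stop("unknown analysis '", analysis, "'; available: ",
         paste(names(adapters), collapse = ", "))
  opts <- c(list(states = states, f = f), list(...))
  run <- adapters[[analysis]]
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, length(trees))
  recs <- vector("list", length(trees))
  errors <- rep(NA_character_, length(trees))
  for (i in seq_along(trees)) {
    set.seed(tree_seeds[i])
    recs[[i]] <- tryCatch({
      tr <- trees[[i]]
      if (!is.null(species_map))
        tr <- prune_to_species(tr, species_map)
      run(tr, opts)
    }, error = function(e) {
      errors[i] <<- conditionMessage(e)
      NULL
    })
  }
  failed <- vapply(recs, is.null, TRUE)
  if (mean(failed) > 0.5)
    stop("analysis failed on ", sum(failed), " of ", length(trees),
         " trees (> 50%); first error: ", errors[which(failed)[1]])
  ok <- which(!failed)
  qnames <- names(recs[[ok[1]]]$quantities)
  qm <- matrix(NA_real_, length(trees), length(qnames),
               dimnames = list(NULL, qnames))
  for (i in ok) qm[i, ] <- recs[[i]]$quantities
  aic <- NULL; model_k <- NULL
  if (!is.null(recs[[ok[1]]]$aic)) {
    mnames <- names(recs[[ok[1]]]$aic)
    aic <- matrix(NA_real_, length(trees), length(mnames),
                  dimnames = list(NULL, mnames))
    for (i in ok) aic[i, ] <- recs[[i]]$aic
    model_k <- recs[[ok[1]]]$k
  }
  structure(list(analysis = analysis, n_trees = length(trees),
                 quantities = qm, aic = aic, model_k = model_k,
                 failed = failed, errors = errors, seed = seed),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("replication of '%s' over %d trees (%d failed)\n",
              x$analysis, x$n_trees, sum(x$failed)))
  for (q in colnames(x$quantities)) {
    a <- aggregate_replication(x, q)
    cat(sprintf("  %-12s median %.4g  [%.4g, %.4g]\n",
                q, a$median, a$lower, a$upper))
  }
  invisible(x)
}

#' Aggregate a replicated quantity
#'
#' Median and central 95% percentile interval (2.5-97.5%, not a true
#' HPD) of one quantity over the successfully analysed trees.
#'
#' @param result A `replication_result`.
#' @param quantity Quantity name (a column of `result$quantities`).
#' @return List `quantity, median, lower, upper, n` (trees used).
#' @export
aggregate_replication <- function(result, quantity) {
  stopifnot(inherits(result, "replication_result"))
  if (!quantity %in% colnames(result$quantities))
    stop("unknown quantity '", quantity, "'; available: ",
         paste(colnames(result$quantities), collapse = ", "))
  v <- result$quantities[!result$failed, quantity]
  list(quantity = quantity, median = median(v),
       lower = unname(quantile(v, 0.025)),
       upper = unname(quantile(v, 0.975)), n = length(v))
}

#' Model-preference proportions across trees
#'
#' For a replicated model ladder: the fraction of trees in which each
#' model attains the minimum AIC (ties within 1e-9 broken towards the
#' model with fewer parameters), and the fraction in which each
#' model's AIC differs from a reference model's by more than a
#' threshold.
#'
#' @param result A `replication_result` from a ladder analysis.
#' @param reference Reference model name (e.g. `"equal_rates"`).
#' @param threshold Delta-AIC threshold (default 2).
#' @return List `best` (named proportions summing to 1), `exceeds`
#'   (fraction of trees with `|AIC - AIC_ref| > threshold` per model),
#'   `better_than_ref` (fraction with `AIC < AIC_ref`), `n_ties`
#'   (trees where the tie-break was used).
#' @export
preference_proportions <- function(result, reference, threshold = 2) {
  stopifnot(inherits(result, "replication_result"))
  if (is.null(result$aic))
    stop("result carries no model ladder AICs")
  models <- colnames(result$aic)
  if (!reference %in% models)
    stop("reference '", reference, "' not among models: ",
         paste(models, collapse = ", "))
  aic <- result$aic[!result$failed, , drop = FALSE]
  k <- result$model_k
  n_ties <- 0L
  best <- apply(aic, 1, function(a) {
    cand <- which(a - min(a) < 1e-9)
    if (length(cand) > 1) {
      n_ties <<- n_ties + 1L
      cand <- cand[order(k[cand])]
    }
    models[cand[1]]
  })
  best_prop <- vapply(models, function(m) mean(best == m), 0)
  d <- sweep(aic, 1, aic[, reference])
  list(best = best_prop,
       exceeds = colMeans(abs(d) > threshold),
       better_than_ref = colMeans(aic < aic[, reference] - 1e-9),
       n_ties = n_ties)
}
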