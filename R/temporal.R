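## Lineage-through-time curves, the Pybus-Harvey gamma statistic, and
## clade crown-age vs species-richness regressions.

#' Lineage-through-time curve
#'
#' Node ages of an ultrametric binary tree sorted from the root
#' towards the present; after the k-th oldest internal node the tree
#' has k + 1 lineages, so the curve runs from (root age, 2) to the
#' youngest node.
#'
#' @param tree Ultrametric binary `phylo` tree.
#' @param rel_tol Ultrametricity tolerance passed to
#'   [check_ultrametric()].
#' @return Data frame `age` (Myr before present, descending) and
#'   `n_lineages` (2 ... n).
#' @export
ltt_curve <- function(tree, rel_tol = 1e-4) {
  chk <- check_ultrametric(tree, rel_tol)
  if (!chk$ultrametric)
    stop("LTT requires an ultrametric tree")
  if (!ape::is.binary(tree)) stop("LTT requires a binary tree")
  bt <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  data.frame(age = bt, n_lineages = seq(2, length(bt) + 1))
}

#' Pybus-Harvey gamma statistic
#'
#' Summarises the temporal spread of internode intervals: gamma near 0
#' is consistent with constant-rate diversification (the statistic is
#' asymptotically standard normal under a pure-birth model), negative
#' values indicate nodes concentrated towards the root, i.e. a
#' diversification slowdown.
#'
#' With internode intervals `g_j` (time during which j lineages
#' exist, j = 2..n) and `T_k = sum_{j=2}^{k} j g_j`:
#' `gamma = (mean_{k=2}^{n-1} T_k - T_n / 2) / (T_n sqrt(1 / (12 (n - 2))))`.
#'
#' @param tree Ultrametric binary `phylo` tree with at least 3 tips.
#' @param tail `"two.sided"` (default) or `"less"` (one-tailed test
#'   for slowdown) for the normal-approximation p-value.
#' @param rel_tol Ultrametricity tolerance.
#' @return List of class `gamma_result`: `gamma`, `p_value`, `n_tips`.
#' @export
gamma_stat <- function(tree, tail = c("two.sided", "less"),
                       rel_tol = 1e-4) {
  tail <- match.arg(tail)
  n <- ape::Ntip(tree)
  if (n < 3) stop("gamma requires at least 3 tips")
  curve <- ltt_curve(tree, rel_tol)
  ages <- c(curve$age, 0)
  g <- -diff(ages)                      # g_2 ... g_n
  j <- seq(2, n)
  Tk <- cumsum(j * g)                   # T_2 ... T_n
  Tn <- Tk[n - 1]
  gam <- (mean(Tk[seq_len(n - 2)]) - Tn / 2) /
    (Tn * sqrt(1 / (12 * (n - 2))))
  p <- if (tail == "two.sided") 2 * pnorm(-abs(gam)) else pnorm(gam)
  structure(list(gamma = gam, p_value = p, n_tips = n, tail = tail),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma = %.4f (n = %d tips), %s p = %.4g\n",
              x$gamma, x$n_tips, x$tail, x$p_value))
  invisible(x)
}

#' Independent clades k nodes down from the root
#'
#' Identifies the set of disjoint clades whose root node is exactly
#' `k` parent-to-child steps from the tree root; tips reached in fewer
#' steps are kept as singleton clades, so the clades always partition
#' the tip set.
#'
#' @param tree Binary `phylo` tree.
#' @param k Number of steps down from the root (default 6).
#' @return Data frame `node` (ape node index), `richness` (tip count),
#'   `crown_age` (Myr; `NA` for singleton clades), with the tip-label
#'   partition attached as attribute `"tips"`.
#' @export
clades_at_depth <- function(tree, k = 6) {
  if (k < 1) stop("k must be >= 1")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  edepth <- integer(ntip + tree$Nnode)        # steps from root
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(tr$edge))))      # preorder
    edepth[tr$edge[e, 2]] <- edepth[tr$edge[e, 1]] + 1L
  nodes <- c(which(edepth == k),
             intersect(which(edepth < k), seq_len(ntip)))
  if (k == 0 || length(nodes) == 0) nodes <- root
  depth <- node_depths(tree)
  root_age <- max(depth[seq_len(ntip)])
  tips <- lapply(nodes, function(v) {
    if (v <= ntip) tree$tip.label[v]
    else ape::extract.clade(tree, v)$tip.label
  })
  out <- data.frame(
    node = nodes,
    richness = lengths(tips),
    crown_age = ifelse(nodes <= ntip, NA_real_, root_age - depth[nodes]))
  attr(out, "tips") <- tips
  out
}

#' Crown age vs species richness regression
#'
#' Ordinary least squares of clade crown age on log species richness
#' (the constant-rates expectation is a positive slope: older clades
#' have had longer to accumulate species).  Singleton clades have no
#' crown age and are excluded.
#'
#' @param points Data frame with columns `crown_age` and `richness`
#'   (e.g. from [clades_at_depth()]).
#' @param log_richness Regress on `log(richness)` (default) or raw
#'   richness.
#' @return List of class `age_richness_fit`: `slope`, `intercept`,
#'   `r` (Pearson correlation), `n` (clades used).
#' @export
age_richness_regression <- function(points, log_richness = TRUE) {
  pts <- points[!is.na(points$crown_age) & points$richness >= 2, ,
                drop = FALSE]
  if (nrow(pts) < 3)
    stop("need at least 3 clades with crown ages (have ", nrow(pts), ")")
  x <- if (log_richness) log(pts$richness) else pts$richness
  if (max(x) - min(x) < 1e-12)
    stop("zero variance in richness predictor")
  fit <- lm(pts$crown_age ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(x, pts$crown_age), n = nrow(pts),
                 log_richness = log_richness),
            class = "age_richness_fit")
}

#' @export
print.age_richness_fit <- function(x, ...) {
  cat(sprintf(
    "crown age ~ %s: slope = %.4f, intercept = %.4f, r = %.4f (n = %d)\n",
    if (x$log_richness) "log(richness)" else "richness",
    x$slope, x$intercept, x$r, x$n))
  invisible(x)
}
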