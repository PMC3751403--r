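## Forward (Gillespie) simulation of trees under constant-rate and
## state-dependent birth-death processes, binomial incomplete
## sampling, and clustered occurrence records in toy zone polygons.
## Continuous time, exact exponential waiting times; no
## discretisation.  Identical seed + configuration gives bit-identical
## output, and conditioning on survival is by bounded retry with the
## retry count reported.

## per-state event tables: each row (rate, event); events are
## "sp" (speciation), "ex" (extinction), "tr" (state change)
sim_rates <- function(model, pars) {
  switch(model,
    yule = list("0" = list(sp = unname(pars["lambda"]), ex = 0,
                           tr = c())),
    bisse = list(
      "0" = list(sp = unname(pars["lambda0"]), ex = unname(pars["mu0"]),
                 tr = c("1" = unname(pars["m01"]))),
      "1" = list(sp = unname(pars["lambda1"]), ex = unname(pars["mu1"]),
                 tr = c("0" = unname(pars["m10"])))),
    geosse = list(
      ## A and B: within-region speciation, extinction, expansion to AB
      A = list(sp = unname(pars["sA"]), ex = unname(pars["xA"]),
               tr = c(AB = unname(pars["dA"]))),
      B = list(sp = unname(pars["sB"]), ex = unname(pars["xB"]),
               tr = c(AB = unname(pars["dB"]))),
      ## AB: three speciation modes, no extinction in one event,
      ## region loss to B (rate xA) or A (rate xB)
      AB = list(sp = unname(pars["sA"] + pars["sB"] + pars["sAB"]),
                ex = 0,
                tr = c(B = unname(pars["xA"]), A = unname(pars["xB"])))))
}

## daughter states at a speciation event
sim_daughters <- function(model, pars, state) {
  if (model != "geosse" || state != "AB") return(c(state, state))
  w <- c(A = unname(pars["sA"]), B = unname(pars["sB"]),
         AB = unname(pars["sAB"]))
  mode <- sample(names(w), 1, prob = w)
  switch(mode, A = c("AB", "A"), B = c("AB", "B"), AB = c("A", "B"))
}

sim_root_state <- function(model, pars) {
  if (model == "yule") return("0")
  if (model == "bisse") {
    s <- pars["m01"] + pars["m10"]
    p0 <- if (s == 0) 0.5 else unname(pars["m10"] / s)
    return(sample(c("0", "1"), 1, prob = c(p0, 1 - p0)))
  }
  ## geosse: stationary distribution of the anagenetic chain
  ## A -> AB (dA), B -> AB (dB), AB -> B (xA), AB -> A (xB)
  Q <- rbind(c(-pars["dA"], 0, pars["dA"]),
             c(0, -pars["dB"], pars["dB"]),
             c(pars["xB"], pars["xA"], -(pars["xA"] + pars["xB"])))
  A <- rbind(t(Q), rep(1, 3))
  pi <- tryCatch(qr.solve(A, c(0, 0, 0, 1)), error = function(e)
    rep(1 / 3, 3))
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  sample(c("A", "B", "AB"), 1, prob = pi)
}

#' Simulate a dated tree under a (state-dependent) birth-death process
#'
#' Exact continuous-time (Gillespie) forward simulation from a crown
#' of two lineages.  Supported models: `"yule"` (pure birth, parameter
#' `lambda`), `"bisse"` (six rates) and `"geosse"` (seven rates; AB
#' lineages speciate within-region at `sA`/`sB` leaving daughters
#' AB + A / AB + B, or between-region at `sAB` splitting into A + B,
#' lose regions at `xA`/`xB`, and single-region lineages expand at
#' `dA`/`dB`).  Extinct lineages are pruned, so the returned tree is
#' ultrametric.  If the clade dies before the stopping rule is met the
#' simulation retries (up to `max_retries`, then errors); the retry
#' count is reported so survivorship bias can be bounded.
#'
#' @param model `"yule"`, `"bisse"` or `"geosse"`.
#' @param pars Named rate vector for the model (events/lineage/Myr).
#' @param n_tips Stop when this many lineages are extant (the final
#'   interval is completed with a fresh exponential draw, so internode
#'   intervals follow the process exactly).
#' @param max_time Alternative stopping rule: crown age in Myr.
#' @param root_state Crown state; default drawn from the stationary
#'   distribution of the transition rates.
#' @param seed Integer seed.
#' @param max_retries Retry bound for survival conditioning.
#' @return List with `tree` (ultrametric `phylo`), `states` (named
#'   character vector for extant tips), and `truth` (model, pars,
#'   root_state, retries, crown age).
#' @export
simulate_tree <- function(model = c("yule", "bisse", "geosse"), pars,
                          n_tips = NULL, max_time = NULL,
                          root_state = NULL, seed = NULL,
                          max_retries = 1000) {
  model <- match.arg(model)
  need <- switch(model, yule = "lambda", bisse = BISSE_PARS,
                 geosse = GEOSSE_PARS)
  pars <- order_pars(pars, need)
  stopifnot(all(pars >= 0))
  if (is.null(n_tips) && is.null(max_time))
    stop("one of n_tips or max_time must be given")
  if (!is.null(n_tips) && n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  rates <- sim_rates(model, pars)
  for (attempt in seq_len(max_retries)) {
    rs <- root_state %||% sim_root_state(model, pars)
    out <- sim_once(model, pars, rates, rs, n_tips, max_time)
    if (!is.null(out)) {
      out$truth <- list(model = model, pars = pars, root_state = rs,
                        retries = attempt - 1L,
                        crown_age = out$crown_age)
      out$crown_age <- NULL
      return(out)
    }
  }
  stop("clade went extinct before meeting the stopping rule in all ",
       max_retries, " attempts")
}

## one forward pass; NULL if the clade dies (or cannot reach n_tips)
sim_once <- function(model, pars, rates, root_state, n_tips, max_time) {
  parent <- c(0L, 0L)           # lineage's parent lineage (0 = crown)
  state <- c(root_state, root_state)
  t_birth <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  died <- c(FALSE, FALSE)
  alive <- c(1L, 2L)
  t <- 0
  tot <- vapply(rates, function(r) r$sp + r$ex + sum(r$tr), 0)
  for (step in seq_len(1000000L)) {
    lr <- tot[state[alive]]
    R <- sum(lr)
    stop_now <- FALSE
    if (!is.null(n_tips) && length(alive) == n_tips) {
      ## final internode interval: exponential with the current total
      ## rate (or, if nothing can happen again, stop immediately)
      t <- t + if (R > 0) rexp(1, R) else 0
      stop_now <- TRUE
    } else if (R == 0) {
      if (is.null(max_time)) return(NULL)  # frozen short of n_tips
      t <- max_time
      stop_now <- TRUE
    } else {
      dt <- rexp(1, R)
      if (!is.null(max_time) && t + dt > max_time) {
        t <- max_time
        stop_now <- TRUE
      } else t <- t + dt
    }
    if (stop_now) {
      t_end[alive] <- t
      break
    }
    i <- alive[sample.int(length(alive), 1, prob = lr)]
    r <- rates[[state[i]]]
    ev <- sample(c("sp", "ex", names(r$tr)), 1,
                 prob = c(r$sp, r$ex, r$tr))
    if (ev == "sp") {
      dg <- sim_daughters(model, pars, state[i])
      t_end[i] <- t
      parent <- c(parent, i, i)
      state <- c(state, dg)
      t_birth <- c(t_birth, t, t)
      t_end <- c(t_end, NA_real_, NA_real_)
      died <- c(died, FALSE, FALSE)
      alive <- c(setdiff(alive, i), length(state) - 1L, length(state))
    } else if (ev == "ex") {
      t_end[i] <- t
      died[i] <- TRUE
      alive <- setdiff(alive, i)
      if (length(alive) == 0L) return(NULL)
    } else {
      state[i] <- ev
    }
  }
  build_sim_tree(parent, state, t_birth, t_end, died, t)
}

## assemble an ape phylo from lineage records; prune extinct tips
build_sim_tree <- function(parent, state, t_birth, t_end, died,
                           crown_age) {
  m <- length(parent)
  has_child <- seq_len(m) %in% parent
  tip_lin <- which(!has_child)
  int_lin <- which(has_child)
  ntip <- length(tip_lin)
  node_id <- integer(m)
  node_id[tip_lin] <- seq_len(ntip)
  node_id[int_lin] <- ntip + 1L + seq_along(int_lin)  # root = ntip + 1
  edge_parent <- ifelse(parent == 0L, ntip + 1L,
                        node_id[pmax(parent, 1L)])
  tree <- list(edge = cbind(edge_parent, node_id),
               edge.length = t_end - t_birth,
               tip.label = paste0("t", seq_len(ntip)),
               Nnode = length(int_lin) + 1L)
  class(tree) <- "phylo"
  storage.mode(tree$edge) <- "integer"
  tree <- ape::reorder.phylo(tree, "cladewise")
  extinct <- tree$tip.label[node_id[tip_lin][died[tip_lin]] ]
  ## states keyed by tip label
  st <- setNames(state[tip_lin], tree$tip.label[node_id[tip_lin]])
  if (length(extinct)) {
    if (ntip - length(extinct) < 2) return(NULL)
    tree <- ape::drop.tip(tree, extinct)
    st <- st[tree$tip.label]
  }
  list(tree = tree, states = st, crown_age = crown_age)
}

#' Thin tips by per-state sampling fractions
#'
#' Retains each tip independently with the sampling probability of its
#' state and prunes the rest, emulating incomplete taxon sampling; the
#' tree stays ultrametric.
#'
#' @param tree A `phylo` tree.
#' @param states Named tip states.
#' @param f Named vector of retention probabilities in (0, 1] keyed by
#'   state (scalar recycled over states).
#' @param seed Integer seed.
#' @return List `tree`, `states` (survivors), `retained` (per-state
#'   kept counts), `dropped` (per-state dropped counts).
#' @export
apply_sampling <- function(tree, states, f, seed = NULL) {
  states <- states[tree$tip.label]
  lev <- unique(states)
  if (length(f) == 1 && is.null(names(f)))
    f <- setNames(rep(f, length(lev)), lev)
  stopifnot(all(lev %in% names(f)), all(f > 0), all(f <= 1))
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(length(states)) <= f[states]
  if (sum(keep) < 3)
    stop("fewer than 3 tips survive sampling (", sum(keep), ")")
  dropped <- tree$tip.label[!keep]
  out <- if (length(dropped)) ape::drop.tip(tree, dropped) else tree
  st <- states[out$tip.label]
  count_by <- function(x) {
    tb <- table(factor(x, levels = names(f)))
    setNames(as.integer(tb), names(f))
  }
  list(tree = out, states = st, retained = count_by(st),
       dropped = count_by(states[!keep]))
}

## uniform point in a polygon ring by rejection from the bounding box
runif_in_polygon <- function(n, ring) {
  ring <- close_ring(ring)
  area <- abs(sum(ring[-nrow(ring), 1] * ring[-1, 2] -
                  ring[-1, 1] * ring[-nrow(ring), 2])) / 2
  if (area <= 0) stop("polygon has zero area")
  lon <- numeric(n); lat <- numeric(n); got <- 0L
  for (iter in seq_len(10000L)) {
    m <- max(2L * (n - got), 10L)
    px <- runif(m, min(ring[, 1]), max(ring[, 1]))
    py <- runif(m, min(ring[, 2]), max(ring[, 2]))
    ok <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0
    take <- min(sum(ok), n - got)
    if (take > 0) {
      lon[got + seq_len(take)] <- px[ok][seq_len(take)]
      lat[got + seq_len(take)] <- py[ok][seq_len(take)]
      got <- got + take
    }
    if (got == n) return(cbind(lon = lon, lat = lat))
  }
  stop("rejection sampling failed to fill the polygon")
}

#' Simulate occurrence records inside toy zone polygons
#'
#' For each species, draws `n_per_species` points: with probability
#' `purity` uniformly inside its home-zone polygon, otherwise
#' uniformly inside one of the other zones.  Lower purity makes the
#' >90% zone-assignment rule harder, so the rule can be exercised at
#' controlled difficulty.
#'
#' @param assignments Named character vector, species -> home zone
#'   (a zone name of `map`).
#' @param map A `region_map`.
#' @param n_per_species Records per species (default 100).
#' @param purity Probability a record falls in the home zone
#'   (in \[0.5, 1\]).
#' @param seed Integer seed.
#' @return Occurrence data frame `species, lon, lat, zone_true`.
#' @export
simulate_occurrences <- function(assignments, map, n_per_species = 100,
                                 purity = 0.95, seed = NULL) {
  stopifnot(inherits(map, "region_map"), purity >= 0.5, purity <= 1,
            all(assignments %in% names(map$zones)))
  if (!is.null(seed)) set.seed(seed)
  zn <- names(map$zones)
  out <- lapply(names(assignments), function(sp) {
    home <- assignments[[sp]]
    zones <- ifelse(runif(n_per_species) <= purity, home,
                    sample(rep(setdiff(zn, home), 2), n_per_species,
                           replace = TRUE))
    pts <- do.call(rbind, lapply(seq_len(n_per_species), function(i)
      runif_in_polygon(1, map$zones[[zones[i]]][[1]])))
    data.frame(species = sp, lon = pts[, "lon"], lat = pts[, "lat"],
               zone_true = zones)
  })
  do.call(rbind, out)
}

#' Toy two-zone region map
#'
#' Two adjacent rectangles standing in for the high-rainfall zone
#' (HRZ) and the pooled transitional-rainfall zone / south-coast
#' province (TRZ_SCP) of a Mediterranean-climate hotspot; their union
#' is the hotspot super-region.  Coordinates are in the southwest of
#' Australia but the geometry is deliberately schematic.
#'
#' @return A `region_map` with zones `HRZ` and `TRZ_SCP`.
#' @export
toy_region_map <- function() {
  region_map(list(
    HRZ = cbind(c(114.5, 117.5, 117.5, 114.5),
                c(-35.5, -35.5, -33.0, -33.0)),
    TRZ_SCP = cbind(c(117.5, 121.0, 121.0, 117.5),
                    c(-35.5, -35.5, -33.0, -33.0))))
}

#' Species counts by geographic state in the hotspot study design
#'
#' Numbers of extant species present in / absent from the phylogeny
#' for each geographic state in the *Banksia* study design: 158
#' species in the tree, a strongly asymmetric binary state (15
#' non-hotspot vs 143 hotspot species), and the three-state
#' within-hotspot split.  These counts define the per-state sampling
#' fractions and the synthetic study conditions.
#'
#' @return Data frame `state, present, absent`.
#' @export
banksia_region_counts <- function() {
  data.frame(
    state = c("nonSWBP", "SWBP", "HRZ", "TRZ_SCP", "both"),
    present = c(15L, 143L, 11L, 78L, 54L),
    absent = c(1L, 12L, 0L, 9L, 3L))
}
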