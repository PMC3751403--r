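# BiSSE / GeoSSE likelihood checks against closed forms, the
# birth-death x Mk2 factorization, a fixed-step RK4 oracle, and the
# model-ladder mechanics.

test_that("BiSSE reduces to closed forms on a cherry", {
  cherry <- ape::read.tree(text = "(A:2,B:2);")
  st <- c(A = 0, B = 0)
  # mu = m = 0, f = 1: E stays 0 and D decays exponentially;
  # L = lambda0 * exp(-2 lambda0 t)
  la <- 0.13
  ll <- bisse_loglik(cherry, st, c(la, 0.3, 0, 0, 0, 0))
  expect_equal(as.numeric(ll), log(la) - 2 * la * 2, tolerance = 1e-8)
  # pure-birth with sampling fraction f: analytic skeletal correction
  # log L = 2 log f + log la + 2 [la T - 2 log(1 + f (e^{la T} - 1))]
  f <- 0.5; T_ <- 2
  ll_f <- bisse_loglik(cherry, st, c(la, la, 0, 0, 0, 0), f = f)
  expect_equal(as.numeric(ll_f),
               2 * log(f) + log(la) +
                 2 * (la * T_ - 2 * log(1 + f * (exp(la * T_) - 1))),
               tolerance = 1e-6)
})

test_that("closed-form birth-death likelihood matches the ODE route", {
  set.seed(5)
  for (rep in 1:5) {
    tr <- rand_ultra_tree(12, depth = 30)
    st <- setNames(rep(0, 12), tr$tip.label)
    la <- runif(1, 0.05, 0.3); mu <- runif(1, 0, 0.9) * la
    f <- sample(c(1, 0.6), 1)
    # no transitions, all tips state 0: state 1 never enters
    ll_ode <- bisse_loglik(tr, st, c(la, la, mu, mu, 0, 0), f = f)
    expect_equal(as.numeric(ll_ode), bd_loglik(tr, la, mu, f = f),
                 tolerance = 1e-6)
  }
  # supercritical extinction (mu > la) is allowed and still matches
  tr <- rand_ultra_tree(8, depth = 10)
  st <- setNames(rep(0, 8), tr$tip.label)
  ll_ode <- bisse_loglik(tr, st, c(0.1, 0.1, 0.15, 0.15, 0, 0))
  expect_equal(as.numeric(ll_ode), bd_loglik(tr, 0.1, 0.15),
               tolerance = 1e-6)
})

test_that("state-independent BiSSE factorises into BD x Mk2", {
  set.seed(8)
  for (rep in 1:20) {
    tr <- rand_ultra_tree(10, depth = runif(1, 10, 40))
    st <- setNames(sample(0:1, 10, replace = TRUE), tr$tip.label)
    la <- runif(1, 0.05, 0.25)
    mu <- runif(1, 0, 0.8) * la
    q <- 10^runif(1, -2, -0.5)
    ll_bisse <- bisse_loglik(tr, st, c(la, la, mu, mu, q, q),
                             root = "obs")
    ll_fact <- bd_loglik(tr, la, mu) +
      mk2_loglik(tr, st, q, q, root = "obs")
    expect_equal(as.numeric(ll_bisse), ll_fact, tolerance = 1e-6)
  }
})

test_that("likelihood is insensitive to solver tolerances and tip order", {
  set.seed(13)
  tr <- rand_ultra_tree(15, depth = 40)
  st <- setNames(sample(0:1, 15, replace = TRUE), tr$tip.label)
  p <- c(0.1, 0.2, 0.03, 0.01, 0.02, 0.05)
  ll1 <- bisse_loglik(tr, st, p)
  ll2 <- bisse_loglik(tr, st, p, atol = 1e-12, rtol = 1e-10)
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-7)
  # rotating internal nodes permutes the traversal but not the value
  tr_rot <- ape::rotate(tr, 18)
  tr_rot <- ape::rotate(tr_rot, 22)
  expect_equal(as.numeric(bisse_loglik(tr_rot, st, p)),
               as.numeric(ll1), tolerance = 1e-9)
})

test_that("GeoSSE obeys label-swap symmetry and matches an RK4 oracle", {
  gp <- c(sA = 0.15, sB = 0.08, sAB = 0.04, xA = 0.02, xB = 0.05,
          dA = 0.03, dB = 0.01)
  sim <- simulate_tree("geosse", gp, n_tips = 40, seed = 19)
  ll <- geosse_loglik(sim$tree, sim$states, gp)
  # swap A <-> B in both data and parameters
  swapped_pars <- c(sA = unname(gp["sB"]), sB = unname(gp["sA"]),
                    sAB = unname(gp["sAB"]), xA = unname(gp["xB"]),
                    xB = unname(gp["xA"]), dA = unname(gp["dB"]),
                    dB = unname(gp["dA"]))
  swapped_states <- c(A = "B", B = "A", AB = "AB")[sim$states]
  names(swapped_states) <- names(sim$states)
  ll_swap <- geosse_loglik(sim$tree, swapped_states, swapped_pars)
  expect_equal(as.numeric(ll), as.numeric(ll_swap), tolerance = 1e-9)

  # brute-force fixed-step RK4 on a cherry reproduces the adaptive
  # solver's likelihood
  cherry <- ape::read.tree(text = "(A:1.5,B:1.5);")
  stc <- c(A = "A", B = "AB")
  f3 <- c(0.9, 0.8, 1)
  ll_pkg <- geosse_loglik(cherry, stc, gp, f = f3,
                          require_all_states = FALSE)
  ll_rk4 <- rk4_geosse_cherry(1.5, 1.5, "A", "AB", gp, f3, dt = 1e-4)
  expect_equal(as.numeric(ll_pkg), ll_rk4, tolerance = 1e-6)

  # unoccupied state is rejected with the model's requirement
  st2 <- setNames(rep(c("A", "B"), 20), names(sim$states))
  expect_error(geosse_loglik(sim$tree, st2, gp),
               "all three geographic states")
})

test_that("GeoSSE without between-region events reduces to per-region BD", {
  set.seed(23)
  sA <- 0.2; sB <- 0.09; xA <- 0.05; xB <- 0.02
  gp <- c(sA = sA, sB = sB, sAB = 0, xA = xA, xB = xB, dA = 0, dB = 0)
  trA <- rand_ultra_tree(8, depth = 15)
  trB <- rand_ultra_tree(8, depth = 22)
  stA <- setNames(rep("A", 8), trA$tip.label)
  stB <- setNames(rep("B", 8), trB$tip.label)
  llA <- geosse_loglik(trA, stA, gp, root = "given",
                       root_p = c(1, 0, 0), require_all_states = FALSE)
  llB <- geosse_loglik(trB, stB, gp, root = "given",
                       root_p = c(0, 1, 0), require_all_states = FALSE)
  expect_equal(as.numeric(llA), bd_loglik(trA, sA, xA), tolerance = 1e-6)
  expect_equal(as.numeric(llB), bd_loglik(trB, sB, xB), tolerance = 1e-6)
  # the two single-region processes are independent: joint = sum
  expect_equal(as.numeric(llA) + as.numeric(llB),
               bd_loglik(trA, sA, xA) + bd_loglik(trB, sB, xB),
               tolerance = 1e-6)
})

test_that("model specifications count free parameters correctly", {
  bm <- bisse_models()
  expect_equal(vapply(bm, function(m) m$k, 0L),
               c(full = 6L, equal_rates = 3L, equal_speciation = 4L,
                 equal_extinction = 4L))
  gm <- geosse_models()
  expect_equal(vapply(gm, function(m) m$k, 0L),
               c(full = 7L, equal_rates = 4L, equal_speciation = 6L,
                 equal_extinction = 6L, equal_migration = 6L))
  # tying works: expanded vector honours the constraints
  er <- bm$equal_rates
  full <- er$expand(c(lambda0 = 0.1, mu0 = 0.02, m01 = 0.01))
  expect_equal(unname(full["lambda1"]), 0.1)
  expect_equal(unname(full["m10"]), 0.01)
})

test_that("fitting respects nesting and the AIC identity", {
  p <- c(lambda0 = 0.1, lambda1 = 0.1, mu0 = 0.02, mu1 = 0.02,
         m01 = 0.02, m10 = 0.02)
  sim <- simulate_tree("bisse", p, n_tips = 80, seed = 31)
  lad <- bisse_ladder(sim$tree, sim$states)
  cmp <- lad$comparison
  # AIC = 2k - 2 logLik, exactly
  expect_equal(cmp$AIC, 2 * cmp$k - 2 * cmp$loglik, tolerance = 1e-9)
  # the full model can never fit worse than its nested constraints
  full_ll <- cmp$loglik[cmp$model == "full"]
  expect_true(all(full_ll >= cmp$loglik - 1e-4))
  # fits from different data refuse to be compared
  sim2 <- simulate_tree("bisse", p, n_tips = 60, seed = 32)
  f2 <- fit_sse(sim2$tree, sim2$states, bisse_models()$equal_rates)
  expect_error(compare_models(list(lad$fits$full, f2)), "different data")
})

test_that("delta-AIC tabulation follows the convention", {
  # two models with AIC 212 and 210: dAIC 2 and 0, neither substantial
  fits <- list(
    structure(list(spec = sse_model_spec("bisse", "a"),
                   loglik = -100, k = 6, AIC = 212,
                   fingerprint = c(1, 2, 3)), class = "sse_fit"),
    structure(list(spec = sse_model_spec("bisse", "b",
                     list(c("lambda0", "lambda1"))),
                   loglik = -100, k = 5, AIC = 210,
                   fingerprint = c(1, 2, 3)), class = "sse_fit"))
  cmp <- compare_models(fits)
  expect_equal(cmp$dAIC, c(2, 0))
  expect_false(any(cmp$substantial))
  expect_equal(compare_models(fits[2])$dAIC, 0)
  # AIC from logLik: -100 with k = 6 gives 212
  expect_equal(2 * 6 - 2 * (-100), 212)
})
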