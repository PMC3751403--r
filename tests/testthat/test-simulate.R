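test_that("stopping rules and determinism hold for simulated trees", {
  s <- simulate_tree("yule", c(lambda = 0.1), n_tips = 158, seed = 1)
  expect_equal(ape::Ntip(s$tree), 158)
  expect_true(check_ultrametric(s$tree)$ultrametric)
  expect_true(ape::is.binary(s$tree))
  # identical config + seed -> bit-identical output
  s2 <- simulate_tree("yule", c(lambda = 0.1), n_tips = 158, seed = 1)
  expect_equal(s$tree$edge.length, s2$tree$edge.length)
  expect_identical(s$states, s2$states)
  # max_time stopping: crown age equals the requested age
  st <- simulate_tree("yule", c(lambda = 0.15), max_time = 30, seed = 3)
  expect_equal(check_ultrametric(st$tree)$root_age, 30, tolerance = 1e-9)
  expect_error(simulate_tree("yule", c(lambda = 0.1)), "n_tips or max_time")
})

test_that("absorbing state configurations stay absorbed", {
  # state 1 cannot arise: lambda1 = 0 and no transitions
  s <- simulate_tree("bisse",
                     c(lambda0 = 0.1, lambda1 = 0, mu0 = 0, mu1 = 0,
                       m01 = 0, m10 = 0),
                     n_tips = 50, root_state = "0", seed = 2)
  expect_true(all(s$states == "0"))
  # geosse: pure within-A dynamics keep everything in A
  g <- simulate_tree("geosse",
                     c(sA = 0.12, sB = 0.05, sAB = 0.05, xA = 0, xB = 0,
                       dA = 0, dB = 0),
                     n_tips = 40, root_state = "A", seed = 4)
  expect_true(all(g$states == "A"))
  # truth record carries the generating configuration
  expect_equal(g$truth$model, "geosse")
  expect_equal(unname(g$truth$pars["sA"]), 0.12)
  expect_equal(g$truth$root_state, "A")
})

test_that("extant richness matches the branching-process expectation", {
  # crown birth-death from 2 lineages: E[N(T)] = 2 exp((la - mu) T)
  # unconditionally; the simulator retries until >= 2 tips survive, so
  # the exact oracle is the conditional expectation
  # E[N | N >= 2] = (2 e^{rT} - P(N = 1)) / (1 - P(N = 0) - P(N = 1))
  # with the linear birth-death law P(N1 = 0) = a,
  # P(N1 = n) = (1 - a)(1 - b) b^{n-1},
  # a = mu (e^{rT} - 1) / (la e^{rT} - mu),
  # b = la (e^{rT} - 1) / (la e^{rT} - mu).
  la <- 0.1; mu <- 0.05; T_ <- 40; r <- la - mu
  a <- mu * (exp(r * T_) - 1) / (la * exp(r * T_) - mu)
  b <- la * (exp(r * T_) - 1) / (la * exp(r * T_) - mu)
  p0 <- a^2
  p1 <- 2 * a * (1 - a) * (1 - b)
  expected <- (2 * exp(r * T_) - p1) / (1 - p0 - p1)
  set.seed(10)
  tips <- vapply(1:300, function(i) {
    s <- simulate_tree("bisse",
                       c(lambda0 = la, lambda1 = la, mu0 = mu, mu1 = mu,
                         m01 = 0, m10 = 0),
                       max_time = T_, seed = 8000 + i, max_retries = 200)
    ape::Ntip(s$tree)
  }, 0)
  expect_gt(mean(tips), expected * 0.85)
  expect_lt(mean(tips), expected * 1.15)
})

test_that("incomplete sampling thins tips binomially per state", {
  s <- simulate_tree("bisse",
                     c(lambda0 = 0.25, lambda1 = 0.25, mu0 = 0, mu1 = 0,
                       m01 = 0.15, m10 = 0.15), n_tips = 1000, seed = 6)
  # f = 1 is the identity
  all1 <- apply_sampling(s$tree, s$states, c("0" = 1, "1" = 1), seed = 1)
  expect_equal(ape::Ntip(all1$tree), 1000)
  # f = 0.5: half retained, binomial spread (4 sd ~ 63)
  half <- apply_sampling(s$tree, s$states, c("0" = 0.5, "1" = 0.5),
                         seed = 2)
  expect_gt(ape::Ntip(half$tree), 500 - 64)
  expect_lt(ape::Ntip(half$tree), 500 + 64)
  expect_true(check_ultrametric(half$tree)$ultrametric)
  expect_equal(sum(half$retained) + sum(half$dropped), 1000)
  # per-state asymmetric design fractions are honoured in expectation
  f_design <- c("0" = 143 / 155, "1" = 15 / 16)
  kept <- apply_sampling(s$tree, s$states, f_design, seed = 3)
  n0 <- sum(s$states == "0")
  expect_gt(kept$retained[["0"]], n0 * (143 / 155) - 4 * sqrt(n0 * 0.25))
  expect_error(apply_sampling(s$tree, s$states, c("0" = 1)))
})

test_that("occurrence simulation respects purity and polygon bounds", {
  map <- toy_region_map()
  homes <- setNames(rep(c("HRZ", "TRZ_SCP"), 5), paste0("s", 1:10))
  occ <- simulate_occurrences(homes, map, n_per_species = 30,
                              purity = 0.9, seed = 11)
  expect_equal(nrow(occ), 300)
  # every record lies inside one of the zone polygons
  counts <- count_in_zones(occ, map)
  expect_equal(unname(counts["outside"]), 0)
  # purity 1: all records in the home zone
  occ1 <- simulate_occurrences(homes, map, n_per_species = 30,
                               purity = 1, seed = 12)
  expect_true(all(occ1$zone_true == homes[occ1$species]))
  # determinism
  occ2 <- simulate_occurrences(homes, map, n_per_species = 30,
                               purity = 0.9, seed = 11)
  expect_identical(occ, occ2)
  expect_error(simulate_occurrences(homes, map, purity = 0.3), "purity")
  degenerate <- region_map(list(Z = cbind(c(0, 1, 2), c(0, 0, 0)),
                                W = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  expect_error(simulate_occurrences(c(x = "Z"), degenerate, 5, 1, 1),
               "zero area")
})
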