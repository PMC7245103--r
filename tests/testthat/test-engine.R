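test_that("effective rate constants follow the collision/template/completion model", {
  net <- giant_network()
  p <- rate_params()
  rx <- net$reactions

  # template acceleration is exactly 10x when one template is present
  k_off <- effective_rate_constant(net, p)
  k_on <- effective_rate_constant(net, p, state = c(M36c = 1))
  hex <- rx$id[rx$kind == "synthesis" & rx$p1 == "M6"][1]
  expect_equal(unname(k_on[hex] / k_off[hex]), p$template_factor)
  untempl <- rx$id[rx$kind == "synthesis" & is.na(rx$template_id)][1]
  expect_equal(k_on[untempl], k_off[untempl])

  # reduced-mass scaling: monomer+monomer vs dimer+dimer at equal base
  # constants differ by sqrt(mu2 / mu1) = sqrt(2)
  p0 <- rate_params(k_nano = 0, D = 1)
  sp4 <- enumerate_species(4)
  net4 <- assign_base_constants(enumerate_reactions(sp4, 4, growth = "all_pairs"), p0)
  k4 <- effective_rate_constant(net4, p0)
  r_mono <- k4["M1+M1>M2c"] / net4$reactions$base_k[net4$reactions$id == "M1+M1>M2c"]
  r_di <- k4["M2c+M2c>M4"] / net4$reactions$base_k[net4$reactions$id == "M2c+M2c>M4"]
  expect_equal(unname(r_mono / r_di), sqrt(2))

  # k_nano = 0 switches the completion bias off entirely
  pk <- rate_params(k_nano = 0)
  kk <- effective_rate_constant(assign_base_constants(net, pk), pk)
  near <- rx$id[rx$kind == "synthesis" & rx$p1 == "M154c"][1]
  far <- rx$id[rx$kind == "synthesis" & rx$p1 == "M100c"][1]
  mu_of <- function(id) {
    row <- rx[rx$id == id, ]
    n <- stats::setNames(net$species$nuclearity, net$species$id)
    m1 <- n[row$r1]; m2 <- n[row$r2]
    m1 * m2 / (m1 + m2)
  }
  expect_equal(unname(kk[near] * sqrt(mu_of(near))),
               unname(kk[far] * sqrt(mu_of(far))))
})

test_that("propensities are mass action with the identical-pair correction", {
  p <- unit_dimer_params()
  net <- dimer_network(p, channels = "corner")
  a <- propensity(net, p, c(M1 = 4, M2c = 5))
  expect_equal(unname(a["M1+M1>M2c"]), 1 * 4 * 3 / 2)
  expect_equal(unname(a["M2c>M1+M1"]), 1 * 5)
  # distinct bimolecular reactants multiply their counts
  sp <- enumerate_species(3)
  net3 <- assign_base_constants(enumerate_reactions(sp, 3, growth = "all_pairs"),
                                rate_params(k_nano = 0))
  a3 <- propensity(net3, rate_params(k_nano = 0), c(M1 = 3, M2c = 4))
  k3 <- effective_rate_constant(net3, rate_params(k_nano = 0))
  expect_equal(unname(a3["M1+M2c>M3"]), unname(k3["M1+M2c>M3"] * 3 * 4))
})

test_that("single Gillespie steps have the right waiting times and selection law", {
  p <- unit_dimer_params()
  net <- dimer_network(p, channels = "corner")

  # exhausted state: nothing fires, time jumps to the horizon
  out <- ssa_step(net, p, c(M1 = 0, M2c = 0), horizon = 7)
  expect_true(is.na(out$fired))
  expect_identical(out$time_increment, 7)

  # waiting time is exponential with rate = total propensity
  set.seed(1)
  state <- c(M1 = 1000)
  total <- sum(propensity(net, p, state))
  dts <- replicate(3000, ssa_step(net, p, state)$time_increment)
  expect_lt(abs(mean(dts) - 1 / total), 3 * sd(dts) / sqrt(length(dts)))

  # reaction choice is proportional to propensity (3:1 -> 75%)
  state2 <- c(M1 = 2, M2c = 0)
  a <- propensity(net, p, state2)
  a_syn <- a["M1+M1>M2c"]
  state3 <- c(M1 = 2, M2c = round(3 * unname(a_syn)))  # reverse propensity ~ 3x forward
  a3 <- propensity(net, p, state3)
  pr <- a3["M2c>M1+M1"] / sum(a3)
  set.seed(2)
  fired <- replicate(4000, ssa_step(net, p, state3)$fired)
  phat <- mean(fired == "M2c>M1+M1")
  expect_lt(abs(phat - pr), 3 * sqrt(pr * (1 - pr) / 4000))
})

test_that("trajectories are deterministic, mass-conserving and well-formed", {
  p <- unit_dimer_params()
  net <- dimer_network(p)
  tr1 <- run_simulation(net, p, c(M1 = 200), horizon = 5, seed = 11)
  tr2 <- run_simulation(net, p, c(M1 = 200), horizon = 5, seed = 11)
  expect_identical(tr1$counts, tr2$counts)
  expect_identical(tr1$events, tr2$events)
  tr3 <- run_simulation(net, p, c(M1 = 200), horizon = 5, seed = 12)
  expect_false(identical(tr1$counts, tr3$counts))

  # the first sample is the initial condition; Mo mass is conserved at
  # every sample (asserted inside the engine, recomputed here)
  expect_equal(unname(tr1$counts[, 1]), c(200, 0, 0))
  nuc <- net$species$nuclearity
  expect_true(all(colSums(tr1$counts * nuc) == 200))
  expect_error(run_simulation(net, p, c(M1 = 10), horizon = 0), "horizon")
  expect_error(run_simulation(net, p, c(M1 = -1), horizon = 1), "non-negative")
})

test_that("simulated dimerization equilibrium matches the master-equation mean", {
  p <- unit_dimer_params()
  net <- dimer_network(p, channels = "corner")
  exact <- dimer_equilibrium_mean(20, kf = 1, kr = 1)
  reps <- 40
  means <- vapply(seq_len(reps), function(r) {
    tr <- run_simulation(net, p, c(M1 = 20), horizon = 60, seed = 500 + r)
    unname(time_average(tr, "M2c", window = c(0.25, 1)))
  }, numeric(1))
  se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - exact), 3 * se + 0.02 * exact)
})

test_that("ensemble means agree with the deterministic mass-action ODE", {
  p <- unit_dimer_params()
  net <- dimer_network(p, channels = "corner")
  k <- effective_rate_constant(net, p)
  kf <- unname(k["M1+M1>M2c"]); kr <- unname(k["M2c>M1+M1"])
  ode <- deSolve::ode(
    y = c(n = 1000, d = 0), times = seq(0, 0.005, length.out = 21),
    func = function(t, y, parms) {
      syn <- kf * y["n"]^2 / 2
      deg <- kr * y["d"]
      list(c(n = -2 * syn + 2 * deg, d = syn - deg))
    }, parms = NULL)
  ens <- run_ensemble(net, p, c(M1 = 1000), horizon = 0.005, n_reps = 40,
                      seed_base = 900, grid = seq(0, 0.005, length.out = 21))
  i_mid <- c(6, 11, 21)
  for (i in i_mid) {
    se <- sqrt(ens$var["M2c", i] / ens$n_replicates)
    expect_lt(abs(ens$mean["M2c", i] - ode[i, "d"]), 3 * se + 0.02 * ode[i, "d"] + 0.5)
  }
})

test_that("ensembles aggregate replicates reproducibly", {
  p <- unit_dimer_params()
  net <- dimer_network(p)
  ens1 <- run_ensemble(net, p, c(M1 = 100), horizon = 2, n_reps = 1, seed_base = 30)
  tr <- run_simulation(net, p, c(M1 = 100), horizon = 2, seed = 31)
  expect_equal(ens1$mean, tr$counts)
  expect_equal(unname(ens1$time_averaged_abundance["M2c"]),
               unname(time_average(tr)["M2c"]))

  # pure degradation: all dimers dissolve back to monomers (absorption)
  netd <- dimer_network(p)
  netd$reactions$base_k[netd$reactions$kind == "synthesis"] <- 1e-300
  ensd <- run_ensemble(netd, p, c(M2c = 50), horizon = 40, n_reps = 8,
                       seed_base = 60)
  expect_equal(unname(ensd$mean["M1", ncol(ensd$mean)]), 100)

  ens2 <- run_ensemble(net, p, c(M1 = 100), horizon = 2, n_reps = 5, seed_base = 30)
  ens3 <- run_ensemble(net, p, c(M1 = 100), horizon = 2, n_reps = 5, seed_base = 30)
  expect_identical(ens2$mean, ens3$mean)
  expect_identical(ens2$seeds, 30 + 1:5)
})

test_that("trajectory and ensemble CSV exports are tidy", {
  p <- unit_dimer_params()
  net <- dimer_network(p)
  tr <- run_simulation(net, p, c(M1 = 50), horizon = 1, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- utils::read.csv(f)
  expect_identical(names(df), c("time", "species", "count", "replicate"))
  expect_identical(nrow(df), nrow(tr$counts) * length(tr$grid))
  ens <- run_ensemble(net, p, c(M1 = 50), horizon = 1, n_reps = 2, seed_base = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(ens, f2)
  expect_identical(names(utils::read.csv(f2)), c("time", "species", "mean", "var"))
})
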