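test_that("species enumeration covers the nuclearity range with two dimers", {
  sp <- enumerate_species(3)
  expect_setequal(sp$id, c("M1", "M2c", "M2e", "M3"))
  expect_identical(nrow(sp), 4L)
  expect_identical(enumerate_species(1)$id, "M1")
  expect_identical(sum(sp$nuclearity == 2L), 2L)

  full <- enumerate_species(154, default_targets())
  tgt <- full[full$is_target, ]
  expect_setequal(tgt$nuclearity, c(36L, 132L, 154L))
  expect_true(full$is_template[full$id == "M36c"])
  # free sites vanish only on completed targets
  expect_identical(full$id[full$free_sites == 0L], tgt$id)
  expect_error(enumerate_species(100, default_targets()), "smaller than the largest")
})

test_that("reaction enumeration is reversible and conserves nuclearity", {
  sp1 <- enumerate_species(2)
  net1 <- enumerate_reactions(sp1[sp1$id != "M2e", ], 2)
  expect_setequal(net1$reactions$id, c("M1+M1>M2c", "M2c>M1+M1"))

  net2 <- enumerate_reactions(sp1, 2)
  expect_identical(nrow(net2$reactions), 4L)
  expect_identical(sum(net2$reactions$kind == "synthesis"), 2L)

  net0 <- enumerate_reactions(enumerate_species(1), 1)
  expect_identical(nrow(net0$reactions), 0L)

  # structural invariants hold for small and giant networks
  expect_length(validate_network(net2), 0L)
  giant <- giant_network()
  expect_length(validate_network(giant), 0L)
  # every synthesis has its reverse degradation
  syn <- giant$reactions[giant$reactions$kind == "synthesis", ]
  deg <- giant$reactions[giant$reactions$kind == "degradation", ]
  expect_identical(nrow(syn), nrow(deg))
})

test_that("giant-network enumeration stays tractable", {
  t0 <- Sys.time()
  net <- mob_network(154, rate_params())
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  expect_gt(nrow(net$reactions), 100)
})

test_that("base constants implement the dimerization ratio and giant stability", {
  p1 <- rate_params(D = 1)
  net <- assign_base_constants(giant_network(), p1)
  rx <- net$reactions
  k2c <- rx$base_k[rx$id == "M1+M1>M2c"]
  k2e <- rx$base_k[rx$id == "M1+M1>M2e"]
  expect_equal(k2c, k2e)

  p2 <- rate_params(D = 2)
  rx2 <- assign_base_constants(net, p2)$reactions
  expect_equal(rx2$base_k[rx2$id == "M1+M1>M2c"] /
                 rx2$base_k[rx2$id == "M1+M1>M2e"], 2)

  # completed giants are stable; ordinary intermediates degrade at 1.0
  deg <- rx[rx$kind == "degradation", ]
  expect_equal(unique(deg$base_k[deg$r1 %in% c("M132e", "M154c")]), p1$k_d)
  expect_equal(deg$base_k[deg$r1 == "M20c"][1], p1$k_uni_default)
  expect_error(rate_params(D = -1), "positive")
})

test_that("template annotation marks the autocatalytic set and supports ablation", {
  net <- giant_network()
  rx <- net$reactions
  hex <- rx[rx$kind == "synthesis" & rx$p1 == "M6", ]
  expect_true(all(hex$template_id == "M36c"))
  # the wheel path above the template is accelerated too
  arm <- rx[rx$kind == "synthesis" & rx$p1 == "M100c", ]
  expect_true(all(arm$template_id == "M36c"))
  # the ball path is untemplated
  ball <- rx[rx$kind == "synthesis" & rx$p1 == "M100e", ]
  expect_true(all(is.na(ball$template_id)))

  abl <- annotate_templates(net, list())
  expect_identical(sum(!is.na(abl$reactions$template_id)), 0L)
  expect_error(annotate_templates(net, list(list(template = "M999", products = "M6"))),
               "unknown species")
  # custom cross-catalysis rules annotate their products
  cust <- annotate_templates(net, list(list(template = "M132e", products = "M6")))
  rx3 <- cust$reactions
  expect_true(all(rx3$template_id[rx3$kind == "synthesis" & rx3$p1 == "M6"] == "M132e"))
})

test_that("the inhibitor extension binds unproductively and conserves mass", {
  p <- unit_dimer_params()
  base <- dimer_network(p)
  ext <- extend_with_inhibitor(base, binding_k = 0.5, release_k = 0.2,
                               bound_targets = "M2c")
  expect_true(all(c("Inh", "Inh:M2c") %in% ext$species$id))
  # the complex appears only in its binding/release pair
  touching <- ext$reactions[
    ext$reactions$r1 == "Inh:M2c" | !is.na(ext$reactions$r2) &
      ext$reactions$r2 == "Inh:M2c" | ext$reactions$p1 == "Inh:M2c", ]
  expect_identical(sort(touching$id), sort(c("Inh+M2c>Inh:M2c", "Inh:M2c>Inh+M2c")))
  expect_error(extend_with_inhibitor(base, -1, 0), "non-negative")
  expect_error(extend_with_inhibitor(base, 1, 0, bound_targets = "M9"), "not in network")

  # zero binding leaves the dynamics identical to the unextended network
  null_inh <- extend_with_inhibitor(base, 0, 0, bound_targets = "M2c")
  tr0 <- run_simulation(base, p, c(M1 = 100), horizon = 3, seed = 9)
  tr1 <- run_simulation(null_inh, p, c(M1 = 100, Inh = 50), horizon = 3, seed = 9)
  expect_identical(tr0$counts["M2c", ], tr1$counts["M2c", ])

  # active binding sequesters the target and conserves Mo mass throughout,
  # and a stronger binder (more hydrogen-bonding sites) suppresses more
  act <- extend_with_inhibitor(base, 5, 0, bound_targets = "M2c")
  tr2 <- run_simulation(act, p, c(M1 = 100, Inh = 200), horizon = 3, seed = 9,
                        check_mass = TRUE)
  expect_lt(time_average(tr2)["M2c"], time_average(tr0)["M2c"])
  weak <- extend_with_inhibitor(base, 0.5, 0, bound_targets = "M2c")
  avg_weak <- mean(vapply(1:6, function(s)
    time_average(run_simulation(weak, p, c(M1 = 100, Inh = 200), 3,
                                seed = s))["M2c"], numeric(1)))
  avg_strong <- mean(vapply(1:6, function(s)
    time_average(run_simulation(act, p, c(M1 = 100, Inh = 200), 3,
                                seed = s))["M2c"], numeric(1)))
  expect_lt(avg_strong, avg_weak)
})

test_that("network JSON round-trips and CSV export writes every reaction", {
  net <- dimer_network(unit_dimer_params())
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_identical(back$species$id, net$species$id)
  expect_identical(back$reactions$id, net$reactions$id)
  expect_equal(back$reactions$base_k, net$reactions$base_k)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, csv)
  expect_identical(nrow(utils::read.csv(csv)), nrow(net$reactions))
})
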