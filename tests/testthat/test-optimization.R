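test_that("fba reproduces closed-form chain optima and oracle values", {
  expect_equal(fba(chain_model())$objective_value, 10)
  expect_equal(fba(chain_model(internal_ub = 4))$objective_value, 4)
  toy <- default_toy()
  sol <- fba(toy$model)
  expect_equal(sol$objective_value, toy$ground_truth$analytic_optimum)
  expect_equal(sol$objective_value,
               brute_force_fba_oracle(toy$model)$objective)
  # min sense
  expect_equal(fba(chain_model(), "EX_B", sense = "min")$objective_value, 0)
  # infeasible model reports status without fluxes
  bad <- toy$model
  bad$reactions$EX_clav$lower_bound <- 5   # above the attainable 2.5
  s <- fba(bad)
  expect_equal(s$status, "infeasible")
  expect_null(s$fluxes)
})

test_that("shadow prices match finite-difference sensitivities", {
  # perturbing metabolite i's balance by a free supply eps changes the
  # optimum by -shadow_price * eps
  toy <- default_toy()
  sol <- fba(toy$model)
  S <- stoichiometric_matrix(toy$model, sparse = FALSE)
  lb <- vapply(toy$model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(toy$model$reactions, `[[`, 0, "upper_bound")
  cvec <- as.numeric(names(toy$model$reactions) == "EX_clav")
  eps <- 1e-4
  for (met in c("glyc", "g3p", "akg", "co2")) {
    rhs <- numeric(nrow(S))
    rhs[match(met, rownames(S))] <- -eps
    pert <- lp_solve(cvec, S, rhs, lb = lb, ub = ub)
    fd <- (pert$objective - sol$objective_value) / eps
    expect_equal(fd, -sol$shadow_prices[[met]], tolerance = 1e-4,
                 label = paste("finite difference for", met))
  }
})

test_that("two-step FBA keeps the optimum and minimizes the L1 norm", {
  # unique-solution chain: identical to plain fba
  ch <- chain_model()
  expect_equal(two_step_fba(ch)$fluxes, fba(ch)$fluxes, tolerance = 1e-9)

  toy <- default_toy(n_parallel_routes = 2)
  ts <- two_step_fba(toy$model)
  expect_equal(ts$step1_objective, toy$ground_truth$analytic_optimum,
               tolerance = 1e-9)
  expect_equal(unname(ts$fluxes["EX_clav"]), ts$step1_objective,
               tolerance = 1e-9)
  # the parsimonious solution routes everything through the one-step path
  expect_equal(unname(ts$fluxes["GLYT_alt1_a"]), 0, tolerance = 1e-9)
  # the alternative distribution (same optimum, longer route) has a strictly
  # larger norm
  forced <- toy$model
  forced$reactions$GLYT$upper_bound <- 0
  alt <- two_step_fba(forced)
  expect_equal(alt$step1_objective, ts$step1_objective, tolerance = 1e-9)
  expect_lt(ts$total_flux, alt$total_flux)
  # and never exceeds the step-1 solution's norm
  expect_lte(ts$total_flux, sum(abs(fba(toy$model)$fluxes)) + 1e-9)
})

test_that("FVA brackets every optimal solution", {
  fv <- fva(chain_model(), 1.0)
  expect_true(all(abs(fv$max - fv$min) < 1e-9))  # unique optimum
  toy <- default_toy(n_parallel_routes = 2)
  fvt <- fva(toy$model, 1.0)
  ranges <- fvt[match(c("GLYT", "GLYT_alt1_a"), fvt$reaction_id), ]
  # either route may carry any share of the full 10 units of uptake
  expect_equal(ranges$min, c(0, 0), tolerance = 1e-6)
  expect_equal(ranges$max, c(10, 10), tolerance = 1e-6)
  # blocked reactions have the degenerate range [0, 0]
  toyb <- default_toy(include_unreachable_branch = TRUE)
  fvb <- fva(toyb$model, 1.0, reactions = "UNR2")
  expect_equal(c(fvb$min, fvb$max), c(0, 0), tolerance = 1e-9)
  # envelope property: sampled optimal-face solutions stay inside ranges
  constrained <- toyb$model
  constrained$reactions$EX_clav$lower_bound <-
    toyb$ground_truth$analytic_optimum
  sm <- chrr_sample(constrained, sampler_config(n_points = 100,
                                                steps_per_point = 20,
                                                seed = 5))
  full <- fva(toyb$model, 1.0)
  for (j in colnames(sm$points)) {
    rng <- full[full$reaction_id == j, ]
    expect_gte(min(sm$points[, j]), rng$min - 1e-6)
    expect_lte(max(sm$points[, j]), rng$max + 1e-6)
  }
})

test_that("scenario constraints are applied with the published conventions", {
  toy <- default_toy()
  fb <- sclav_rates("fedbatch")
  glyc_batch <- fb$exp[fb$phase == "batch" & fb$reaction == "Glycerol"]
  sc <- scenario("batch", growth_rate = 0.042,
                 lower_bounded = list(EX_glyc = glyc_batch),
                 upper_bounded = list(EX_co2 = 1.640),
                 objective_id = "EX_clav")
  m <- apply_scenario(toy$model, sc)
  expect_equal(m$reactions$EX_glyc$lower_bound, -0.182)
  expect_equal(m$reactions$EX_glyc$upper_bound, 0)      # ub untouched
  expect_equal(m$reactions$EX_co2$upper_bound, 1.640)
  expect_equal(m$reactions$GROWTH$lower_bound, 0.042)
  expect_equal(m$reactions$GROWTH$upper_bound, 0.042)
  gr_fed <- fb$exp[fb$phase == "fedbatch" & fb$reaction == "Growth"]
  m2 <- apply_scenario(toy$model, scenario("fed", growth_rate = gr_fed))
  expect_equal(unname(c(m2$reactions$GROWTH$lower_bound,
                        m2$reactions$GROWTH$upper_bound)), c(0.031, 0.031))
  # empty scenario leaves the model unchanged
  m3 <- apply_scenario(toy$model, scenario("empty"))
  expect_identical(lapply(m3$reactions, `[[`, "lower_bound"),
                   lapply(toy$model$reactions, `[[`, "lower_bound"))
  # contradictory bounds are rejected by name
  expect_error(apply_scenario(toy$model,
                              scenario("bad", upper_bounded =
                                         list(EX_glyc = 0))),
               NA)  # ub 0 on an uptake-only exchange is fine
  bad <- toy$model
  bad$reactions$EX_clav$lower_bound <- 1
  expect_error(apply_scenario(bad, scenario("bad2", upper_bounded =
                                              list(EX_clav = 0.5))),
               "EX_clav")
})

test_that("scenario CSV round trip preserves roles and values", {
  sc <- scenario("s", growth_rate = 0.042,
                 lower_bounded = list(EX_glyc = -0.182, EX_o2 = -1.35),
                 upper_bounded = list(EX_co2 = 1.64),
                 growth_id = "GROWTH")
  p <- withr::local_tempfile(fileext = ".csv")
  write_scenario(sc, p)
  sc2 <- read_scenario(p, name = "s")
  expect_equal(sc2$growth_rate, 0.042)
  expect_equal(sc2$lower_bounded, unlist(sc$lower_bounded))
  expect_equal(sc2$upper_bounded, unlist(sc$upper_bounded))
  expect_equal(sc2$growth_id, "GROWTH")
  expect_error(scenario("x", lower_bounded = list(EX_a = 0.5)), "<= 0")
  expect_error(scenario("x", upper_bounded = list(EX_a = -0.5)), ">= 0")
})
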