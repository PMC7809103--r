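test_that("growth flow reproduces the competition equation", {
  s <- pest_scenario("Cp")
  ## hand value: 0.83 * 1000 * (1 - 1000/62500) = 816.72, mid-crop
  st <- system_state(1.5, c(Cp = 1000), c(Cp = 0))
  expect_equal(unname(growth_flow(st, s)), 816.72)
  ## logistic fixed point: N = K gives zero growth
  st_k <- system_state(1.5, c(Cp = 62500), c(Cp = 0))
  expect_equal(unname(growth_flow(st_k, s)), 0)
  ## equilibrium states of the linear system are fixed points of the flow
  s4 <- constant_k_scenario(pest_species_ids(), K = 62500)
  K <- rep(62500, 4)
  N_eq <- solve_equilibrium(s4$matrix, K)
  st_eq <- system_state(0, N_eq, stats::setNames(rep(0, 4), names(N_eq)))
  G <- growth_flow(st_eq, s4)
  expect_lt(max(abs(G) / (s4$species$r * N_eq)), 1e-9)
})

test_that("parasitism flow is gated and the bilinear form matches its hand value", {
  s_ma <- pest_scenario("Cp", parasitism_form = "mass_action")
  ## phi=0.3, p=0.035, N=1000, P=1000, K=62500 -> 0.168
  st <- system_state(2.5, c(Cp = 1000), c(Cp = 1000))
  expect_equal(unname(parasitism_flow(st, s_ma)), 0.168)
  ## no parasitoids, no parasitism (either form)
  st0 <- system_state(2.5, c(Cp = 1000), c(Cp = 0))
  expect_equal(unname(parasitism_flow(st0, s_ma)), 0)
  expect_equal(unname(parasitism_flow(st0, pest_scenario("Cp"))), 0)
  ## inside the onset-delay window the fraction is zero
  st_early <- system_state(1.0, c(Cp = 1000), c(Cp = 1000))
  expect_equal(unname(parasitism_flow(st_early, s_ma)), 0)
  ## saturating form never exceeds phi * N per month
  s_sat <- pest_scenario("Cp")
  st_big <- system_state(2.5, c(Cp = 1000), c(Cp = 1e9))
  expect_lte(unname(parasitism_flow(st_big, s_sat)), 0.3 * 1000)
})

test_that("parasitoid flows follow emergence, sex ratio and decrease rate", {
  s <- pest_scenario("Cp")
  st <- system_state(2.5, c(Cp = 1000), c(Cp = 100))
  fl <- parasitoid_flows(st, s, L = c(Cp = 1))
  expect_equal(unname(fl$R), 5 * 0.46 * 1)  # 2.3 parasitoids per lost host
  expect_equal(unname(fl$D), 70)            # 0.7 * 100
  st0 <- system_state(2.5, c(Cp = 0), c(Cp = 0))
  fl0 <- parasitoid_flows(st0, s, L = c(Cp = 0))
  expect_equal(unname(fl0$R), 0)
  expect_equal(unname(fl0$D), 0)
})

test_that("one Euler step integrates the recorded flows and clips at zero", {
  s <- pest_scenario("Cp")
  ## logistic case: N = 1000 -> 1000 + 0.25 * 816.72 = 1204.18 (L = 0)
  st <- system_state(1.5, c(Cp = 1000), c(Cp = 0))
  st2 <- step_state(st, s)
  expect_equal(unname(st2$N), 1204.18)
  expect_equal(st2$t, 1.75)
  ## empty state is absorbing
  st_zero <- system_state(0, c(Cp = 0), c(Cp = 0))
  st_zero2 <- step_state(st_zero, s)
  expect_equal(unname(st_zero2$N), 0)
  expect_equal(unname(st_zero2$P), 0)
  ## recorded parasitoid inflow is emergence * sex ratio * recorded loss
  s2 <- pest_scenario("Bf")
  st_p <- system_state(2.5, c(Bf = 5000), c(Bf = 500))
  fl <- attr(step_state(st_p, s2), "flows")
  expect_identical(fl$R, s2$parasitoid$per_host_emergence *
                           s2$parasitoid$sex_ratio * fl$L)
})

test_that("season transition applies the carryover once, to pests only", {
  s <- pest_scenario("Cp")
  st <- system_state(3, c(Cp = 1000), c(Cp = 200))
  st2 <- apply_season_transition(st, s)
  expect_equal(unname(st2$N), 100)
  expect_equal(unname(st2$P), 200)
  ## identity override
  s_id <- pest_scenario("Cp", calendar = list(carryover_fraction = 1))
  expect_equal(unname(apply_season_transition(st, s_id)$N), 1000)
  ## double application at one boundary is an error
  expect_error(apply_season_transition(st2, s), "already applied")
  ## off-boundary call is an error
  expect_error(apply_season_transition(system_state(2, c(Cp = 1), c(Cp = 0)), s),
               "not a cropping-to-non-cropping boundary")
})

test_that("simulate matches the closed-form logistic and converges as dt halves", {
  errs <- vapply(c(0.25, 0.125, 0.0625), function(dt) {
    s <- constant_k_scenario("Cp", K = 62500, dt = dt)
    tr <- simulate(s)
    expected <- logistic_solution(tr$time_months, r = 0.83, K = 62500,
                                  N0 = 156.25)
    max(abs(tr$N_Cp - expected) / expected)
  }, numeric(1))
  ## forward Euler at dt = 0.25 undershoots the exponential phase; the
  ## error is bounded and halves (roughly) with the step
  expect_lt(errs[1], 0.30)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 2)
})

test_that("zero initial stocks give a flat zero trajectory", {
  s <- pest_scenario(c("Bf", "Cp"),
                     init_pest = c(Bf = 0, Cp = 0),
                     init_parasitoid = c(Bf = 0, Cp = 0))
  tr <- simulate(s)
  expect_true(all(tr[, grep("^[NPGLRD]_", names(tr))] == 0))
})

test_that("a zero competition matrix decouples species exactly", {
  a0 <- labelled_matrix(c(1, 0, 0, 1), c("Bf", "Cp"))
  tr2 <- simulate(pest_scenario(c("Bf", "Cp"), matrix = a0))
  tr_bf <- simulate(pest_scenario("Bf"))
  tr_cp <- simulate(pest_scenario("Cp"))
  expect_identical(tr2$N_Bf, tr_bf$N_Bf)
  expect_identical(tr2$P_Bf, tr_bf$P_Bf)
  expect_identical(tr2$N_Cp, tr_cp$N_Cp)
  expect_identical(tr2$P_Cp, tr_cp$P_Cp)
})

test_that("stocks stay non-negative for randomized valid scenarios", {
  base <- pest_scenario(pest_species_ids())
  ensemble <- perturb_parameters(base, relative_sd = 0.3, n = 8, seed = 42)
  set.seed(42)
  for (cfg in ensemble) {
    cfg$init_pest[] <- stats::runif(4, 0, 5000)
    cfg$init_parasitoid[] <- stats::runif(4, 0, 2000)
    tr <- simulate(cfg)
    expect_true(all(as.matrix(tr[, grep("^[NP]_", names(tr))]) >= 0))
  }
})

test_that("flow bookkeeping: stock change equals dt x net flow at every step", {
  s <- pest_scenario(c("Sf", "Cp"))
  tr <- simulate(s)
  dt <- s$dt
  carry <- s$calendar$carryover_fraction
  boundary <- abs(tr$time_months %% 6 - 3) < 1e-9 & tr$time_months > 0
  clip_times <- attr(tr, "clip_events")$time_months
  for (sp in c("Sf", "Cp")) {
    n_next <- tr[[paste0("N_", sp)]][-1]
    n_exp <- tr[[paste0("N_", sp)]] + dt * (tr[[paste0("G_", sp)]] -
                                            tr[[paste0("L_", sp)]])
    n_exp <- n_exp[-nrow(tr)]
    ## boundary rows carry the season haircut; clipped rows are logged
    at_boundary <- boundary[-1]
    free <- !at_boundary & !(tr$time_months[-1] %in% clip_times)
    expect_identical(n_next[free], n_exp[free])
    expect_identical(n_next[at_boundary], carry * pmax(0, n_exp[at_boundary]))
    p_next <- tr[[paste0("P_", sp)]][-1]
    p_exp <- (tr[[paste0("P_", sp)]] + dt * (tr[[paste0("R_", sp)]] -
                                             tr[[paste0("D_", sp)]]))[-nrow(tr)]
    expect_identical(p_next[free], p_exp[free])
    ## emergence bookkeeping holds at every recorded time
    expect_identical(tr[[paste0("R_", sp)]],
                     s$parasitoid$per_host_emergence * s$parasitoid$sex_ratio *
                       tr[[paste0("L_", sp)]])
  }
})

test_that("default single-species systems cycle with parasitoids tracking hosts", {
  for (sp in pest_species_ids()) {
    cyc <- detect_cycles(simulate(pest_scenario(sp)), sp)
    expect_gte(nrow(cyc$pest_peaks), 2)
    expect_gte(nrow(cyc$parasitoid_peaks), 2)
    expect_true(all(cyc$lags > 0))
  }
})

test_that("simulate validates its scenario and rejects nsim > 1", {
  s <- pest_scenario("Cp")
  s$dt <- -1
  expect_error(simulate(s), "invalid scenario")
  expect_error(simulate(pest_scenario("Cp"), nsim = 3), "deterministic")
})
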