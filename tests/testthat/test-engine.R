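test_that("waiting times are exponential with mean 1/R and signal absorption at R = 0", {
  set.seed(1)
  draws <- vapply(seq_len(10000L), function(i) draw_time_step(100), numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.01), 3 * se)
  expect_true(is.na(draw_time_step(0)))
})

test_that("identical seeds give bit-identical trajectories", {
  I <- canonical_I("full")
  P <- canonical_P("full")
  cfg <- simulation_config(I, P, scaled_params(), scaled_init(I),
                           t_max = 40, seed = 123L)
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$final_state, tr2$final_state)
  expect_identical(tr1$snapshots, tr2$snapshots)
  expect_identical(tr1$n_events, tr2$n_events)
  # and a different seed diverges
  cfg$seed <- 124L
  tr3 <- run_simulation(cfg)
  expect_false(identical(tr1$final_state, tr3$final_state))
})

test_that("event execution follows the bookkeeping table", {
  st <- matrix(0L, 1L, 4L)
  st[1L, 1L] <- 10L
  st[1L, 2L] <- 5L

  grown <- execute_event(st, list(channel = "growth", actor = c(host = 1L, profile = 1L)))
  expect_equal(grown[1L, 1L], 11L)

  dead <- execute_event(st, list(channel = "death", actor = c(host = 1L, profile = 2L)))
  expect_equal(dead[1L, 2L], 4L)

  seg <- execute_event(st, list(channel = "segregation", actor = c(host = 1L, profile = 2L)))
  expect_equal(seg[1L, 1L], 11L)  # plasmid-free daughter
  expect_equal(seg[1L, 2L], 5L)   # actor unchanged

  inf <- execute_event(st, list(channel = "infection",
                                actor = c(host = 1L, profile = 2L),
                                recipient = c(host = 1L, profile = 1L),
                                transconjugant = c(host = 1L, profile = 2L)))
  expect_equal(inf[1L, 1L], 9L)   # recipient -1
  expect_equal(inf[1L, 2L], 6L)   # transconjugant +1

  expect_error(execute_event(st, list(channel = "death", actor = c(host = 1L, profile = 3L))))
})

test_that("the compiled engine's event log conserves abundance and matches full rate recomputation", {
  I <- canonical_I("full")
  P <- canonical_P("full")
  params <- scaled_params()
  lists <- build_transfer_lists(I, P)
  cfg <- simulation_config(I, P, params, scaled_init(I), t_max = 1.5, seed = 77L)
  tr <- run_simulation(cfg, record_events = TRUE)
  ev <- tr$events
  expect_gt(nrow(ev), 100L)

  M <- 16L
  st <- cfg$initial_state
  for (j in seq_len(nrow(ev))) {
    before <- sum(st)
    ch <- ev$channel[j]
    a <- ev$cell_actor[j]
    ai <- a %/% M + 1L
    ap <- a %% M + 1L
    # independent full recomputation of the total rate at this state
    expect_equal(ev$total_rate[j],
                 total_rates(st, params, lists)[["R"]], tolerance = 1e-8)
    if (ch == 0L || ch == 3L) {
      st[ai, ap] <- st[ai, ap] - 1L
      expect_equal(sum(st), before - 1L)
    } else if (ch == 1L) {
      st[ai, ap] <- st[ai, ap] + 1L
      expect_equal(sum(st), before + 1L)
    } else if (ch == 2L) {
      st[ai, 1L] <- st[ai, 1L] + 1L
      expect_equal(sum(st), before + 1L)
    } else {
      b <- ev$cell_recipient[j]
      cc <- ev$cell_transconjugant[j]
      st[b %/% M + 1L, b %% M + 1L] <- st[b %/% M + 1L, b %% M + 1L] - 1L
      st[cc %/% M + 1L, cc %% M + 1L] <- st[cc %/% M + 1L, cc %% M + 1L] + 1L
      expect_equal(sum(st), before) # infection conserves abundance
    }
    expect_true(all(st >= 0L))
  }
  # the replayed end state equals the engine's final state
  expect_equal(unname(st), unname(tr$final_state))
})

test_that("event sampling weights actors by per-capita rate times abundance", {
  # death-only configuration: two subpopulations with abundances 100 vs 300
  sys <- mini_system()
  params <- trait_params(n_hosts = 1L, n_plasmids = 2L, eta = 0, gamma = 0, e = 0)
  tensor <- build_propensity_tensor(sys$I, sys$P)
  lists <- build_transfer_lists(sys$I, sys$P, tensor)
  st <- matrix(0L, 1L, 4L)
  st[1L, 1L] <- 100L
  st[1L, 2L] <- 300L
  set.seed(5)
  draws <- vapply(seq_len(3000L), function(i) {
    ev <- sample_event(st, params, tensor, lists)
    expect_equal(ev$channel, "death")
    ev$actor[["profile"]]
  }, integer(1))
  frac <- mean(draws == 1L)
  expect_lt(abs(frac - 0.25), 4 * sqrt(0.25 * 0.75 / 3000))
})

test_that("transconjugants are sampled from the normalized tensor column", {
  sys <- mini_system()
  # only infection possible: no growth, death, segregation
  params <- trait_params(n_hosts = 1L, n_plasmids = 2L, eta = 0, mu = 0,
                         gamma = 1e-3, e = 0, K = 1000)
  tensor <- build_propensity_tensor(sys$I, sys$P)
  lists <- build_transfer_lists(sys$I, sys$P, tensor)
  st <- matrix(0L, 1L, 4L)
  st[1L, 4L] <- 10L  # donors [1,1]
  st[1L, 1L] <- 10L  # recipients [0,0]
  set.seed(9)
  draws <- vapply(seq_len(2000L), function(i) {
    ev <- sample_event(st, params, tensor, lists)
    expect_equal(ev$channel, "infection")
    ev$transconjugant[["profile"]]
  }, integer(1))
  frac <- mean(draws == 4L)
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / 2000))
})

test_that("a plasmid-free single-host run settles at the demographic equilibrium", {
  sys <- unihost_system()
  params <- trait_params(n_hosts = 1L, n_plasmids = 1L, K = 2000)
  init <- matrix(c(500L, 0L), 1L, 2L)
  cfg <- simulation_config(sys$I, sys$P, params, init, t_max = 300, seed = 31L)
  tr <- run_simulation(cfg)
  # mean-field equilibrium K (1 - mu/eta) = 1760
  expect_lt(abs(sum(tr$final_state) - 1760) / 1760, 0.1)
  expect_equal(tr$termination, "t_max")
})

test_that("snapshots sit on the recording grid and reconstruct dense states", {
  I <- canonical_I("modular")
  P <- canonical_P("full")
  cfg <- simulation_config(I, P, scaled_params(), scaled_init(I),
                           t_max = 30, record_interval = 5, seed = 3L)
  tr <- run_simulation(cfg)
  expect_equal(tr$times, seq(0, 30, by = 5))
  st0 <- state_at(tr, 0)
  expect_equal(unname(st0), unname(cfg$initial_state))
  stT <- state_at(tr, 30)
  expect_equal(unname(stT), unname(tr$final_state))
  expect_true(all(tr$snapshots$abundance >= 0L))
  expect_error(state_at(tr, 2.5), "not on the recorded grid")
})

test_that("infeasible initial states are rejected", {
  I <- canonical_I("modular")
  P <- canonical_P("full")
  bad <- scaled_init(I)
  bad[3L, profile_index(c(1L, 0L, 0L, 0L))] <- 5L # P1 cannot infect H3
  expect_error(simulation_config(I, P, scaled_params(), bad, t_max = 10),
               "infeasible initial state")
})

test_that("early stopping at single-host absorption is flagged and final", {
  I <- canonical_I("full")
  P <- canonical_P("full")
  cfg <- simulation_config(I, P, scaled_params(), scaled_init(I),
                           t_max = 20000, seed = 11L)
  tr <- run_simulation(cfg, stop_single_host = TRUE)
  expect_equal(tr$termination, "single_host")
  expect_lte(sum(rowSums(tr$final_state) > 0L), 1L)
  expect_lt(tr$t_end, 20000)
})

test_that("a community under pure mortality collapses and is recorded as such", {
  sys <- unihost_system()
  params <- trait_params(n_hosts = 1L, n_plasmids = 1L, eta = 0, gamma = 0,
                         e = 0, mu = 1)
  init <- matrix(c(30L, 0L), 1L, 2L)
  cfg <- simulation_config(sys$I, sys$P, params, init, t_max = 1000, seed = 2L)
  tr <- run_simulation(cfg)
  expect_equal(tr$termination, "collapse")
  expect_equal(sum(tr$final_state), 0L)
  expect_lt(tr$t_end, 1000)
})
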