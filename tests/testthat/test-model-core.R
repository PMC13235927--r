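test_that("profile catalog is canonically ordered with P1 as the leftmost bit", {
  cat2 <- enumerate_profiles(2L)
  expect_equal(rownames(cat2), c("00", "10", "01", "11"))
  expect_equal(nrow(enumerate_profiles(4L)), 16L)
  expect_equal(3L * nrow(enumerate_profiles(4L)), 48L) # subpopulation slots
  expect_equal(nrow(enumerate_profiles(0L)), 1L)       # single empty profile

  # round trips between bits, index and bitstring
  for (idx in 1:16) {
    expect_equal(profile_index(profile_bits(idx, 4L)), idx)
  }
  expect_equal(profile_string(profile_index(c(0L, 0L, 1L, 1L)), 4L), "0011")
})

test_that("profile feasibility combines infection and compatibility constraints", {
  Im <- canonical_I("modular")
  Pm <- canonical_P("modular")
  Pf <- canonical_P("full")
  expect_true(profile_feasible(c(1L, 1L, 0L, 0L), 1L, Im, Pm))  # H1 module pair
  expect_false(profile_feasible(c(0L, 1L, 1L, 0L), 2L, Im, Pm)) # P2-P3 incompatible
  expect_true(profile_feasible(c(0L, 1L, 1L, 0L), 2L, Im, Pf))  # bridge co-infection
  expect_false(profile_feasible(c(1L, 0L, 0L, 0L), 3L, Im, Pf)) # P1 cannot reach H3
  expect_true(profile_feasible(rep(0L, 4L), 3L, Im, Pm))        # plasmid-free always
})

test_that("growth rate applies multiplicative plasmid costs", {
  params <- trait_params()
  expect_equal(growth_rate(1L, rep(0L, 4L), params), 1.0)
  expect_equal(growth_rate(1L, c(1L, 0L, 0L, 0L), params), 0.7)  # 30% reduction
  expect_equal(growth_rate(1L, c(1L, 1L, 0L, 0L), params), 0.49)
  expect_equal(growth_rate(1L, rep(1L, 4L), params), 0.7^4)

  # monotonically non-increasing in every cost; equals eta at zero cost
  set.seed(42)
  for (rep in 1:20) {
    cost <- runif(4L, 0, 0.9)
    a <- sample.int(4L, 1L)
    bump <- cost
    bump[a] <- min(0.99, cost[a] + runif(1L, 0, 0.09))
    p <- as.integer(runif(4L) < 0.5)
    g1 <- growth_rate(1L, p, trait_params(cost = cost))
    g2 <- growth_rate(1L, p, trait_params(cost = bump))
    expect_lte(g2, g1 + 1e-12)
  }
  expect_equal(growth_rate(2L, c(1L, 1L, 1L, 1L), trait_params(cost = 0)), 1.0)
})

test_that("segregation rate is e times realized growth, zero for plasmid-free", {
  params <- trait_params(e = 1e-8)
  expect_equal(segregation_rate(1L, c(1L, 1L, 0L, 0L), params), 1e-8 * 0.49)
  expect_equal(segregation_rate(1L, rep(0L, 4L), params), 0)
  expect_equal(segregation_rate(1L, c(1L, 0L, 0L, 0L), trait_params(e = 0)), 0)
})

test_that("competition rate is realized growth times shared density pressure", {
  params <- trait_params(n_hosts = 1L, K = 2000)
  state <- matrix(0L, 1L, 16L)
  state[1L, 1L] <- 2000L
  expect_equal(competition_rate(1L, rep(0L, 4L), state, params), 1.0)

  expect_equal(competition_rate(1L, rep(0L, 4L), 0L * state, params), 0)

  params2 <- trait_params(n_hosts = 2L, a = 0.01, K = 20000)
  state2 <- matrix(0L, 2L, 16L)
  state2[, 1L] <- 10000L # each host at K/2
  expect_equal(competition_rate(1L, rep(0L, 4L), state2, params2), 1.005)
})

test_that("infection rate sums recipient abundances in the donor's list", {
  I <- canonical_I("full")
  P <- canonical_P("full")
  lists <- build_transfer_lists(I, P)
  params <- trait_params()
  state <- matrix(0L, 3L, 16L)
  state[1L, 1L] <- 2000L # the only extant recipients
  p1 <- c(1L, 0L, 0L, 0L)
  expect_equal(infection_rate(1L, p1, state, lists, params), 1e-5 * 2000)
  expect_equal(infection_rate(1L, rep(0L, 4L), state, lists, params), 0)
  expect_equal(infection_rate(1L, p1, 0L * state, lists, params), 0)
})

test_that("channel totals sum per-capita rates times abundances", {
  I <- canonical_I("full")
  P <- canonical_P("full")
  lists <- build_transfer_lists(I, P)
  params <- trait_params()

  empty <- matrix(0L, 3L, 16L)
  expect_equal(unname(total_rates(empty, params, lists)), rep(0, 6L))

  one <- empty
  one[2L, 1L] <- 100L
  tr <- total_rates(one, params, lists)
  expect_equal(unname(tr[["R_D"]]), 12)

  # R equals the sum of the five channels on random states
  set.seed(7)
  for (k in 1:5) {
    st <- matrix(rpois(48L, 50), 3L, 16L)
    tr <- total_rates(st, params, lists)
    expect_equal(tr[["R"]], sum(tr[1:5]))
  }
})
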