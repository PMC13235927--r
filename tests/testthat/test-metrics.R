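mk_state <- function(nb, M, cells) {
  st <- matrix(0L, nb, M, dimnames = list(paste0("H", seq_len(nb)),
                                          rownames(enumerate_profiles(round(log2(M))))))
  for (cl in cells) st[cl[1L], cl[2L]] <- cl[3L]
  st
}

test_that("relative host abundance normalizes by total community size", {
  st <- mk_state(3L, 16L, list(c(1L, 1L, 900L), c(3L, 1L, 100L)))
  expect_equal(unname(relative_host_abundance(st)), c(0.9, 0.0, 0.1))
  expect_equal(sum(relative_host_abundance(st)), 1)

  solo <- mk_state(3L, 16L, list(c(2L, 1L, 50L)))
  expect_equal(unname(relative_host_abundance(solo)), c(0, 1, 0))

  thirds <- mk_state(3L, 16L, list(c(1L, 1L, 7L), c(2L, 1L, 7L), c(3L, 1L, 7L)))
  expect_equal(unname(relative_host_abundance(thirds)), rep(1 / 3, 3L))

  empty <- mk_state(3L, 16L, list())
  expect_true(all(is.na(relative_host_abundance(empty))))
})

test_that("plasmid prevalence counts carriers across all hosts", {
  st <- mk_state(1L, 4L, list(c(1L, 1L, 50L), c(1L, 2L, 50L)))
  expect_equal(unname(plasmid_prevalence(st)), c(0.5, 0.0))

  # a community composed solely of hub pairs carries the hub everywhere
  hubst <- mk_state(1L, 16L, list(
    c(1L, profile_index(c(1L, 1L, 0L, 0L)), 30L),
    c(1L, profile_index(c(1L, 0L, 1L, 0L)), 30L),
    c(1L, profile_index(c(1L, 0L, 0L, 1L)), 40L)))
  expect_equal(unname(plasmid_prevalence(hubst))[1L], 1.0)

  free <- mk_state(2L, 4L, list(c(1L, 1L, 10L), c(2L, 1L, 10L)))
  expect_equal(unname(plasmid_prevalence(free)), c(0, 0))
})

test_that("host composition averages per-replicate proportions over strict survivors", {
  M <- 16L
  p1100 <- profile_index(c(1L, 1L, 0L, 0L))
  # host 1 survives in exactly 5 of 10 replicates (filtered out at threshold 5),
  # host 2 survives in 6, always 100% in one profile
  trajs <- lapply(1:10, function(r) {
    cells <- list()
    if (r <= 5L) cells <- c(cells, list(c(1L, 1L, 20L)))
    if (r <= 6L) cells <- c(cells, list(c(2L, p1100, 30L)))
    st <- mk_state(3L, M, cells)
    fake_trajectory(list(st, st), times = c(0, 5))
  })
  comp <- host_composition(fake_ensemble(trajs), min_surviving_replicates = 5L)
  expect_false("H1" %in% comp$host)
  expect_true("H2" %in% comp$host)
  h2 <- comp[comp$host == "H2", ]
  expect_equal(sum(h2$proportion), 1)
  expect_equal(h2$proportion[h2$profile == "1100"], 1)
})

test_that("coexistence probability tracks extant host counts and is monotone in k", {
  M <- 4L
  three <- mk_state(3L, M, list(c(1L, 1L, 10L), c(2L, 1L, 10L), c(3L, 1L, 10L)))
  two <- mk_state(3L, M, list(c(1L, 1L, 10L), c(3L, 1L, 10L)))
  one <- mk_state(3L, M, list(c(1L, 1L, 10L)))
  # 4 of 10 replicates keep two hosts to the end, the rest collapse to one
  trajs <- lapply(1:10, function(r) {
    fin <- if (r <= 4L) two else one
    fake_trajectory(list(three, fin), times = c(0, 5))
  })
  ens <- fake_ensemble(trajs)
  cp3 <- coexistence_probability(ens, k = 3L)
  expect_equal(cp3$probability[cp3$time == 0], 1.0)
  cp2 <- coexistence_probability(ens, k = 2L)
  expect_equal(cp2$probability[cp2$time == 5], 0.4)
  for (tt in cp2$time) {
    expect_gte(cp2$probability[cp2$time == tt], cp3$probability[cp3$time == tt])
  }
  cp1 <- coexistence_probability(ens, k = 1L)
  expect_true(all(cp1$probability >= cp2$probability))
})

test_that("trajectories are classified as stable, transient-only, or no coexistence", {
  M <- 4L
  three <- mk_state(3L, M, list(c(1L, 1L, 5L), c(2L, 1L, 5L), c(3L, 1L, 5L)))
  one <- mk_state(3L, M, list(c(2L, 1L, 5L)))
  expect_equal(classify_coexistence(fake_trajectory(list(three, three), c(0, 5))), "stable")
  expect_equal(classify_coexistence(fake_trajectory(list(three, one), c(0, 5))), "transient_only")
  expect_equal(classify_coexistence(fake_trajectory(list(one, one), c(0, 5))), "none")
})

test_that("ensemble prevalence summaries report mean and standard error", {
  M <- 4L
  stA <- mk_state(1L, M, list(c(1L, 2L, 10L), c(1L, 1L, 10L))) # P1 prevalence 0.5
  stB <- mk_state(1L, M, list(c(1L, 2L, 10L)))                 # P1 prevalence 1.0
  ens <- fake_ensemble(list(fake_trajectory(list(stA, stA), c(0, 5)),
                            fake_trajectory(list(stB, stB), c(0, 5))))
  sp <- summarize_prevalence(ens)
  expect_equal(sp$mean[sp$plasmid == "P1"], 0.75)
  expect_equal(sp$se[sp$plasmid == "P1"], sd(c(0.5, 1)) / sqrt(2))
  expect_true(all(sp$mean >= 0 & sp$mean <= 1))
})

test_that("tidy metric export is long-format with one row per entity", {
  M <- 4L
  st <- mk_state(2L, M, list(c(1L, 1L, 10L), c(2L, 2L, 30L)))
  ens <- fake_ensemble(list(fake_trajectory(list(st, st), c(0, 5))))
  td <- tidy_metrics(ens)
  expect_setequal(unique(td$metric), c("relative_host_abundance", "plasmid_prevalence"))
  expect_equal(td$value[td$metric == "relative_host_abundance" & td$entity == "H2"], 0.75)
  expect_equal(td$value[td$metric == "plasmid_prevalence" & td$entity == "P1"], 0.75)
})
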