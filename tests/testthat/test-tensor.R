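test_that("the two-plasmid transfer column reproduces the worked example", {
  sys <- mini_system()
  tn <- build_propensity_tensor(sys$I, sys$P)
  # donor [1,1] -> recipient [0,0]; transfer of both plasmids has raw 1/2
  col <- tensor_column(tn, donor_profile = 4L, rec_host = 1L, rec_profile = 1L)
  expect_equal(nrow(col), 3L)
  expect_equal(col$raw[col$tc_profile == 4L], 0.5)
  # after normalization: single transfers 0.4 each, double transfer 0.2
  expect_equal(col$weight[order(col$tc_profile)], c(0.4, 0.4, 0.2))
})

test_that("columns without a transferable plasmid are absent", {
  sys <- mini_system()
  tn <- build_propensity_tensor(sys$I, sys$P)
  # donor [1,0] -> recipient [1,0]: recipient already has everything
  expect_equal(nrow(tensor_column(tn, 2L, 1L, 2L)), 0L)
})

test_that("every non-empty column is normalized to 1 in all nine canonical cells", {
  for (nm in names(canonical_cells())) {
    cell <- canonical_cells()[[nm]]
    tn <- build_propensity_tensor(cell$I, cell$P)
    if (nrow(tn) == 0L) next
    key <- paste(tn$donor_profile, tn$rec_host, tn$rec_profile)
    sums <- tapply(tn$weight, key, sum)
    expect_true(all(abs(sums - 1) < 1e-12), info = nm)
    expect_true(all(tn$weight >= 0), info = nm)
  }
})

test_that("tensor construction agrees entry-by-entry with the brute-force oracle", {
  cells <- canonical_cells()
  for (nm in names(cells)) {
    a <- build_propensity_tensor(cells[[nm]]$I, cells[[nm]]$P)
    b <- brute_force_tensor(cells[[nm]]$I, cells[[nm]]$P)
    ka <- paste(a$donor_profile, a$rec_host, a$rec_profile, a$tc_profile)
    kb <- paste(b$donor_profile, b$rec_host, b$rec_profile, b$tc_profile)
    expect_setequal(ka, kb)
    m <- match(ka, kb)
    expect_equal(a$weight, b$weight[m], info = nm)
    expect_equal(a$raw, b$raw[m], info = nm)
  }
  # the mini system too, including its worked element
  sys <- mini_system()
  bb <- brute_force_tensor(sys$I, sys$P)
  expect_equal(tensor_column(bb, 4L, 1L, 1L)$raw[tensor_column(bb, 4L, 1L, 1L)$tc_profile == 4L], 0.5)
})

test_that("structured compatibility prunes feasible profiles as enumerated", {
  If <- canonical_I("full")
  # hub: free + 4 singles + 3 hub pairs = 8 of 16
  sh <- summarize_structure(If, canonical_P("hub", hub = 1L))
  expect_equal(unname(sh$feasible_profiles), rep(8L, 3L))
  # modular: free + 4 singles + 2 within-module pairs = 7 of 16
  sm <- summarize_structure(If, canonical_P("modular"))
  expect_equal(unname(sm$feasible_profiles), rep(7L, 3L))
  # no hub-P feasible profile contains two non-hub plasmids
  Ph <- canonical_P("hub", hub = 1L)
  cat4 <- enumerate_profiles(4L)
  for (r in seq_len(16L)) {
    if (profile_feasible(cat4[r, ], 1L, If, Ph)) {
      expect_lte(sum(cat4[r, -1L]), 1L)
    }
  }
})

test_that("transfer lists cover within-host transfer and honor the infection network", {
  If <- canonical_I("full")
  Pf <- canonical_P("full")
  lists <- build_transfer_lists(If, Pf)
  p1 <- profile_index(c(1L, 0L, 0L, 0L))
  rec <- lists$recipients[[p1]]
  expect_true(any(rec$host == 1L & rec$profile == 1L))   # within-host, plasmid-free
  expect_false(any(rec$profile == p1))                   # recipient lacking nothing

  Im <- canonical_I("modular")
  lm <- build_transfer_lists(Im, Pf)
  expect_false(any(lm$recipients[[p1]]$host == 3L))      # P1 cannot reach H3

  # every donor is a non-empty feasible profile; every recipient has a column
  tn <- build_propensity_tensor(Im, Pf)
  expect_true(all(lm$donors$profile != 1L))
  for (p in unique(lm$donors$profile)) {
    rec <- lm$recipients[[p]]
    for (j in seq_len(nrow(rec))) {
      expect_gt(nrow(tensor_column(tn, p, rec$host[j], rec$profile[j])), 0L)
    }
  }
})
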