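test_that("replicate profiles average arithmetically with zero-fill", {
  p <- fraction_profile(c("t1", "t1"), a13H = c(0.04, 0.06),
                        a13L = c(0.01, 0.03), a12H = c(0, 0.002),
                        a12L = c(0.001, 0.001))
  m <- mean_profile(p)
  expect_equal(m$a13H, 0.05)
  expect_equal(m$a13L, 0.02)
  expect_equal(m$a12H, 0.001)

  single <- fraction_profile("t2", 0.1, 0.01, 0.001, 0.002)
  expect_equal(mean_profile(single), single)

  # taxon seen in 1 of 2 replicates at 0.02: absent replicate contributes 0
  p2 <- fraction_profile(c("t3", "t3"), a13H = c(0.02, 0), a13L = 0,
                         a12H = 0, a12L = 0)
  expect_equal(mean_profile(p2)$a13H, 0.01)

  expect_error(mean_profile(p[0, ]), "empty")
  expect_error(mean_profile(fraction_profile(c("a", "b"), 0.1, 0, 0, 0)),
               "single taxon")
})

test_that("the printed decision rule is applied with the stated strictness", {
  params10 <- call_params(floor = 0.001, k = 10)
  # clear positive
  c1 <- call_taxon(fraction_profile("t", 0.05, 0.004, 0.0005, 0.001), params10)
  expect_identical(c1$final_status, "labelled")
  expect_true(all(c1$passes_floor, c1$criterion1, c1$criterion2))

  # k-dependence: fails the 10x heavy/light test, passes the 2x test
  p <- fraction_profile("t", 0.02, 0.005, 0.001, 0.002)
  expect_identical(call_taxon(p, params10)$final_status, "not_labelled")
  expect_identical(call_taxon(p, call_params(k = 2))$final_status, "labelled")

  # floor boundary: exactly 0.1% fails the strict inequality
  pb <- fraction_profile("t", 0.001, 0, 0, 0)
  expect_identical(call_taxon(pb, params10)$final_status, "below_floor")
  expect_false(call_taxon(pb, params10)$passes_floor)

  # 12C heavy exceeding 12C light violates criterion 2
  pc <- call_taxon(fraction_profile("t", 0.05, 0.001, 0.04, 0.01), params10)
  expect_identical(pc$final_status, "not_labelled")
  expect_true(pc$criterion1)
  expect_false(pc$criterion2)

  # a13L = 0 with positive a13H passes the k test at any k
  pz <- fraction_profile("t", 0.01, 0, 0.001, 0.001)
  expect_true(call_taxon(pz, call_params(k = 1000))$criterion2)

  # the 12CH <= 12CL comparison is non-strict: equality passes
  pe <- call_taxon(fraction_profile("t", 0.05, 0.001, 0.002, 0.002), params10)
  expect_identical(pe$final_status, "labelled")
})

test_that("call_taxon agrees with the brute-force oracle on random profiles", {
  prof <- random_profiles(2000, seed = 8)
  for (k in c(2, 10)) {
    params <- call_params(floor = 0.001, k = k)
    got <- call_taxon(fraction_profile(prof$taxon_id, prof$a13H, prof$a13L,
                                       prof$a12H, prof$a12L), params)
    want <- mapply(oracle_labelled, prof$a13H, prof$a13L, prof$a12H,
                   prof$a12L, MoreArgs = list(floor = 0.001, k = k))
    expect_identical(got$labelled, unname(want))
  }
})

test_that("labelled sets shrink weakly as k or the floor increases", {
  prof <- random_profiles(400, seed = 13)
  fp <- fraction_profile(prof$taxon_id, prof$a13H, prof$a13L, prof$a12H,
                         prof$a12L)
  ks <- c(1, 2, 5, 10, 50)
  sets <- lapply(ks, function(k) {
    calls <- call_taxon(fp, call_params(k = k))
    calls$taxon_id[calls$labelled]
  })
  for (i in seq_along(ks)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  floors <- c(0, 0.001, 0.01, 0.1)
  fsets <- lapply(floors, function(f) {
    calls <- call_taxon(fp, call_params(floor = f, k = 2))
    calls$taxon_id[calls$labelled]
  })
  for (i in seq_along(floors)[-1]) {
    expect_true(all(fsets[[i]] %in% fsets[[i - 1]]))
  }
})

test_that("control exclusion removes exactly the intersection, preserving order", {
  mk <- function(ids, labelled_ids) {
    calls <- call_taxon(fraction_profile(ids,
                                         ifelse(ids %in% labelled_ids, 0.05, 0.0001),
                                         0.001, 0.0005, 0.001),
                        call_params(k = 10))
    calls
  }
  test <- mk(c("A", "B", "C", "D"), c("A", "B", "C"))
  ctrl <- mk(c("A", "B", "C", "D"), "B")
  out <- apply_control_exclusion(test, ctrl)
  expect_identical(out$taxon_id, test$taxon_id)
  expect_identical(out$final_status,
                   c("labelled", "excluded_control", "labelled", "below_floor"))

  # empty control leaves the test calls unchanged
  none <- mk(c("A", "B", "C", "D"), character())
  expect_identical(apply_control_exclusion(test, none), test)

  # control superset empties the labelled set
  all_ctrl <- mk(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  out2 <- apply_control_exclusion(test, all_ctrl)
  expect_false(any(out2$final_status == "labelled"))
  # non-labelled statuses are never touched
  expect_identical(out2$final_status[4], "below_floor")
})

test_that("call_experiment validates inputs and names missing fraction classes", {
  ex <- simulate_experiment(sip_sim_config(n_taxa = 30, n_labelled = 3,
                                           n_crossfeeders = 1,
                                           n_autotrophs = 1, seed = 2))
  keep <- ex$samples$fraction_class == "light" |
    ex$samples$isotope == "12C" |
    ex$samples$treatment == "unplanted"
  sub <- ex$samples[keep, ]
  expect_error(call_experiment(ex$abundance[, sub$sample_id], sub),
               "13C-heavy")
  bad_ab <- ex$abundance
  colnames(bad_ab)[1] <- "mystery_sample"
  expect_error(call_experiment(bad_ab, ex$samples), "mystery_sample")
})

test_that("no-signal simulations produce an empty labelled set", {
  cfg <- sip_sim_config(n_taxa = 100, n_labelled = 10, n_crossfeeders = 5,
                        n_autotrophs = 5, enrichment_mean = 1,
                        crossfeed_enrichment_mean = 1,
                        background_leakage = 1, seed = 1)
  calls <- call_experiment(simulate_experiment(cfg),
                           params = call_params(k = 10))
  # false-positive rate bounded at 5% (empty in expectation)
  expect_lte(mean(calls$final_status == "labelled"), 0.05)
})

test_that("strong-signal recovery: the seed-42 design recovers the labelled guild", {
  ex <- simulate_experiment(sip_sim_config(seed = 42))
  calls <- call_experiment(ex, params = call_params(k = 10))
  rz <- calls[calls$treatment == "rhizosphere", ]
  lab <- ex$truth$taxon_id[ex$truth$status == "labelled"]
  recovered <- sum(lab %in% rz$taxon_id[rz$final_status == "labelled"])
  expect_gte(recovered, 18)
})

test_that("floor_per_replicate and voting modes only tighten calls", {
  ex <- simulate_experiment(sip_sim_config(n_taxa = 60, seed = 9,
                                           n_labelled = 6, n_crossfeeders = 2,
                                           n_autotrophs = 2))
  base <- call_experiment(ex, params = call_params(k = 10))
  strict <- call_experiment(ex, params = call_params(k = 10),
                            floor_per_replicate = TRUE)
  expect_true(all(strict$taxon_id[strict$final_status == "labelled"] %in%
                    base$taxon_id[base$final_status == "labelled"]))
  voted <- call_experiment(ex, params = call_params(k = 10), mode = "vote")
  expect_true(all(voted$final_status %in%
                    c("labelled", "not_labelled", "below_floor")))
})
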