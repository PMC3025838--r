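# Resource-limited total rates, proportional allocation and TF weights.

test_that("total transcription is linear in polymerase and saturating in NT", {
  p <- list(k_txs_per_pol = 3e-3, K_NT = 5e8)
  b0 <- resource_budget(1e8, 0, 1e9, 5e4, 1e3)
  expect_equal(total_transcription_rate(b0, p), 0)
  b1 <- resource_budget(1e8, 1e12, 1e9, 5e4, 0)
  expect_equal(total_transcription_rate(b1, p), 0)
  # pol-limited regime: doubling polymerase doubles the flux
  b2 <- resource_budget(1e8, 1e12, 1e9, 5e4, 1e3)
  b3 <- resource_budget(1e8, 1e12, 1e9, 5e4, 2e3)
  expect_equal(total_transcription_rate(b3, p),
               2 * total_transcription_rate(b2, p), tolerance = 1e-9)
  # monotone non-decreasing in both limiting resources
  expect_gte(total_transcription_rate(b2, p),
             total_transcription_rate(resource_budget(1e8, 1e8, 1e9, 5e4,
                                                      1e3), p))
})

test_that("total translation vanishes without ribosomes or amino acids", {
  p <- list(k_txl_per_ribosome = 2e-2, K_AA = 5e5)
  expect_equal(total_translation_rate(
    resource_budget(0, 1e9, 1e9, 5e4, 1e3), p), 0)
  expect_equal(total_translation_rate(
    resource_budget(1e8, 1e9, 1e9, 0, 1e3), p), 0)
  expect_gt(total_translation_rate(
    resource_budget(1e8, 1e9, 1e9, 5e4, 1e3), p), 0)
})

test_that("allocation partitions the total exactly and proportionally", {
  expect_equal(unname(allocate_flux(100, c(a = 1, b = 1, c = 2))),
               c(25, 25, 50))
  expect_equal(unname(allocate_flux(9, c(a = 3, b = 3, c = 3))),
               c(3, 3, 3))
  expect_equal(unname(allocate_flux(5, c(a = 0, b = 0))), c(0, 0))
  expect_error(allocate_flux(1, c(a = -1)), "non-negative")
  set.seed(123)
  for (i in 1:1000) {
    w <- runif(sample(1:8, 1), 0, 10)
    tot <- runif(1, 0, 1e6)
    expect_equal(sum(allocate_flux(tot, w)), tot, tolerance = 1e-12)
  }
})

test_that("TF weights multiply locus visibility by summed factor amounts", {
  expect_equal(tf_weight(1, 500), 500)
  expect_equal(tf_weight(0, c(1e5, 2e5)), 0)       # condensed chromatin
  expect_equal(tf_weight(1, constitutive = 7), 7)  # purely constitutive
  expect_equal(tf_weight(0.5, c(10, 20), 30), 30)
})

test_that("compiled allocation members share the capacity exactly", {
  con <- new_construct("pool", "bookkeeping")
  con <- add_state(con, "res", 1000)
  con <- add_state(con, "a", 0)
  con <- add_state(con, "b", 0)
  con <- add_state(con, "wa", 30)
  con <- add_state(con, "wb", 10)
  con <- add_rate(con, "mk_a", 1, law_kind = "allocation", group = "g",
                  weight_states = "wa", sinks = "a")
  con <- add_rate(con, "mk_b", 2, law_kind = "allocation", group = "g",
                  weight_states = "wb", sinks = "b")
  m <- compile_model(list(con),
                     groups = list(g = list(k = 5, factors = list(
                       law_factor("pool.res", "sat", 500)))))
  f <- m$fluxes(0, initial_state(m))
  cap <- 5 * 1000 / (500 + 1000)
  expect_equal(sum(f[c("pool.mk_a", "pool.mk_b")]), cap, tolerance = 1e-12)
  # member rate constants act as relative efficiencies
  expect_equal(unname(f[["pool.mk_a"]] / f[["pool.mk_b"]]),
               (1 * 30) / (2 * 10), tolerance = 1e-12)
})

test_that("reducing a limiting resource never increases an allocation flux", {
  con <- new_construct("pool", "bookkeeping")
  con <- add_state(con, "res", 1000)
  con <- add_state(con, "a", 0)
  con <- add_state(con, "wa", 30)
  con <- add_rate(con, "mk_a", 1, law_kind = "allocation", group = "g",
                  weight_states = "wa", sinks = "a")
  m <- compile_model(list(con),
                     groups = list(g = list(k = 5, factors = list(
                       law_factor("pool.res", "sat", 500)))))
  x <- initial_state(m)
  f1 <- m$fluxes(0, x)[["pool.mk_a"]]
  x["pool.res"] <- 400
  f2 <- m$fluxes(0, x)[["pool.mk_a"]]
  expect_lt(f2, f1)
})
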