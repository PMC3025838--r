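# Integration, stimulus events and the division transformation.

toy_div_model <- function() {
  con <- new_construct("c", "bookkeeping")
  con <- add_state(con, "grow", 10)
  con <- add_state(con, "dna", 100)
  con <- add_state(con, "slots", 15, dimensionless = TRUE, halve = FALSE)
  con <- add_rate(con, "synth", 0.5, sinks = "grow")
  m <- compile_model(list(con))
  m$division <- division_spec("c.grow", threshold = 20,
                              dna_state = "c.dna", genome_nt = 50,
                              reset = function(x, model) {
                                x[model$state_index[["c.slots"]]] <- 15
                                x
                              })
  m
}

test_that("a zero-rate model yields a constant trajectory", {
  con <- add_state(add_state(new_construct("z", "bookkeeping"), "a", 3),
                   "b", 7)
  con <- add_rate(con, "r", 0, reactants = "a", sources = "a", sinks = "b")
  m <- compile_model(list(con))
  tr <- simulate_model(m, t_end = 1000)
  expect_equal(unname(tr$amounts[, ncol(tr$amounts)]), c(3, 7))
})

test_that("stimulus schedules validate ordering and apply step changes", {
  expect_error(stimulus_schedule(c(10, 5), c("mitogen", "adhesion"),
                                 c(1, 1)), "non-decreasing")
  con <- new_construct("signals", "bookkeeping")
  con <- add_state(con, "mitogen", 0, dimensionless = TRUE)
  con <- add_state(con, "x", 1)
  con <- add_rate(con, "drive", 0.1, modifiers = "mitogen", sinks = "x")
  m <- compile_model(list(con))
  m$signals <- list(mitogen = "signals.mitogen")
  sched <- stimulus_schedule(50, "mitogen", 1)
  tr <- simulate_model(m, schedule = sched, t_end = 100,
                       solver = solver_settings(dt_report = 1))
  expect_equal(unname(tr$amounts["signals.x", tr$times <= 50]),
               rep(1, sum(tr$times <= 50)), tolerance = 1e-8)
  expect_gt(tr$amounts["signals.x", ncol(tr$amounts)], 1)
  expect_true(any(tr$event_log$kind == "stimulus"))
})

test_that("division halves extensive states and leaves concentrations unchanged", {
  m <- toy_div_model()
  x <- initial_state(m)
  x["c.dna"] <- 95   # replicated
  y <- apply_division(x, m)
  expect_equal(unname(y["c.grow"]), 5)
  expect_equal(unname(y["c.dna"]), 47.5)
  expect_equal(unname(y["c.slots"]), 15)  # bookkeeping reset, not halved
})

test_that("dividing with unreplicated DNA warns", {
  m <- toy_div_model()
  x <- initial_state(m)   # dna = 100 > 1.8 * 50, fine
  expect_silent(apply_division(x, m))
  x["c.dna"] <- 60
  expect_warning(apply_division(x, m), "pathological")
})

test_that("the division event fires on the root crossing and is guarded by DNA", {
  m <- toy_div_model()
  x <- initial_state(m)
  x["c.dna"] <- 95
  tr <- simulate_model(m, t_end = 100, x0 = x,
                       solver = solver_settings(dt_report = 0.5))
  div <- tr$event_log[tr$event_log$kind == "division", ]
  expect_equal(nrow(div), 1L)   # after halving, dna < 1.8 genomes: no refire
  expect_lt(abs(div$time - 20), 2)
  expect_true(any(tr$event_log$kind == "root_skipped"))
})

test_that("concentration-normalized fluxes are invariant under halving", {
  mm <- build_machinery_model()
  m <- compile_model(mm$constructs, groups = mm$groups, size = mm$size)
  x <- initial_state(m)
  f1 <- m$fluxes(0, x)
  f2 <- m$fluxes(0, 0.5 * x)
  scaled <- vapply(m$rates, function(r) isTRUE(r$scale_size), TRUE)
  const_w <- vapply(m$rates, function(r)
    !is.null(r$group) && r$weight_const > 0, TRUE)
  nz <- f1 > 0 & scaled & !const_w
  expect_equal(unname(f2[nz] / f1[nz]), rep(0.5, sum(nz)),
               tolerance = 1e-4)
})
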