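# Dynamic behavior of the calibrated model.  The reference 10-day
# mitogen simulation and the quiescent control are shared across files
# through helper-model.R.

test_that("the quiescent state holds: drift below 1% over 10 days", {
  g0 <- cached_g0_run()
  x0 <- g0$amounts[, 1]
  x1 <- g0$amounts[, ncol(g0$amounts)]
  big <- pmax(x0, x1) > 10          # pools; ignore near-empty states
  drift <- abs(x1 - x0)[big] / pmax(x0[big], 10)
  expect_lt(max(drift), 0.01)
})

test_that("mitogen triggers RNA-polymerase release from cycC/Cdk8", {
  tr <- cached_reference_run()
  seq0 <- traj_amount(tr, "rnapol.sequestered")
  act <- traj_amount(tr, "rnapol.active") +
    traj_amount(tr, "rnapol.transcribing")
  t1d <- which.min(abs(tr$times - 86400))
  expect_gt(seq0[1], 3 * act[1])            # G0: most pol held inactive
  expect_lt(seq0[t1d], 0.5 * seq0[1])       # released within a day
  expect_gt(act[t1d], 2 * act[1])
})

test_that("the cell exits quiescence and divides", {
  tr <- cached_reference_run()
  divs <- tr$event_log[tr$event_log$kind == "division", ]
  expect_gte(nrow(divs), 1)
  # every division halves the cell (log details carry 3 decimals)
  pre <- as.numeric(sub("size ([0-9.]+) -> .*", "\\1", divs$detail))
  post <- as.numeric(sub(".* -> ([0-9.]+)$", "\\1", divs$detail))
  expect_equal(pre / post, rep(2, nrow(divs)), tolerance = 0.01)
})

test_that("division halves every extensive state of the full model", {
  m <- cached_model()
  tr <- cached_reference_run()
  x <- tr$amounts[, which.min(abs(tr$times - 86400 * 1.3))]
  x[m$state_index[["dna.nt"]]] <- 2 * m$division$genome_nt
  y <- apply_division(x, m)
  h <- m$states$halve
  # the reset hook then strips replication complexes from the chromatin,
  # so exclude the states it rewrites from the exact-halving check
  reset_states <- c("rc.dna_b", "rc.lic", "rc.trav", "dnapol.nuc",
                    "dnapol.on_dna")
  h[m$state_index[reset_states]] <- FALSE
  expect_equal(unname(y[h] / pmax(x[h], 1e-12))[x[h] > 0],
               rep(0.5, sum(x[h] > 0)), tolerance = 1e-9)
  # chromatin stripping: licensed/traversing complexes delicensed, the
  # polymerase released, the origin counter rebuilt
  ix <- m$state_index
  expect_equal(unname(y[ix[["rc.lic"]]]), 0)
  expect_equal(unname(y[ix[["rc.trav"]]]), 0)
  expect_equal(unname(y[ix[["rc.dna_b"]]]),
               unname(sum(x[ix[reset_states[1:3]]]) / 2), tolerance = 1e-9)
  # bookkeeping states are reset, not halved
  expect_equal(unname(y[ix[["signals.mitogen"]]]),
               unname(x[ix[["signals.mitogen"]]]))
  expect_equal(unname(y[ix[["oric.fired"]]]), 0)
})

test_that("DNA goes one to two genome equivalents and halves at division", {
  tr <- cached_reference_run()
  m <- cached_model()
  genome <- m$division$genome_nt
  dna <- traj_amount(tr, "dna.nt") / genome
  expect_lt(abs(dna[1] - 1), 0.05)
  expect_gt(max(dna), 1.9)
  div1 <- attr(cached_reference_timeline(), "divisions")[1]
  after <- dna[which(tr$times > div1)[1]]
  expect_lt(abs(after - 1), 0.15)
})

test_that("bound replication complexes never exceed the origin capacity", {
  tr <- cached_reference_run()
  bound <- colSums(tr$amounts[c("rc.dna_b", "rc.lic", "rc.trav"), ])
  expect_lte(max(bound), 15000 * 1.001)
  expect_gt(max(bound), 0.4 * 15000)   # and the cap is approached in S
})

test_that("first-cycle events are ordered: mitogen, S onset, cascade, division", {
  tl <- cached_reference_timeline()
  onset <- attr(tl, "mitogen_onset")
  s1 <- attr(tl, "s_intervals")[1, ]
  div1 <- attr(tl, "divisions")[1]
  casc <- attr(tl, "cascades")
  casc1 <- casc[casc > s1[2]][1]
  expect_lt(onset, s1[1])
  expect_lt(s1[1], s1[2])
  expect_lt(s1[2], casc1)
  expect_lt(casc1, div1)
})

test_that("the timeline is contiguous and M intervals end at divisions", {
  tl <- cached_reference_timeline()
  expect_equal(tl$start[-1], tl$end[-nrow(tl)])
  m_rows <- which(tl$phase == "M")
  expect_true(all(tl$end[m_rows] %in% attr(tl, "divisions")))
})

test_that("phase boundaries are insensitive to halved solver tolerances", {
  m <- cached_model()
  sched <- stimulus_schedule(c(2e4, 2e4), c("mitogen", "adhesion"),
                             c(1, 1))
  horizon <- 1.45 * 86400             # covers G1 and S of the first cycle
  t1 <- simulate_model(m, sched, t_end = horizon)
  t2 <- simulate_model(m, sched, t_end = horizon,
                       solver = solver_settings(rtol = 5e-7,
                                                atol = 5e-4))
  s1 <- attr(detect_phases(t1), "s_intervals")
  s2 <- attr(detect_phases(t2), "s_intervals")
  expect_gte(nrow(s1), 1)
  expect_gte(nrow(s2), 1)
  expect_lt(abs(s1[1, 1] - s2[1, 1]) / s1[1, 1], 0.01)
  expect_lt(abs(s1[1, 2] - s2[1, 2]) / s1[1, 2], 0.01)
})
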