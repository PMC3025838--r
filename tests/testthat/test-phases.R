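# Phase detection on synthetic trajectories with known structure.

synth_traj <- function(times, dna, cycb, divisions = numeric(),
                       onset = NA) {
  ev <- data.frame(time = divisions,
                   kind = rep("division", length(divisions)),
                   detail = rep("", length(divisions)),
                   stringsAsFactors = FALSE)
  if (!is.na(onset))
    ev <- rbind(data.frame(time = onset, kind = "stimulus",
                           detail = "mitogen=1", stringsAsFactors = FALSE),
                ev)
  model <- list(phase_states = list(dna = "dna.nt",
                                    cycb_active = "cycb.cdk1_n"))
  am <- rbind(dna, cycb)
  rownames(am) <- c("dna.nt", "cycb.cdk1_n")
  structure(list(times = times, amounts = am, event_log = ev,
                 model = model), class = "Trajectory")
}

test_that("a trajectory with constant DNA has no S phase", {
  tt <- seq(0, 86400, by = 600)
  tr <- synth_traj(tt, rep(100, length(tt)), rep(0, length(tt)))
  tl <- detect_phases(tr)
  expect_false("S" %in% tl$phase)
})

test_that("S spans the DNA-synthesis ramp; G2/M split at the cascade", {
  tt <- seq(0, 10 * 86400, by = 600)
  h <- 3600
  onset <- 2e4
  s0 <- onset + 24 * h; s1 <- s0 + 8 * h       # S: 8 h
  casc <- s1 + 12 * h                          # G2: 12 h
  div <- casc + 4 * h                          # M: 4 h
  dna <- 100 + 100 * pmin(pmax((tt - s0) / (s1 - s0), 0), 1)
  dna[tt >= div] <- 100
  cycb <- ifelse(tt >= casc & tt < div, 1000, 1)
  tl <- detect_phases(synth_traj(tt, dna, cycb, divisions = div,
                                 onset = onset))
  expect_equal(tl$phase[1:5], c("G0", "G1", "S", "G2", "M"))
  sm <- phase_summary(tl)
  expect_equal(sm$first_g1_h, 24, tolerance = 0.05)
  expect_equal(sm$s_first_h, 8, tolerance = 0.1)
  expect_equal(sm$first_g2_h, 12, tolerance = 0.05)
  expect_equal(sm$m_h, 4, tolerance = 0.05)
  expect_equal(sm$first_division_d, div / 86400, tolerance = 1e-6)
  # the timeline is contiguous and non-overlapping, every division ends M
  expect_equal(tl$start[-1], tl$end[-nrow(tl)])
  expect_true(all(tl$end[tl$phase == "M"] %in% attr(tl, "divisions")))
})

test_that("phase summaries separate first-cycle from steady cycling", {
  tt <- seq(0, 8 * 86400, by = 600)
  h <- 3600
  onset <- 2e4
  dna <- rep(100, length(tt)); cycb <- rep(1, length(tt))
  divs <- c(); cascs <- c()
  cur <- onset
  g1 <- 24 * h
  for (cyc in 1:4) {
    s0 <- cur + g1; s1 <- s0 + 8 * h; ca <- s1 + 7 * h; dv <- ca + 4 * h
    if (dv > max(tt)) break
    idx <- tt >= s0 & tt < s1
    dna[tt >= s0] <- dna[which(tt >= s0)[1] - 1] +
      100 * pmin(pmax((tt[tt >= s0] - s0) / (s1 - s0), 0), 1)
    dna[tt >= dv] <- 100
    cycb[tt >= ca & tt < dv] <- 1000
    divs <- c(divs, dv); cascs <- c(cascs, ca)
    cur <- dv
    g1 <- 15 * h
  }
  tl <- detect_phases(synth_traj(tt, dna, cycb, divisions = divs,
                                 onset = onset))
  sm <- phase_summary(tl)
  expect_equal(sm$first_g1_h, 24, tolerance = 0.1)
  expect_equal(sm$g1_h, 15, tolerance = 0.1)
  expect_equal(sm$s_h, 8, tolerance = 0.2)
  expect_equal(sm$g2_h, 7, tolerance = 0.2)
  expect_equal(sm$period_d, (15 + 8 + 7 + 4) / 24, tolerance = 0.02)
})

test_that("timeline and trajectory exports are tidy and faithful", {
  tt <- seq(0, 86400, by = 600)
  tr <- synth_traj(tt, 100 + tt / 1000, rep(0, length(tt)))
  tl <- detect_phases(tr)
  f <- tempfile(fileext = ".tsv")
  df <- timeline_table(tl, f)
  back <- utils::read.delim(f)
  expect_equal(back$phase, tl$phase)
  expect_equal(back$start_s, tl$start)
  unlink(f)
  tab <- trajectory_table(tr)
  expect_equal(nrow(tab), 2 * length(tt))
  expect_setequal(unique(tab$construct), c("dna", "cycb"))
  expect_equal(tab$amount[tab$construct == "dna"][1], 100)
})
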