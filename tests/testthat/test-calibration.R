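# Constraint scoring and the seeded generate-and-test search.

fake_traj <- function(times, amounts) {
  structure(list(times = times, amounts = amounts,
                 event_log = data.frame(time = numeric(),
                                        kind = character(),
                                        detail = character()),
                 model = NULL), class = "Trajectory")
}

fake_tl <- function(df = data.frame(phase = character(), start = numeric(),
                                    end = numeric()),
                    divisions = numeric(), cascades = numeric(),
                    s_intervals = cbind(start = numeric(),
                                        end = numeric())) {
  structure(df, class = c("PhaseTimeline", "data.frame"),
            divisions = divisions, cascades = cascades,
            s_intervals = s_intervals, t_end = if (nrow(df)) max(df$end)
            else 0)
}

test_that("an empty constraint set scores zero", {
  traj <- fake_traj(0:10, matrix(1, 1, 11, dimnames = list("a.x", NULL)))
  out <- evaluate_constraints(traj, constraint_set(list()), fake_tl())
  expect_equal(out$score, 0)
})

test_that("a window violated by twice its half-width scores exactly 2", {
  traj <- fake_traj(0:10, matrix(30, 1, 11, dimnames = list("a.x", NULL)))
  cs <- constraint_set(constraint("pool_size", "a.x", c(10, 20)))
  out <- evaluate_constraints(traj, cs, fake_tl())
  expect_equal(out$score, 2)        # value 30 exceeds hi=20 by 10 = 2 * 5
  expect_false(out$report$pass)
})

test_that("an unmeasurable target fails with a reason", {
  traj <- fake_traj(0:10, matrix(1, 1, 11, dimnames = list("a.x", NULL)))
  cs <- constraint_set(constraint("phase_duration", "S", c(6.4, 9.6)))
  out <- evaluate_constraints(traj, cs, fake_tl())
  expect_equal(out$score, 1)
  expect_match(out$report$reason, "unmeasurable")
})

test_that("enlarging every window can never increase the score", {
  traj <- fake_traj(0:10, matrix(30, 1, 11, dimnames = list("a.x", NULL)))
  narrow <- constraint_set(constraint("pool_size", "a.x", c(10, 20)))
  wide <- constraint_set(constraint("pool_size", "a.x", c(5, 25)))
  s1 <- evaluate_constraints(traj, narrow, fake_tl())$score
  s2 <- evaluate_constraints(traj, wide, fake_tl())$score
  expect_lte(s2, s1)
})

# toy objective with an analytically known feasible region: a
# synthesis/decay pool has steady state k_synth / k_decay; the constraint
# asks for a steady level in [50, 200], so the feasible region is the band
# 50 <= k_synth / k_decay <= 200 of the (k_synth, k_decay) plane.
toy_objective <- function(par) {
  steady <- par$k_synth / par$k_decay
  lo <- 50; hi <- 200; half <- (hi - lo) / 2
  if (steady < lo) (lo - steady) / half
  else if (steady > hi) (steady - hi) / half
  else 0
}

test_that("budget one returns the single sampled set; seeds reproduce traces", {
  sp <- list(k_synth = c(0.1, 100), k_decay = c(1e-3, 1))
  r1 <- generate_and_test(toy_objective, sp, seed = 4, budget = 1)
  expect_equal(nrow(r1$trace), 1L)
  r2 <- generate_and_test(toy_objective, sp, seed = 4, budget = 25)
  r3 <- generate_and_test(toy_objective, sp, seed = 4, budget = 25)
  expect_identical(r2$trace, r3$trace)
  r4 <- generate_and_test(toy_objective, sp, seed = 5, budget = 25)
  expect_false(identical(r2$trace, r4$trace))
})

test_that("the search finds the feasible region for nearly every seed", {
  sp <- list(k_synth = c(0.1, 100), k_decay = c(1e-3, 1))
  hits <- vapply(1:100, function(seed)
    generate_and_test(toy_objective, sp, seed = seed,
                      budget = 200)$best_score == 0, TRUE)
  expect_gte(sum(hits), 95)
})

test_that("failing objectives are scored Inf, not crashed", {
  boom <- function(par) if (par$a > 1) stop("unstable") else 0.5
  r <- generate_and_test(boom, list(a = c(0.5, 2)), seed = 1, budget = 20)
  expect_true(all(is.finite(r$trace$score) | r$trace$score == Inf))
  expect_lte(r$best_score, 0.5)
})

test_that("sensitivity scan: zero perturbation gives zero deltas, dead parameters too", {
  obj <- function(p) abs(p$a - 1) + 0 * p$dead
  params <- list(a = 1.5, dead = 3)
  s0 <- sensitivity_scan(obj, params, perturbation = 0)
  expect_equal(s0$delta, c(0, 0))
  s <- sensitivity_scan(obj, params, perturbation = 0.2)
  expect_equal(s$delta[s$parameter == "dead"], 0)
  expect_gt(s$delta[s$parameter == "a"], 0)
})
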