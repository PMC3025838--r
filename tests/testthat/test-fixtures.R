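# Toy fixtures: the figure construct and closed-form first-order chains.

test_that("the figure fixture has the canonical 4-state / 8-rate census", {
  con <- make_fig1_construct()
  expect_equal(unname(census(con)), c(4L, 8L))
  expect_setequal(names(con$rates),
                  c("txl_p", "fold_p", "bind_p", "unbind_p", "dk_p_unfold",
                    "dk_p_cytosol", "dk_p_in_use", "dispose_p"))
})

test_that("with synthesis and disposal zeroed, total protein mass is conserved", {
  con <- make_fig1_construct(params = list(txl_p = 0, dispose_p = 0,
                                           dk_p_unfold = 0,
                                           dk_p_cytosol = 5e-3,
                                           dk_p_in_use = 5e-3),
                             x0 = list(p_unfold = 10, p_cytosol = 5))
  m <- compile_model(list(con))
  tr <- simulate_model(m, t_end = 500,
                       solver = solver_settings(atol = 1e-10,
                                                dt_report = 10))
  expect_equal(max(abs(colSums(tr$amounts) - 15)), 0, tolerance = 1e-6)
})

test_that("the chain refuses repeated rate constants", {
  expect_error(make_linear_chain(3, c(1, 1)), "repeated")
})

test_that("simulated chains match the closed-form solution", {
  ch <- make_linear_chain(2, 1)
  m <- compile_model(list(ch))
  tr <- simulate_model(m, t_end = 5,
                       solver = solver_settings(rtol = 1e-8, atol = 1e-12,
                                                dt_report = 0.05))
  expect_equal(unname(tr$amounts["chain.s1", ]),
               exp(-tr$times), tolerance = 1e-6)
  expect_equal(unname(tr$amounts["chain.s2", ]),
               1 - exp(-tr$times), tolerance = 1e-6)

  set.seed(5)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    k <- sort(runif(n - 1, 0.1, 2))
    x0 <- runif(n, 0, 2)
    ch <- make_linear_chain(n, k, x0)
    m <- compile_model(list(ch))
    tr <- simulate_model(m, t_end = 8,
                         solver = solver_settings(rtol = 1e-8,
                                                  atol = 1e-12,
                                                  dt_report = 0.08))
    sol <- attr(ch, "solution")(tr$times)
    expect_lt(max(abs(t(tr$amounts) - sol)), 1e-7 * 10)
    expect_equal(unname(colSums(tr$amounts)), rep(sum(x0),
                                                  length(tr$times)),
                 tolerance = 1e-8)
  }
})

test_that("fixtures round-trip exactly through the model config format", {
  f <- tempfile(fileext = ".yaml")
  for (con in list(make_fig1_construct(x0 = list(p_unfold = 2.7182818)),
                   make_linear_chain(4, c(0.3141592, 1.5, 2.71)))) {
    write_model_config(list(con), f)
    back <- read_model_config(f)[[1]]
    attr(con, "solution") <- NULL
    expect_identical(back, con)
  }
  unlink(f)
})
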