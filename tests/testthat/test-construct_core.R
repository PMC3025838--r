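# Construct definition, validation, rate-law evaluation and compilation.

test_that("state registration enforces naming and non-negativity", {
  con <- new_construct("p", "protein")
  con <- add_state(con, "x", 0)
  expect_equal(census(con)[["states"]], 1L)
  expect_error(add_state(con, "x", 1), "duplicate")
  expect_error(add_state(con, "y", -1), "non-negative")
})

test_that("the canonical lifecycle census is enforced with flagged exceptions", {
  con <- new_construct("p", "protein")
  for (s in c("unfold", "cytosol", "nucleus", "bound", "pho", "ubq",
              "trash"))
    con <- add_state(con, s, 0)
  expect_silent(validate_construct(con))
  short <- new_construct("q", "protein")
  short <- add_state(short, "only", 0)
  expect_error(validate_construct(short), "7 expected")
  expect_silent(validate_construct(flag_exception(short, "minimal")))
  m <- new_construct("m", "mrna")
  for (s in c("nascent", "nuclear", "cytosol", "bound", "trash"))
    m <- add_state(m, s, 0)
  expect_silent(validate_construct(m))
})

test_that("rate registration rejects dangling references and negative k", {
  con <- add_state(new_construct("c", "bookkeeping"), "a", 1)
  expect_error(add_rate(con, "r", -1, reactants = "a"), ">= 0")
  con <- add_rate(con, "r", 1, reactants = "b", sources = "b")
  expect_error(validate_construct(con), "unknown states")
  expect_error(compile_model(list(
    add_rate(add_state(new_construct("d", "bookkeeping"), "a", 1),
             "r", 1, modifiers = "other.missing"))),
    "unresolved|missing")
})

test_that("mass-action flux is the product of k and reactant amounts", {
  con <- add_state(add_state(new_construct("c", "bookkeeping"), "a", 3),
                   "b", 4)
  con <- add_rate(con, "r", 2, reactants = c("a", "b"),
                  sources = c("a", "b"), sinks = "a")
  expect_equal(evaluate_rate(con$rates$r, c(a = 3, b = 4)), 24)
  expect_equal(evaluate_rate(con$rates$r, c(a = 0, b = 4)), 0)
  expect_error(evaluate_rate(con$rates$r, c(a = 3)), "missing amount")
})

test_that("flux agrees with an independently expanded symbolic law", {
  set.seed(41)
  for (i in 1:100) {
    con <- random_construct()
    sz <- runif(1, 0.5, 2)
    x <- stats::setNames(runif(length(con$states), 0, 50),
                         names(con$states))
    for (r in con$rates) {
      got <- evaluate_rate(r, x, size = sz)
      rq <- within_rate_qualified(r, con$name)
      xq <- stats::setNames(as.list(unname(x)),
                            paste(con$name, names(x), sep = "."))
      want <- symbolic_flux(rq, xq, sz)
      expect_equal(got, want, tolerance = 1e-12)
      expect_gte(got, 0)
    }
  }
})

test_that("doubling one rate constant exactly doubles its flux", {
  set.seed(7)
  con <- random_construct(4, 4)
  x <- stats::setNames(runif(4, 1, 10), names(con$states))
  for (r in con$rates) {
    r2 <- r; r2$k <- 2 * r$k
    expect_equal(evaluate_rate(r2, x), 2 * evaluate_rate(r, x))
  }
})

test_that("compiled rhs equals S %*% fluxes and the brute-force oracle", {
  set.seed(99)
  for (i in 1:100) {
    con <- random_construct()
    m <- compile_model(list(con))
    x <- stats::setNames(runif(nrow(m$states), 0, 50), m$states$qname)
    rhs <- m$rhs(0, x)
    expect_equal(rhs, as.vector(m$S %*% m$fluxes(0, x)), tolerance = 1e-14)
    want <- brute_force_rhs(con, x)
    expect_equal(unname(rhs), unname(want[m$states$qname]),
                 tolerance = 1e-12)
  }
})

test_that("an empty model compiles to the zero function", {
  m <- compile_model(list())
  expect_length(m$rhs(0, numeric(0)), 0)
})

test_that("zero rate constants give an identically zero rhs", {
  con <- make_fig1_construct(params = list(txl_p = 0, fold_p = 0,
                                           bind_p = 0, unbind_p = 0,
                                           dk_p_unfold = 0,
                                           dk_p_cytosol = 0,
                                           dk_p_in_use = 0, dispose_p = 0),
                             x0 = list(p_unfold = 5, p_cytosol = 7))
  m <- compile_model(list(con))
  expect_equal(m$rhs(0, initial_state(m)), rep(0, 4))
})

test_that("the canonical figure construct wires p_cytosol correctly", {
  con <- make_fig1_construct(x0 = list(p_unfold = 10, p_cytosol = 5,
                                       p_in_use = 2))
  m <- compile_model(list(con))
  x <- initial_state(m)
  f <- m$fluxes(0, x)
  want <- f[["p.fold_p"]] + f[["p.unbind_p"]] - f[["p.bind_p"]] -
    f[["p.dk_p_cytosol"]]
  expect_equal(m$rhs(0, x)[m$state_index[["p.p_cytosol"]]], want)
})

test_that("trajectories from non-negative starts remain non-negative", {
  set.seed(11)
  for (i in 1:5) {
    con <- random_construct(4, 5)
    m <- compile_model(list(con))
    tr <- simulate_model(m, t_end = 50,
                         solver = solver_settings(dt_report = 1))
    expect_gte(min(tr$amounts), 0)
  }
})

test_that("moiety conservation reporting distinguishes boundaries", {
  con <- make_fig1_construct()
  m <- compile_model(list(con))
  w <- stats::setNames(rep(1, 4), m$states$qname)
  cc <- check_conservation(m, w,
                           boundary = c("p.txl_p", "p.dispose_p"))
  expect_true(attr(cc, "conserved"))
  expect_setequal(cc$rate, c("p.txl_p", "p.dispose_p"))
  cc2 <- check_conservation(m, w)
  expect_false(attr(cc2, "conserved"))
})
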