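# The basic-cellular-machinery construct set.

test_that("the default machinery census is 41 states and 69 rates", {
  mm <- build_machinery_model()
  expect_equal(mm$state_count, 41L)
  expect_equal(mm$rate_count, 69L)
  m <- compile_model(mm$constructs, groups = mm$groups, size = mm$size)
  expect_equal(nrow(m$states), 41L)
  expect_length(m$rates, 69L)
})

test_that("a missing machinery parameter is a build error naming it", {
  p <- machinery_params()
  p$k.aa.import_aa <- NULL
  expect_error(build_machinery_model(p), "k\\.aa\\.import_aa")
})

test_that("tRNA charging requires cytosolic amino acids", {
  mm <- build_machinery_model()
  m <- compile_model(mm$constructs, groups = mm$groups, size = mm$size)
  x <- initial_state(m)
  x[["aa.cytosol"]] <- 0
  f <- m$fluxes(0, x)
  expect_equal(unname(f[["aa.bind_trna"]]), 0)
})

test_that("the amino-acid moiety changes only through membrane transport", {
  mm <- build_machinery_model()
  m <- compile_model(mm$constructs, groups = mm$groups, size = mm$size)
  cc <- check_conservation(m, aa_moiety(), aa_boundaries())
  expect_true(attr(cc, "conserved"))
  expect_setequal(cc$rate, aa_boundaries())
})

test_that("with imports zeroed the amino-acid moiety is constant on a trajectory", {
  p <- machinery_params(k.aa.import_aa = 0, k.aa.export_aa = 0)
  mm <- build_machinery_model(p)
  m <- compile_model(mm$constructs, groups = mm$groups, size = mm$size)
  tr <- simulate_model(m, t_end = 3600 * 6,
                       solver = solver_settings(dt_report = 1200))
  tot <- colSums(tr$amounts[names(aa_moiety()), ])
  expect_equal(max(abs(tot - tot[1])) / tot[1], 0, tolerance = 1e-6)
})

test_that("cell size is 1 at the reference state and intensive under doubling", {
  mm <- build_machinery_model()
  m <- compile_model(mm$constructs, groups = mm$groups, size = mm$size)
  x <- initial_state(m)
  expect_equal(cell_size(m, x), 1)
  expect_equal(cell_size(m, 2 * x), 2)
  # intensive invariance: after doubling every pool, concentrations (and
  # hence all per-concentration factors) are unchanged, so every
  # size-scaled flux exactly doubles
  f1 <- m$fluxes(0, x)
  f2 <- m$fluxes(0, 2 * x)
  scaled <- vapply(m$rates, function(r) isTRUE(r$scale_size), TRUE)
  # allocation members with constitutive weights are per-gene-copy terms:
  # their share is not tied to cytoplasmic amounts, so exclude them
  const_w <- vapply(m$rates, function(r)
    !is.null(r$group) && r$weight_const > 0, TRUE)
  nz <- f1 > 0 & scaled & !const_w
  expect_equal(unname(f2[nz] / f1[nz]), rep(2, sum(nz)), tolerance = 1e-4)
})

test_that("transcription capacity follows polymerase count, not DNA", {
  mm <- build_machinery_model()
  m <- compile_model(mm$constructs, groups = mm$groups, size = mm$size)
  x <- initial_state(m)
  base <- sum(m$fluxes(0, x)[grep("txs", names(m$rates))])
  x2 <- x; x2[["rnapol.transcribing"]] <- 2 * x[["rnapol.transcribing"]]
  dbl <- sum(m$fluxes(0, x2)[grep("txs", names(m$rates))])
  expect_equal(dbl / base, 2, tolerance = 1e-6)
})
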