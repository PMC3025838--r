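# Structure of the example cell-cycle model: census, regulatory-relation
# coverage, and local mechanisms that do not need a full simulation.

test_that("the protein table ships 33 proteins with parseable relations", {
  specs <- protein_specs()
  expect_equal(nrow(specs), 33L)
  expect_true(all(lengths(specs$inducers) >= 1))
  expect_setequal(specs$G0[specs$PROTEIN %in% c("p27", "Rb", "Wee1",
                                                "APC", "Cdh1", "Cdc14")],
                  "high")
})

test_that("the assembled model has the documented census", {
  m <- cached_model()
  expect_equal(m$cellcycle_census[["states"]], 387L)
  expect_gte(m$cellcycle_census[["rates"]], 990L)
  expect_lte(m$cellcycle_census[["rates"]], 1210L)
  # machinery portion unchanged by the rewiring
  mach <- intersect(names(m$constructs),
                    c("aa", "nt", "atp", "rrna", "ribo", "trna", "snrna",
                      "mrna", "rnapol", "prot", "lipid", "glc"))
  cen <- census(unname(m$constructs[mach]))
  expect_equal(unname(cen), c(41L, 69L))
})

test_that("the cycA lifecycle is the flagged 10-state / 23-rate exception", {
  m <- cached_model()
  cyca <- m$constructs[["cyca"]]
  expect_equal(unname(census(cyca)), c(10L, 23L))
  expect_false(is.null(cyca$exception))
})

test_that("every tabulated regulatory relation is realized as a rate", {
  m <- cached_model()
  cov <- relation_coverage(m, protein_specs())
  expect_gt(nrow(cov), 150)
  expect_true(all(cov$realized))
})

test_that("protein lifecycles build as protein + mRNA construct pairs", {
  specs <- protein_specs()
  pr <- build_protein_lifecycle(protein_spec(specs, "Wee1"))
  expect_equal(length(pr$protein$states), 7L)
  expect_equal(length(pr$mrna$states), 5L)
  # the Wee1 spec wires Plk1 as an inactivation modifier
  expect_true("plk1.act" %in% pr$protein$rates$pho_plk1$modifiers)
  # G0 'high' proteins start with nonzero amounts, cyclins start at zero
  expect_gt(pr$protein$states$act$initial_amount, 0)
  cycd <- build_protein_lifecycle(protein_spec(specs, "cycD"))
  expect_equal(sum(vapply(cycd$protein$states, `[[`, 0,
                          "initial_amount")), 0)
})

test_that("the SCF subsystem validates the affinity ordering", {
  expect_error(build_scf_subsystem(cellcycle_params(
    k.scf.bind_fbw7 = 1e-7)), "ordering")
  scf <- build_scf_subsystem()
  expect_setequal(names(scf), c("scf", "skp2", "btrc", "fbw7"))
})

test_that("SCF autoubiquitination is suppressed while substrates are present", {
  m <- cached_model()
  x <- initial_state(m)
  x[m$state_index[["fbw7.scf_c"]]] <- 1000
  f0 <- m$fluxes(0, x)[["fbw7.auto_ubq"]]
  x2 <- x
  x2[m$state_index[["cyce.cdk2_i"]]] <- 2e4   # substrate present
  f1 <- m$fluxes(0, x2)[["fbw7.auto_ubq"]]
  expect_gt(f0, 0)
  expect_lt(f1, 0.05 * f0)
  # destroying a subunit returns the SCF core: stoichiometry check
  S <- m$S[, "fbw7.auto_ubq"]
  expect_equal(unname(S[m$state_index[["scf.nuc"]]]), 1)
  expect_equal(unname(S[m$state_index[["fbw7.scf_c"]]]), -1)
})

test_that("replication is licensed by the Cdk2 complexes, not cycD/Cdk4or6", {
  m <- cached_model()
  x <- initial_state(m)
  x[m$state_index[["rc.dna_b"]]] <- 1000
  x[m$state_index[["cycd.cdk_c"]]] <- 1e4
  f <- m$fluxes(0, x)
  lic <- f[grep("^rc\\.license", names(f))]
  expect_equal(unname(sum(lic)), 0)   # no licensing without Cdk2 activity
  x[m$state_index[["cyce.cdk2_a"]]] <- 1e3
  f2 <- m$fluxes(0, x)
  expect_gt(sum(f2[grep("^rc\\.license", names(f2))]), 0)
})

test_that("zero licensed complexes means zero DNA synthesis", {
  m <- cached_model()
  x <- initial_state(m)
  expect_equal(unname(m$fluxes(0, x)[["rc.traverse"]]), 0)
})

test_that("Securin binding inhibits Cdc14 activation flux", {
  m <- cached_model()
  x <- initial_state(m)
  x[m$state_index[["plk1.nuc"]]] <- 2e3
  free_flux <- m$fluxes(0, x)[["cdc14.act_plk1"]]
  expect_gt(free_flux, 0)
  # with all Cdc14 bound by Securin there is nothing to activate
  x2 <- x
  i_nuc <- m$state_index[["cdc14.nuc"]]
  x2[m$state_index[["cdc14.securin_c"]]] <- x2[i_nuc]
  x2[i_nuc] <- 0
  expect_equal(unname(m$fluxes(0, x2)[["cdc14.act_plk1"]]), 0)
})

test_that("total RNA polymerase is conserved across its state transitions", {
  m <- cached_model()
  pol_states <- paste0("rnapol.", c("sequestered", "active",
                                    "transcribing"))
  w <- stats::setNames(rep(1, 3), pol_states)
  cc <- check_conservation(m, w)
  # the only rates changing the pool are synthesis (fold) and decay paths
  moving <- cc$rate[!cc$declared_boundary]
  expect_true(all(grepl("fold_pol|dk_pol|txl_pol", moving)))
})

test_that("Cdk1 total is conserved up to synthesis and degradation", {
  m <- cached_model()
  # free pool + parallel in-complex count
  w <- c(cdk1.cyt = 1, cdk1.nuc = 1, cdk1.in_use = 1, cdk1.unf = 1)
  cc <- check_conservation(m, w)
  ok <- grepl("^cdk1\\.(txl|dk|dispose)|^m_cdk1", cc$rate) |
    grepl("dk_cdk1|ubq_clear|dk_|ubq_", cc$rate)
  expect_true(all(ok[!cc$declared_boundary]))
})
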