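# ---------------------------------------------------------------------------
# Lifecycle constructs for the G1/S regulators and the transcription
# factors.  Conventions: rate names encode the regulatory relation they
# realize (ubq_<ubiquitinator>, act_<activator>, pho_/deact_<inactivator>,
# bind_/unbind_<partner>); complexes live as single states in one partner's
# construct, with parallel bookkeeping states (e.g. Cdk2 `in_use`) where a
# conservation invariant is worth tracking.  Modifier references are the
# thin-line inter-construct couplings.
# ---------------------------------------------------------------------------

X0 <- function(params, name) {
  v <- params[[name]]
  if (is.null(v)) 0 else v
}

# p27: maintains G0; binds cycD/Cdk4or6 (without blocking it) and
# cycE/Cdk2 (blocking it); free p27 is ubiquitinated by mitogen-activated
# KPC, complexed p27 released abruptly once active cycE/Cdk2 appears.
cc_build_p27 <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("p27", "protein")
  con <- add_state(con, "unf", 0)
  con <- add_state(con, "cyt", 0)
  con <- add_state(con, "nuc", X0(params, "x0.p27.nuc"), "nucleus")
  con <- add_state(con, "cycd_c", 0, "nucleus")   # bound to cycD/Cdk4or6
  con <- add_state(con, "cdk2_c", 0, "nucleus")   # bound to cycE/Cdk2
  con <- add_state(con, "ubq", 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "p27", params)
  con <- add_rate(con, "bind_cycd", P("k.p27.bind_cycd"),
                  reactants = c("nuc", "cycd.cdk_c"),
                  sources = c(nuc = 1, cycd.cdk_c = 1),
                  sinks = c(cycd_c = 1, cycd.cdk_p27 = 1))
  con <- add_rate(con, "unbind_cycd", 1e-6, reactants = "cycd_c",
                  sources = c(cycd_c = 1, cycd.cdk_p27 = 1),
                  sinks = c(nuc = 1, cycd.cdk_c = 1))
  con <- add_rate(con, "bind_cyce_i", P("k.p27.bind_cyce_i"),
                  reactants = c("nuc", "cyce.cdk2_i"),
                  sources = c(nuc = 1, cyce.cdk2_i = 1),
                  sinks = c(cdk2_c = 1))
  con <- add_rate(con, "bind_cyce_a", P("k.p27.bind_cyce_a"),
                  reactants = c("nuc", "cyce.cdk2_a"),
                  sources = c(nuc = 1, cyce.cdk2_a = 1),
                  sinks = c(cdk2_c = 1))
  con <- add_rate(con, "unbind_cyce", 1e-6, reactants = "cdk2_c",
                  sources = c(cdk2_c = 1), sinks = c(nuc = 1, cyce.cdk2_i = 1))
  # abrupt release: active cycE/Cdk2 phosphorylates complexed p27, which is
  # then destroyed, returning the cyclin/kinase complex
  con <- add_rate(con, "release_active", P("k.p27.release_active"),
                  reactants = "cdk2_c", modifiers = "cyce.cdk2_a",
                  sources = c(cdk2_c = 1),
                  sinks = c(ubq = 1, cyce.cdk2_i = 1))
  con <- add_rate(con, "release_kpc", P("k.p27.release_kpc"),
                  reactants = "cdk2_c", modifiers = "kpc.act",
                  sources = c(cdk2_c = 1),
                  sinks = c(ubq = 1, cyce.cdk2_i = 1))
  con <- add_rate(con, "ubq_kpc", P("k.p27.ubq_kpc"),
                  reactants = "nuc", modifiers = "kpc.act",
                  sources = "nuc", sinks = "ubq")
  con <- add_rate(con, "ubq_skp2", P("k.p27.ubq_skp2"),
                  reactants = "nuc", modifiers = "skp2.scf_c",
                  sources = "nuc", sinks = "ubq")
  if (isTRUE(params$on.p27_ubq_cdc20))
    con <- add_rate(con, "ubq_cdc20", P("k.p27.ubq_cdc20"),
                    reactants = "nuc", modifiers = "apc.cdc20_a",
                    sources = "nuc", sinks = "ubq")
  # the whole triple is degraded; the stable kinase subunit is returned
  con <- add_rate(con, "dk_cdk2_c", P("k.common.dk"), reactants = "cdk2_c",
                  sources = c(cdk2_c = 1, cdk2.in_use = 1),
                  sinks = c(trash = 1, cyce.trash = 1, cdk2.nuc = 1))
  con
}

# Rb: inhibits E2F by binding; hypo-phosphorylated by cycD/Cdk4or6
# (releasing E2F), hyper-phosphorylated by the other cyclin/Cdks,
# re-activated by Cdc14 at mitotic exit.
cc_build_rb <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("rb", "protein")
  con <- add_state(con, "unf", 0)
  con <- add_state(con, "cyt", 0)
  con <- add_state(con, "nuc", X0(params, "x0.rb.nuc"), "nucleus")
  con <- add_state(con, "e2f_c", 0, "nucleus")
  con <- add_state(con, "pho", 0, "nucleus")
  con <- add_state(con, "pho2", 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "rb", params)
  con <- add_rate(con, "bind_e2f", P("k.rb.bind_e2f"),
                  reactants = c("nuc", "e2f.nuc"),
                  sources = c(nuc = 1, e2f.nuc = 1), sinks = c(e2f_c = 1))
  con <- add_rate(con, "unbind_e2f", 1e-6, reactants = "e2f_c",
                  sources = c(e2f_c = 1), sinks = c(nuc = 1, e2f.nuc = 1))
  con <- add_rate(con, "pho_cycd", P("k.rb.pho_cycd"),
                  reactants = "nuc", modifiers = "cycd.cdk_c",
                  sources = "nuc", sinks = "pho")
  con <- add_rate(con, "pho_cycd_p27", P("k.rb.pho_cycd"),
                  reactants = "nuc", modifiers = "cycd.cdk_p27",
                  sources = "nuc", sinks = "pho")
  con <- add_rate(con, "release_cycd", P("k.rb.pho_cycd"),
                  reactants = "e2f_c", modifiers = "cycd.cdk_c",
                  sources = c(e2f_c = 1), sinks = c(pho = 1, e2f.nuc = 1))
  con <- add_rate(con, "release_cycd_p27", P("k.rb.pho_cycd"),
                  reactants = "e2f_c", modifiers = "cycd.cdk_p27",
                  sources = c(e2f_c = 1), sinks = c(pho = 1, e2f.nuc = 1))
  con <- add_rate(con, "pho2_cyce", P("k.rb.pho2"),
                  reactants = "pho", modifiers = "cyce.cdk2_a",
                  sources = "pho", sinks = "pho2")
  con <- add_rate(con, "pho2_cyca", P("k.rb.pho2"),
                  reactants = "pho", modifiers = "cyca.cdk2_a",
                  sources = "pho", sinks = "pho2")
  con <- add_rate(con, "pho2_cycb", P("k.rb.pho2"),
                  reactants = "pho", modifiers = "cycb.cdk1_n",
                  sources = "pho", sinks = "pho2")
  con <- add_rate(con, "depho", P("k.rb.depho"), reactants = "pho",
                  sources = "pho", sinks = "nuc")
  if (isTRUE(params$on.rb_act_cdc14))
    con <- add_rate(con, "act_cdc14", P("k.rb.depho_cdc14"),
                    reactants = "pho", modifiers = "cdc14.act",
                    sources = "pho", sinks = "nuc")
  con <- add_rate(con, "depho2", P("k.rb.depho2"), reactants = "pho2",
                  sources = "pho2", sinks = "pho")
  con <- add_rate(con, "dk_e2f_c", P("k.common.dk"), reactants = "e2f_c",
                  sources = c(e2f_c = 1), sinks = c(trash = 1, e2f.trash = 1))
  con <- add_rate(con, "dk_pho", P("k.common.dk"), reactants = "pho",
                  sources = "pho", sinks = "trash")
  con <- add_rate(con, "dk_pho2", P("k.common.dk"), reactants = "pho2",
                  sources = "pho2", sinks = "trash")
  con
}

# cycD: mitogen-induced; activates Cdk4or6 (implicit, abundant); the
# complex stays active whether or not p27 is bound.
cc_build_cycd <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("cycd", "protein")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  for (s in c("nuc", "cdk_c", "cdk_p27", "ubq"))
    con <- add_state(con, s, 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "cycd", params)
  con <- add_rate(con, "act_cdk4or6", P("k.cycd.bind_cdk"),
                  reactants = "nuc", sources = "nuc", sinks = "cdk_c")
  con <- add_rate(con, "ubq_skp2", P("k.cycd.ubq_skp2"),
                  reactants = "cdk_c", modifiers = "skp2.scf_c",
                  sources = c(cdk_c = 1), sinks = c(ubq = 1))
  con <- add_rate(con, "ubq_skp2_p27", P("k.cycd.ubq_skp2"),
                  reactants = "cdk_p27", modifiers = "skp2.scf_c",
                  sources = c(cdk_p27 = 1, p27.cycd_c = 1),
                  sinks = c(ubq = 1, p27.nuc = 1))
  if (isTRUE(params$on.cycd_ubq_cdc20))
    con <- add_rate(con, "ubq_cdc20", P("k.cycd.ubq_cdc20"),
                    reactants = "cdk_c", modifiers = "apc.cdc20_a",
                    sources = c(cdk_c = 1), sinks = c(ubq = 1))
  con <- add_rate(con, "dk_cdk_c", P("k.common.dk"), reactants = "cdk_c",
                  sources = c(cdk_c = 1), sinks = c(trash = 1))
  con <- add_rate(con, "dk_cdk_p27", P("k.common.dk"), reactants = "cdk_p27",
                  sources = c(cdk_p27 = 1, p27.cycd_c = 1),
                  sinks = c(trash = 1, p27.nuc = 1))
  con
}

# Cdk2 / Cdk1: constitutive kinases; complexes are tracked in the cyclin
# constructs, with `in_use` as a parallel count of kinase molecules
# currently inside complexes (Cdk conservation bookkeeping).
cc_build_cdk2 <- function(params) {
  con <- new_construct("cdk2", "protein")
  con <- flag_exception(con, "free-pool lifecycle; complexes live in the cyclin constructs")
  con <- add_state(con, "unf", 0)
  con <- add_state(con, "cyt", 0)
  con <- add_state(con, "nuc", X0(params, "x0.cdk2.nuc"), "nucleus")
  con <- add_state(con, "in_use", 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  cc_prot_core(con, "cdk2", params)
}

cc_build_cdk1 <- function(params) {
  con <- new_construct("cdk1", "protein")
  con <- flag_exception(con, "free-pool lifecycle; complexes live in the cyclin constructs")
  con <- add_state(con, "unf", 0)
  con <- add_state(con, "cyt", X0(params, "x0.cdk1.cyt"))
  con <- add_state(con, "nuc", X0(params, "x0.cdk1.nuc"), "nucleus")
  con <- add_state(con, "in_use", 0)
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  cc_prot_core(con, "cdk1", params)
}

# cycE: E2F-induced; cycE/Cdk2 forms phosphorylated (inactive), is
# activated by Cdc25A (with a low spontaneous leak seeding the cascade)
# and degraded by SCF(Fbw7) on Cdk2 / SCF(Skp2) when free.
cc_build_cyce <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("cyce", "protein")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  for (s in c("nuc", "cdk2_i", "cdk2_a", "ubq"))
    con <- add_state(con, s, 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "cyce", params)
  con <- add_rate(con, "bind_cdk2", P("k.cyce.bind_cdk2"),
                  reactants = c("nuc", "cdk2.nuc"),
                  sources = c(nuc = 1, cdk2.nuc = 1),
                  sinks = c(cdk2_i = 1, cdk2.in_use = 1))
  con <- add_rate(con, "unbind_cdk2", 1e-6, reactants = "cdk2_i",
                  sources = c(cdk2_i = 1, cdk2.in_use = 1),
                  sinks = c(nuc = 1, cdk2.nuc = 1))
  con <- add_rate(con, "spont_act", P("k.cyce.spont_act"),
                  reactants = "cdk2_i", modifiers = "apc.cdh1_c",
                  inhib = c(apc.cdh1_c = P("K.cdh1.seed")),
                  sources = "cdk2_i", sinks = "cdk2_a")
  con <- add_rate(con, "act_cdc25a", P("k.cyce.act_cdc25a"),
                  reactants = "cdk2_i", modifiers = "cdc25a.act",
                  sources = "cdk2_i", sinks = "cdk2_a")
  con <- add_rate(con, "spont_inact", 6e-4, reactants = "cdk2_a",
                  sources = "cdk2_a", sinks = "cdk2_i")
  con <- add_rate(con, "ubq_fbw7_i", P("k.cyce.ubq_fbw7"),
                  reactants = "cdk2_i", modifiers = "fbw7.scf_c",
                  sources = c(cdk2_i = 1, cdk2.in_use = 1),
                  sinks = c(ubq = 1, cdk2.nuc = 1))
  con <- add_rate(con, "ubq_fbw7_a", P("k.cyce.ubq_fbw7"),
                  reactants = "cdk2_a", modifiers = "fbw7.scf_c",
                  sources = c(cdk2_a = 1, cdk2.in_use = 1),
                  sinks = c(ubq = 1, cdk2.nuc = 1))
  con <- add_rate(con, "ubq_skp2", P("k.cyce.ubq_skp2"),
                  reactants = "nuc", modifiers = "skp2.scf_c",
                  sources = "nuc", sinks = "ubq")
  con <- add_rate(con, "dk_cdk2_i", P("k.common.dk"), reactants = "cdk2_i",
                  sources = c(cdk2_i = 1, cdk2.in_use = 1),
                  sinks = c(trash = 1, cdk2.nuc = 1))
  con <- add_rate(con, "dk_cdk2_a", P("k.common.dk"), reactants = "cdk2_a",
                  sources = c(cdk2_a = 1, cdk2.in_use = 1),
                  sinks = c(trash = 1, cdk2.nuc = 1))
  con
}

cc_build_bmyb <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("bmyb", "protein")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  for (s in c("nuc", "act", "on_dna", "ubq"))
    con <- add_state(con, s, 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "bmyb", params)
  con <- add_rate(con, "act_cyca", P("k.bmyb.act_cyca"),
                  reactants = "nuc", modifiers = "cyca.cdk2_a",
                  sources = "nuc", sinks = "act")
  if (isTRUE(params$on.bmyb_act_cyce))
    con <- add_rate(con, "act_cyce", P("k.bmyb.act_cyce"),
                    reactants = "nuc", modifiers = "cyce.cdk2_a",
                    sources = "nuc", sinks = "act")
  con <- add_rate(con, "deact", P("k.bmyb.deact"), reactants = "act",
                  sources = "act", sinks = "nuc")
  con <- add_rate(con, "on_dna", P("k.bmyb.on_dna"), reactants = "act",
                  sources = "act", sinks = "on_dna")
  con <- add_rate(con, "off_dna", P("k.bmyb.off_dna"), reactants = "on_dna",
                  sources = "on_dna", sinks = "act")
  con <- add_rate(con, "ubq_skp2", P("k.bmyb.ubq_skp2"),
                  reactants = "nuc", modifiers = "skp2.scf_c",
                  sources = "nuc", sinks = "ubq")
  con <- add_rate(con, "dk_act", P("k.common.dk"), reactants = "act",
                  sources = "act", sinks = "trash")
  con <- add_rate(con, "dk_on_dna", P("k.common.dk"), reactants = "on_dna",
                  sources = "on_dna", sinks = "trash")
  con
}

cc_build_nfy <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("nfy", "protein")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  for (s in c("nuc", "act", "pho", "on_dna"))
    con <- add_state(con, s, X0(params, paste0("x0.nfy.", s)), "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "nfy", params)
  con <- add_rate(con, "act_cyca", P("k.nfy.act_cyca"),
                  reactants = "nuc", modifiers = "cyca.cdk2_a",
                  sources = "nuc", sinks = "act")
  if (isTRUE(params$on.bmyb_act_cyce))
    con <- add_rate(con, "act_cyce", P("k.nfy.act_cyce"),
                    reactants = "nuc", modifiers = "cyce.cdk2_a",
                    sources = "nuc", sinks = "act")
  con <- add_rate(con, "deact", P("k.nfy.deact"), reactants = "act",
                  sources = "act", sinks = "nuc")
  if (isTRUE(params$on.nfy_deact_cdc14))
    con <- add_rate(con, "deact_cdc14", P("k.nfy.deact_cdc14"),
                    reactants = "act", modifiers = "cdc14.act",
                    sources = "act", sinks = "pho")
  con <- add_rate(con, "depho", P("k.nfy.deact"), reactants = "pho",
                  sources = "pho", sinks = "nuc")
  con <- add_rate(con, "on_dna", P("k.nfy.on_dna"), reactants = "act",
                  sources = "act", sinks = "on_dna")
  con <- add_rate(con, "off_dna", P("k.nfy.off_dna"), reactants = "on_dna",
                  sources = "on_dna", sinks = "act")
  con <- add_rate(con, "dk_act", P("k.common.dk"), reactants = "act",
                  sources = "act", sinks = "trash")
  con <- add_rate(con, "dk_pho", P("k.common.dk"), reactants = "pho",
                  sources = "pho", sinks = "trash")
  con <- add_rate(con, "dk_on_dna", P("k.common.dk"), reactants = "on_dna",
                  sources = "on_dna", sinks = "trash")
  con
}

# E2F: the central G1/S transcription factor; sequestered by Rb (complex in
# the Rb construct), inactivated by mitotic kinases, degraded by SCF(Skp2).
cc_build_e2f <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("e2f", "protein")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  for (s in c("nuc", "on_dna", "pho", "ubq"))
    con <- add_state(con, s, 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "e2f", params)
  con <- add_rate(con, "on_dna", P("k.e2f.on_dna"), reactants = "nuc",
                  sources = "nuc", sinks = "on_dna")
  con <- add_rate(con, "off_dna", P("k.e2f.off_dna"), reactants = "on_dna",
                  sources = "on_dna", sinks = "nuc")
  con <- add_rate(con, "pho_cycb", P("k.e2f.pho_cycb"),
                  reactants = "nuc", modifiers = "cycb.cdk1_n",
                  sources = "nuc", sinks = "pho")
  con <- add_rate(con, "pho_cyca_cdk2", P("k.e2f.pho_cycb") / 4,
                  reactants = "nuc", modifiers = "cyca.cdk2_a",
                  sources = "nuc", sinks = "pho")
  con <- add_rate(con, "pho_cyca_cdk1", P("k.e2f.pho_cycb") / 4,
                  reactants = "nuc", modifiers = "cyca.cdk1_n",
                  sources = "nuc", sinks = "pho")
  con <- add_rate(con, "pho_cycd", P("k.e2f.pho_cycb") / 10,
                  reactants = "nuc", modifiers = "cycd.cdk_c",
                  sources = "nuc", sinks = "pho")
  con <- add_rate(con, "depho", P("k.e2f.depho"), reactants = "pho",
                  sources = "pho", sinks = "nuc")
  con <- add_rate(con, "ubq_skp2", P("k.e2f.ubq_skp2"),
                  reactants = "nuc", modifiers = "skp2.scf_c",
                  sources = "nuc", sinks = "ubq")
  if (isTRUE(params$on.e2f_ubq_cdc20))
    con <- add_rate(con, "ubq_cdc20", P("k.e2f.ubq_cdc20"),
                    reactants = "nuc", modifiers = "apc.cdc20_a",
                    sources = "nuc", sinks = "ubq")
  con <- add_rate(con, "dk_pho", P("k.common.dk"), reactants = "pho",
                  sources = "pho", sinks = "trash")
  con <- add_rate(con, "dk_on_dna", P("k.common.dk"), reactants = "on_dna",
                  sources = "on_dna", sinks = "trash")
  con
}

# TF-grow: generic growth transcription factor (c-myc, c-Jun, Notch ...);
# boosts bulk transcription and RNA-polymerase expression.
cc_build_tfg <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("tfg", "protein")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  for (s in c("nuc", "on_dna", "pho", "ubq"))
    con <- add_state(con, s, 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "tfg", params)
  con <- add_rate(con, "on_dna", P("k.tfg.on_dna"), reactants = "nuc",
                  sources = "nuc", sinks = "on_dna")
  con <- add_rate(con, "off_dna", P("k.tfg.off_dna"), reactants = "on_dna",
                  sources = "on_dna", sinks = "nuc")
  con <- add_rate(con, "pho", P("k.tfg.pho"), reactants = "nuc",
                  sources = "nuc", sinks = "pho")
  con <- add_rate(con, "ubq_skp2", P("k.tfg.ubq_skp2"),
                  reactants = "nuc", modifiers = "skp2.scf_c",
                  sources = "nuc", sinks = "ubq")
  con <- add_rate(con, "ubq_fbw7", P("k.tfg.ubq_fbw7"),
                  reactants = "pho", modifiers = "fbw7.scf_c",
                  sources = "pho", sinks = "ubq")
  con <- add_rate(con, "dk_on_dna", P("k.common.dk"), reactants = "on_dna",
                  sources = "on_dna", sinks = "trash")
  con <- add_rate(con, "dk_pho", P("k.common.dk"), reactants = "pho",
                  sources = "pho", sinks = "trash")
  # growth-coupled nutrient supply: amino-acid and nucleotide import scale
  # with the growth program (TF-grow), damped by pool sensing
  con <- add_rate(con, "import_aa_growth", P("k.tfg.import_aa"),
                  modifiers = c("nuc", "aa.cytosol"),
                  inhib = c(aa.cytosol = 2e8),
                  sinks = c(aa.cytosol = 1))
  con <- add_rate(con, "import_nt_growth", P("k.tfg.import_nt"),
                  modifiers = c("nuc", "nt.cytosol"),
                  inhib = c(nt.cytosol = 1.6e10),
                  sinks = c(nt.cytosol = 1))
  # growth boost: an extra allocation member feeding the bulk mRNA pool,
  # weighted by TF-grow amount
  con <- add_rate(con, "txs_bulk_boost", P("w.bulk.tfg"),
                  law_kind = "allocation", group = "txs",
                  weight_states = c("nuc", "on_dna"),
                  sources = c(nt.cytosol = 1000, atp.atp = 2000),
                  sinks = c(mrna.nascent = 1, nt.in_rna = 1000,
                            atp.adp = 2000))
  con
}

# eIF-4: translation-initiation factor; its cytosolic amount saturates the
# total translation capacity (wired into the txl group at assembly).
cc_build_eif4 <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("eif4", "protein")
  con <- flag_exception(con, "minimal initiation-factor lifecycle")
  con <- add_state(con, "unf", 0)
  con <- add_state(con, "cyt", X0(params, "x0.eif4.cyt"))
  con <- add_state(con, "act", 0)
  con <- add_state(con, "in_use", 0)
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "eif4", params)
  con <- add_rate(con, "act_mrna", 2e-6, reactants = "cyt",
                  modifiers = "mrna.cytosol",
                  sat = c(mrna.cytosol = 1e4),
                  sources = "cyt", sinks = "act")
  con <- add_rate(con, "bind", 1e-4, reactants = "act",
                  sources = "act", sinks = "in_use")
  con <- add_rate(con, "unbind", 1e-3, reactants = "in_use",
                  sources = "in_use", sinks = "act")
  con <- add_rate(con, "dk_act", P("k.common.dk"), reactants = "act",
                  sources = "act", sinks = "trash")
  con <- add_rate(con, "dk_in_use", P("k.common.dk"), reactants = "in_use",
                  sources = "in_use", sinks = "trash")
  con
}

# KPC: ubiquitinase for free p27, activated by mitogen.
cc_build_kpc <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("kpc", "protein")
  con <- flag_exception(con, "minimal mitogen-sensing lifecycle")
  con <- add_state(con, "unf", 0)
  con <- add_state(con, "nuc", X0(params, "x0.kpc.nuc"), "nucleus")
  con <- add_state(con, "act", 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "kpc", params)
  con <- add_rate(con, "act_mitogen", P("k.kpc.act_mitogen"),
                  reactants = "nuc", modifiers = "signals.mitogen",
                  sources = "nuc", sinks = "act")
  con <- add_rate(con, "deact", P("k.kpc.deact"), reactants = "act",
                  sources = "act", sinks = "nuc")
  con <- add_rate(con, "dk_act", P("k.common.dk"), reactants = "act",
                  sources = "act", sinks = "trash")
  # KPC-gated release of cycC/Cdk8-sequestered RNA polymerase
  con <- add_rate(con, "release_pol", P("k.pol.release_kpc"),
                  reactants = "rnapol.sequestered", modifiers = "act",
                  sources = c(rnapol.sequestered = 1),
                  sinks = c(rnapol.active = 1))
  con
}

# cycC: with Cdk8 (implicit) sequesters RNA polymerase during G0;
# ubiquitinated via mitogen-activated KPC, restored by Cdc14 at M exit.
cc_build_cycc <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("cycc", "protein")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  con <- add_state(con, "nuc", X0(params, "x0.cycc.nuc"), "nucleus")
  con <- add_state(con, "cdk8_c", X0(params, "x0.cycc.cdk8_c"), "nucleus")
  con <- add_state(con, "pho", 0, "nucleus")
  con <- add_state(con, "ubq", 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "cycc", params)
  con <- add_rate(con, "act_cdk8", P("k.cycc.bind_cdk8"),
                  reactants = "nuc", sources = "nuc", sinks = "cdk8_c")
  con <- add_rate(con, "ubq_kpc", P("k.cycc.ubq_kpc"),
                  reactants = "cdk8_c", modifiers = "kpc.act",
                  sources = "cdk8_c", sinks = "ubq")
  con <- add_rate(con, "pho_mitogen", P("k.cycc.pho_mitogen"),
                  reactants = "cdk8_c", modifiers = "signals.mitogen",
                  sources = "cdk8_c", sinks = "pho")
  if (isTRUE(params$on.cycc_react_cdc14))
    con <- add_rate(con, "act_cdc14", P("k.cycc.react_cdc14"),
                    reactants = "pho", modifiers = "cdc14.act",
                    sources = "pho", sinks = "cdk8_c")
  con <- add_rate(con, "dk_cdk8_c", P("k.common.dk"), reactants = "cdk8_c",
                  sources = "cdk8_c", sinks = "trash")
  con <- add_rate(con, "dk_pho", P("k.common.dk"), reactants = "pho",
                  sources = "pho", sinks = "trash")
  if (isTRUE(params$on.pol_detach_cdc20))
    con <- add_rate(con, "detach_pol_cdc20", P("k.pol.detach_cdc20"),
                    reactants = "rnapol.transcribing",
                    modifiers = "apc.cdc20_a",
                    sources = c(rnapol.transcribing = 1),
                    sinks = c(rnapol.active = 1))
  con
}
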