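# ---------------------------------------------------------------------------
# The mechanistic subsystems: SCF subunit sequencing, replication-origin
# licensing, the cycA module, and the mitotic cascades with Cdc14-driven
# exit.
# ---------------------------------------------------------------------------

#' Build the SCF ubiquitin-ligase subsystem
#'
#' The SCF core binds its three substrate-specificity subunits with ordered
#' affinity (Fbw7 > Skp2 > Btrc); each subunit autoubiquitinates when its
#' substrates are absent (inhibitory factors on the substrate pools), while
#' the core survives and immediately binds the next subunit.  This sequences
#' SCF(Fbw7) -> SCF(Skp2) -> SCF(Btrc) through the cycle.
#'
#' @param params [cellcycle_params()].
#' @return list of `Construct`s: scf, skp2, btrc, fbw7.
#' @export
build_scf_subsystem <- function(params = cellcycle_params()) {
  P <- function(n) ccp(params, n)
  if (!(P("k.scf.bind_fbw7") > P("k.scf.bind_skp2") &&
        P("k.scf.bind_skp2") > P("k.scf.bind_btrc")))
    stop("SCF affinity ordering violated: need k_bind(Fbw7) > k_bind(Skp2) > k_bind(Btrc)")

  scf <- new_construct("scf", "protein")
  scf <- flag_exception(scf, "core-only lifecycle; subunit complexes live in the subunit constructs")
  scf <- add_state(scf, "unf", 0)
  scf <- add_state(scf, "nuc", 0, "nucleus")
  scf <- add_state(scf, "ubq", 0, "nucleus")
  scf <- add_state(scf, "trash", 0, is_sink = TRUE)
  scf <- cc_prot_core(scf, "scf", params)
  scf <- add_rate(scf, "ubq_cdh1", P("k.scf.ubq_cdh1"),
                  reactants = "nuc", modifiers = "apc.cdh1_c",
                  sources = "nuc", sinks = "ubq")

  subunit <- function(name, k_bind, auto_k, auto_K, auto_substrates,
                      pho_tag) {
    con <- new_construct(name, "protein")
    for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
    for (s in c("nuc", "scf_c", "pho", "ubq"))
      con <- add_state(con, s, 0, "nucleus")
    con <- add_state(con, "trash", 0, is_sink = TRUE)
    con <- cc_prot_core(con, name, params)
    con <- add_rate(con, "bind_scf", k_bind,
                    reactants = c("nuc", "scf.nuc"),
                    sources = c(nuc = 1, scf.nuc = 1), sinks = c(scf_c = 1))
    con <- add_rate(con, "unbind_scf", P("k.scf.unbind_sub"),
                    reactants = "scf_c", sources = c(scf_c = 1),
                    sinks = c(nuc = 1, scf.nuc = 1))
    # autoubiquitination: only the subunit is destroyed; suppressed while
    # any substrate pool is populated
    con <- add_rate(con, "auto_ubq", auto_k, reactants = "scf_c",
                    modifiers = auto_substrates,
                    inhib = stats::setNames(rep(auto_K,
                                                length(auto_substrates)),
                                            auto_substrates),
                    sources = c(scf_c = 1),
                    sinks = c(ubq = 1, scf.nuc = 1))
    con <- add_rate(con, "ubq_cdh1", P(paste0("k.", name, ".ubq_cdh1")),
                    reactants = "nuc", modifiers = "apc.cdh1_c",
                    sources = "nuc", sinks = "ubq")
    con <- add_rate(con, "dk_scf_c", P("k.common.dk"), reactants = "scf_c",
                    sources = c(scf_c = 1),
                    sinks = c(trash = 1, scf.nuc = 1))
    con <- add_rate(con, "dk_pho", P("k.common.dk"), reactants = "pho",
                    sources = "pho", sinks = "trash")
    con
  }

  skp2 <- subunit("skp2", P("k.scf.bind_skp2"), P("k.skp2.auto"),
                  P("K.skp2.auto"),
                  c("p27.cdk2_c", "cyce.cdk2_i", "e2f.nuc", "rc.rel"))
  skp2 <- add_rate(skp2, "pho_cyca", P("k.skp2.pho_cyca"),
                   reactants = "nuc", modifiers = "cyca.cdk2_a",
                   sources = "nuc", sinks = "pho")
  skp2 <- add_rate(skp2, "depho", P("k.skp2.depho"), reactants = "pho",
                   sources = "pho", sinks = "nuc")

  btrc <- subunit("btrc", P("k.scf.bind_btrc"), P("k.btrc.auto"),
                  P("K.btrc.auto"),
                  c("emi1.nuc", "wee1.pho", "cdc25a.nuc"))
  btrc <- add_rate(btrc, "pho", P("k.btrc.pho"), reactants = "nuc",
                   sources = "nuc", sinks = "pho")
  btrc <- add_rate(btrc, "depho", P("k.btrc.depho"), reactants = "pho",
                   sources = "pho", sinks = "nuc")
  btrc <- add_rate(btrc, "ubq_cdc20", P("k.btrc.ubq_cdc20"),
                   reactants = "nuc", modifiers = "apc.cdc20_a",
                   sources = "nuc", sinks = "ubq")

  fbw7 <- new_construct("fbw7", "protein")
  for (s in c("unf", "cyt")) fbw7 <- add_state(fbw7, s, 0)
  for (s in c("nuc", "dimer", "scf_c", "ubq"))
    fbw7 <- add_state(fbw7, s, 0, "nucleus")
  fbw7 <- add_state(fbw7, "trash", 0, is_sink = TRUE)
  fbw7 <- cc_prot_core(fbw7, "fbw7", params)
  fbw7 <- add_rate(fbw7, "bind_scf", P("k.scf.bind_fbw7"),
                   reactants = c("nuc", "scf.nuc"),
                   sources = c(nuc = 1, scf.nuc = 1), sinks = c(scf_c = 1))
  fbw7 <- add_rate(fbw7, "unbind_scf", P("k.scf.unbind_sub"),
                   reactants = "scf_c", sources = c(scf_c = 1),
                   sinks = c(nuc = 1, scf.nuc = 1))
  fbw7 <- add_rate(fbw7, "auto_ubq", P("k.fbw7.auto"),
                   reactants = "scf_c",
                   modifiers = c("cyce.cdk2_i", "cyce.cdk2_a"),
                   inhib = c(cyce.cdk2_i = P("K.fbw7.auto"),
                             cyce.cdk2_a = P("K.fbw7.auto")),
                   sources = c(scf_c = 1), sinks = c(ubq = 1, scf.nuc = 1))
  fbw7 <- add_rate(fbw7, "dimerize", P("k.fbw7.dimer"), reactants = "nuc",
                   sources = "nuc", sinks = "dimer")
  fbw7 <- add_rate(fbw7, "undimerize", P("k.fbw7.undimer"),
                   reactants = "dimer", sources = "dimer", sinks = "nuc")
  fbw7 <- add_rate(fbw7, "dk_scf_c", P("k.common.dk"), reactants = "scf_c",
                   sources = c(scf_c = 1), sinks = c(trash = 1, scf.nuc = 1))
  fbw7 <- add_rate(fbw7, "dk_dimer", P("k.common.dk"), reactants = "dimer",
                   sources = "dimer", sinks = "trash")

  list(scf = scf, skp2 = skp2, btrc = btrc, fbw7 = fbw7)
}

#' Build the DNA-replication subsystem
#'
#' Replication complexes (RC) bind a capped pool of replication origins
#' (the RC-count bookkeeping construct, 15,000 sites), are licensed by
#' cycE/Cdk2 and cycA/Cdk2 (not cycD/Cdk4or6), traversed by DNA polymerase
#' (crediting the DNA nucleotide pool and consuming cytosolic nucleotides),
#' then released and ubiquitinated by SCF(Skp2).  Fired origins only return
#' at division.
#'
#' @param params [cellcycle_params()].
#' @return list of `Construct`s: rc, dnapol, oric (origin bookkeeping),
#'   dna (nucleotides in DNA).
#' @export
build_replication_subsystem <- function(params = cellcycle_params()) {
  P <- function(n) ccp(params, n)
  nt_o <- P("nt.per_origin")

  oric <- new_construct("oric", "bookkeeping")
  oric <- add_state(oric, "free", P("n.origins"), "nucleus",
                    dimensionless = TRUE, halve = FALSE)
  oric <- add_state(oric, "fired", 0, "nucleus",
                    dimensionless = TRUE, halve = FALSE)

  dna <- new_construct("dna", "bookkeeping")
  dna <- add_state(dna, "nt", P("nt.genome"), "nucleus")

  rc <- new_construct("rc", "protein")
  rc <- flag_exception(rc, "replication-complex lifecycle with origin binding, licensing and polymerase traversal")
  for (s in c("unf", "cyt")) rc <- add_state(rc, s, 0)
  for (s in c("nuc", "dna_b", "lic", "trav", "rel", "ubq"))
    rc <- add_state(rc, s, 0, "nucleus")
  rc <- add_state(rc, "trash", 0, is_sink = TRUE)
  rc <- cc_prot_core(rc, "rc", params)
  rc <- add_rate(rc, "bind_origin", P("k.rc.bind_origin"),
                 reactants = c("nuc", "oric.free"),
                 sources = c(nuc = 1, oric.free = 1), sinks = c(dna_b = 1))
  rc <- add_rate(rc, "unbind_origin", P("k.rc.unbind_origin"),
                 reactants = "dna_b", sources = c(dna_b = 1),
                 sinks = c(nuc = 1, oric.free = 1))
  # active APC(Cdh1) blocks licensing (it destroys the licensing factors),
  # which is what holds G1 and prevents re-replication after division
  rc <- add_rate(rc, "license_cyce", P("k.rc.license_cyce"),
                 reactants = "dna_b",
                 modifiers = c("cyce.cdk2_a", "apc.cdh1_c"),
                 inhib = c(apc.cdh1_c = P("K.cdh1.gate")),
                 sources = "dna_b", sinks = "lic")
  rc <- add_rate(rc, "license_cyca", P("k.rc.license_cyca"),
                 reactants = "dna_b",
                 modifiers = c("cyca.cdk2_a", "apc.cdh1_c"),
                 inhib = c(apc.cdh1_c = P("K.cdh1.gate")),
                 sources = "dna_b", sinks = "lic")
  if (isTRUE(params$on.rc_delicense)) {
    rc <- add_rate(rc, "delicense_cdk1", P("k.rc.delicense_cdk1"),
                   reactants = "lic", modifiers = "cyca.cdk1_n",
                   sources = "lic", sinks = "dna_b")
    rc <- add_rate(rc, "delicense_p27", P("k.rc.delicense_cdk1"),
                   reactants = "lic", modifiers = "p27.nuc",
                   sources = "lic", sinks = "dna_b")
  }
  rc <- add_rate(rc, "attach_pol", P("k.rc.attach_pol"),
                 reactants = c("lic", "dnapol.nuc"),
                 sources = c(lic = 1, dnapol.nuc = 1),
                 sinks = c(trav = 1, dnapol.on_dna = 1))
  rc <- add_rate(rc, "traverse", P("k.rc.traverse"),
                 reactants = "trav", modifiers = "nt.cytosol",
                 sat = c(nt.cytosol = 2e8),
                 sources = c(trav = 1, dnapol.on_dna = 1,
                             nt.cytosol = nt_o),
                 sinks = c(rel = 1, dnapol.spent = 1, dna.nt = nt_o,
                           oric.fired = 1))
  rc <- add_rate(rc, "ubq_skp2", P("k.rc.ubq_skp2"),
                 reactants = "rel", modifiers = "skp2.scf_c",
                 sources = "rel", sinks = "ubq")
  rc <- add_rate(rc, "ubq_fbw7", P("k.rc.ubq_skp2") / 10,
                 reactants = "rel", modifiers = "fbw7.scf_c",
                 sources = "rel", sinks = "ubq")
  rc <- add_rate(rc, "ubq_cdh1", P("k.rc.ubq_cdh1"),
                 reactants = "nuc", modifiers = "apc.cdh1_c",
                 sources = "nuc", sinks = "ubq")
  rc <- add_rate(rc, "ubq_cdh1_bound", P("k.rc.ubq_cdh1_b"),
                 reactants = "dna_b", modifiers = "apc.cdh1_c",
                 sources = c(dna_b = 1),
                 sinks = c(ubq = 1, oric.free = 1))
  rc <- add_rate(rc, "dk_dna_b", P("k.common.dk"), reactants = "dna_b",
                 sources = c(dna_b = 1), sinks = c(trash = 1, oric.free = 1))
  rc <- add_rate(rc, "dk_lic", P("k.common.dk"), reactants = "lic",
                 sources = c(lic = 1), sinks = c(trash = 1, oric.free = 1))
  rc <- add_rate(rc, "dk_rel", P("k.common.dk"), reactants = "rel",
                 sources = "rel", sinks = "trash")

  dnapol <- new_construct("dnapol", "protein")
  for (s in c("unf", "cyt")) dnapol <- add_state(dnapol, s, 0)
  for (s in c("nuc", "on_dna", "spent", "ubq"))
    dnapol <- add_state(dnapol, s, 0, "nucleus")
  dnapol <- add_state(dnapol, "trash", 0, is_sink = TRUE)
  dnapol <- cc_prot_core(dnapol, "dnapol", params)
  dnapol <- add_rate(dnapol, "recycle", P("k.dnapol.recycle"),
                     reactants = "spent", sources = "spent", sinks = "nuc")
  dnapol <- add_rate(dnapol, "ubq_skp2", P("k.dnapol.ubq"),
                     reactants = "nuc", modifiers = "skp2.scf_c",
                     sources = "nuc", sinks = "ubq")
  # a polymerase dying mid-traversal also kills its replication complex
  # and frees the origin for re-licensing
  dnapol <- add_rate(dnapol, "dk_on_dna", P("k.common.dk") / 2,
                     reactants = "on_dna",
                     sources = c(on_dna = 1, rc.trav = 1),
                     sinks = c(trash = 1, rc.trash = 1, oric.free = 1))
  dnapol <- add_rate(dnapol, "dk_spent", P("k.common.dk"),
                     reactants = "spent", sources = "spent", sinks = "trash")

  list(rc = rc, dnapol = dnapol, oric = oric, dna = dna)
}

# cycA: the most complex lifecycle (10 states, 23 rates): cycA/Cdk2
# (p27-inhibitable, S-phase licensing kinase) and cycA/Cdk1 (Wee1-held,
# Cdc25B-activated, Plk1-translocated mitotic primer).  Folding requires
# both mitogen and adhesion.
cc_build_cyca <- function(params) {
  P <- function(n) ccp(params, n)
  con <- new_construct("cyca", "protein")
  con <- flag_exception(con, "10-state lifecycle covering Cdk2, p27 and Cdk1 interactions in cytosol and nucleus")
  for (s in c("unf", "cyt")) con <- add_state(con, s, 0)
  for (s in c("nuc", "cdk2_a", "cdk2_p27", "cdk1_i", "cdk1_a", "cdk1_n",
              "ubq"))
    con <- add_state(con, s, 0, "nucleus")
  con <- add_state(con, "trash", 0, is_sink = TRUE)
  con <- cc_prot_core(con, "cyca", params,
                      txl_gate = if (isTRUE(params$on.cyca_adhesion))
                        c("signals.mitogen", "signals.adhesion")
                      else "signals.mitogen",
                      split_txl = FALSE, export = FALSE)
  con <- add_rate(con, "bind_cdk2", P("k.cyca.bind_cdk2"),
                  reactants = c("nuc", "cdk2.nuc"),
                  sources = c(nuc = 1, cdk2.nuc = 1),
                  sinks = c(cdk2_a = 1, cdk2.in_use = 1))
  con <- add_rate(con, "bind_p27", P("k.cyca.bind_p27"),
                  reactants = c("cdk2_a", "p27.nuc"),
                  sources = c(cdk2_a = 1, p27.nuc = 1),
                  sinks = c(cdk2_p27 = 1))
  con <- add_rate(con, "ubq_cdh1_s", P("k.cyca.ubq_cdh1") / 2,
                  reactants = "cdk2_a", modifiers = "apc.cdh1_c",
                  sources = c(cdk2_a = 1, cdk2.in_use = 1),
                  sinks = c(ubq = 1, cdk2.nuc = 1))
  con <- add_rate(con, "bind_cdk1", P("k.cyca.bind_cdk1"),
                  reactants = c("nuc", "cdk1.nuc"),
                  sources = c(nuc = 1, cdk1.nuc = 1),
                  sinks = c(cdk1_i = 1, cdk1.in_use = 1))
  con <- add_rate(con, "spont_act", P("k.cyca.spont_act"),
                  reactants = "cdk1_i", modifiers = "wee1.act",
                  inhib = c(wee1.act = P("K.wee1.gate")),
                  sources = "cdk1_i", sinks = "cdk1_a")
  con <- add_rate(con, "act_cdc25b", P("k.cyca.act_cdc25b"),
                  reactants = "cdk1_i",
                  modifiers = c("cdc25b.act", "wee1.act"),
                  inhib = c(wee1.act = P("K.wee1.gate")),
                  sources = "cdk1_i", sinks = "cdk1_a")
  con <- add_rate(con, "act_cdc25a", P("k.cyca.act_cdc25a"),
                  reactants = "cdk1_i",
                  modifiers = c("cdc25a.act", "wee1.act"),
                  inhib = c(wee1.act = P("K.wee1.gate")),
                  sources = "cdk1_i", sinks = "cdk1_a")
  con <- add_rate(con, "pho_wee1", P("k.cyca.pho_wee1"),
                  reactants = "cdk1_a", modifiers = "wee1.act",
                  sources = "cdk1_a", sinks = "cdk1_i")
  con <- add_rate(con, "transloc_plk1", P("k.cyca.transloc_plk1"),
                  reactants = "cdk1_a", modifiers = "plk1.act",
                  sources = "cdk1_a", sinks = "cdk1_n")
  con <- add_rate(con, "ubq_cdh1", P("k.cyca.ubq_cdh1"),
                  reactants = "nuc", modifiers = "apc.cdh1_c",
                  sources = "nuc", sinks = "ubq")
  if (isTRUE(params$on.cyca_ubq_cdc20)) {
    con <- add_rate(con, "ubq_cdc20", P("k.cyca.ubq_cdc20"),
                    reactants = "cdk1_n", modifiers = "apc.cdc20_a",
                    sources = c(cdk1_n = 1, cdk1.in_use = 1),
                    sinks = c(ubq = 1, cdk1.nuc = 1))
    con <- add_rate(con, "ubq_cdc20_s", P("k.cyca.ubq_cdc20"),
                    reactants = "cdk2_a", modifiers = "apc.cdc20_a",
                    sources = c(cdk2_a = 1, cdk2.in_use = 1),
                    sinks = c(ubq = 1, cdk2.nuc = 1))
  }
  if (isTRUE(params$on.cyca_ubq_skp2))
    con <- add_rate(con, "ubq_skp2", P("k.cyca.ubq_skp2"),
                    reactants = "cdk2_a", modifiers = "skp2.scf_c",
                    sources = c(cdk2_a = 1, cdk2.in_use = 1),
                    sinks = c(ubq = 1, cdk2.nuc = 1))
  con <- add_rate(con, "dk_cdk2_a", P("k.common.dk"), reactants = "cdk2_a",
                  sources = c(cdk2_a = 1, cdk2.in_use = 1),
                  sinks = c(trash = 1, cdk2.nuc = 1))
  con <- add_rate(con, "dk_cdk1_i", P("k.common.dk"), reactants = "cdk1_i",
                  sources = c(cdk1_i = 1, cdk1.in_use = 1),
                  sinks = c(trash = 1, cdk1.nuc = 1))
  con
}

#' Build the mitotic subsystem
#'
#' Wee1 suppression of the Cdk1 complexes (stronger on cycB/Cdk1 than
#' cycA/Cdk1), the cycA/Cdk1-Cdc25B and cycB/Cdk1-Cdc25C activation
#' cascades (Cdc25B can weakly substitute for Cdc25C, not vice versa),
#' Plk1-driven nuclear translocation, APC(Cdc20) destruction of Securin and
#' the cyclins, and Cdc14-driven mitotic exit (reactivating Wee1 and Cdh1,
#' deactivating the Cdc25s and Cdc20).
#'
#' @param params [cellcycle_params()].
#' @return list of `Construct`s.
#' @export
build_mitotic_subsystem <- function(params = cellcycle_params()) {
  P <- function(n) ccp(params, n)

  ## Wee1 -------------------------------------------------------------------
  wee1 <- new_construct("wee1", "protein")
  wee1 <- add_state(wee1, "unf", 0)
  wee1 <- add_state(wee1, "cyt", 0)
  wee1 <- add_state(wee1, "act", X0(params, "x0.wee1.act"))
  wee1 <- add_state(wee1, "pho", 0)
  wee1 <- add_state(wee1, "react", 0)
  wee1 <- add_state(wee1, "ubq", 0)
  wee1 <- add_state(wee1, "trash", 0, is_sink = TRUE)
  wee1 <- cc_prot_core(wee1, "wee1", params)
  wee1 <- add_rate(wee1, "mature", P("k.wee1.mature"), reactants = "cyt",
                   sources = "cyt", sinks = "act")
  wee1 <- add_rate(wee1, "pho_plk1", P("k.wee1.pho_plk1"),
                   reactants = "act", modifiers = "plk1.act",
                   sources = "act", sinks = "pho")
  if (isTRUE(params$on.wee1_pho_cdk1)) {
    wee1 <- add_rate(wee1, "pho_cycbcdk1", P("k.wee1.pho_cdk1"),
                     reactants = "act", modifiers = "cycb.cdk1_a",
                     sources = "act", sinks = "pho")
    wee1 <- add_rate(wee1, "pho_cycacdk1", P("k.wee1.pho_cdk1"),
                     reactants = "act", modifiers = "cyca.cdk1_a",
                     sources = "act", sinks = "pho")
    wee1 <- add_rate(wee1, "pho_cycacdk2", P("k.wee1.pho_cdk1"),
                     reactants = "act", modifiers = "cyca.cdk2_a",
                     sources = "act", sinks = "pho")
  }
  # spontaneous reactivation through a dephosphorylating intermediate
  wee1 <- add_rate(wee1, "react", P("k.wee1.react"), reactants = "pho",
                   sources = "pho", sinks = "react")
  wee1 <- add_rate(wee1, "reactivate", P("k.wee1.reactivate"),
                   reactants = "react", sources = "react", sinks = "act")
  wee1 <- add_rate(wee1, "act_cdc14", P("k.wee1.react_cdc14"),
                   reactants = "pho", modifiers = "cdc14.act",
                   sources = "pho", sinks = "act")
  wee1 <- add_rate(wee1, "ubq_btrc", P("k.wee1.ubq_btrc"),
                   reactants = "pho", modifiers = "btrc.scf_c",
                   sources = "pho", sinks = "ubq")
  wee1 <- add_rate(wee1, "dk_act", P("k.common.dk"), reactants = "act",
                   sources = "act", sinks = "trash")
  wee1 <- add_rate(wee1, "dk_pho", P("k.common.dk"), reactants = "pho",
                   sources = "pho", sinks = "trash")
  wee1 <- add_rate(wee1, "dk_react", P("k.common.dk"), reactants = "react",
                   sources = "react", sinks = "trash")

  ## cycB -------------------------------------------------------------------
  cycb <- new_construct("cycb", "protein")
  for (s in c("unf", "cyt", "cdk1_i", "cdk1_a")) cycb <- add_state(cycb, s, 0)
  cycb <- add_state(cycb, "cdk1_n", 0, "nucleus")
  cycb <- add_state(cycb, "ubq", 0)
  cycb <- add_state(cycb, "trash", 0, is_sink = TRUE)
  cycb <- cc_prot_core(cycb, "cycb", params)
  cycb <- add_rate(cycb, "bind_cdk1", P("k.cycb.bind_cdk1"),
                   reactants = c("cyt", "cdk1.cyt"),
                   sources = c(cyt = 1, cdk1.cyt = 1),
                   sinks = c(cdk1_i = 1, cdk1.in_use = 1))
  gate <- c(wee1.act = P("K.wee1.gate"))
  cycb <- add_rate(cycb, "spont_act", P("k.cycb.spont_act"),
                   reactants = "cdk1_i", modifiers = "wee1.act",
                   inhib = gate,
                   sources = "cdk1_i", sinks = "cdk1_a")
  cycb <- add_rate(cycb, "act_cdc25c", P("k.cycb.act_cdc25c"),
                   reactants = "cdk1_i",
                   modifiers = c("cdc25c.act", "wee1.act"),
                   inhib = gate,
                   sources = "cdk1_i", sinks = "cdk1_a")
  cycb <- add_rate(cycb, "act_cdc25c_cyt", P("k.cycb.act_cdc25c"),
                   reactants = "cdk1_i",
                   modifiers = c("cdc25c.cyt_a", "wee1.act"),
                   inhib = gate,
                   sources = "cdk1_i", sinks = "cdk1_a")
  # Cdc25B substitutes for Cdc25C, albeit less efficiently
  cycb <- add_rate(cycb, "act_cdc25b", P("k.cycb.act_cdc25b"),
                   reactants = "cdk1_i",
                   modifiers = c("cdc25b.act", "wee1.act"),
                   inhib = gate,
                   sources = "cdk1_i", sinks = "cdk1_a")
  if (isTRUE(params$on.cdc25a_act_cdk1))
    cycb <- add_rate(cycb, "act_cdc25a", P("k.cdc25a.act_cdk1"),
                     reactants = "cdk1_i",
                     modifiers = c("cdc25a.act", "wee1.act"),
                     inhib = gate,
                     sources = "cdk1_i", sinks = "cdk1_a")
  cycb <- add_rate(cycb, "pho_wee1", P("k.cycb.pho_wee1"),
                   reactants = "cdk1_a", modifiers = "wee1.act",
                   sources = "cdk1_a", sinks = "cdk1_i")
  cycb <- add_rate(cycb, "inact_cdc14", P("k.cdc25a.deact_cdc14"),
                   reactants = "cdk1_a", modifiers = "cdc14.act",
                   sources = "cdk1_a", sinks = "cdk1_i")
  cycb <- add_rate(cycb, "transloc_plk1", P("k.cycb.transloc_plk1"),
                   reactants = "cdk1_a", modifiers = "plk1.act",
                   sources = "cdk1_a", sinks = "cdk1_n")
  cycb <- add_rate(cycb, "transloc", P("k.cycb.transloc"),
                   reactants = "cdk1_a", sources = "cdk1_a",
                   sinks = "cdk1_n")
  for (st in c("cdk1_i", "cdk1_a", "cdk1_n")) {
    ret <- if (st == "cdk1_n") "cdk1.nuc" else "cdk1.cyt"
    src <- stats::setNames(c(1, 1), c(st, "cdk1.in_use"))
    cycb <- add_rate(cycb, paste0("ubq_cdc20_", st), P("k.cycb.ubq_cdc20"),
                     reactants = st, modifiers = "apc.cdc20_a",
                     sources = src,
                     sinks = stats::setNames(c(1, 1), c("ubq", ret)))
    cycb <- add_rate(cycb, paste0("dk_", st), P("k.common.dk"),
                     reactants = st, sources = src,
                     sinks = stats::setNames(c(1, 1), c("trash", ret)))
  }
  cycb <- add_rate(cycb, "ubq_cdh1", P("k.cycb.ubq_cdh1"),
                   reactants = "cyt", modifiers = "apc.cdh1_c",
                   sources = "cyt", sinks = "ubq")
  cycb <- add_rate(cycb, "ubq_cdh1_i", P("k.cycb.ubq_cdh1"),
                   reactants = "cdk1_i", modifiers = "apc.cdh1_c",
                   sources = c(cdk1_i = 1, cdk1.in_use = 1),
                   sinks = c(ubq = 1, cdk1.cyt = 1))

  ## Cdc25A -----------------------------------------------------------------
  cdc25a <- new_construct("cdc25a", "protein")
  for (s in c("unf", "cyt")) cdc25a <- add_state(cdc25a, s, 0)
  for (s in c("nuc", "act", "pho", "ubq"))
    cdc25a <- add_state(cdc25a, s, 0, "nucleus")
  cdc25a <- add_state(cdc25a, "trash", 0, is_sink = TRUE)
  cdc25a <- cc_prot_core(cdc25a, "cdc25a", params)
  cdc25a <- add_rate(cdc25a, "spont_act", P("k.cdc25a.spont_act"),
                     reactants = "nuc", modifiers = "apc.cdh1_c",
                     inhib = c(apc.cdh1_c = P("K.cdh1.seed")),
                     sources = "nuc", sinks = "act")
  cdc25a <- add_rate(cdc25a, "act_cyce", P("k.cdc25a.act_cyce"),
                     reactants = "nuc", modifiers = "cyce.cdk2_a",
                     sources = "nuc", sinks = "act")
  cdc25a <- add_rate(cdc25a, "act_cyca", P("k.cdc25a.act_cyca"),
                     reactants = "nuc", modifiers = "cyca.cdk2_a",
                     sources = "nuc", sinks = "act")
  if (isTRUE(params$on.cdc25a_act_cdk1))
    cdc25a <- add_rate(cdc25a, "act_cycacdk1", P("k.cdc25a.act_cdk1"),
                       reactants = "nuc", modifiers = "cyca.cdk1_a",
                       sources = "nuc", sinks = "act")
  cdc25a <- add_rate(cdc25a, "deact_cdc14", P("k.cdc25a.deact_cdc14"),
                     reactants = "act", modifiers = "cdc14.act",
                     sources = "act", sinks = "pho")
  cdc25a <- add_rate(cdc25a, "repho", P("k.cdc25a.repho"),
                     reactants = "pho", sources = "pho", sinks = "nuc")
  cdc25a <- add_rate(cdc25a, "ubq_cdh1", P("k.cdc25a.ubq_cdh1"),
                     reactants = "nuc", modifiers = "apc.cdh1_c",
                     sources = "nuc", sinks = "ubq")
  cdc25a <- add_rate(cdc25a, "ubq_cdh1_act", P("k.cdc25a.ubq_cdh1"),
                     reactants = "act", modifiers = "apc.cdh1_c",
                     sources = "act", sinks = "ubq")
  if (isTRUE(params$on.cdc25a_ubq_btrc))
    cdc25a <- add_rate(cdc25a, "ubq_btrc", P("k.cdc25a.ubq_btrc"),
                       reactants = "nuc", modifiers = "btrc.scf_c",
                       sources = "nuc", sinks = "ubq")
  cdc25a <- add_rate(cdc25a, "dk_act", P("k.common.dk"), reactants = "act",
                     sources = "act", sinks = "trash")
  cdc25a <- add_rate(cdc25a, "dk_pho", P("k.common.dk"), reactants = "pho",
                     sources = "pho", sinks = "trash")

  ## Cdc25B -----------------------------------------------------------------
  cdc25b <- new_construct("cdc25b", "protein")
  for (s in c("unf", "cyt", "act", "pho", "ubq"))
    cdc25b <- add_state(cdc25b, s, 0)
  cdc25b <- add_state(cdc25b, "nuc", 0, "nucleus")
  cdc25b <- add_state(cdc25b, "trash", 0, is_sink = TRUE)
  cdc25b <- cc_prot_core(cdc25b, "cdc25b", params)
  cdc25b <- add_rate(cdc25b, "spont_act", P("k.cdc25b.spont_act"),
                     reactants = "cyt", sources = "cyt", sinks = "act")
  cdc25b <- add_rate(cdc25b, "act_cycacdk1", P("k.cdc25b.act_cycacdk1"),
                     reactants = "cyt", modifiers = "cyca.cdk1_a",
                     sources = "cyt", sinks = "act")
  cdc25b <- add_rate(cdc25b, "act_cycbcdk1", P("k.cdc25b.act_cycbcdk1"),
                     reactants = "cyt", modifiers = "cycb.cdk1_a",
                     sources = "cyt", sinks = "act")
  cdc25b <- add_rate(cdc25b, "act_tfg", P("k.cdc25b.act_tfg"),
                     reactants = "cyt", modifiers = "tfg.nuc",
                     sources = "cyt", sinks = "act")
  cdc25b <- add_rate(cdc25b, "spont_deact", 2e-4, reactants = "act",
                     sources = "act", sinks = "cyt")
  cdc25b <- add_rate(cdc25b, "deact_cdc14", P("k.cdc25b.deact_cdc14"),
                     reactants = "act", modifiers = "cdc14.act",
                     sources = "act", sinks = "pho")
  cdc25b <- add_rate(cdc25b, "repho", P("k.cdc25b.repho"),
                     reactants = "pho", sources = "pho", sinks = "cyt")
  if (isTRUE(params$on.cdc25b_ubq)) {
    cdc25b <- add_rate(cdc25b, "ubq_cdh1", P("k.cdc25b.ubq_cdh1"),
                       reactants = "cyt", modifiers = "apc.cdh1_c",
                       sources = "cyt", sinks = "ubq")
    cdc25b <- add_rate(cdc25b, "ubq_btrc", P("k.cdc25b.ubq_btrc"),
                       reactants = "cyt", modifiers = "btrc.scf_c",
                       sources = "cyt", sinks = "ubq")
  }
  cdc25b <- add_rate(cdc25b, "dk_act", P("k.common.dk"), reactants = "act",
                     sources = "act", sinks = "trash")
  cdc25b <- add_rate(cdc25b, "dk_pho", P("k.common.dk"), reactants = "pho",
                     sources = "pho", sinks = "trash")

  ## Cdc25C -----------------------------------------------------------------
  cdc25c <- new_construct("cdc25c", "protein")
  for (s in c("unf", "cyt", "cyt_a")) cdc25c <- add_state(cdc25c, s, 0)
  cdc25c <- add_state(cdc25c, "nuc", X0(params, "x0.cdc25c.nuc"), "nucleus")
  cdc25c <- add_state(cdc25c, "act", 0, "nucleus")
  cdc25c <- add_state(cdc25c, "pho", 0, "nucleus")
  cdc25c <- add_state(cdc25c, "trash", 0, is_sink = TRUE)
  cdc25c <- cc_prot_core(cdc25c, "cdc25c", params)
  cdc25c <- add_rate(cdc25c, "act_cycb_cyt", P("k.cdc25c.act_cycb"),
                     reactants = "cyt", modifiers = "cycb.cdk1_a",
                     sources = "cyt", sinks = "cyt_a")
  if (isTRUE(params$on.cdc25c_act_cycacdk1))
    cdc25c <- add_rate(cdc25c, "act_cyca", P("k.cdc25c.act_cyca"),
                       reactants = "cyt", modifiers = "cyca.cdk1_a",
                       sources = "cyt", sinks = "cyt_a")
  cdc25c <- add_rate(cdc25c, "transloc_plk1", P("k.cdc25c.transloc_plk1"),
                     reactants = "cyt_a", modifiers = "plk1.act",
                     sources = "cyt_a", sinks = "act")
  cdc25c <- add_rate(cdc25c, "act_cycb_nuc", P("k.cdc25c.act_cycb"),
                     reactants = "nuc", modifiers = "cycb.cdk1_n",
                     sources = "nuc", sinks = "act")
  cdc25c <- add_rate(cdc25c, "act_plk1", P("k.cdc25c.act_plk1"),
                     reactants = "nuc", modifiers = "plk1.nuc",
                     sources = "nuc", sinks = "act")
  cdc25c <- add_rate(cdc25c, "spont_deact", 4e-4, reactants = "act",
                     sources = "act", sinks = "nuc")
  cdc25c <- add_rate(cdc25c, "deact_cdc14", P("k.cdc25c.deact_cdc14"),
                     reactants = "act", modifiers = "cdc14.act",
                     sources = "act", sinks = "pho")
  cdc25c <- add_rate(cdc25c, "deact_cdc14_cyt", P("k.cdc25c.deact_cdc14"),
                     reactants = "cyt_a", modifiers = "cdc14.act",
                     sources = "cyt_a", sinks = "cyt")
  cdc25c <- add_rate(cdc25c, "repho", P("k.cdc25c.repho"),
                     reactants = "pho", sources = "pho", sinks = "nuc")
  cdc25c <- add_rate(cdc25c, "dk_cyt_a", P("k.common.dk"),
                     reactants = "cyt_a", sources = "cyt_a", sinks = "trash")
  cdc25c <- add_rate(cdc25c, "dk_act", P("k.common.dk"), reactants = "act",
                     sources = "act", sinks = "trash")
  cdc25c <- add_rate(cdc25c, "dk_pho", P("k.common.dk"), reactants = "pho",
                     sources = "pho", sinks = "trash")

  ## Plk1 -------------------------------------------------------------------
  plk1 <- new_construct("plk1", "protein")
  for (s in c("unf", "cyt", "act")) plk1 <- add_state(plk1, s, 0)
  for (s in c("nuc", "pho")) plk1 <- add_state(plk1, s, 0, "nucleus")
  plk1 <- add_state(plk1, "ubq", 0)
  plk1 <- add_state(plk1, "trash", 0, is_sink = TRUE)
  plk1 <- cc_prot_core(plk1, "plk1", params, import = FALSE)
  plk1 <- add_rate(plk1, "export_nuc", P("k.common.export"),
                   reactants = "nuc", sources = "nuc", sinks = "cyt")
  plk1 <- add_rate(plk1, "dk_nuc2", 0, reactants = "nuc",
                   sources = "nuc", sinks = "trash")
  plk1 <- add_rate(plk1, "act_cycb", P("k.plk1.act_cycb"),
                   reactants = "cyt", modifiers = "cycb.cdk1_a",
                   sources = "cyt", sinks = "act")
  if (isTRUE(params$on.plk1_act_cycacdk1))
    plk1 <- add_rate(plk1, "act_cyca", P("k.plk1.act_cyca"),
                     reactants = "cyt", modifiers = "cyca.cdk1_a",
                     sources = "cyt", sinks = "act")
  plk1 <- add_rate(plk1, "transloc", P("k.plk1.transloc"),
                   reactants = "act", sources = "act", sinks = "nuc")
  plk1 <- add_rate(plk1, "deact_cdc14", P("k.plk1.deact_cdc14"),
                   reactants = "act", modifiers = "cdc14.act",
                   sources = "act", sinks = "pho")
  plk1 <- add_rate(plk1, "deact_cdc14_nuc", P("k.plk1.deact_cdc14"),
                   reactants = "nuc", modifiers = "cdc14.act",
                   sources = "nuc", sinks = "pho")
  plk1 <- add_rate(plk1, "repho", P("k.plk1.repho"), reactants = "pho",
                   sources = "pho", sinks = "cyt")
  plk1 <- add_rate(plk1, "ubq_cdh1", P("k.plk1.ubq_cdh1"),
                   reactants = "cyt", modifiers = "apc.cdh1_c",
                   sources = "cyt", sinks = "ubq")
  plk1 <- add_rate(plk1, "dk_act", P("k.common.dk"), reactants = "act",
                   sources = "act", sinks = "trash")
  plk1 <- add_rate(plk1, "dk_pho", P("k.common.dk"), reactants = "pho",
                   sources = "pho", sinks = "trash")

  ## Emi1 -------------------------------------------------------------------
  emi1 <- new_construct("emi1", "protein")
  for (s in c("unf", "cyt")) emi1 <- add_state(emi1, s, 0)
  for (s in c("nuc", "cdc20_c", "cdh1_c", "ubq"))
    emi1 <- add_state(emi1, s, 0, "nucleus")
  emi1 <- add_state(emi1, "trash", 0, is_sink = TRUE)
  emi1 <- cc_prot_core(emi1, "emi1", params)
  emi1 <- add_rate(emi1, "bind_cdc20", P("k.emi1.bind_cdc20"),
                   reactants = c("nuc", "cdc20.nuc"),
                   sources = c(nuc = 1, cdc20.nuc = 1),
                   sinks = c(cdc20_c = 1))
  emi1 <- add_rate(emi1, "bind_cdh1", P("k.emi1.bind_cdh1"),
                   reactants = c("nuc", "cdh1.nuc"),
                   sources = c(nuc = 1, cdh1.nuc = 1),
                   sinks = c(cdh1_c = 1))
  emi1 <- add_rate(emi1, "unbind_cdc20", 1e-6, reactants = "cdc20_c",
                   sources = c(cdc20_c = 1),
                   sinks = c(nuc = 1, cdc20.nuc = 1))
  emi1 <- add_rate(emi1, "unbind_cdh1", 1e-6, reactants = "cdh1_c",
                   sources = c(cdh1_c = 1),
                   sinks = c(nuc = 1, cdh1.nuc = 1))
  # phosphorylation by mitotic kinases releases the partner and routes
  # Emi1 to destruction by SCF(Btrc)
  emi1 <- add_rate(emi1, "pho_cycb_20", P("k.emi1.pho_cycb"),
                   reactants = "cdc20_c", modifiers = "cycb.cdk1_a",
                   sources = c(cdc20_c = 1),
                   sinks = c(ubq = 1, cdc20.nuc = 1))
  emi1 <- add_rate(emi1, "pho_cycb_h1", P("k.emi1.pho_cycb"),
                   reactants = "cdh1_c", modifiers = "cycb.cdk1_a",
                   sources = c(cdh1_c = 1),
                   sinks = c(ubq = 1, cdh1.nuc = 1))
  if (isTRUE(params$on.emi1_pho_cycacdk1)) {
    emi1 <- add_rate(emi1, "pho_cyca_20", P("k.emi1.pho_cyca"),
                     reactants = "cdc20_c", modifiers = "cyca.cdk1_n",
                     sources = c(cdc20_c = 1),
                     sinks = c(ubq = 1, cdc20.nuc = 1))
    emi1 <- add_rate(emi1, "pho_cyca_h1", P("k.emi1.pho_cyca"),
                     reactants = "cdh1_c", modifiers = "cyca.cdk1_n",
                     sources = c(cdh1_c = 1),
                     sinks = c(ubq = 1, cdh1.nuc = 1))
  }
  emi1 <- add_rate(emi1, "ubq_btrc", P("k.emi1.ubq_btrc"),
                   reactants = "nuc", modifiers = "btrc.scf_c",
                   sources = "nuc", sinks = "ubq")
  emi1 <- add_rate(emi1, "ubq_skp2", P("k.emi1.ubq_skp2"),
                   reactants = "nuc", modifiers = "skp2.scf_c",
                   sources = "nuc", sinks = "ubq")
  emi1 <- add_rate(emi1, "dk_cdc20_c", P("k.common.dk"),
                   reactants = "cdc20_c", sources = c(cdc20_c = 1),
                   sinks = c(trash = 1, cdc20.nuc = 1))
  emi1 <- add_rate(emi1, "dk_cdh1_c", P("k.common.dk"),
                   reactants = "cdh1_c", sources = c(cdh1_c = 1),
                   sinks = c(trash = 1, cdh1.nuc = 1))

  ## APC core with its two coactivators -------------------------------------
  apc <- new_construct("apc", "protein")
  for (s in c("unf", "cyt")) apc <- add_state(apc, s, 0)
  apc <- add_state(apc, "nuc", X0(params, "x0.apc.nuc"), "nucleus")
  apc <- add_state(apc, "cdh1_c", X0(params, "x0.apc.cdh1_c"), "nucleus")
  apc <- add_state(apc, "cdc20_i", 0, "nucleus")
  apc <- add_state(apc, "cdc20_a", 0, "nucleus")
  apc <- add_state(apc, "trash", 0, is_sink = TRUE)
  apc <- cc_prot_core(apc, "apc", params)
  apc <- add_rate(apc, "bind_cdh1", P("k.cdh1.bind_apc"),
                  reactants = c("nuc", "cdh1.nuc"),
                  sources = c(nuc = 1, cdh1.nuc = 1),
                  sinks = c(cdh1_c = 1, cdh1.in_apc = 1))
  apc <- add_rate(apc, "unbind_cdh1", P("k.cdh1.unbind_apc"),
                  reactants = "cdh1_c",
                  sources = c(cdh1_c = 1, cdh1.in_apc = 1),
                  sinks = c(nuc = 1, cdh1.nuc = 1))
  for (ki in c("cycd.cdk_c", "cycd.cdk_p27", "cyce.cdk2_a", "cyca.cdk2_a",
               "cycb.cdk1_n")) {
    tag <- sub("\\..*$", "", ki)
    if (tag == "cycd" && grepl("p27", ki)) tag <- "cycd_p27"
    apc <- add_rate(apc, paste0("inact_cdh1_", tag),
                    P(paste0("k.cdh1.inact_",
                             if (tag == "cycd_p27") "cycd" else tag)),
                    reactants = "cdh1_c", modifiers = ki,
                    sources = c(cdh1_c = 1, cdh1.in_apc = 1),
                    sinks = c(nuc = 1, cdh1.pho = 1))
  }
  # Cdk1 phosphorylation of the APC core promotes Cdc20 loading, so the
  # APC(Cdc20) form only assembles once the mitotic cascade has fired
  apc <- add_rate(apc, "bind_cdc20", P("k.apc.bind_cdc20"),
                  reactants = c("nuc", "cdc20.nuc"),
                  modifiers = "cycb.cdk1_n",
                  sources = c(nuc = 1, cdc20.nuc = 1),
                  sinks = c(cdc20_i = 1, cdc20.in_apc = 1))
  apc <- add_rate(apc, "unbind_cdc20", 1e-4, reactants = "cdc20_i",
                  sources = c(cdc20_i = 1, cdc20.in_apc = 1),
                  sinks = c(nuc = 1, cdc20.nuc = 1))
  apc <- add_rate(apc, "act_cdc20_cycb", P("k.apc.act_cdc20_cycb"),
                  reactants = "cdc20_i", modifiers = "cycb.cdk1_n",
                  sources = "cdc20_i", sinks = "cdc20_a")
  apc <- add_rate(apc, "act_cdc20_cycb_c", P("k.apc.act_cdc20_cycb") / 4,
                  reactants = "cdc20_i", modifiers = "cycb.cdk1_a",
                  sources = "cdc20_i", sinks = "cdc20_a")
  apc <- add_rate(apc, "act_cdc20_cyca", P("k.apc.act_cdc20_cyca"),
                  reactants = "cdc20_i", modifiers = "cyca.cdk1_n",
                  sources = "cdc20_i", sinks = "cdc20_a")
  apc <- add_rate(apc, "act_cdc20_cyca2", P("k.apc.act_cdc20_cyca"),
                  reactants = "cdc20_i", modifiers = "cyca.cdk2_a",
                  sources = "cdc20_i", sinks = "cdc20_a")
  apc <- add_rate(apc, "deact_cdc20", P("k.apc.deact_cdc20"),
                  reactants = "cdc20_a", sources = "cdc20_a",
                  sinks = "cdc20_i")
  apc <- add_rate(apc, "unbind_cdc20_cdc14", P("k.apc.unbind_cdc20_cdc14"),
                  reactants = "cdc20_a", modifiers = "cdc14.act",
                  sources = c(cdc20_a = 1, cdc20.in_apc = 1),
                  sinks = c(nuc = 1, cdc20.pho = 1))
  apc <- add_rate(apc, "dk_cdh1_c", P("k.common.dk"), reactants = "cdh1_c",
                  sources = c(cdh1_c = 1, cdh1.in_apc = 1),
                  sinks = c(trash = 1, cdh1.trash = 1))
  apc <- add_rate(apc, "dk_cdc20_i", P("k.common.dk"),
                  reactants = "cdc20_i",
                  sources = c(cdc20_i = 1, cdc20.in_apc = 1),
                  sinks = c(trash = 1, cdc20.nuc = 1))
  apc <- add_rate(apc, "dk_cdc20_a", P("k.common.dk"),
                  reactants = "cdc20_a",
                  sources = c(cdc20_a = 1, cdc20.in_apc = 1),
                  sinks = c(trash = 1, cdc20.nuc = 1))

  ## Cdh1 -------------------------------------------------------------------
  cdh1 <- new_construct("cdh1", "protein")
  for (s in c("unf", "cyt")) cdh1 <- add_state(cdh1, s, 0)
  cdh1 <- add_state(cdh1, "nuc", X0(params, "x0.cdh1.nuc"), "nucleus")
  cdh1 <- add_state(cdh1, "in_apc", X0(params, "x0.cdh1.in_apc"), "nucleus")
  cdh1 <- add_state(cdh1, "pho", 0, "nucleus")
  cdh1 <- add_state(cdh1, "ubq", 0, "nucleus")
  cdh1 <- add_state(cdh1, "trash", 0, is_sink = TRUE)
  cdh1 <- cc_prot_core(cdh1, "cdh1", params)
  cdh1 <- add_rate(cdh1, "depho", P("k.cdh1.depho"), reactants = "pho",
                   sources = "pho", sinks = "nuc")
  cdh1 <- add_rate(cdh1, "act_cdc14", P("k.cdh1.depho_cdc14"),
                   reactants = "pho", modifiers = "cdc14.act",
                   sources = "pho", sinks = "nuc")
  cdh1 <- add_rate(cdh1, "auto_ubq", P("k.cdh1.auto"),
                   reactants = "nuc",
                   modifiers = c("skp2.nuc", "cdc25a.nuc", "cdc20.nuc"),
                   inhib = c(skp2.nuc = P("K.cdh1.auto"),
                             cdc25a.nuc = P("K.cdh1.auto"),
                             cdc20.nuc = P("K.cdh1.auto")),
                   sources = "nuc", sinks = "ubq")
  cdh1 <- add_rate(cdh1, "dk_pho", P("k.common.dk"), reactants = "pho",
                   sources = "pho", sinks = "trash")

  ## Cdc20 ------------------------------------------------------------------
  cdc20 <- new_construct("cdc20", "protein")
  for (s in c("unf", "cyt")) cdc20 <- add_state(cdc20, s, 0)
  for (s in c("nuc", "in_apc", "pho", "ubq"))
    cdc20 <- add_state(cdc20, s, 0, "nucleus")
  cdc20 <- add_state(cdc20, "trash", 0, is_sink = TRUE)
  cdc20 <- cc_prot_core(cdc20, "cdc20", params)
  cdc20 <- add_rate(cdc20, "ubq_cdh1", P("k.cdc20.ubq_cdh1"),
                    reactants = "nuc", modifiers = "apc.cdh1_c",
                    sources = "nuc", sinks = "ubq")
  cdc20 <- add_rate(cdc20, "depho", 1e-4, reactants = "pho",
                    sources = "pho", sinks = "nuc")
  cdc20 <- add_rate(cdc20, "dk_pho", P("k.common.dk"), reactants = "pho",
                    sources = "pho", sinks = "trash")

  ## Cdc14 (the mitotic-exit network) ---------------------------------------
  cdc14 <- new_construct("cdc14", "protein")
  for (s in c("unf", "cyt")) cdc14 <- add_state(cdc14, s, 0)
  cdc14 <- add_state(cdc14, "nuc", X0(params, "x0.cdc14.nuc"), "nucleus")
  for (s in c("securin_c", "act", "react"))
    cdc14 <- add_state(cdc14, s, 0, "nucleus")
  cdc14 <- add_state(cdc14, "trash", 0, is_sink = TRUE)
  cdc14 <- cc_prot_core(cdc14, "cdc14", params)
  cdc14 <- add_rate(cdc14, "bind_securin", P("k.securin.bind_cdc14"),
                    reactants = c("nuc", "securin.nuc"),
                    sources = c(nuc = 1, securin.nuc = 1),
                    sinks = c(securin_c = 1, securin.cdc14_c = 1))
  cdc14 <- add_rate(cdc14, "unbind_securin", P("k.securin.unbind_cdc14"),
                    reactants = "securin_c",
                    sources = c(securin_c = 1, securin.cdc14_c = 1),
                    sinks = c(nuc = 1, securin.nuc = 1))
  cdc14 <- add_rate(cdc14, "release_cdc20", P("k.securin.ubq_cdc20"),
                    reactants = "securin_c", modifiers = "apc.cdc20_a",
                    sources = c(securin_c = 1, securin.cdc14_c = 1),
                    sinks = c(nuc = 1, securin.ubq = 1))
  cdc14 <- add_rate(cdc14, "act_plk1", P("k.cdc14.act_plk1"),
                    reactants = "nuc", modifiers = "plk1.nuc",
                    sources = "nuc", sinks = "act")
  cdc14 <- add_rate(cdc14, "spend", P("k.cdc14.spend"), reactants = "act",
                    sources = "act", sinks = "react")
  cdc14 <- add_rate(cdc14, "recover", P("k.cdc14.recover"),
                    reactants = "react", sources = "react", sinks = "nuc")
  cdc14 <- add_rate(cdc14, "dk_securin_c", P("k.common.dk"),
                    reactants = "securin_c",
                    sources = c(securin_c = 1, securin.cdc14_c = 1),
                    sinks = c(trash = 1, securin.trash = 1))
  cdc14 <- add_rate(cdc14, "dk_act", P("k.common.dk"), reactants = "act",
                    sources = "act", sinks = "trash")
  cdc14 <- add_rate(cdc14, "dk_react", P("k.common.dk"),
                    reactants = "react", sources = "react", sinks = "trash")

  ## Securin ----------------------------------------------------------------
  securin <- new_construct("securin", "protein")
  for (s in c("unf", "cyt")) securin <- add_state(securin, s, 0)
  for (s in c("nuc", "cdc14_c", "pho", "ubq"))
    securin <- add_state(securin, s, 0, "nucleus")
  securin <- add_state(securin, "trash", 0, is_sink = TRUE)
  securin <- cc_prot_core(securin, "securin", params)
  securin <- add_rate(securin, "pho_cdk1", P("k.securin.pho_cdk1"),
                      reactants = "nuc", modifiers = "cycb.cdk1_n",
                      sources = "nuc", sinks = "pho")
  securin <- add_rate(securin, "depho", P("k.securin.depho"),
                      reactants = "pho", sources = "pho", sinks = "nuc")
  securin <- add_rate(securin, "ubq_cdc20", P("k.securin.ubq_cdc20"),
                      reactants = "nuc", modifiers = "apc.cdc20_a",
                      sources = "nuc", sinks = "ubq")
  securin <- add_rate(securin, "ubq_cdc20_pho", P("k.securin.ubq_cdc20"),
                      reactants = "pho", modifiers = "apc.cdc20_a",
                      sources = "pho", sinks = "ubq")
  securin <- add_rate(securin, "dk_pho", P("k.common.dk"),
                      reactants = "pho", sources = "pho", sinks = "trash")

  list(wee1 = wee1, cycb = cycb, cdc25a = cdc25a, cdc25b = cdc25b,
       cdc25c = cdc25c, plk1 = plk1, emi1 = emi1, apc = apc, cdh1 = cdh1,
       cdc20 = cdc20, cdc14 = cdc14, securin = securin)
}
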