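# ---------------------------------------------------------------------------
# Calibrated parameters of the example cell-cycle model.  All rate constants
# are in count/concentration units per second; concentrations are
# count / normalized-cell-size.  The shipped values are the calibrated set:
# they hold the quiescent (G0) state near a fixed point with mitogen off and
# reproduce the cell-cycle phase timing with mitogen on.
# ---------------------------------------------------------------------------

cc_defaults <- function() list(
  ## weak-evidence interaction toggles (table entries marked * / **)
  on.cycd_ubq_cdc20 = TRUE, on.p27_ubq_cdc20 = TRUE,
  on.bmyb_act_cyce = TRUE, on.nfy_deact_cdc14 = TRUE,
  on.rb_act_cdc14 = TRUE, on.e2f_ubq_cdc20 = TRUE,
  on.cyca_ubq_skp2 = TRUE, on.cyca_ubq_cdc20 = TRUE,
  on.cyca_adhesion = TRUE, on.cdc25a_act_cdk1 = TRUE,
  on.cdc25a_ubq_btrc = TRUE, on.cdc25b_ubq = TRUE,
  on.cdc25c_act_cycacdk1 = TRUE, on.plk1_act_cycacdk1 = TRUE,
  on.emi1_pho_cycacdk1 = TRUE, on.wee1_pho_cdk1 = TRUE,
  on.rc_delicense = TRUE, on.cycc_react_cdc14 = TRUE,
  on.pol_detach_cdc20 = TRUE, on.tfg_protect_on_dna = TRUE,

  ## common protein-lifecycle plumbing
  k.common.fold = 2.5e-3, k.common.import = 1.5e-3,
  k.common.export = 1e-4, k.common.dk = 2e-5, k.common.dk_unf = 1e-5,
  k.common.ubq_clear = 5e-4, k.common.dispose = 2e-4,
  cost.aa_per_protein = 400, cost.atp_per_aa = 4,

  ## common mRNA lifecycle
  k.m.splice = 6e-3, K.m.splice = 1e4, k.m.export = 1.5e-3,
  k.m.bind_ribo = 2e-8, k.m.unbind_ribo = 1.6e-3,
  k.m.dk_nascent = 1e-5, k.m.dk_nuclear = 1e-5,
  k.m.dk_cytosol = 7e-5, k.m.dk_bound = 7e-5, k.m.dispose = 1e-4,
  cost.nt_per_mrna = 1000, cost.atp_per_nt = 2,

  ## transcription weights: w.<gene>.<inducer>; constitutive entries are
  ## absolute weights, TF entries are efficiencies multiplying the TF amount
  w.p27.const = 1.15, w.rb.const = 0.6, w.cdk2.const = 1.0,
  w.cdk2.e2f = 1e-5, w.cycd.mitogen = 0.22, w.cycd.bmyb = 1e-5,
  w.cyce.e2f = 1.2e-4, w.bmyb.e2f = 3e-5, w.bmyb.self = 1e-5,
  w.nfy.const = 0.02, w.nfy.e2f = 3e-5,
  w.e2f.const = 0.1, w.e2f.self = 2e-4,
  w.cyca.e2f = 5e-5, w.cyca.nfy = 5e-5,
  w.scf.const = 0.17, w.skp2.const = 0.09, w.btrc.e2f = 2e-5,
  w.fbw7.e2f = 2e-5, w.tfg.mitogen = 0.12, w.tfg.skp2 = 1e-5,
  w.tfg.bmyb = 1e-5, w.rc.e2f = 4e-4,
  w.dnapol.e2f = 6e-5, w.dnapol.bmyb = 2.9e-5, w.dnapol.nfy = 1e-5,
  w.wee1.const = 0.3, w.cycb.e2f = 1.2e-4, w.cycb.bmyb = 4e-4,
  w.cycb.nfy = 4e-4, w.cdk1.const = 0.5, w.cdk1.e2f = 1e-5,
  w.cdk1.bmyb = 1e-5, w.cdk1.nfy = 1e-5,
  w.cdc25c.const = 0.05, w.cdc25c.nfy = 1e-5,
  w.plk1.e2f = 8e-5, w.plk1.tfg = 8e-5,
  w.emi1.e2f = 2.5e-4, w.apc.const = 0.5, w.cdh1.const = 0.06,
  w.cdc20.const = 0.08, w.cdc14.const = 0.1,
  w.cdc25a.const = 0.03, w.cdc25a.e2f = 4e-5, w.cdc25a.tfg = 1e-5,
  w.cdc25b.e2f = 2e-5, w.cdc25b.tfg = 2e-5,
  w.securin.e2f = 1.2e-4, w.cycc.const = 1.0, w.kpc.const = 0.1,
  w.rnapol.const = 0.024, w.rnapol.tfg = 6e-5, w.eif4.const = 2.0,
  w.bulk.tfg = 2e-4,
  k.m.polysome_load = 2e-8, k.m.polysome_unload = 4e-8,
  k.tfg.import_aa = 550, k.tfg.import_nt = 150,          # TF-grow boost of bulk (growth) transcripts
  K.txl.eif4 = 2e3,           # eIF-4 half-saturation of total translation
  K.txs.mphase = 2e3,         # chromatin-visibility inhibition by
                              # nuclear active cycB/Cdk1 during M

  ## mitogen sensing / RNA-polymerase control
  k.kpc.act_mitogen = 2e-4, k.kpc.deact = 1e-5,
  k.cycc.bind_cdk8 = 1e-3, k.cycc.ubq_kpc = 1.4e-7,
  k.cycc.pho_mitogen = 1e-6, k.cycc.react_cdc14 = 2e-7,
  k.pol.sequester_cdk8 = 7e-8, k.pol.release_const = 2.0e-4,
  k.pol.release_kpc = 2e-5, k.pol.detach_cdc20 = 4e-7,

  ## G1 control
  k.p27.bind_cycd = 1e-5, k.p27.bind_cyce_i = 1e-5,
  k.p27.bind_cyce_a = 1e-5,
  k.p27.release_active = 5.6e-7, k.p27.release_kpc = 5e-8,
  k.p27.ubq_kpc = 1e-8, k.p27.ubq_skp2 = 1e-7, k.p27.ubq_cdc20 = 1e-8,
  k.rb.bind_e2f = 1e-5, k.rb.pho_cycd = 3e-7, k.rb.pho2 = 3e-8,
  k.rb.depho = 1e-5, k.rb.depho_cdc14 = 2e-7, k.rb.depho2 = 1e-5,
  k.cycd.bind_cdk = 1e-3, k.cycd.ubq_skp2 = 3e-8,
  k.cycd.ubq_cdc20 = 1e-8,
  k.cyce.bind_cdk2 = 1e-5, k.cyce.spont_act = 2e-6,
  k.cyce.act_cdc25a = 5e-7, k.cyce.ubq_fbw7 = 1e-7,
  k.cyce.ubq_skp2 = 1e-7,
  k.e2f.pho_cycb = 5.6e-7, k.e2f.depho = 1e-5, k.e2f.ubq_skp2 = 1e-7,
  k.e2f.ubq_cdc20 = 1e-8, k.e2f.on_dna = 1e-3, k.e2f.off_dna = 1e-3,
  k.bmyb.act_cyca = 5e-7, k.bmyb.act_cyce = 1e-7, k.bmyb.deact = 1e-5,
  k.bmyb.ubq_skp2 = 1e-7, k.bmyb.on_dna = 1e-3, k.bmyb.off_dna = 1e-3,
  k.nfy.act_cyca = 5e-7, k.nfy.act_cyce = 1e-7, k.nfy.deact = 1e-5,
  k.nfy.deact_cdc14 = 2e-7, k.nfy.on_dna = 1e-3, k.nfy.off_dna = 1e-3,
  k.tfg.pho = 1e-5, k.tfg.ubq_skp2 = 1e-7, k.tfg.ubq_fbw7 = 1e-7,
  k.tfg.on_dna = 1e-3, k.tfg.off_dna = 1e-3,

  ## APC(Cdh1) timing
  k.cdh1.inact_cycd = 3.2e-8, k.cdh1.inact_cyce = 3e-7,
  k.cdh1.inact_cyca = 1.5e-6, k.cdh1.inact_cycb = 1e-6,
  k.cdh1.bind_apc = 2e-5, k.cdh1.unbind_apc = 1e-5,
  k.cdh1.depho = 5e-6, k.cdh1.depho_cdc14 = 6e-6,
  k.cdh1.bind_emi1 = 1e-5, k.cdh1.auto = 1e-5, K.cdh1.auto = 200, K.cdh1.gate = 6e1, K.cdh1.seed = 8e2,
  k.cdc25a.ubq_cdh1 = 6e-7, k.scf.ubq_cdh1 = 1.2e-6,
  k.cyca.ubq_cdh1 = 8e-7, k.cdc20.ubq_cdh1 = 1.05e-7,
  k.plk1.ubq_cdh1 = 1.05e-7, k.skp2.ubq_cdh1 = 1.05e-7,
  k.btrc.ubq_cdh1 = 1.05e-7, k.fbw7.ubq_cdh1 = 0,
  k.rc.ubq_cdh1 = 2e-8, k.rc.ubq_cdh1_b = 8e-7, k.cycb.ubq_cdh1 = 5e-8,
  k.cdc25b.ubq_cdh1 = 2e-8,

  ## Cdc25A / S entry
  k.cdc25a.spont_act = 1.5e-6, k.cdc25a.act_cyce = 5e-7,
  k.cdc25a.act_cyca = 5e-7, k.cdc25a.act_cdk1 = 1e-8,
  k.cdc25a.deact_cdc14 = 3e-6, k.cdc25a.repho = 1e-4,
  k.cdc25a.ubq_btrc = 2e-8,

  ## SCF subsystem: affinity ordering Fbw7 > Skp2 > Btrc
  k.scf.bind_fbw7 = 4e-6, k.scf.bind_skp2 = 2e-6, k.scf.bind_btrc = 8e-7,
  k.scf.unbind_sub = 2e-4,
  k.skp2.auto = 3e-4, K.skp2.auto = 200,
  k.fbw7.auto = 3e-4, K.fbw7.auto = 400,
  k.btrc.auto = 1e-4, K.btrc.auto = 200,
  k.skp2.pho_cyca = 1e-7, k.skp2.depho = 1e-5,
  k.fbw7.dimer = 1e-4, k.fbw7.undimer = 1e-4,
  k.btrc.pho = 1e-6, k.btrc.depho = 1e-5, k.btrc.ubq_cdc20 = 1e-8,

  ## replication subsystem
  n.origins = 15000, nt.genome = 6e9, nt.per_origin = 4e5,
  k.rc.bind_origin = 3e-8, k.rc.unbind_origin = 1e-5,
  k.rc.license_cyce = 1.7e-6, k.rc.license_cyca = 1.7e-6,
  k.rc.delicense_cdk1 = 1e-8, k.rc.attach_pol = 3e-7,
  k.rc.traverse = 1.1e-3, k.rc.ubq_skp2 = 2.8e-7,
  k.dnapol.recycle = 1e-3, k.dnapol.ubq = 1e-7,

  ## cycA module
  k.cyca.bind_cdk2 = 1e-5, k.cyca.bind_p27 = 1e-5,
  k.cyca.bind_cdk1 = 2e-6, k.cyca.spont_act = 3e-6,
  k.cyca.act_cdc25b = 2e-6, k.cyca.act_cdc25a = 1e-7,
  k.cyca.pho_wee1 = 1.2e-6, k.cyca.transloc_plk1 = 5.6e-7,
  k.cyca.transloc = 1e-5,

  ## mitotic subsystem
  k.wee1.mature = 1e-3, k.wee1.pho_plk1 = 2.5e-7,
  k.wee1.pho_cdk1 = 6e-9, K.wee1.gate = 8e2, k.wee1.react = 2e-4, k.wee1.reactivate = 3e-5,
  k.wee1.react_cdc14 = 2.8e-7, k.wee1.ubq_btrc = 2.8e-7,
  k.cycb.bind_cdk1 = 5e-6, k.cycb.spont_act = 3e-7,
  k.cycb.act_cdc25c = 3e-6, k.cycb.act_cdc25b = 1.5e-7,
  k.cycb.pho_wee1 = 6e-6, k.cycb.transloc_plk1 = 5.6e-7,
  k.cycb.transloc = 1e-7, k.cycb.ubq_cdc20 = 6e-7,
  k.cdc25b.spont_act = 2e-7, k.cdc25b.act_cycacdk1 = 1e-6,
  k.cdc25b.act_cycbcdk1 = 2e-7, k.cdc25b.act_tfg = 1e-8,
  k.cdc25b.deact_cdc14 = 1.5e-6, k.cdc25b.repho = 1e-4,
  k.cdc25b.ubq_btrc = 2e-8,
  k.cdc25c.act_cycb = 3e-6, k.cdc25c.act_cyca = 1e-7,
  k.cdc25c.act_plk1 = 2e-8, k.cdc25c.transloc_plk1 = 5.6e-7,
  k.cdc25c.deact_cdc14 = 1.5e-6, k.cdc25c.repho = 1e-4,
  k.plk1.act_cycb = 2.2e-7, k.plk1.act_cyca = 2.2e-7,
  k.plk1.transloc = 2e-4, k.plk1.deact_cdc14 = 3e-6,
  k.plk1.repho = 1e-4,
  k.emi1.bind_cdc20 = 1e-4, k.emi1.bind_cdh1 = 1e-5,
  k.emi1.pho_cycb = 5.6e-7, k.emi1.pho_cyca = 2.8e-7,
  k.emi1.ubq_btrc = 2.8e-7, k.emi1.ubq_skp2 = 2e-8,
  k.apc.bind_cdc20 = 3e-10, k.apc.bind_cdh1 = 1e-5,
  k.apc.unbind_cdc20_cdc14 = 5.6e-7, k.apc.act_cdc20_cycb = 2e-6,
  k.apc.act_cdc20_cyca = 1e-8, k.apc.deact_cdc20 = 1e-4,
  k.securin.bind_cdc14 = 2e-5, k.securin.unbind_cdc14 = 1e-5,
  k.securin.pho_cdk1 = 1e-7, k.securin.depho = 1e-4,
  k.securin.ubq_cdc20 = 2.5e-7,
  k.cdc14.act_plk1 = 2.5e-7, k.cdc14.spend = 4e-4,
  k.cdc14.recover = 1e-3,
  k.cyca.ubq_cdc20 = 1e-6, k.cyca.ubq_skp2 = 2e-8,

  ## division trigger (mitotic exit)
  div.root_state = "cdc14.act", div.threshold = 3.5e2,
  div.cdc14_min = 1.5e2, div.cdh1_min = 1.2e3, div.securin_max = 4e2,
  div.cyce_max = 1e6,

  ## G0 (quiescent) pools: the calibration anchors
  x0.p27.nuc = 1.3e4, x0.rb.nuc = 1.1e4,
  x0.cdk2.nuc = 2e4, x0.cdk1.cyt = 8e3, x0.cdk1.nuc = 2e3,
  x0.wee1.act = 4e3, x0.apc.nuc = 2e3, x0.apc.cdh1_c = 8e3,
  x0.cdh1.in_apc = 8e3, x0.cdh1.nuc = 2e3,
  x0.cdc25c.nuc = 3e3, x0.cdc14.nuc = 5e3,
  x0.cycc.cdk8_c = 2e4, x0.cycc.nuc = 1e3,
  x0.kpc.nuc = 2e3, x0.eif4.cyt = 5e4,
  ## G0 mRNA pools of the constitutively expressed proteins
  x0_states = cc_calibrated_state(),
  x0.m_p27 = 35, x0.m_rb = 30, x0.m_cdk2 = 55, x0.m_cdk1 = 27,
  x0.m_wee1 = 18, x0.m_apc = 27, x0.m_cdh1 = 27, x0.m_cdc20 = 13,
  x0.m_cdc14 = 16, x0.m_cdc25c = 8, x0.m_cdc25a = 2, x0.m_scf = 18,
  x0.m_skp2 = 6, x0.m_nfy = 1, x0.m_e2f = 1, x0.m_cycc = 32,
  x0.m_kpc = 13, x0.m_rnapol = 70, x0.m_eif4 = 65
)

#' Parameters of the example cell-cycle model
#'
#' Returns the shipped calibrated parameter set, optionally overridden.
#' Overriding an unknown name is an error (protects against typos).
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
cellcycle_params <- function(...) {
  p <- cc_defaults()
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown cell-cycle parameter(s): ", paste(bad, collapse = ", "))
    p <- utils::modifyList(p, ov)
  }
  p
}
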