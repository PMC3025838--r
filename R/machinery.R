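# ---------------------------------------------------------------------------
# The basic-cellular-machinery construct set: pools of amino acids,
# nucleotides, adenylates, rRNA/tRNA/snRNA/bulk mRNA, ribosomes, RNA
# polymerase, bulk protein and lipids, wired so that global transcription is
# limited by engaged polymerase and nucleotides and global translation by
# engaged ribosomes and amino acids.  The census of the default topology is
# fixed: 41 states and 69 rates.
#
# Cross-construct bookkeeping entries (amino acids consumed per protein,
# nucleotides per transcript, ATP per bond) ride on the synthesis and
# disposal rates themselves, so moiety conservation is structural rather
# than approximate.
# ---------------------------------------------------------------------------

#' Default machinery parameters
#'
#' Rate constants (`k.*`), initial amounts (`x0.*`), per-molecule costs
#' (`cost.*`) and allocation-group capacities (`cap.*`) for the machinery
#' construct set.  All amounts are molecule counts; the quiescent values
#' put ~1e8 bulk proteins and ~3e4 RNA polymerases (mostly sequestered by
#' cycC/Cdk8) in the cell.
#'
#' @param ... overrides, e.g. `machinery_params(k.rnapol.release_pol = 0)`.
#' @return named list of parameters.
#' @export
machinery_params <- function(...) {
  p <- list(
    ## per-molecule costs (tunable, never hard-coded)
    cost.aa_per_protein = 400,
    cost.aa_per_pol     = 4000,
    cost.nt_per_mrna    = 1000,
    cost.nt_per_rrna    = 4000,
    cost.nt_per_trna    = 80,
    cost.nt_per_snrna   = 150,
    cost.atp_per_aa     = 4,
    cost.atp_per_nt     = 2,

    ## allocation-group capacities: transcription limited by engaged
    ## polymerase x nucleotide saturation; translation by engaged
    ## ribosomes x amino-acid saturation
    cap.txs.k_per_pol  = 3.9e-3,   # transcripts /s per engaged polymerase
    cap.txs.K_NT       = 1e9,      # NT half-saturation (counts at size 1)
    cap.txl.k_per_ribo = 2.2e-2,   # proteins /s per engaged ribosome
    cap.K_ATP          = 2e8,      # ATP half-saturation of both capacities
    cap.txl.K_AA       = 2e6,

    ## amino acids
    x0.aa.cytosol = 1.0e8, x0.aa.on_trna = 2.0e6,
    x0.aa.in_protein = 4.4e10, x0.aa.trash = 1.0e8,
    k.aa.import_aa = 1.2e4,      # count/s at size 1, damped by pool sensing
    K.aa.import_aa = 2.0e8,
    k.aa.bind_trna = 2.7e-7,     # /s per (AA conc x free-tRNA conc)
    K.aa.bind_trna = 4.0e6,      # product inhibition by the charged pool
    k.aa.dk_aa_cytosol = 1.0e-7,
    k.aa.recycle_aa = 1.0e-4,
    k.aa.export_aa = 5.0e-6,

    ## nucleotides
    x0.nt.cytosol = 1.0e9, x0.nt.in_rna = 1.4e9, x0.nt.trash = 1.0e8,
    k.nt.import_nt = 2.5e3,
    K.nt.import_nt = 1.0e9,
    k.nt.dk_nt_cytosol = 1.0e-9,
    k.nt.recycle_nt = 1.0e-4,
    k.nt.export_nt = 1.0e-4,

    ## adenylates: lumped saturating ATP regeneration
    x0.atp.atp = 1.0e9, x0.atp.adp = 1.0e8, x0.atp.amp = 1.0e7,
    k.atp.synth_atp = 2.0e7,     # max count/s at size 1
    K.atp.synth_atp = 5.0e7,     # ADP half-saturation
    K.atp.synth_glc = 2.0e8,     # glucose half-saturation
    k.atp.basal_use_atp = 2.0e-3,
    k.atp.deaden_adp = 1.0e-6,
    k.atp.regen_amp = 1.0e-5,

    ## rRNA / ribosomes
    x0.rrna.nascent = 5.0e3, x0.rrna.in_ribosome = 1.56e5,
    x0.rrna.trash = 1.0e3,
    w.txs_rrna = 35,             # constitutive transcription weight
    k.rrna.assemble_ribosome = 2.0e-5,
    k.rrna.dk_rrna_nascent = 1.0e-6,
    k.rrna.dispose_rrna = 1.0e-4,
    x0.ribo.assembling = 2.0e3, x0.ribo.free = 1.0e5,
    x0.ribo.translating = 2.0e4, x0.ribo.trash = 1.0e3,
    k.ribo.mature_ribo = 1.0e-4,
    k.ribo.dk_ribo_assembling = 1.0e-7,
    k.ribo.dk_ribosome = 3.0e-6,
    k.ribo.dk_ribo_translating = 1.0e-7,
    k.ribo.dispose_ribosome = 1.0e-4,

    ## tRNA
    x0.trna.free = 1.0e4, x0.trna.trash = 1.0e4,
    w.txs_trna = 2.2,
    k.trna.dk_trna = 2.0e-6,
    k.trna.dispose_trna = 1.0e-4,

    ## snRNA / spliceosome
    x0.snrna.free = 1.0e4, x0.snrna.spliceosome = 1.0e5,
    x0.snrna.trash = 1.0e3,
    w.txs_snrna = 2,
    k.snrna.assemble_spliceosome = 1.0e-5,
    k.snrna.dk_snrna = 1.0e-6,
    k.snrna.dk_spliceosome = 1.0e-6,
    k.snrna.dispose_snrna = 1.0e-4,

    ## bulk mRNA (all transcripts not individually modeled)
    x0.mrna.nascent = 4.3e2, x0.mrna.nuclear = 1.7e3,
    x0.mrna.cytosol = 1.45e4, x0.mrna.ribosome_bound = 2.0e4,
    x0.mrna.trash = 5.0e2,
    w.txs_mrna = 700,
    k.mrna.splice_mrna = 6.0e-3,
    K.mrna.splice_mrna = 1.0e4,  # spliceosome half-saturation
    k.mrna.export_mrna = 1.5e-3,
    k.mrna.bind_ribosome = 2.3e-8,
    k.mrna.unbind_ribosome = 1.6e-3,
    k.mrna.dk_mrna_nascent = 1.0e-5,
    k.mrna.dk_mrna_nuclear = 1.0e-5,
    k.mrna.dk_mrna_cytosol = 7.0e-5,
    k.mrna.dk_mrna_bound = 7.0e-5,
    k.mrna.dispose_mrna = 1.0e-4,

    ## RNA polymerase (pol I+II+III as one pool)
    x0.rnapol.unfold = 1.0e2, x0.rnapol.sequestered = 2.72e4,
    x0.rnapol.active = 2.0e3, x0.rnapol.transcribing = 1.0e3,
    x0.rnapol.trash = 1.0e2,
    w.txl_pol = 0.7,              # translation weight (bulk-mRNA units)
    k.rnapol.fold_pol = 1.0e-3,
    k.rnapol.sequester_pol = 5.0e-4,   # rewired to cycC/Cdk8 by the
    k.rnapol.release_pol = 3.7e-5,     # cell-cycle model
    k.rnapol.bind_dna_pol = 2.0e-3,
    k.rnapol.unbind_dna_pol = 4.0e-3,
    k.rnapol.dk_pol_unfold = 1.0e-5,
    k.rnapol.dk_pol_sequestered = 1.0e-7,
    k.rnapol.dk_pol = 2.0e-6,
    k.rnapol.dk_pol_transcribing = 1.0e-7,
    k.rnapol.dispose_pol = 1.0e-4,

    ## bulk protein (the size reference)
    x0.prot.unfold = 2.0e5, x0.prot.cytosol = 5.6e7,
    x0.prot.nucleus = 1.0e7, x0.prot.in_use = 3.0e7,
    x0.prot.trash = 2.0e6,
    w.txl_prot = 1,              # weight per bulk-mRNA molecule
    k.prot.fold_prot = 2.5e-3,
    k.prot.import_prot_nuc = 1.0e-6,
    k.prot.export_prot_nuc = 5.0e-6,
    k.prot.bind_prot = 3.0e-6,
    k.prot.unbind_prot = 5.0e-6,
    k.prot.dk_unfold = 1.0e-5,
    k.prot.dk_cytosol = 5.0e-6,
    k.prot.dk_nucleus = 5.0e-6,
    k.prot.dk_in_use = 5.0e-6,
    k.prot.dispose_prot = 3.0e-4,

    ## lipids (minimal lifecycle; membranes abstracted)
    x0.lipid.precursor = 1.0e6, x0.lipid.membrane = 5.0e7,
    x0.lipid.trash = 1.0e6,
    k.lipid.import_lipid = 1.0e2,
    k.lipid.synth_lipid = 2.0e2,
    K.lipid.synth_lipid = 5.0e7,  # ATP half-saturation
    k.lipid.incorporate_lipid = 3.0e-4,
    k.lipid.dk_lipid = 5.0e-6,
    k.lipid.dispose_lipid = 1.0e-4,

    ## energy substrate
    x0.glc.cytosol = 1.0e9,
    k.glc.import_glc = 1.2e5,
    K.glc.import_glc = 2.0e9,
    cost.glc_per_atp = 0.03,
    k.glc.use_glc_basal = 1.0e-6
  )
  utils::modifyList(p, list(...))
}

mp <- function(params, name) {
  v <- params[[name]]
  if (is.null(v)) stop(sprintf("missing machinery parameter '%s'", name))
  v
}

#' Build the basic-cellular-machinery construct set
#'
#' @param params parameter map from [machinery_params()]; a missing
#'   parameter is a build error naming it.
#' @return a list of class `MachineryModel`: `constructs`, the allocation
#'   `groups` (total transcription `txs`, total translation `txl`), the
#'   `size` definition (bulk-protein states), and the census.
#' @export
build_machinery_model <- function(params = machinery_params()) {
  P <- function(n) mp(params, n)
  aa_p <- P("cost.aa_per_protein"); aa_pol <- P("cost.aa_per_pol")
  atp_aa <- P("cost.atp_per_aa"); atp_nt <- P("cost.atp_per_nt")

  ## -- amino acids ---------------------------------------------------------
  aa <- new_construct("aa", "machinery")
  aa <- add_state(aa, "cytosol", P("x0.aa.cytosol"))
  aa <- add_state(aa, "on_trna", P("x0.aa.on_trna"))
  aa <- add_state(aa, "in_protein", P("x0.aa.in_protein"))
  aa <- add_state(aa, "trash", P("x0.aa.trash"), is_sink = TRUE)
  aa <- add_rate(aa, "import_aa", P("k.aa.import_aa"),
                 modifiers = "cytosol", inhib = c(cytosol = P("K.aa.import_aa")),
                 sinks = "cytosol", scale_size = FALSE)
  aa <- add_rate(aa, "bind_trna", P("k.aa.bind_trna"),
                 reactants = c("cytosol", "trna.free"),
                 modifiers = "on_trna",
                 inhib = c(on_trna = P("K.aa.bind_trna")),
                 sources = "cytosol", sinks = "on_trna")
  aa <- add_rate(aa, "dk_aa_cytosol", P("k.aa.dk_aa_cytosol"),
                 reactants = "cytosol", sources = "cytosol", sinks = "trash")
  aa <- add_rate(aa, "recycle_aa", P("k.aa.recycle_aa"),
                 reactants = "trash", sources = "trash", sinks = "cytosol")
  aa <- add_rate(aa, "export_aa", P("k.aa.export_aa"),
                 reactants = "trash", sources = "trash")

  ## -- nucleotides ---------------------------------------------------------
  nt <- new_construct("nt", "machinery")
  nt <- add_state(nt, "cytosol", P("x0.nt.cytosol"))
  nt <- add_state(nt, "in_rna", P("x0.nt.in_rna"))
  nt <- add_state(nt, "trash", P("x0.nt.trash"), is_sink = TRUE)
  nt <- add_rate(nt, "import_nt", P("k.nt.import_nt"),
                 modifiers = "cytosol", inhib = c(cytosol = P("K.nt.import_nt")),
                 sinks = "cytosol", scale_size = FALSE)
  nt <- add_rate(nt, "dk_nt_cytosol", P("k.nt.dk_nt_cytosol"),
                 reactants = "cytosol", sources = "cytosol", sinks = "trash")
  nt <- add_rate(nt, "recycle_nt", P("k.nt.recycle_nt"),
                 reactants = "trash", sources = "trash", sinks = "cytosol")
  nt <- add_rate(nt, "export_nt", P("k.nt.export_nt"),
                 reactants = "trash", sources = "trash")

  ## -- adenylates ----------------------------------------------------------
  atp <- new_construct("atp", "machinery")
  atp <- add_state(atp, "atp", P("x0.atp.atp"))
  atp <- add_state(atp, "adp", P("x0.atp.adp"))
  atp <- add_state(atp, "amp", P("x0.atp.amp"))
  atp <- add_rate(atp, "synth_atp", P("k.atp.synth_atp"),
                  reactants = "adp", modifiers = "glc.cytosol",
                  sat = c(adp = P("K.atp.synth_atp"),
                          glc.cytosol = P("K.atp.synth_glc")),
                  sources = c(adp = 1,
                              glc.cytosol = P("cost.glc_per_atp")),
                  sinks = "atp", law_kind = "saturating")
  atp <- add_rate(atp, "basal_use_atp", P("k.atp.basal_use_atp"),
                  reactants = "atp", sources = "atp", sinks = "adp")
  atp <- add_rate(atp, "deaden_adp", P("k.atp.deaden_adp"),
                  reactants = "adp", sources = "adp", sinks = "amp")
  atp <- add_rate(atp, "regen_amp", P("k.atp.regen_amp"),
                  reactants = "amp", sources = "amp", sinks = "adp")

  ## -- rRNA ----------------------------------------------------------------
  nt_rr <- P("cost.nt_per_rrna")
  rrna <- new_construct("rrna", "machinery")
  rrna <- add_state(rrna, "nascent", P("x0.rrna.nascent"), "nucleus")
  rrna <- add_state(rrna, "in_ribosome", P("x0.rrna.in_ribosome"))
  rrna <- add_state(rrna, "trash", P("x0.rrna.trash"), is_sink = TRUE)
  rrna <- add_rate(rrna, "txs_rrna", 1, law_kind = "allocation",
                   group = "txs", weight_const = P("w.txs_rrna"),
                   sources = c(nt.cytosol = nt_rr,
                               atp.atp = atp_nt * nt_rr),
                   sinks = c(nascent = 1, nt.in_rna = nt_rr,
                             atp.adp = atp_nt * nt_rr))
  rrna <- add_rate(rrna, "assemble_ribosome", P("k.rrna.assemble_ribosome"),
                   reactants = "nascent",
                   sources = "nascent",
                   sinks = c(in_ribosome = 1, ribo.assembling = 1))
  rrna <- add_rate(rrna, "dk_rrna_nascent", P("k.rrna.dk_rrna_nascent"),
                   reactants = "nascent", sources = "nascent",
                   sinks = "trash")
  rrna <- add_rate(rrna, "dispose_rrna", P("k.rrna.dispose_rrna"),
                   reactants = "trash",
                   sources = c(trash = 1, nt.in_rna = nt_rr),
                   sinks = c(nt.trash = nt_rr))

  ## -- ribosomes -----------------------------------------------------------
  ribo <- new_construct("ribo", "machinery")
  ribo <- add_state(ribo, "assembling", P("x0.ribo.assembling"), "nucleus")
  ribo <- add_state(ribo, "free", P("x0.ribo.free"))
  ribo <- add_state(ribo, "translating", P("x0.ribo.translating"))
  ribo <- add_state(ribo, "trash", P("x0.ribo.trash"), is_sink = TRUE)
  ribo <- add_rate(ribo, "mature_ribo", P("k.ribo.mature_ribo"),
                   reactants = "assembling", sources = "assembling",
                   sinks = "free")
  ribo <- add_rate(ribo, "dk_ribo_assembling", P("k.ribo.dk_ribo_assembling"),
                   reactants = "assembling",
                   sources = c(assembling = 1, rrna.in_ribosome = 1),
                   sinks = c(trash = 1, rrna.trash = 1))
  ribo <- add_rate(ribo, "dk_ribosome", P("k.ribo.dk_ribosome"),
                   reactants = "free",
                   sources = c(free = 1, rrna.in_ribosome = 1),
                   sinks = c(trash = 1, rrna.trash = 1))
  ribo <- add_rate(ribo, "dk_ribo_translating", P("k.ribo.dk_ribo_translating"),
                   reactants = "translating",
                   sources = c(translating = 1, rrna.in_ribosome = 1,
                               mrna.ribosome_bound = 1),
                   sinks = c(trash = 1, rrna.trash = 1, mrna.trash = 1))
  ribo <- add_rate(ribo, "dispose_ribosome", P("k.ribo.dispose_ribosome"),
                   reactants = "trash", sources = "trash")

  ## -- tRNA ----------------------------------------------------------------
  nt_tr <- P("cost.nt_per_trna")
  trna <- new_construct("trna", "machinery")
  trna <- add_state(trna, "free", P("x0.trna.free"))
  trna <- add_state(trna, "trash", P("x0.trna.trash"), is_sink = TRUE)
  trna <- add_rate(trna, "txs_trna", 1, law_kind = "allocation",
                   group = "txs", weight_const = P("w.txs_trna"),
                   sources = c(nt.cytosol = nt_tr,
                               atp.atp = atp_nt * nt_tr),
                   sinks = c(free = 1, nt.in_rna = nt_tr,
                             atp.adp = atp_nt * nt_tr))
  trna <- add_rate(trna, "dk_trna", P("k.trna.dk_trna"),
                   reactants = "free", sources = "free", sinks = "trash")
  trna <- add_rate(trna, "dispose_trna", P("k.trna.dispose_trna"),
                   reactants = "trash",
                   sources = c(trash = 1, nt.in_rna = nt_tr),
                   sinks = c(nt.trash = nt_tr))

  ## -- snRNA / spliceosome -------------------------------------------------
  nt_sn <- P("cost.nt_per_snrna")
  snrna <- new_construct("snrna", "machinery")
  snrna <- add_state(snrna, "free", P("x0.snrna.free"), "nucleus")
  snrna <- add_state(snrna, "spliceosome", P("x0.snrna.spliceosome"),
                     "nucleus")
  snrna <- add_state(snrna, "trash", P("x0.snrna.trash"), is_sink = TRUE)
  snrna <- add_rate(snrna, "txs_snrna", 1, law_kind = "allocation",
                    group = "txs", weight_const = P("w.txs_snrna"),
                    sources = c(nt.cytosol = nt_sn,
                                atp.atp = atp_nt * nt_sn),
                    sinks = c(free = 1, nt.in_rna = nt_sn,
                              atp.adp = atp_nt * nt_sn))
  snrna <- add_rate(snrna, "assemble_spliceosome",
                    P("k.snrna.assemble_spliceosome"),
                    reactants = "free", sources = "free",
                    sinks = "spliceosome")
  snrna <- add_rate(snrna, "dk_snrna", P("k.snrna.dk_snrna"),
                    reactants = "free", sources = "free", sinks = "trash")
  snrna <- add_rate(snrna, "dk_spliceosome", P("k.snrna.dk_spliceosome"),
                    reactants = "spliceosome", sources = "spliceosome",
                    sinks = "trash")
  snrna <- add_rate(snrna, "dispose_snrna", P("k.snrna.dispose_snrna"),
                    reactants = "trash",
                    sources = c(trash = 1, nt.in_rna = nt_sn),
                    sinks = c(nt.trash = nt_sn))

  ## -- bulk mRNA -----------------------------------------------------------
  nt_m <- P("cost.nt_per_mrna")
  mrna <- new_construct("mrna", "mrna")
  mrna <- add_state(mrna, "nascent", P("x0.mrna.nascent"), "nucleus")
  mrna <- add_state(mrna, "nuclear", P("x0.mrna.nuclear"), "nucleus")
  mrna <- add_state(mrna, "cytosol", P("x0.mrna.cytosol"))
  mrna <- add_state(mrna, "ribosome_bound", P("x0.mrna.ribosome_bound"))
  mrna <- add_state(mrna, "trash", P("x0.mrna.trash"), is_sink = TRUE)
  mrna <- add_rate(mrna, "txs_mrna", 1, law_kind = "allocation",
                   group = "txs", weight_const = P("w.txs_mrna"),
                   sources = c(nt.cytosol = nt_m, atp.atp = atp_nt * nt_m),
                   sinks = c(nascent = 1, nt.in_rna = nt_m,
                             atp.adp = atp_nt * nt_m))
  mrna <- add_rate(mrna, "splice_mrna", P("k.mrna.splice_mrna"),
                   reactants = "nascent",
                   modifiers = "snrna.spliceosome",
                   sat = c(snrna.spliceosome = P("K.mrna.splice_mrna")),
                   sources = "nascent", sinks = "nuclear")
  mrna <- add_rate(mrna, "export_mrna", P("k.mrna.export_mrna"),
                   reactants = "nuclear", sources = "nuclear",
                   sinks = "cytosol")
  mrna <- add_rate(mrna, "bind_ribosome", P("k.mrna.bind_ribosome"),
                   reactants = c("cytosol", "ribo.free"),
                   sources = c(cytosol = 1, ribo.free = 1),
                   sinks = c(ribosome_bound = 1, ribo.translating = 1))
  mrna <- add_rate(mrna, "unbind_ribosome", P("k.mrna.unbind_ribosome"),
                   reactants = "ribosome_bound",
                   sources = c(ribosome_bound = 1, ribo.translating = 1),
                   sinks = c(cytosol = 1, ribo.free = 1))
  mrna <- add_rate(mrna, "dk_mrna_nascent", P("k.mrna.dk_mrna_nascent"),
                   reactants = "nascent", sources = "nascent",
                   sinks = "trash")
  mrna <- add_rate(mrna, "dk_mrna_nuclear", P("k.mrna.dk_mrna_nuclear"),
                   reactants = "nuclear", sources = "nuclear",
                   sinks = "trash")
  mrna <- add_rate(mrna, "dk_mrna_cytosol", P("k.mrna.dk_mrna_cytosol"),
                   reactants = "cytosol", sources = "cytosol",
                   sinks = "trash")
  mrna <- add_rate(mrna, "dk_mrna_bound", P("k.mrna.dk_mrna_bound"),
                   reactants = "ribosome_bound",
                   sources = c(ribosome_bound = 1, ribo.translating = 1),
                   sinks = c(trash = 1, ribo.free = 1))
  mrna <- add_rate(mrna, "dispose_mrna", P("k.mrna.dispose_mrna"),
                   reactants = "trash",
                   sources = c(trash = 1, nt.in_rna = nt_m),
                   sinks = c(nt.trash = nt_m))

  ## -- RNA polymerase ------------------------------------------------------
  pol <- new_construct("rnapol", "machinery")
  pol <- add_state(pol, "unfold", P("x0.rnapol.unfold"))
  pol <- add_state(pol, "sequestered", P("x0.rnapol.sequestered"), "nucleus")
  pol <- add_state(pol, "active", P("x0.rnapol.active"), "nucleus")
  pol <- add_state(pol, "transcribing", P("x0.rnapol.transcribing"),
                   "nucleus")
  pol <- add_state(pol, "trash", P("x0.rnapol.trash"), is_sink = TRUE)
  pol <- add_rate(pol, "txl_pol", 1, law_kind = "allocation",
                  group = "txl", weight_const = P("w.txl_pol"),
                  sources = c(aa.on_trna = aa_pol,
                              atp.atp = atp_aa * aa_pol),
                  sinks = c(unfold = 1, aa.in_protein = aa_pol,
                            atp.adp = atp_aa * aa_pol))
  pol <- add_rate(pol, "fold_pol", P("k.rnapol.fold_pol"),
                  reactants = "unfold", sources = "unfold", sinks = "active")
  pol <- add_rate(pol, "sequester_pol", P("k.rnapol.sequester_pol"),
                  reactants = "active", sources = "active",
                  sinks = "sequestered")
  pol <- add_rate(pol, "release_pol", P("k.rnapol.release_pol"),
                  reactants = "sequestered", sources = "sequestered",
                  sinks = "active")
  pol <- add_rate(pol, "bind_dna_pol", P("k.rnapol.bind_dna_pol"),
                  reactants = "active", sources = "active",
                  sinks = "transcribing")
  pol <- add_rate(pol, "unbind_dna_pol", P("k.rnapol.unbind_dna_pol"),
                  reactants = "transcribing", sources = "transcribing",
                  sinks = "active")
  pol <- add_rate(pol, "dk_pol_unfold", P("k.rnapol.dk_pol_unfold"),
                  reactants = "unfold", sources = "unfold", sinks = "trash")
  pol <- add_rate(pol, "dk_pol_sequestered",
                  P("k.rnapol.dk_pol_sequestered"),
                  reactants = "sequestered", sources = "sequestered",
                  sinks = "trash")
  pol <- add_rate(pol, "dk_pol", P("k.rnapol.dk_pol"),
                  reactants = "active", sources = "active", sinks = "trash")
  pol <- add_rate(pol, "dk_pol_transcribing",
                  P("k.rnapol.dk_pol_transcribing"),
                  reactants = "transcribing", sources = "transcribing",
                  sinks = "trash")
  pol <- add_rate(pol, "dispose_pol", P("k.rnapol.dispose_pol"),
                  reactants = "trash",
                  sources = c(trash = 1, aa.in_protein = aa_pol),
                  sinks = c(aa.trash = aa_pol))

  ## -- bulk protein (size reference) ---------------------------------------
  prot <- new_construct("prot", "machinery")
  prot <- add_state(prot, "unfold", P("x0.prot.unfold"))
  prot <- add_state(prot, "cytosol", P("x0.prot.cytosol"))
  prot <- add_state(prot, "nucleus", P("x0.prot.nucleus"), "nucleus")
  prot <- add_state(prot, "in_use", P("x0.prot.in_use"))
  prot <- add_state(prot, "trash", P("x0.prot.trash"), is_sink = TRUE)
  prot <- add_rate(prot, "txl_prot", P("w.txl_prot"),
                   law_kind = "allocation", group = "txl",
                   weight_states = c("mrna.cytosol", "mrna.ribosome_bound"),
                   sources = c(aa.on_trna = aa_p, atp.atp = atp_aa * aa_p),
                   sinks = c(unfold = 1, aa.in_protein = aa_p,
                             atp.adp = atp_aa * aa_p))
  prot <- add_rate(prot, "fold_prot", P("k.prot.fold_prot"),
                   reactants = "unfold", sources = "unfold",
                   sinks = "cytosol")
  prot <- add_rate(prot, "import_prot_nuc", P("k.prot.import_prot_nuc"),
                   reactants = "cytosol", sources = "cytosol",
                   sinks = "nucleus")
  prot <- add_rate(prot, "export_prot_nuc", P("k.prot.export_prot_nuc"),
                   reactants = "nucleus", sources = "nucleus",
                   sinks = "cytosol")
  prot <- add_rate(prot, "bind_prot", P("k.prot.bind_prot"),
                   reactants = "cytosol", sources = "cytosol",
                   sinks = "in_use")
  prot <- add_rate(prot, "unbind_prot", P("k.prot.unbind_prot"),
                   reactants = "in_use", sources = "in_use",
                   sinks = "cytosol")
  prot <- add_rate(prot, "dk_unfold", P("k.prot.dk_unfold"),
                   reactants = "unfold", sources = "unfold", sinks = "trash")
  prot <- add_rate(prot, "dk_cytosol", P("k.prot.dk_cytosol"),
                   reactants = "cytosol", sources = "cytosol",
                   sinks = "trash")
  prot <- add_rate(prot, "dk_nucleus", P("k.prot.dk_nucleus"),
                   reactants = "nucleus", sources = "nucleus",
                   sinks = "trash")
  prot <- add_rate(prot, "dk_in_use", P("k.prot.dk_in_use"),
                   reactants = "in_use", sources = "in_use", sinks = "trash")
  prot <- add_rate(prot, "dispose_prot", P("k.prot.dispose_prot"),
                   reactants = "trash",
                   sources = c(trash = 1, aa.in_protein = aa_p),
                   sinks = c(aa.trash = aa_p))

  ## -- lipids --------------------------------------------------------------
  lipid <- new_construct("lipid", "machinery")
  lipid <- add_state(lipid, "precursor", P("x0.lipid.precursor"))
  lipid <- add_state(lipid, "membrane", P("x0.lipid.membrane"), "membrane")
  lipid <- add_state(lipid, "trash", P("x0.lipid.trash"), is_sink = TRUE)
  lipid <- add_rate(lipid, "import_lipid", P("k.lipid.import_lipid"),
                    sinks = "precursor", scale_size = FALSE)
  lipid <- add_rate(lipid, "synth_lipid", P("k.lipid.synth_lipid"),
                    modifiers = "atp.atp",
                    sat = c(atp.atp = P("K.lipid.synth_lipid")),
                    sinks = "precursor", law_kind = "saturating")
  lipid <- add_rate(lipid, "incorporate_lipid",
                    P("k.lipid.incorporate_lipid"),
                    reactants = "precursor", sources = "precursor",
                    sinks = "membrane")
  lipid <- add_rate(lipid, "dk_lipid", P("k.lipid.dk_lipid"),
                    reactants = "membrane", sources = "membrane",
                    sinks = "trash")
  lipid <- add_rate(lipid, "dispose_lipid", P("k.lipid.dispose_lipid"),
                    reactants = "trash", sources = "trash")

  ## -- energy substrate ----------------------------------------------------
  glc <- new_construct("glc", "machinery")
  glc <- add_state(glc, "cytosol", P("x0.glc.cytosol"))
  glc <- add_rate(glc, "import_glc", P("k.glc.import_glc"),
                  modifiers = "cytosol",
                  inhib = c(cytosol = P("K.glc.import_glc")),
                  sinks = "cytosol", scale_size = FALSE)
  glc <- add_rate(glc, "use_glc_basal", P("k.glc.use_glc_basal"),
                  reactants = "cytosol", sources = "cytosol")

  constructs <- list(aa, nt, atp, rrna, ribo, trna, snrna, mrna, pol, prot,
                     lipid, glc)
  groups <- list(
    txs = list(k = P("cap.txs.k_per_pol"),
               factors = list(law_factor("rnapol.transcribing"),
                              law_factor("nt.cytosol", "sat",
                                         P("cap.txs.K_NT")),
                              law_factor("atp.atp", "sat",
                                         P("cap.K_ATP")))),
    txl = list(k = P("cap.txl.k_per_ribo"),
               factors = list(law_factor("ribo.translating"),
                              law_factor("aa.on_trna", "sat",
                                         P("cap.txl.K_AA")),
                              law_factor("atp.atp", "sat",
                                         P("cap.K_ATP")))))
  size_states <- paste0("prot.", c("unfold", "cytosol", "nucleus",
                                   "in_use", "trash"))
  size <- list(states = size_states,
               reference = sum(vapply(
                 c("x0.prot.unfold", "x0.prot.cytosol", "x0.prot.nucleus",
                   "x0.prot.in_use", "x0.prot.trash"), P, 0)))
  cen <- census(constructs)
  if (cen[["states"]] != 41L || cen[["rates"]] != 69L)
    stop(sprintf("machinery census is %d states / %d rates; expected 41 / 69",
                 cen[["states"]], cen[["rates"]]))
  structure(list(constructs = constructs, groups = groups, size = size,
                 params = params, state_count = cen[["states"]],
                 rate_count = cen[["rates"]], size_reference = size_states),
            class = "MachineryModel")
}

#' Amino-acid moiety weights of the machinery model
#'
#' Weight vector for [check_conservation()]: 1 per free/charged/trash amino
#' acid and per residue bound in protein.
#' @param params machinery parameters.
#' @return named numeric vector over qualified states.
#' @export
aa_moiety <- function(params = machinery_params()) {
  c(aa.cytosol = 1, aa.on_trna = 1, aa.in_protein = 1, aa.trash = 1)
}

#' Machinery boundary (membrane-transport) rates for the amino-acid moiety
#' @return character vector of qualified rate names.
#' @export
aa_boundaries <- function() c("aa.import_aa", "aa.export_aa")

#' @export
print.MachineryModel <- function(x, ...) {
  cat(sprintf("<MachineryModel: %d states, %d rates, %d constructs>\n",
              x$state_count, x$rate_count, length(x$constructs)))
  invisible(x)
}
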