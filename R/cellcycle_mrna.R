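# ---------------------------------------------------------------------------
# Per-gene mRNA lifecycles.  Each of the 33 regulatory proteins has a 5-state
# mRNA construct (nascent -> spliced/nuclear -> cytosolic -> ribosome-bound
# -> trash).  Transcription is realized as allocation members of the global
# `txs` group: one member per inducer (weights add, so a gene's total weight
# is the constitutive term plus the summed amounts of its transcription
# factors) plus a small basal leak.  Ribosome engagement (including
# additional loading of already-engaged messages, i.e. polysomes) is tracked
# against the machinery ribosome pool.
# ---------------------------------------------------------------------------

ccp <- function(params, name) {
  v <- params[[name]]
  if (is.null(v)) stop(sprintf("missing cell-cycle parameter '%s'", name))
  v
}

# inducers: list of entries list(tag = "e2f", states = c("e2f.nuc", ...),
# w = efficiency or constitutive weight).  Entries with NULL states are
# constitutive weights.
cc_mrna <- function(gene, params, inducers, x0_pool = 0) {
  P <- function(n) ccp(params, n)
  nt_m <- P("cost.nt_per_mrna"); atp_nt <- P("cost.atp_per_nt")
  nm <- paste0("m_", gene)
  con <- new_construct(nm, "mrna")
  con <- add_state(con, "nascent", 0.01 * x0_pool, "nucleus")
  con <- add_state(con, "nuclear", 0.03 * x0_pool, "nucleus")
  con <- add_state(con, "cytosol", 0.31 * x0_pool)
  con <- add_state(con, "ribosome_bound", 0.64 * x0_pool)
  con <- add_state(con, "trash", 0.01 * x0_pool, is_sink = TRUE)
  txs_io <- list(
    sources = c(nt.cytosol = nt_m, atp.atp = atp_nt * nt_m),
    sinks = c(nascent = 1, nt.in_rna = nt_m, atp.adp = atp_nt * nt_m))
  for (ind in inducers) {
    con <- add_rate(con, paste0("txs_", ind$tag), ind$w,
                    law_kind = "allocation", group = "txs",
                    weight_const = if (is.null(ind$states)) 1 else 0,
                    weight_states = if (is.null(ind$states)) character()
                                    else ind$states,
                    sources = txs_io$sources, sinks = txs_io$sinks)
  }
  con <- add_rate(con, "txs_basal", 1e-4, law_kind = "allocation",
                  group = "txs", weight_const = 1,
                  sources = txs_io$sources, sinks = txs_io$sinks)
  con <- add_rate(con, "splice", P("k.m.splice"), reactants = "nascent",
                  modifiers = "snrna.spliceosome",
                  sat = c(snrna.spliceosome = P("K.m.splice")),
                  sources = "nascent", sinks = "nuclear")
  con <- add_rate(con, "export", P("k.m.export"), reactants = "nuclear",
                  sources = "nuclear", sinks = "cytosol")
  con <- add_rate(con, "bind_ribosome", P("k.m.bind_ribo"),
                  reactants = c("cytosol", "ribo.free"),
                  sources = c(cytosol = 1, ribo.free = 1),
                  sinks = c(ribosome_bound = 1, ribo.translating = 1))
  con <- add_rate(con, "unbind_ribosome", P("k.m.unbind_ribo"),
                  reactants = "ribosome_bound",
                  sources = c(ribosome_bound = 1, ribo.translating = 1),
                  sinks = c(cytosol = 1, ribo.free = 1))
  # additional ribosome loading/unloading on engaged messages (polysomes);
  # moves ribosomes between pools without changing the mRNA state
  con <- add_rate(con, "polysome_load", P("k.m.polysome_load"),
                  reactants = c("ribosome_bound", "ribo.free"),
                  sources = c(ribo.free = 1), sinks = c(ribo.translating = 1))
  con <- add_rate(con, "polysome_unload", P("k.m.polysome_unload"),
                  reactants = c("ribosome_bound", "ribo.translating"),
                  sources = c(ribo.translating = 1), sinks = c(ribo.free = 1))
  con <- add_rate(con, "dk_nascent", P("k.m.dk_nascent"),
                  reactants = "nascent", sources = "nascent", sinks = "trash")
  con <- add_rate(con, "dk_nuclear", P("k.m.dk_nuclear"),
                  reactants = "nuclear", sources = "nuclear", sinks = "trash")
  con <- add_rate(con, "dk_cytosol", P("k.m.dk_cytosol"),
                  reactants = "cytosol", sources = "cytosol", sinks = "trash")
  con <- add_rate(con, "dk_bound", P("k.m.dk_bound"),
                  reactants = "ribosome_bound",
                  sources = c(ribosome_bound = 1, ribo.translating = 1),
                  sinks = c(trash = 1, ribo.free = 1))
  con <- add_rate(con, "dispose", P("k.m.dispose"), reactants = "trash",
                  sources = c(trash = 1, nt.in_rna = nt_m),
                  sinks = c(nt.trash = nt_m))
  con
}

# Standard protein-lifecycle plumbing.  Adds the translation allocation
# members (one weighted by the free cytosolic mRNA pool, one by the
# ribosome-engaged pool), folding, nucleocytoplasmic transport, per-state
# decay, ubiquitinated-state clearance and trash disposal with amino-acid
# recycling.  `states` must already be added; which plumbing applies is
# inferred from which canonical states exist.
cc_prot_core <- function(con, gene, params, txl_gate = NULL,
                         split_txl = TRUE, export = TRUE,
                         import = TRUE) {
  P <- function(n) ccp(params, n)
  aa <- P("cost.aa_per_protein"); atp <- P("cost.atp_per_aa") * aa
  m <- paste0("m_", gene)
  has <- function(s) s %in% names(con$states)
  first_pool <- if (has("cyt")) "cyt" else "nuc"
  if (split_txl) {
    con <- add_rate(con, "txl_free", 1, law_kind = "allocation",
                    group = "txl",
                    weight_states = paste0(m, ".cytosol"),
                    sources = c(aa.on_trna = aa, atp.atp = atp),
                    sinks = c(unf = 1, aa.in_protein = aa, atp.adp = atp))
    con <- add_rate(con, "txl_poly", 1, law_kind = "allocation",
                    group = "txl",
                    weight_states = paste0(m, ".ribosome_bound"),
                    sources = c(aa.on_trna = aa, atp.atp = atp),
                    sinks = c(unf = 1, aa.in_protein = aa, atp.adp = atp))
  } else {
    con <- add_rate(con, "txl", 1, law_kind = "allocation", group = "txl",
                    weight_states = paste0(m, c(".cytosol",
                                                ".ribosome_bound")),
                    sources = c(aa.on_trna = aa, atp.atp = atp),
                    sinks = c(unf = 1, aa.in_protein = aa, atp.adp = atp))
  }
  con <- add_rate(con, "fold", P("k.common.fold"), reactants = "unf",
                  modifiers = txl_gate,
                  sources = "unf", sinks = first_pool)
  if (has("cyt") && has("nuc") && import) {
    con <- add_rate(con, "import_nuc", P("k.common.import"),
                    reactants = "cyt", sources = "cyt", sinks = "nuc")
    if (export)
      con <- add_rate(con, "export_nuc", P("k.common.export"),
                      reactants = "nuc", sources = "nuc", sinks = "cyt")
  }
  con <- add_rate(con, "dk_unf", P("k.common.dk_unf"), reactants = "unf",
                  sources = "unf", sinks = "trash")
  if (has("cyt"))
    con <- add_rate(con, "dk_cyt", P("k.common.dk"), reactants = "cyt",
                    sources = "cyt", sinks = "trash")
  if (has("nuc"))
    con <- add_rate(con, "dk_nuc", P("k.common.dk"), reactants = "nuc",
                    sources = "nuc", sinks = "trash")
  if (has("ubq"))
    con <- add_rate(con, "ubq_clear", P("k.common.ubq_clear"),
                    reactants = "ubq", sources = "ubq", sinks = "trash")
  con <- add_rate(con, "dispose", P("k.common.dispose"), reactants = "trash",
                  sources = c(trash = 1, aa.in_protein = aa),
                  sinks = c(aa.trash = aa))
  con
}
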