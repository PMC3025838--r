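# ---------------------------------------------------------------------------
# Resource-limited total rates and proportional allocation.  Transcription in
# total is limited by RNA polymerase and nucleotides; translation in total by
# ribosomes and amino acids.  Transcription-factor weights (and mRNA amounts
# for translation) then determine the fraction of the total devoted to each
# gene (protein).
# ---------------------------------------------------------------------------

#' Resource budget snapshot
#'
#' Free amino acids, free nucleotides, ATP, actively translating ribosomes
#' and active RNA polymerase (pol I+II+III as a single pool).
#'
#' @param free_AA,free_NT,ATP,active_ribosomes,active_RNA_pol non-negative
#'   counts.
#' @return a list of class `ResourceBudget`.
#' @export
resource_budget <- function(free_AA, free_NT, ATP, active_ribosomes,
                            active_RNA_pol) {
  b <- list(free_AA = free_AA, free_NT = free_NT, ATP = ATP,
            active_ribosomes = active_ribosomes,
            active_RNA_pol = active_RNA_pol)
  if (any(vapply(b, function(v) !is.numeric(v) || is.na(v) || v < 0, TRUE)))
    stop("all resource-budget components must be non-negative numbers")
  structure(b, class = "ResourceBudget")
}

#' Total cellular transcription rate
#'
#' `flux = k_per_pol * active_RNA_pol * NT/(NT + K_NT)`: linear in the
#' polymerase count (the pol-limited regime; doubling DNA does not increase
#' it) and Michaelis-saturating in free nucleotides.  Zero if either pool is
#' zero.
#'
#' @param budget a [resource_budget()].
#' @param params list with `k_txs_per_pol` (transcripts per second per
#'   engaged polymerase) and `K_NT` (nucleotide half-saturation, counts).
#' @return flux in transcripts per second.
#' @export
total_transcription_rate <- function(budget, params) {
  with(params, k_txs_per_pol * budget$active_RNA_pol *
         budget$free_NT / (K_NT + budget$free_NT))
}

#' Total cellular translation rate
#'
#' `flux = k_per_ribosome * active_ribosomes * AA/(AA + K_AA)`; linear in
#' the ribosome count and saturating in free amino acids.
#'
#' @param budget a [resource_budget()].
#' @param params list with `k_txl_per_ribosome` and `K_AA`.
#' @return flux in proteins per second.
#' @export
total_translation_rate <- function(budget, params) {
  with(params, k_txl_per_ribosome * budget$active_ribosomes *
         budget$free_AA / (K_AA + budget$free_AA))
}

#' Partition a total flux proportionally to non-negative weights
#'
#' `allocation_i = total * w_i / sum(w)`; allocations sum exactly to the
#' total.  If every weight is zero all allocations are zero.
#'
#' @param total total flux to divide.
#' @param weights named non-negative numeric vector.
#' @return named numeric vector of per-species fluxes.
#' @export
allocate_flux <- function(total, weights) {
  if (any(is.na(weights)) || any(weights < 0))
    stop("weights must be non-negative")
  W <- sum(weights)
  if (W <= 0) return(weights * 0)
  total * weights / W
}

#' Transcription weight of one gene
#'
#' The induction of a gene is the product of a factor quantifying the
#' visibility of the gene locus (0 for condensed M-phase chromatin) and the
#' summed amounts of its transcription factors plus any constitutive term.
#'
#' @param locus_visibility factor in `[0, 1]`.
#' @param tf_amounts numeric vector of transcription-factor amounts
#'   (may be empty for purely constitutive genes).
#' @param constitutive constitutive weight term.
#' @return non-negative weight.
#' @export
tf_weight <- function(locus_visibility, tf_amounts = numeric(),
                      constitutive = 0) {
  stopifnot(locus_visibility >= 0, constitutive >= 0,
            all(tf_amounts >= 0))
  locus_visibility * (constitutive + sum(tf_amounts))
}

#' Normalized cell size from a model state
#'
#' Size is the summed count over the declared protein-mass states divided by
#' the reference (quiescent, G0) count, so size is 1 in G0 and about 2 just
#' before division.  Concentrations used by the rate laws are count/size,
#' which makes them invariant under cell division.
#'
#' @param model a `CompiledModel` compiled with a `size` definition.
#' @param x state vector (defaults to the initial state).
#' @return dimensionless normalized size.
#' @export
cell_size <- function(model, x = initial_state(model)) {
  stopifnot(inherits(model, "CompiledModel"))
  model$cell_size(x)
}
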