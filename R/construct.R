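# ---------------------------------------------------------------------------
# Molecule-lifecycle constructs: named groups of states (molecular pools) and
# rates (mass-action fluxes moving material between pools).  A construct is a
# plain list with class "Construct"; operations are functional (they return
# the modified construct).
# ---------------------------------------------------------------------------

COMPARTMENTS <- c("cytosol", "nucleus", "membrane", "external")
LAW_KINDS    <- c("mass_action", "saturating", "allocation")
FACTOR_KINDS <- c("linear", "sat", "inhib")

#' Create an empty molecule-lifecycle construct
#'
#' A construct describes one molecule type (or one machinery subsystem) as a
#' small state machine: rectangles are pools of molecules in a given state
#' (unfolded, cytosolic, bound, ubiquitinated, ...), circles are the
#' mass-action rates that move molecules between pools.  Protein constructs
#' canonically carry 7 states and mRNA constructs 5; other layouts must be
#' flagged with [flag_exception()].
#'
#' @param name identifier, unique within a model.
#' @param kind one of `"protein"`, `"mrna"`, `"machinery"`, `"bookkeeping"`.
#' @return an object of class `Construct`.
#' @seealso [add_state()], [add_rate()], [compile_model()]
#' @export
new_construct <- function(name, kind = c("protein", "mrna", "machinery",
                                         "bookkeeping")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, kind = kind, states = list(), rates = list(),
                 exception = NULL),
            class = "Construct")
}

#' Flag a construct as an allowed exception to the canonical state census
#'
#' @param construct a `Construct`.
#' @param reason character, why the construct deviates from the canonical
#'   7-state protein / 5-state mRNA layout.
#' @export
flag_exception <- function(construct, reason) {
  stopifnot(inherits(construct, "Construct"))
  construct$exception <- as.character(reason)
  construct
}

#' Add a state (molecular pool) to a construct
#'
#' @param construct a `Construct`.
#' @param name state identifier, unique within the construct.
#' @param initial_amount non-negative molecule count (dimensionless count,
#'   not a concentration).
#' @param compartment one of cytosol, nucleus, membrane, external.
#' @param is_sink logical; trash/disposal states.
#' @param dimensionless logical; `TRUE` for bookkeeping quantities (external
#'   signal levels, origin counters) that are not molecule counts.  Such
#'   states enter rate laws at face value rather than as count/size
#'   concentrations, and are not halved at division.
#' @param halve logical; whether the state is divided by two at cell
#'   division (extensive molecule counts are; bookkeeping states are not).
#' @return the modified construct.
#' @export
add_state <- function(construct, name, initial_amount = 0,
                      compartment = "cytosol", is_sink = FALSE,
                      dimensionless = FALSE, halve = !dimensionless) {
  stopifnot(inherits(construct, "Construct"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("state name must be a single non-empty string")
  if (name %in% names(construct$states))
    stop(sprintf("duplicate state '%s' in construct '%s'",
                 name, construct$name))
  if (!is.numeric(initial_amount) || length(initial_amount) != 1L ||
      is.na(initial_amount) || initial_amount < 0)
    stop(sprintf("initial_amount of state '%s' must be a non-negative count",
                 name))
  compartment <- match.arg(compartment, COMPARTMENTS)
  construct$states[[name]] <- list(name = name,
                                   initial_amount = as.numeric(initial_amount),
                                   compartment = compartment,
                                   is_sink = isTRUE(is_sink),
                                   dimensionless = isTRUE(dimensionless),
                                   halve = isTRUE(halve))
  construct
}

#' Create a rate-law factor specification
#'
#' `ref` is a state reference ("state" for local states, "construct.state"
#' for foreign ones); kind `"linear"` multiplies the flux by the state's
#' concentration, `"sat"` by `C/(K+C)` and `"inhib"` by `K/(K+C)`.  Used
#' directly when defining allocation-group capacities.
#' @param ref state reference.
#' @param kind one of linear, sat, inhib.
#' @param K half-saturation / inhibition constant (concentration units).
#' @export
law_factor <- function(ref, kind = "linear", K = NA_real_) {
  kind <- match.arg(kind, FACTOR_KINDS)
  if (kind != "linear" && (!is.numeric(K) || is.na(K) || K <= 0))
    stop(sprintf("factor on '%s': kind '%s' needs a positive K", ref, kind))
  list(ref = ref, kind = kind, K = as.numeric(K))
}

#' Add a rate (mass-action flux) to a construct
#'
#' The evaluated flux is `k * size * prod(g(C_f))` where the product runs
#' over all reactant and modifier factors, `C_f` is the factor state's
#' concentration (count / normalized cell size; bookkeeping states enter at
#' face value), and `g` is identity for mass action, `C/(K+C)` for
#' Michaelis-type saturating factors and `K/(K+C)` for inhibitory factors.
#' For a single linear factor this reduces to the familiar first-order
#' `k * count`; for two factors to `k * count1 * count2 / size`.  Sources
#' are debited and sinks credited by the flux times their multiplicity; a
#' source-free rate is a synthesis boundary, a sink-free rate a disposal
#' boundary.
#'
#' @param construct a `Construct`.
#' @param name rate identifier, unique within the construct.
#' @param k non-negative rate constant, units `count^(1-n)/s` for `n`
#'   linear factors.
#' @param reactants character vector of state references whose amounts
#'   multiply into the flux (and are conventionally also listed in
#'   `sources`).
#' @param sources,sinks states debited/credited by the flux.  Either a
#'   character vector (multiplicity 1 each) or a named numeric vector of
#'   multiplicities (e.g. `c(NT_cytosol = 1000)` nucleotides per
#'   transcript).
#' @param modifiers character vector of state references that multiply the
#'   flux but are not consumed (inter-construct couplings).
#' @param law_kind `"mass_action"`, `"saturating"` or `"allocation"`.
#' @param sat,inhib named numeric vectors giving Michaelis / inhibition
#'   constants (in concentration units) for the named reactants or
#'   modifiers; any named factor becomes saturating/inhibitory instead of
#'   linear.
#' @param group,weight_const,weight_states for `law_kind = "allocation"`:
#'   the allocation-group name, the constitutive weight term and the states
#'   whose summed amounts (times the group visibility factor) form this
#'   member's transcription/translation weight.
#' @param scale_size logical; if `FALSE` the flux does not scale with cell
#'   size (saturable membrane transporters whose capacity is not tied to
#'   cell mass).
#' @return the modified construct.
#' @export
add_rate <- function(construct, name, k, reactants = character(),
                     sources = character(), sinks = character(),
                     modifiers = character(),
                     law_kind = "mass_action",
                     sat = NULL, inhib = NULL,
                     group = NULL, weight_const = 0,
                     weight_states = character(), scale_size = TRUE) {
  stopifnot(inherits(construct, "Construct"))
  if (name %in% names(construct$rates))
    stop(sprintf("duplicate rate '%s' in construct '%s'",
                 name, construct$name))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop(sprintf("rate constant of '%s' must be >= 0", name))
  law_kind <- match.arg(law_kind, LAW_KINDS)

  as_mult <- function(x) {
    if (length(x) == 0L) return(numeric(0))
    if (is.character(x)) return(stats::setNames(rep(1, length(x)), x))
    if (is.numeric(x) && !is.null(names(x))) return(x)
    stop(sprintf("rate '%s': sources/sinks must be a character vector or a ",
                 name), "named numeric vector of multiplicities")
  }
  factors <- c(
    lapply(reactants, function(r) {
      if (!is.null(sat) && r %in% names(sat)) law_factor(r, "sat", sat[[r]])
      else if (!is.null(inhib) && r %in% names(inhib))
        law_factor(r, "inhib", inhib[[r]])
      else law_factor(r)
    }),
    lapply(modifiers, function(r) {
      if (!is.null(sat) && r %in% names(sat)) law_factor(r, "sat", sat[[r]])
      else if (!is.null(inhib) && r %in% names(inhib))
        law_factor(r, "inhib", inhib[[r]])
      else law_factor(r)
    }))
  if (law_kind == "mass_action" &&
      any(vapply(factors, function(f) f$kind, "") != "linear"))
    law_kind <- "saturating"
  if (law_kind == "allocation" && is.null(group))
    stop(sprintf("allocation rate '%s' needs a group", name))

  construct$rates[[name]] <- list(
    name = name, k = as.numeric(k), law_kind = law_kind,
    reactants = reactants, modifiers = modifiers, factors = factors,
    sources = as_mult(sources), sinks = as_mult(sinks),
    group = group, weight_const = as.numeric(weight_const),
    weight_states = weight_states, scale_size = isTRUE(scale_size))
  construct
}

#' Evaluate one rate law at a given set of amounts
#'
#' @param rate a rate as stored in a `Construct` (see [add_rate()]).
#' @param amounts named numeric vector of state amounts covering every
#'   reactant and modifier of the rate.
#' @param size normalized cell size used to convert counts to
#'   concentrations (default 1).
#' @param dimensionless character vector naming amounts that are
#'   bookkeeping values rather than counts.
#' @return the flux in count/s; always non-negative for non-negative
#'   amounts.
#' @export
evaluate_rate <- function(rate, amounts, size = 1,
                          dimensionless = character()) {
  if (identical(rate$law_kind, "allocation"))
    stop("allocation rates are evaluated through their group; see compile_model")
  f <- rate$k * if (isTRUE(rate$scale_size)) size else 1
  for (fc in rate$factors) {
    if (!fc$ref %in% names(amounts))
      stop(sprintf("missing amount for '%s' in rate '%s'", fc$ref, rate$name))
    a <- amounts[[fc$ref]]
    if (is.na(a) || a < 0)
      stop(sprintf("amount of '%s' must be a non-negative number", fc$ref))
    conc <- if (fc$ref %in% dimensionless) a else a / size
    f <- f * switch(fc$kind,
                    linear = conc,
                    sat    = conc / (fc$K + conc),
                    inhib  = fc$K / (fc$K + conc))
  }
  unname(f)
}

#' State and rate census of a construct or compiled model
#'
#' @param x a `Construct` or `CompiledModel`.
#' @return named integer vector `c(states = ..., rates = ...)`.
#' @export
census <- function(x) UseMethod("census")

#' @export
census.Construct <- function(x)
  c(states = length(x$states), rates = length(x$rates))

#' @export
census.list <- function(x) {
  stopifnot(all(vapply(x, inherits, TRUE, "Construct")))
  Reduce(`+`, lapply(x, census.Construct), c(states = 0L, rates = 0L))
}

#' Validate a construct against the canonical lifecycle layout
#'
#' Protein constructs carry 7 states and mRNA constructs 5 unless flagged as
#' exceptions; referenced local states must exist; sink states must have no
#' outgoing rates other than disposal/recycle rates.
#'
#' @param construct a `Construct`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_construct <- function(construct) {
  stopifnot(inherits(construct, "Construct"))
  n <- length(construct$states)
  if (is.null(construct$exception)) {
    if (construct$kind == "protein" && n != 7L)
      stop(sprintf("protein construct '%s' has %d states (7 expected; use flag_exception)",
                   construct$name, n))
    if (construct$kind == "mrna" && n != 5L)
      stop(sprintf("mRNA construct '%s' has %d states (5 expected; use flag_exception)",
                   construct$name, n))
  }
  local <- names(construct$states)
  for (r in construct$rates) {
    refs <- c(r$reactants, r$modifiers, names(r$sources), names(r$sinks))
    bare <- refs[!grepl(".", refs, fixed = TRUE)]
    bad <- setdiff(bare, local)
    if (length(bad))
      stop(sprintf("rate '%s' in construct '%s' references unknown states: %s",
                   r$name, construct$name, paste(bad, collapse = ", ")))
    for (src in names(r$sources)) {
      if (!grepl(".", src, fixed = TRUE) &&
          isTRUE(construct$states[[src]]$is_sink) &&
          !grepl("^(dispose|recycle|export)", r$name))
        stop(sprintf("sink state '%s' drained by non-disposal rate '%s'",
                     src, r$name))
    }
  }
  invisible(TRUE)
}

#' @export
print.Construct <- function(x, ...) {
  cat(sprintf("<Construct '%s' (%s): %d states, %d rates%s>\n",
              x$name, x$kind, length(x$states), length(x$rates),
              if (!is.null(x$exception)) ", flagged exception" else ""))
  invisible(x)
}
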