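# ---------------------------------------------------------------------------
# Compile a set of lifecycle constructs into a coupled mass-action ODE
# system:  d x / d t = S %*% r(t, x)  with S the sparse stoichiometry matrix
# and r the vector of rate fluxes.
# ---------------------------------------------------------------------------

qualify <- function(ref, construct_name) {
  ifelse(grepl(".", ref, fixed = TRUE), ref,
         paste(construct_name, ref, sep = "."))
}

#' Compile lifecycle constructs into an ODE system
#'
#' Assembles the state vector layout, the sparse stoichiometry matrix and a
#' vectorized right-hand-side evaluator from a list of constructs.  States
#' are qualified as `construct.state`; rates may reference states in other
#' constructs as modifiers (the thin-line inter-construct couplings).
#'
#' @param constructs list of `Construct` objects.
#' @param groups named list of allocation groups, each
#'   `list(k = capacity constant, factors = list of factor specs)` created
#'   with the same linear/sat/inhib factor algebra as rates.  An allocation
#'   group realizes a resource-limited total flux (total transcription or
#'   translation) that member rates share in proportion to their weights.
#' @param size `NULL` (size fixed at 1) or `list(states = qualified state
#'   names whose summed count defines cell mass, reference = count that
#'   corresponds to normalized size 1)`.
#' @return an object of class `CompiledModel` with elements `states`
#'   (data.frame), `state_index`, `S`, `rhs(t, x)`, `fluxes(t, x)`,
#'   `groups`, `size`.
#' @export
compile_model <- function(constructs, groups = list(), size = NULL) {
  stopifnot(is.list(constructs),
            all(vapply(constructs, inherits, TRUE, "Construct")))
  for (con in constructs) validate_construct(con)
  cnames <- vapply(constructs, `[[`, "", "name")
  if (anyDuplicated(cnames))
    stop("duplicate construct names: ",
         paste(unique(cnames[duplicated(cnames)]), collapse = ", "))

  ## ---- state table -------------------------------------------------------
  st <- do.call(rbind, lapply(constructs, function(con) {
    if (!length(con$states))
      return(NULL)
    data.frame(construct = con$name,
               state = names(con$states),
               qname = paste(con$name, names(con$states), sep = "."),
               x0 = vapply(con$states, `[[`, 0, "initial_amount"),
               dimensionless = vapply(con$states, `[[`, TRUE, "dimensionless"),
               halve = vapply(con$states, `[[`, TRUE, "halve"),
               is_sink = vapply(con$states, `[[`, TRUE, "is_sink"),
               compartment = vapply(con$states, `[[`, "", "compartment"),
               kind = con$kind,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(st))
    st <- data.frame(construct = character(), state = character(),
                     qname = character(), x0 = numeric(),
                     dimensionless = logical(), halve = logical(),
                     is_sink = logical(), compartment = character(),
                     kind = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(st$qname))
    stop("duplicate qualified state names: ",
         paste(unique(st$qname[duplicated(st$qname)]), collapse = ", "))
  n_states <- nrow(st)
  state_index <- stats::setNames(seq_len(n_states), st$qname)

  resolve <- function(refs, who) {
    idx <- state_index[refs]
    if (anyNA(idx))
      stop(sprintf("unresolved state reference(s) in %s: %s", who,
                   paste(refs[is.na(idx)], collapse = ", ")))
    unname(idx)
  }

  ## ---- rate table --------------------------------------------------------
  rates <- list()
  for (con in constructs) {
    for (r in con$rates) {
      r$qname <- paste(con$name, r$name, sep = ".")
      r$factors <- lapply(r$factors, function(fc) {
        fc$ref <- qualify(fc$ref, con$name)
        fc$idx <- resolve(fc$ref, r$qname)
        fc
      })
      names(r$sources) <- qualify(names(r$sources), con$name)
      names(r$sinks) <- qualify(names(r$sinks), con$name)
      r$src_idx <- resolve(names(r$sources), r$qname)
      r$snk_idx <- resolve(names(r$sinks), r$qname)
      if (!is.null(r$group)) {
        if (!r$group %in% names(groups))
          stop(sprintf("rate '%s' references unknown allocation group '%s'",
                       r$qname, r$group))
        r$weight_states <- qualify(r$weight_states, con$name)
        r$weight_idx <- resolve(r$weight_states, r$qname)
      }
      rates[[r$qname]] <- r
    }
  }
  n_rates <- length(rates)

  ## ---- allocation groups -------------------------------------------------
  groups <- lapply(groups, function(g) {
    g$factors <- lapply(g$factors, function(fc) {
      fc$idx <- resolve(fc$ref, "allocation group")
      fc
    })
    g
  })
  for (gn in names(groups))
    groups[[gn]]$members <- unname(which(vapply(
      rates, function(r) identical(r$group, gn), TRUE)))

  ## ---- stoichiometry -----------------------------------------------------
  trip_i <- integer(); trip_j <- integer(); trip_x <- numeric()
  for (j in seq_along(rates)) {
    r <- rates[[j]]
    if (length(r$src_idx)) {
      trip_i <- c(trip_i, r$src_idx); trip_j <- c(trip_j, rep(j, length(r$src_idx)))
      trip_x <- c(trip_x, -unname(r$sources))
    }
    if (length(r$snk_idx)) {
      trip_i <- c(trip_i, r$snk_idx); trip_j <- c(trip_j, rep(j, length(r$snk_idx)))
      trip_x <- c(trip_x, unname(r$sinks))
    }
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n_states, n_rates),
                            dimnames = list(st$qname, names(rates)))

  ## ---- vectorized flux evaluator ----------------------------------------
  k_vec <- vapply(rates, `[[`, 0, "k")
  sz_scaled <- vapply(rates, function(r) isTRUE(r$scale_size), TRUE)
  nfac <- vapply(rates, function(r) length(r$factors), 0L)
  maxf <- if (n_rates) max(nfac) else 0L
  fac_idx <- fac_kind <- fac_K <- vector("list", maxf)
  for (j in seq_len(maxf)) {
    fac_idx[[j]] <- vapply(rates, function(r)
      if (length(r$factors) >= j) r$factors[[j]]$idx else NA_integer_, 0L)
    fac_kind[[j]] <- vapply(rates, function(r)
      if (length(r$factors) >= j) r$factors[[j]]$kind else "none", "")
    fac_K[[j]] <- vapply(rates, function(r)
      if (length(r$factors) >= j) r$factors[[j]]$K else NA_real_, 0)
  }
  dimless <- st$dimensionless
  alloc_member <- vapply(rates, function(r) !is.null(r$group), TRUE)
  wconst <- vapply(rates, `[[`, 0, "weight_const")
  widx <- lapply(rates, function(r) r$weight_idx)

  size_idx <- NULL; size_ref <- 1
  if (!is.null(size)) {
    size_idx <- resolve(size$states, "size definition")
    size_ref <- size$reference
  }
  cell_size_fn <- function(x) {
    if (is.null(size_idx)) return(1)
    sum(pmax(x[size_idx], 0)) / size_ref
  }

  fluxes <- function(t, x) {
    xe <- pmax(x, 0)
    sz <- cell_size_fn(xe)
    conc <- xe / sz
    if (any(dimless)) conc[dimless] <- xe[dimless]
    f <- k_vec * ifelse(sz_scaled, sz, 1)
    for (j in seq_len(maxf)) {
      v <- conc[fac_idx[[j]]]
      v[is.na(v)] <- 1
      kd <- fac_kind[[j]]
      is_sat <- kd == "sat"; is_inh <- kd == "inhib"
      if (any(is_sat)) v[is_sat] <- v[is_sat] / (fac_K[[j]][is_sat] + v[is_sat])
      if (any(is_inh)) v[is_inh] <- fac_K[[j]][is_inh] /
          (fac_K[[j]][is_inh] + v[is_inh])
      f <- f * v
    }
    if (any(alloc_member)) {
      for (g in groups) {
        cap <- g$k * sz
        for (fc in g$factors) {
          v <- conc[fc$idx]
          cap <- cap * switch(fc$kind,
                              linear = v,
                              sat = v / (fc$K + v),
                              inhib = fc$K / (fc$K + v))
        }
        m <- g$members
        w <- wconst[m]
        for (ii in seq_along(m)) {
          wi <- widx[[m[ii]]]
          if (length(wi)) w[ii] <- w[ii] + sum(xe[wi])
        }
        # member rate constants act as relative efficiencies inside the
        # normalized weights, so the allocations always sum to the capacity
        w <- pmax(w, 0) * k_vec[m]
        W <- sum(w)
        f[m] <- if (W > 0) cap * w / W else 0
      }
    }
    f
  }

  rhs <- function(t, x) as.vector(S %*% fluxes(t, x))

  structure(list(states = st, state_index = state_index, rates = rates,
                 S = S, groups = groups, fluxes = fluxes, rhs = rhs,
                 cell_size = cell_size_fn, size = size,
                 constructs = stats::setNames(constructs, cnames)),
            class = "CompiledModel")
}

#' Initial state vector of a compiled model
#' @param model a `CompiledModel`.
#' @return named numeric vector of initial amounts.
#' @export
initial_state <- function(model) {
  stats::setNames(model$states$x0, model$states$qname)
}

#' Report moiety conservation across the stoichiometry
#'
#' Computes `w . S` for every rate, where `w` assigns a moiety weight (e.g.
#' amino-acid residues) to each state carrying the moiety.  A rate with a
#' nonzero residual creates or destroys the moiety; the moiety is conserved
#' iff the only such rates are declared import/export boundaries.  This
#' enforces the framework claim that molecules are tracked from birth to
#' death.
#'
#' @param model a `CompiledModel`.
#' @param moiety named numeric vector of weights over qualified state names
#'   (states not named carry weight 0).
#' @param boundary character vector of rate names (qualified) that are
#'   declared import/export boundaries.
#' @return data.frame with one row per rate with nonzero residual, columns
#'   `rate`, `residual`, `declared_boundary`; attribute `conserved` is TRUE
#'   iff every nonzero residual belongs to a declared boundary.
#' @export
check_conservation <- function(model, moiety, boundary = character()) {
  stopifnot(inherits(model, "CompiledModel"))
  w <- numeric(nrow(model$states))
  idx <- model$state_index[names(moiety)]
  if (anyNA(idx))
    stop("moiety names unknown: ",
         paste(names(moiety)[is.na(idx)], collapse = ", "))
  w[idx] <- moiety
  res <- as.vector(Matrix::crossprod(model$S, w))
  names(res) <- colnames(model$S)
  nz <- which(abs(res) > 1e-9)
  out <- data.frame(rate = names(res)[nz], residual = unname(res[nz]),
                    declared_boundary = names(res)[nz] %in% boundary,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "conserved") <- all(out$declared_boundary)
  out
}

#' @export
print.CompiledModel <- function(x, ...) {
  cat(sprintf("<CompiledModel: %d states, %d rates, %d constructs%s>\n",
              nrow(x$states), length(x$rates), length(x$constructs),
              if (!is.null(x$size)) ", size-normalized" else ""))
  invisible(x)
}
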