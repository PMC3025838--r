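# ---------------------------------------------------------------------------
# Self-contained toy models: the canonical protein-lifecycle figure construct
# and unidirectional first-order chains with a closed-form (Bateman)
# reference solution.  Fixtures use the ordinary construct API, so tests of
# the compiler and solver exercise the same code path as the full model.
# ---------------------------------------------------------------------------

#' Canonical protein-lifecycle toy construct
#'
#' Four explicit pools (`p_unfold`, `p_cytosol`, `p_in_use`, `p_trash`) and
#' eight rates: translation entering from the synthesis boundary (`txl_p`),
#' folding (`fold_p`), a binding/unbinding use cycle (`bind_p`,
#' `unbind_p`), per-state decay (`dk_p_unfold`, `dk_p_cytosol`,
#' `dk_p_in_use`) and disposal of the trash pool (`dispose_p`).
#'
#' @param params named list of rate constants (any of the eight rate names);
#'   defaults give a well-behaved relaxing system.
#' @param x0 named initial amounts for any of the four pools.
#' @return a `Construct` (flagged exception: 4-state simplified layout).
#' @export
make_fig1_construct <- function(params = list(), x0 = list()) {
  p <- utils::modifyList(list(txl_p = 1, fold_p = 1e-3, bind_p = 1e-3,
                              unbind_p = 5e-4, dk_p_unfold = 1e-4,
                              dk_p_cytosol = 1e-4, dk_p_in_use = 1e-4,
                              dispose_p = 1e-3), params)
  a <- utils::modifyList(list(p_unfold = 0, p_cytosol = 0, p_in_use = 0,
                              p_trash = 0), x0)
  con <- new_construct("p", kind = "protein")
  con <- flag_exception(con, "simplified 4-state lifecycle figure layout")
  con <- add_state(con, "p_unfold", a$p_unfold)
  con <- add_state(con, "p_cytosol", a$p_cytosol)
  con <- add_state(con, "p_in_use", a$p_in_use)
  con <- add_state(con, "p_trash", a$p_trash, is_sink = TRUE)
  con <- add_rate(con, "txl_p", p$txl_p, sinks = "p_unfold")
  con <- add_rate(con, "fold_p", p$fold_p, reactants = "p_unfold",
                  sources = "p_unfold", sinks = "p_cytosol")
  con <- add_rate(con, "bind_p", p$bind_p, reactants = "p_cytosol",
                  sources = "p_cytosol", sinks = "p_in_use")
  con <- add_rate(con, "unbind_p", p$unbind_p, reactants = "p_in_use",
                  sources = "p_in_use", sinks = "p_cytosol")
  con <- add_rate(con, "dk_p_unfold", p$dk_p_unfold, reactants = "p_unfold",
                  sources = "p_unfold", sinks = "p_trash")
  con <- add_rate(con, "dk_p_cytosol", p$dk_p_cytosol,
                  reactants = "p_cytosol", sources = "p_cytosol",
                  sinks = "p_trash")
  con <- add_rate(con, "dk_p_in_use", p$dk_p_in_use, reactants = "p_in_use",
                  sources = "p_in_use", sinks = "p_trash")
  con <- add_rate(con, "dispose_p", p$dispose_p, reactants = "p_trash",
                  sources = "p_trash")
  con
}

#' Unidirectional first-order chain with closed-form reference solution
#'
#' States `s1 -> s2 -> ... -> sn` with distinct first-order rate constants
#' `k_list` (length `n - 1`); the final state is absorbing, so total mass is
#' conserved.  The closed-form sum-of-exponentials (Bateman) solution is
#' attached as attribute `"solution"`, a function of a time vector returning
#' a `length(t) x n` matrix.
#'
#' @param n number of states (>= 2).
#' @param k_list positive, pairwise-distinct rate constants, length `n - 1`.
#' @param x0 initial amounts (length `n`; default mass 1 in the first
#'   state).
#' @return a `Construct` of kind `bookkeeping` with attribute `solution`.
#' @export
make_linear_chain <- function(n, k_list, x0 = c(1, rep(0, n - 1))) {
  stopifnot(n >= 2, length(k_list) == n - 1, all(k_list > 0),
            length(x0) == n, all(x0 >= 0))
  if (anyDuplicated(signif(k_list, 12)))
    stop("repeated rate constants: closed-form reference refuses degenerate eigenvalues")
  con <- new_construct("chain", kind = "bookkeeping")
  for (i in seq_len(n))
    con <- add_state(con, paste0("s", i), x0[i],
                     is_sink = identical(i, as.integer(n)))
  for (i in seq_len(n - 1))
    con <- add_rate(con, sprintf("step_%d_%d", i, i + 1L), k_list[i],
                    reactants = paste0("s", i),
                    sources = paste0("s", i), sinks = paste0("s", i + 1L))

  lambda <- c(k_list, 0)  # decay eigenvalue per state; last state absorbing
  # Bateman cascade started from unit mass in state `m`
  bateman <- function(t, m) {
    out <- matrix(0, length(t), n)
    for (i in m:n) {
      js <- m:i
      acc <- 0
      for (j in js) {
        denom <- prod(lambda[setdiff(js, j)] - lambda[j])
        acc <- acc + exp(-lambda[j] * t) /
          (if (length(js) == 1L) 1 else denom)
      }
      out[, i] <- prod(k_list[seq_len(i - 1)][seq_len(i - 1) >= m]) * acc
    }
    out
  }
  solution <- function(t) {
    out <- matrix(0, length(t), n,
                  dimnames = list(NULL, paste0("chain.s", seq_len(n))))
    for (m in seq_len(n)) if (x0[m] > 0) out <- out + x0[m] * bateman(t, m)
    out
  }
  attr(con, "solution") <- solution
  con
}
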