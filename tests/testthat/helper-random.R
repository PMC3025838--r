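# Random small constructs and an independent symbolic flux oracle used to
# cross-check the compiler.

random_construct <- function(n_states = sample(2:5, 1),
                             n_rates = sample(2:6, 1)) {
  con <- new_construct(paste0("rc", sample.int(1e6, 1)), "bookkeeping")
  sn <- paste0("s", seq_len(n_states))
  for (s in sn) con <- add_state(con, s, runif(1, 0, 100))
  for (j in seq_len(n_rates)) {
    reac <- sample(sn, sample(0:2, 1))
    avail <- setdiff(sn, reac)
    mods <- if (length(avail)) sample(avail, min(sample(0:1, 1),
                                                 length(avail)))
            else character(0)
    srcs <- if (length(reac)) stats::setNames(sample(1:3, length(reac),
                                                     TRUE), reac)
            else character()
    snks <- stats::setNames(sample(1:2, 1), sample(sn, 1))
    sat <- NULL; inhib <- NULL
    if (length(mods) && runif(1) < 0.5) {
      if (runif(1) < 0.5) sat <- stats::setNames(runif(1, 1, 50), mods)
      else inhib <- stats::setNames(runif(1, 1, 50), mods)
    }
    con <- add_rate(con, paste0("r", j), runif(1, 0, 2), reactants = reac,
                    sources = srcs, sinks = snks, modifiers = mods,
                    sat = sat, inhib = inhib)
  }
  con
}

# symbolic oracle: build the flux expression as text, then evaluate it with
# base R -- an independent path from the vectorized compiler
symbolic_flux <- function(rate, amounts, size = 1) {
  terms <- sprintf("%.17g", rate$k * size)
  for (fc in rate$factors) {
    cexp <- sprintf("(%.17g / %.17g)", amounts[[fc$ref]], size)
    terms <- c(terms, switch(fc$kind,
      linear = cexp,
      sat = sprintf("(%s / (%.17g + %s))", cexp, fc$K, cexp),
      inhib = sprintf("(%.17g / (%.17g + %s))", fc$K, fc$K, cexp)))
  }
  eval(parse(text = paste(terms, collapse = " * ")))
}

# brute-force per-state derivative: loop over every rate, debit sources and
# credit sinks by the oracle flux
brute_force_rhs <- function(con, x, size = 1) {
  dx <- stats::setNames(numeric(length(x)), names(x))
  local <- function(ref) if (grepl(".", ref, fixed = TRUE)) ref else
    paste(con$name, ref, sep = ".")
  for (r in con$rates) {
    am <- as.list(x)
    names(am) <- names(x)
    amq <- stats::setNames(as.list(unname(x)), names(x))
    flux <- symbolic_flux(
      within_rate_qualified(r, con$name), amq, size)
    for (j in seq_along(r$sources))
      dx[local(names(r$sources)[j])] <-
        dx[local(names(r$sources)[j])] - r$sources[[j]] * flux
    for (j in seq_along(r$sinks))
      dx[local(names(r$sinks)[j])] <-
        dx[local(names(r$sinks)[j])] + r$sinks[[j]] * flux
  }
  dx
}

within_rate_qualified <- function(r, cname) {
  r$factors <- lapply(r$factors, function(fc) {
    if (!grepl(".", fc$ref, fixed = TRUE))
      fc$ref <- paste(cname, fc$ref, sep = ".")
    fc
  })
  r
}
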