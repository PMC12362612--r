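# SSA realization: each rate term maps to one reaction with an integer
# stoichiometry vector and a propensity descriptor. At system size omega
# (molecules per uM), zeroth-order propensities scale by omega and
# second-order ones by 1/omega, so the reaction drift equals the ODE
# right-hand side at every state after count <-> concentration conversion.

PROP_CONST <- 0L
PROP_HILL <- 1L
PROP_LINEAR <- 2L
PROP_BIMOL <- 3L
PROP_MM <- 4L

#' Derive the stochastic reaction list of a model
#'
#' Maps every rate term of the spec to a reaction (stoichiometry change
#' vector + propensity rule). The summed drift
#' \code{sum_j stoich_j * a_j(x) / omega} equals [rhs()] at every
#' nonnegative state. Input-driven terms (exogenous time-varying signals)
#' have no exact SSA realization and raise an error.
#'
#' @param spec a [model_spec()].
#' @return An object of class \code{"reaction_list"}: a list of reactions,
#'   each with \code{stoich} (named integer vector over species) and a
#'   propensity descriptor.
#' @export
reactions <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  sp <- spec$species
  zero <- stats::setNames(integer(length(sp)), sp)
  out <- list()
  add <- function(stoich, type, rate, s1 = NA, s2 = NA,
                  K = NA, m = NA, regulation = NA, label) {
    out[[length(out) + 1L]] <<- list(
      stoich = stoich, type = type, rate = rate, s1 = s1, s2 = s2,
      K = K, m = m, regulation = regulation, label = label)
  }
  for (tm in spec$terms) {
    switch(tm$type,
      hill_production = {
        st <- zero; st[tm$target] <- 1L
        add(st, PROP_HILL, tm$rate, s1 = tm$source, K = tm$K, m = tm$m,
            regulation = tm$regulation,
            label = paste0("0 -> ", tm$target, " (Hill of ", tm$source, ")"))
      },
      constant_production = {
        st <- zero; st[tm$target] <- 1L
        add(st, PROP_CONST, tm$rate, label = paste0("0 -> ", tm$target))
      },
      catalytic_production = ,
      additive_control = {
        st <- zero; st[tm$target] <- 1L
        add(st, PROP_LINEAR, tm$rate, s1 = tm$source,
            label = paste0(tm$source, " -> ", tm$source, " + ", tm$target))
      },
      linear_decay = {
        st <- zero; st[tm$target] <- -1L
        add(st, PROP_LINEAR, tm$rate, s1 = tm$target,
            label = paste0(tm$target, " -> 0"))
      },
      pairwise_sequestration = {
        st <- zero; st[tm$source] <- -1L; st[tm$source2] <- -1L
        add(st, PROP_BIMOL, tm$rate, s1 = tm$source, s2 = tm$source2,
            label = paste0(tm$source, " + ", tm$source2, " -> 0"))
      },
      mm_degradation_control = {
        st <- zero; st[tm$target] <- -1L
        add(st, PROP_MM, tm$rate, s1 = tm$source, s2 = tm$target, K = tm$K,
            label = paste0(tm$target, " -> 0 (MM, catalysed by ",
                           tm$source, ")"))
      },
      stop("term of type '", tm$type,
           "' has no stochastic reaction mapping", call. = FALSE)
    )
  }
  structure(out, class = "reaction_list", species = sp)
}

#' @export
print.reaction_list <- function(x, ...) {
  cat(length(x), "reactions over species",
      paste(attr(x, "species"), collapse = ", "), "\n")
  for (r in x) cat("  ", r$label, " @", r$rate, "\n")
  invisible(x)
}

# propensities at integer count state x, system size omega
propensities <- function(rx, x, omega = 1) {
  sp <- attr(rx, "species")
  names(x) <- sp
  vapply(rx, function(r) {
    switch(as.character(r$type),
      "0" = r$rate * omega,
      "1" = r$rate * omega *
              hill_value(x[r$s1] / omega, r$K, r$m, r$regulation),
      "2" = r$rate * x[r$s1],
      "3" = r$rate * x[r$s1] * x[r$s2] / omega,
      "4" = {
        y <- x[r$s2] / omega
        r$rate * x[r$s1] * y / (y + r$K)
      })
  }, numeric(1), USE.NAMES = FALSE)
}

# reaction drift in concentration units: sum_j stoich_j a_j / omega
reaction_drift <- function(rx, state, omega = 1) {
  a <- propensities(rx, state * omega, omega)
  S <- stoich_matrix(rx)
  drop(S %*% a) / omega
}

stoich_matrix <- function(rx) {
  nsp <- length(attr(rx, "species"))
  matrix(vapply(rx, function(r) as.numeric(r$stoich), numeric(nsp)),
         nrow = nsp)
}

# flat numeric encoding for the C++ direct-method core
encode_reactions <- function(rx) {
  sp <- attr(rx, "species")
  idx <- function(s) if (is.na(s)) -1L else match(s, sp) - 1L
  list(
    stoich = stoich_matrix(rx),
    type = vapply(rx, function(r) as.integer(r$type), integer(1)),
    rate = vapply(rx, function(r) as.numeric(r$rate), numeric(1)),
    s1 = vapply(rx, function(r) idx(r$s1), integer(1)),
    s2 = vapply(rx, function(r) idx(r$s2), integer(1)),
    K = vapply(rx, function(r) as.numeric(r$K), numeric(1)),
    m = vapply(rx, function(r) as.numeric(r$m), numeric(1)),
    act = vapply(rx, function(r)
      as.integer(identical(r$regulation, "activating")), integer(1))
  )
}
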