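# Declarative model specifications: a species list plus typed rate terms from
# which both the ODE right-hand side and the stochastic reaction list derive.

SPECIES_ORDER <- c("Y1", "Y2", "X", "U1", "U2", "Xp", "U1p", "U2p")

# term constructors (internal) ------------------------------------------------

term_hill_production <- function(target, source, regulation, rate, K, m) {
  list(type = "hill_production", target = target, source = source,
       regulation = regulation, rate = rate, K = K, m = m)
}
term_constant_production <- function(target, rate) {
  list(type = "constant_production", target = target, rate = rate)
}
term_input_production <- function(target, rate) {
  list(type = "input_production", target = target, rate = rate)
}
term_catalytic_production <- function(target, source, rate) {
  list(type = "catalytic_production", target = target, source = source,
       rate = rate)
}
term_additive_control <- function(target, source, rate) {
  list(type = "additive_control", target = target, source = source,
       rate = rate)
}
term_linear_decay <- function(target, rate) {
  list(type = "linear_decay", target = target, rate = rate)
}
term_pairwise_sequestration <- function(a, b, rate) {
  list(type = "pairwise_sequestration", source = a, source2 = b, rate = rate)
}
term_mm_degradation <- function(target, source, rate, K) {
  list(type = "mm_degradation_control", target = target, source = source,
       rate = rate, K = K)
}

hill_value <- function(y, K, m, regulation) {
  y <- pmax(y, 0)
  if (regulation == "repressing") K^m / (K^m + y^m) else y^m / (K^m + y^m)
}

#' Construct a model specification
#'
#' Usually called through the model factories ([make_toggle()] and friends)
#' rather than directly. A spec holds an ordered species list, the kinetic
#' parameters, a list of typed rate terms, and (for controlled models) the
#' controller wiring used for quasi-steady-state reduction.
#'
#' @param name model identifier.
#' @param species ordered character vector, a subset of
#'   Y1, Y2, X, U1, U2, Xp, U1p, U2p (the primed names are the second
#'   controller's species).
#' @param params a [kinetic_params()] object.
#' @param terms list of rate terms (internal constructors).
#' @param controllers list of controller descriptors (internal).
#' @param input_signal optional nonnegative function of time driving
#'   input-production terms (isolated controller only).
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(name, species, params, terms,
                       controllers = list(), input_signal = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!all(species %in% SPECIES_ORDER))
    stop("unknown species: ",
         paste(setdiff(species, SPECIES_ORDER), collapse = ", "),
         call. = FALSE)
  species <- SPECIES_ORDER[SPECIES_ORDER %in% species]
  for (tm in terms) {
    refs <- unlist(tm[names(tm) %in% c("target", "source", "source2")])
    bad <- setdiff(refs, species)
    if (length(bad))
      stop("term of type '", tm$type, "' references undeclared species: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, species = species, params = params,
                 terms = terms, controllers = controllers,
                 input_signal = input_signal),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s': %d species (%s), %d terms, %d controller(s)\n",
              x$name, length(x$species), paste(x$species, collapse = ", "),
              length(x$terms), length(x$controllers)))
  invisible(x)
}

# internal rhs without state validation; tolerates slightly negative probes
# from the stiff integrator by clamping inside the Hill/MM evaluations
rhs_eval <- function(spec, state, t = 0) {
  sp <- spec$species
  dx <- numeric(length(sp))
  names(dx) <- sp
  s <- state
  names(s) <- sp
  for (tm in spec$terms) {
    switch(tm$type,
      hill_production = {
        dx[tm$target] <- dx[tm$target] +
          tm$rate * hill_value(s[tm$source], tm$K, tm$m, tm$regulation)
      },
      constant_production = {
        dx[tm$target] <- dx[tm$target] + tm$rate
      },
      input_production = {
        y <- spec$input_signal(t)
        if (any(y < 0))
          stop("input signal is negative at t = ", t, call. = FALSE)
        dx[tm$target] <- dx[tm$target] + tm$rate * y
      },
      catalytic_production = ,
      additive_control = {
        dx[tm$target] <- dx[tm$target] + tm$rate * s[tm$source]
      },
      linear_decay = {
        dx[tm$target] <- dx[tm$target] - tm$rate * s[tm$target]
      },
      pairwise_sequestration = {
        flux <- tm$rate * max(s[tm$source], 0) * max(s[tm$source2], 0)
        dx[tm$source] <- dx[tm$source] - flux
        dx[tm$source2] <- dx[tm$source2] - flux
      },
      mm_degradation_control = {
        y <- max(s[tm$target], 0)
        dx[tm$target] <- dx[tm$target] -
          tm$rate * max(s[tm$source], 0) * y / (y + tm$K)
      },
      stop("unknown term type: ", tm$type, call. = FALSE)
    )
  }
  unname(dx)
}

#' Evaluate the deterministic right-hand side of a model
#'
#' Term-additive evaluation of the mass-action / Hill ODEs encoded in the
#' spec, in uM/h. Every species' total removal rate vanishes when that
#' species is zero, so the nonnegative orthant is forward-invariant.
#'
#' @param spec a [model_spec()].
#' @param state numeric state vector (uM), one entry per species, all >= 0.
#' @param t time (h); only used by input-driven terms.
#' @return The derivative vector (uM/h), in species order.
#' @export
rhs <- function(spec, state, t = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(state) != length(spec$species))
    stop("state length ", length(state), " does not match ",
         length(spec$species), " species", call. = FALSE)
  if (any(!is.finite(state)))
    stop("state contains non-finite values", call. = FALSE)
  if (any(state < 0))
    stop("state contains negative concentrations", call. = FALSE)
  rhs_eval(spec, state, t)
}
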