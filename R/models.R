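# Model factories: every dynamical variant assembled from the shared term
# vocabulary. Controlled variants carry controller descriptors so the
# equilibrium module can eliminate the controller at quasi-steady state.

controller_species <- function(prime) {
  if (prime) c("Xp", "U1p", "U2p") else c("X", "U1", "U2")
}

# terms + descriptor for one adaptive controller wired per `config`
build_controller <- function(params, config, gain, prime = FALSE) {
  sp <- controller_species(prime)
  names(sp) <- c("X", "U1", "U2")
  input <- sp[[config$input_species]]
  terms <- list(
    term_hill_production(sp[["X"]], config$sense_species,
                         config$sense_regulation, params$theta,
                         params$K, params$m),
    term_hill_production(sp[["U2"]], config$sense_species,
                         config$sense_regulation, params$xi,
                         params$K, params$m),
    term_catalytic_production(sp[["U1"]], sp[["X"]], params$k),
    term_linear_decay(sp[["X"]], params$delta),
    term_linear_decay(sp[["U1"]], params$delta),
    term_linear_decay(sp[["U2"]], params$delta),
    term_pairwise_sequestration(sp[["U1"]], sp[["U2"]], params$gamma)
  )
  actuation_term <- if (config$actuation == "additive_activation") {
    term_additive_control(config$target_species, input, gain)
  } else {
    term_mm_degradation(config$target_species, input, gain, params$K_deg)
  }
  list(species = unname(sp),
       terms = c(terms, list(actuation_term)),
       descriptor = list(sense_species = config$sense_species,
                         sense_regulation = config$sense_regulation,
                         input_species = config$input_species,
                         actuation = config$actuation,
                         target_species = config$target_species,
                         gain = gain))
}

toggle_base_terms <- function(params) {
  list(
    term_hill_production("Y1", "Y2", "repressing", params$alpha1,
                         params$K, params$m),
    term_hill_production("Y2", "Y1", "repressing", params$alpha2,
                         params$K, params$m),
    term_linear_decay("Y1", params$delta),
    term_linear_decay("Y2", params$delta)
  )
}

#' Toggle switch: two mutually repressing genes
#'
#' The canonical bistable motif: each species represses the other through a
#' Hill function, and both decay linearly. With unequal maximal production
#' rates (alpha1 != alpha2) this is the unbalanced toggle switch used for the
#' robustness analysis.
#'
#' @param params a [kinetic_params()] object.
#' @return A [model_spec()] with species Y1, Y2.
#' @examples
#' tg <- make_toggle(kinetic_params())
#' rhs(tg, c(0, 0))  # (alpha1, alpha2) at the origin
#' @export
make_toggle <- function(params) {
  validate_params(params)
  model_spec("toggle", c("Y1", "Y2"), params, toggle_base_terms(params))
}

#' Isolated adaptive controller driven by an exogenous input
#'
#' The incoherent-feedforward/sequestration controller on its own: the input
#' signal y(t) produces the intermediate X (rate theta) and the sequestering
#' species U2 (rate xi); X produces the output U1 (rate k); U1 and U2
#' annihilate pairwise (rate gamma); all three species decay at delta.
#'
#' @param params a [kinetic_params()] object.
#' @param input_signal nonnegative function of time (h) giving the exogenous
#'   drive y(t) in uM.
#' @return A [model_spec()] with species X, U1, U2.
#' @export
make_isolated_controller <- function(params, input_signal) {
  validate_params(params)
  if (!is.function(input_signal))
    stop("input_signal must be a function of time", call. = FALSE)
  if (any(input_signal(0) < 0))
    stop("input_signal must be nonnegative", call. = FALSE)
  terms <- list(
    term_input_production("X", params$theta),
    term_input_production("U2", params$xi),
    term_catalytic_production("U1", "X", params$k),
    term_linear_decay("X", params$delta),
    term_linear_decay("U1", params$delta),
    term_linear_decay("U2", params$delta),
    term_pairwise_sequestration("U1", "U2", params$gamma)
  )
  model_spec("isolated_controller", c("X", "U1", "U2"), params, terms,
             input_signal = input_signal)
}

#' Toggle switch under adaptive control
#'
#' The toggle switch in closed loop with one (or two mirrored) adaptive
#' controllers. The controller senses an endogenous species through a
#' repressing Hill function, and its output actuates the target species.
#' Setting beta = 0 recovers the isolated (possibly unbalanced) toggle
#' exactly on the shared subspace.
#'
#' @param params a [kinetic_params()] object; \code{params$beta} is the gain
#'   of the (first) controller and \code{params$beta_prime} that of the
#'   mirrored second controller when \code{config$duplicated == "double"}.
#' @param config a [controller_config()]; the toggle is sensed through
#'   repressing Hill functions, so \code{sense_regulation} must be
#'   "repressing".
#' @return A [model_spec()] with 5 species (single) or 8 (double).
#' @examples
#' ct <- make_controlled_toggle(kinetic_params(), negative_feedback_config())
#' @export
make_controlled_toggle <- function(params, config) {
  validate_params(params)
  stopifnot(inherits(config, "controller_config"))
  if (config$sense_regulation != "repressing")
    stop("the toggle switch is sensed through repressing Hill functions",
         call. = FALSE)
  c1 <- build_controller(params, config, params$beta)
  species <- c("Y1", "Y2", c1$species)
  terms <- c(toggle_base_terms(params), c1$terms)
  controllers <- list(c1$descriptor)
  if (config$duplicated == "double") {
    if (is.null(params$beta_prime))
      stop("double controller requested but beta_prime is unset",
           call. = FALSE)
    mirror <- config
    mirror$sense_species <- setdiff(c("Y1", "Y2"), config$sense_species)
    mirror$target_species <- setdiff(c("Y1", "Y2"), config$target_species)
    c2 <- build_controller(params, mirror, params$beta_prime, prime = TRUE)
    species <- c(species, c2$species)
    terms <- c(terms, c2$terms)
    controllers <- c(controllers, list(c2$descriptor))
  }
  model_spec("controlled_toggle", species, params, terms, controllers)
}

#' Toggle switch with self-activation
#'
#' Adds an activating Hill self-loop of strength alpha3 to Y1
#' (\code{double = FALSE}) or to both species (\code{double = TRUE}). With
#' the dedicated nominal set ([tristable_params()]) the double variant is
#' tristable: three stable equilibria separated by two saddles.
#'
#' @param params a [kinetic_params()] object (alpha3 is the loop strength).
#' @param double add the self-loop to both species?
#' @return A [model_spec()] with species Y1, Y2.
#' @export
make_toggle_selfactivation <- function(params, double = FALSE) {
  validate_params(params)
  terms <- c(toggle_base_terms(params), list(
    term_hill_production("Y1", "Y1", "activating", params$alpha3,
                         params$K, params$m)))
  if (double)
    terms <- c(terms, list(
      term_hill_production("Y2", "Y2", "activating", params$alpha3,
                           params$K, params$m)))
  model_spec(if (double) "toggle_selfactivation_double"
             else "toggle_selfactivation",
             c("Y1", "Y2"), params, terms)
}

#' Mutual activation motif under adaptive control
#'
#' Two mutually activating species (stable states: both high or both absent)
#' with an adaptive controller that degrades its target through a saturated
#' (Michaelis-Menten) term, favouring the zero state. Sensing uses activating
#' Hill functions; an additive actuation is rejected for this factory.
#'
#' @param params a [kinetic_params()] object.
#' @param config a [controller_config()] with
#'   \code{actuation = "saturated_degradation"} and activating sensing;
#'   defaults to sensing the target Y1 (negative feedback). The positive
#'   feedback mirror senses the non-target species instead.
#' @return A [model_spec()] with species Y1, Y2, X, U1, U2.
#' @export
make_controlled_mutual_activation <- function(params,
    config = controller_config("Y1", "activating", "U1",
                               "saturated_degradation", "Y1")) {
  validate_params(params)
  stopifnot(inherits(config, "controller_config"))
  if (config$actuation != "saturated_degradation")
    stop("the mutual activation motif is controlled through saturated ",
         "degradation; additive activation is not supported here",
         call. = FALSE)
  if (config$sense_regulation != "activating")
    stop("the mutual activation motif is sensed through activating Hill ",
         "functions", call. = FALSE)
  base <- list(
    term_hill_production("Y1", "Y2", "activating", params$alpha1,
                         params$K, params$m),
    term_hill_production("Y2", "Y1", "activating", params$alpha2,
                         params$K, params$m),
    term_linear_decay("Y1", params$delta),
    term_linear_decay("Y2", params$delta)
  )
  c1 <- build_controller(params, config, params$beta)
  model_spec("controlled_mutual_activation",
             c("Y1", "Y2", c1$species), params,
             c(base, c1$terms), list(c1$descriptor))
}

#' Tristable toggle switch under double adaptive control
#'
#' The toggle switch with self-activation on both species, plus one adaptive
#' controller per species. Each controller may inhibit its target through
#' saturated degradation or activate it additively, so both the
#' double-inhibition design (suppressing the intermediate state) and the
#' mixed design (activate Y1, inhibit Y2) are expressible.
#'
#' @param params a [kinetic_params()] object, typically [tristable_params()];
#'   gains are \code{beta} (controller on Y1) and \code{beta_prime}
#'   (controller on Y2; defaults to \code{beta}).
#' @param config_y1 a [controller_config()] with \code{target_species="Y1"}.
#' @param config_y2 a [controller_config()] with \code{target_species="Y2"}.
#' @return A [model_spec()] with 8 species.
#' @seealso [tristable_inhibition_configs()], [tristable_mixed_configs()]
#' @export
make_controlled_tristable <- function(params, config_y1, config_y2) {
  validate_params(params)
  if (missing(config_y2) || is.null(config_y2))
    stop("the tristable network needs one controller per species: ",
         "config_y2 is missing", call. = FALSE)
  stopifnot(inherits(config_y1, "controller_config"),
            inherits(config_y2, "controller_config"))
  if (config_y1$target_species != "Y1" || config_y2$target_species != "Y2")
    stop("config_y1 must target Y1 and config_y2 must target Y2",
         call. = FALSE)
  base_spec <- make_toggle_selfactivation(params, double = TRUE)
  bp <- if (is.null(params$beta_prime)) params$beta else params$beta_prime
  c1 <- build_controller(params, config_y1, params$beta)
  c2 <- build_controller(params, config_y2, bp, prime = TRUE)
  model_spec("controlled_tristable",
             c("Y1", "Y2", c1$species, c2$species), params,
             c(base_spec$terms, c1$terms, c2$terms),
             list(c1$descriptor, c2$descriptor))
}

#' Controller configurations for the tristable network
#'
#' \code{tristable_inhibition_configs()} gives the double-inhibition design
#' (each controller senses its own target through an activating Hill and
#' degrades it), which suppresses the intermediate state.
#' \code{tristable_mixed_configs()} gives the mixed design: additive
#' activation of Y1 (sensed through the repressing Hill, as in the controlled
#' toggle) combined with inhibition of Y2.
#'
#' @return A list with elements \code{y1} and \code{y2}, each a
#'   [controller_config()].
#' @export
tristable_inhibition_configs <- function() {
  list(y1 = controller_config("Y1", "activating", "U1",
                              "saturated_degradation", "Y1"),
       y2 = controller_config("Y2", "activating", "U1",
                              "saturated_degradation", "Y2"))
}

#' @rdname tristable_inhibition_configs
#' @export
tristable_mixed_configs <- function() {
  list(y1 = controller_config("Y1", "repressing", "U1",
                              "additive_activation", "Y1"),
       y2 = controller_config("Y2", "activating", "U1",
                              "saturated_degradation", "Y2"))
}
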