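#' Kinetic parameters for the endogenous networks and the adaptive controller
#'
#' Bundles every rate constant used by the model factories. Defaults are the
#' nominal values for the toggle switch / mutual activation motif (alpha = 2.2
#' uM/h, K = 1 uM, m = 3, delta = 1 /h) and the adaptive controller
#' (xi = theta = k = 1, beta = 1 /h, gamma = 100 /uM/h). The toggle switch
#' with self-activation uses its own nominal set, available via
#' \code{tristable_params()}.
#'
#' @param alpha1 maximal production rate of Y1 (uM/h).
#' @param alpha2 maximal production rate of Y2 (uM/h).
#' @param alpha3 self-activation strength (uM/h); 0 disables the self loop.
#' @param K Hill constant (uM).
#' @param m Hill cooperativity (dimensionless integer, >= 1).
#' @param delta first-order decay rate shared by all species (/h).
#' @param xi maximal production rate of the sequestering species U2 (uM/h).
#' @param theta maximal production rate of the intermediate species X (uM/h).
#' @param k production rate of the controller output U1 from X (/h).
#' @param beta control gain: strength of the actuation on the target (/h).
#' @param beta_prime gain of the mirrored second controller (/h); defaults to
#'   \code{beta} when a double controller is requested.
#' @param gamma sequestration rate of U1 + U2 -> 0 (/uM/h).
#' @param K_deg Michaelis constant of the saturated-degradation actuation
#'   (uM); defaults to \code{K}.
#'
#' @return An object of class \code{"kinetic_params"} (a validated list).
#' @examples
#' p <- kinetic_params()
#' adaptive_metric(p)  # xi*delta/(k*theta) = 1 at nominal values
#' @export
kinetic_params <- function(alpha1 = 2.2, alpha2 = 2.2, alpha3 = 0,
                           K = 1, m = 3, delta = 1,
                           xi = 1, theta = 1, k = 1,
                           beta = 1, beta_prime = NULL,
                           gamma = 100, K_deg = K) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            K = K, m = m, delta = delta,
            xi = xi, theta = theta, k = k,
            beta = beta, beta_prime = beta_prime,
            gamma = gamma, K_deg = K_deg)
  validate_params(p)
  class(p) <- "kinetic_params"
  p
}

#' Nominal parameters of the tristable toggle switch with double self-activation
#'
#' @param ... overrides passed on to [kinetic_params()].
#' @return A \code{"kinetic_params"} object with alpha1 = alpha2 = alpha3 =
#'   1.2 uM/h, K = 0.5 uM, m = 4, delta = 1 /h and nominal controller rates.
#' @export
tristable_params <- function(...) {
  args <- list(alpha1 = 1.2, alpha2 = 1.2, alpha3 = 1.2, K = 0.5, m = 4)
  args[names(list(...))] <- list(...)
  do.call(kinetic_params, args)
}

validate_params <- function(p) {
  num <- c("alpha1", "alpha2", "alpha3", "K", "m", "delta",
           "xi", "theta", "k", "beta", "gamma", "K_deg")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", f, "' must be >= 0, got ", v, call. = FALSE)
  }
  if (!is.null(p$beta_prime)) {
    if (!is.numeric(p$beta_prime) || length(p$beta_prime) != 1L ||
        !is.finite(p$beta_prime) || p$beta_prime < 0)
      stop("parameter 'beta_prime' must be a single finite number >= 0",
           call. = FALSE)
  }
  if (p$m < 1 || p$m != round(p$m))
    stop("parameter 'm' must be an integer >= 1, got ", p$m, call. = FALSE)
  if (p$delta <= 0)
    stop("parameter 'delta' must be > 0", call. = FALSE)
  invisible(p)
}

#' Adaptive metric r = xi * delta / (k * theta)
#'
#' The design parameter of the controller: at r = 1 the controller output
#' adapts perfectly (it converges to zero for any input that settles to a
#' constant), so the equilibrium landscape of the controlled network is
#' asymptotically unperturbed in the fast-sequestration regime.
#'
#' @param params a [kinetic_params()] object.
#' @return The scalar metric r.
#' @export
adaptive_metric <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  kt <- params$k * params$theta
  if (kt == 0)
    stop("adaptive metric undefined: k * theta = 0", call. = FALSE)
  params$xi * params$delta / kt
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters:\n")
  cat(sprintf("  endogenous: alpha1=%g alpha2=%g alpha3=%g K=%g m=%g delta=%g\n",
              x$alpha1, x$alpha2, x$alpha3, x$K, x$m, x$delta))
  cat(sprintf("  controller: xi=%g theta=%g k=%g beta=%g beta'=%s gamma=%g K_deg=%g\n",
              x$xi, x$theta, x$k, x$beta,
              if (is.null(x$beta_prime)) "-" else format(x$beta_prime),
              x$gamma, x$K_deg))
  if (x$k * x$theta > 0)
    cat(sprintf("  adaptive metric r = %g\n", x$xi * x$delta / (x$k * x$theta)))
  invisible(x)
}

#' Controller architecture configuration
#'
#' Describes how the adaptive controller is wired to the endogenous network:
#' which species it senses (and through an activating or repressing Hill
#' function), which controller species actuates the network, whether the
#' actuation adds production or degrades the target through a saturated
#' (Michaelis-Menten) term, and whether a mirrored second controller is
#' present. Sensing the target species of a target-raising actuation closes a
#' negative feedback loop; sensing the opposing species closes a positive one.
#'
#' @param sense_species endogenous species whose Hill function drives the
#'   production of X and U2 ("Y1" or "Y2").
#' @param sense_regulation "repressing" (K^m/(K^m+y^m)) or "activating"
#'   (y^m/(K^m+y^m)).
#' @param input_species controller species that actuates the network, "U1"
#'   (default) or "U2".
#' @param actuation "additive_activation" (+ beta*u on the target) or
#'   "saturated_degradation" (- beta*u*y/(y+K_deg)).
#' @param target_species endogenous species receiving the actuation.
#' @param duplicated "single" (default) or "double" (a mirrored second
#'   controller with gain beta_prime acting on the other species).
#' @return An object of class \code{"controller_config"}.
#' @seealso [negative_feedback_config()], [positive_feedback_config()]
#' @export
controller_config <- function(sense_species,
                              sense_regulation = c("repressing", "activating"),
                              input_species = c("U1", "U2"),
                              actuation = c("additive_activation",
                                            "saturated_degradation"),
                              target_species,
                              duplicated = c("single", "double")) {
  sense_regulation <- match.arg(sense_regulation)
  input_species <- match.arg(input_species)
  actuation <- match.arg(actuation)
  duplicated <- match.arg(duplicated)
  if (!sense_species %in% c("Y1", "Y2"))
    stop("sense_species must be 'Y1' or 'Y2'", call. = FALSE)
  if (!target_species %in% c("Y1", "Y2"))
    stop("target_species must be 'Y1' or 'Y2'", call. = FALSE)
  cfg <- list(sense_species = sense_species,
              sense_regulation = sense_regulation,
              input_species = input_species,
              actuation = actuation,
              target_species = target_species,
              duplicated = duplicated)
  class(cfg) <- "controller_config"
  cfg
}

#' Standard architectures for the controlled toggle switch
#'
#' In the toggle switch the controller raises the target Y1; sensing Y1
#' itself (whose increase then represses the controller drive) closes a
#' negative feedback loop, while sensing the opposing species Y2 closes a
#' positive one. Both sense through the repressing Hill function, matching
#' the transcriptional repression exerted by the sensed species.
#'
#' @param input_species controller species actuating the network ("U1" or "U2").
#' @param duplicated "single" or "double".
#' @return A [controller_config()] object.
#' @export
negative_feedback_config <- function(input_species = "U1",
                                     duplicated = "single") {
  controller_config("Y1", "repressing", input_species,
                    "additive_activation", "Y1", duplicated)
}

#' @rdname negative_feedback_config
#' @export
positive_feedback_config <- function(input_species = "U1",
                                     duplicated = "single") {
  controller_config("Y2", "repressing", input_species,
                    "additive_activation", "Y1", duplicated)
}

#' Feedback-architecture label of a configuration
#'
#' Derived, not stored. The architecture convention: a controller that
#' senses the species it actuates closes the negative feedback loop (its
#' own action feeds back into its drive), while sensing the opposing
#' species closes the positive one.
#'
#' @param config a [controller_config()] object.
#' @return "negative" or "positive".
#' @export
feedback_label <- function(config) {
  stopifnot(inherits(config, "controller_config"))
  if (config$sense_species == config$target_species) "negative"
  else "positive"
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf(
    "Controller config: sense %s (%s), input %s, %s on %s [%s, %s feedback]\n",
    x$sense_species, x$sense_regulation, x$input_species, x$actuation,
    x$target_species, x$duplicated, feedback_label(x)))
  invisible(x)
}
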