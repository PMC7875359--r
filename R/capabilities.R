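# The capability contract: the interface between tests and models.
# A test only communicates with a model through these generics, so any
# backend (the built-in mock, or a user adapter around a real simulator)
# can be validated without changing test code.  Repeated identical calls
# must yield identical traces (the determinism contract); tests refuse to
# run when a required capability is missing.

#' Capabilities exposed by a model
#'
#' @param model a model object.
#' @return character vector of capability names, a subset of
#'   `c("step_current", "synaptic_activation", "morphology")`.
#' @export
capabilities <- function(model) UseMethod("capabilities")

#' @export
capabilities.default <- function(model) character(0)

#' Check a capability, or fail with a contract error
#'
#' @param model a model object.
#' @param name capability name.
#' @param context human-readable description of what needs it.
#' @keywords internal
#' @export
require_capability <- function(model, name, context = "this test") {
  if (!(name %in% capabilities(model)))
    hv_stop("hippoval_capability_error",
            "%s requires the '%s' capability, which the model does not provide",
            context, name)
  invisible(TRUE)
}

#' Step-current injection with multi-site voltage recording
#'
#' @param model a model providing the `step_current` capability.
#' @param amplitude current amplitude, nA.
#' @param delay stimulus onset, ms.
#' @param duration stimulus duration, ms.
#' @param tstop simulated time, ms.
#' @param sites recording sites: `"soma"` and/or location rows from the
#'   morphology module; a list mixes both.
#' @param dt time step, ms (`NULL` = model default).
#' @return named list of [voltage_trace()] objects, one per site.
#' @export
step_current_response <- function(model, amplitude, delay, duration, tstop,
                                  sites = "soma", dt = NULL)
  UseMethod("step_current_response")

#' Synaptic activation with somatic and local recording
#'
#' Activates `count` clustered synaptic inputs at `location`, spaced
#' `interval` ms apart, each with weight `weight`.
#'
#' @param model a model providing the `synaptic_activation` capability.
#' @param location a location row (section, arc position, path distance).
#' @param weight synaptic weight per input.
#' @param count number of inputs (0 gives the baseline run).
#' @param interval inter-input interval, ms.
#' @param tstop simulated time, ms.
#' @param delay onset of the first input, ms.
#' @param dt time step, ms (`NULL` = model default).
#' @return list with elements `soma` and `dendrite`, both
#'   [voltage_trace()] objects.
#' @export
synaptic_response <- function(model, location, weight, count, interval,
                              tstop, delay = 150, dt = NULL)
  UseMethod("synaptic_response")

#' Morphology access
#'
#' @param model a model providing the `morphology` capability.
#' @return list with elements `tree` (a `morph_tree`) and `classification`
#'   (an `apical_classification`).
#' @export
model_morphology <- function(model) UseMethod("model_morphology")

#' Simulation settings of a model
#'
#' @param model a model object.
#' @return list with `v_init` (mV), `celsius` (temperature label) and
#'   `dt` (ms).
#' @export
simulation_settings <- function(model) UseMethod("simulation_settings")
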