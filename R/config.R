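#' Simulation configuration
#'
#' Builds the full parameter set of the model with its published defaults.
#' Every numeric constant of the model lives here: population sizes, the
#' 150-step host lifespan with a 5-step equilibration prelude and a 50-step
#' developmental window, the protein-use coefficient, resource limits, death
#' rules, and mutation rates and event weights for hosts and parasites.
#'
#' @param ... named overrides of any default listed below.
#'
#' @details
#' Defaults:
#' \describe{
#'   \item{host_pop, parasite_pop}{500 hosts coevolving with 250 parasites in
#'     independent simulations (infection prevalence 50\%).}
#'   \item{burn_in_host_pop, burn_in_parasite_pop}{250 / 125, the isolated
#'     burn-in phase of a competitive simulation.}
#'   \item{generations}{1000 generations of independent evolution.}
#'   \item{burn_in_generations}{isolated generations before competition
#'     (250, 500 or 1000).}
#'   \item{competition_generations}{competition horizon; reaching it with both
#'     architectures extant is a draw (1000).}
#'   \item{life_steps, equilibrium_steps, dev_window}{150 / 5 / 50 time-steps.}
#'   \item{use_coef}{0.01, the per-interaction inactivation cost.}
#'   \item{initial_active}{0.5, starting active fraction of every protein.}
#'   \item{resource}{"scarce" (cap 0.1), "plentiful" (cap 1.0) or
#'     "alternating" (scarce on even generations, plentiful on odd,
#'     counted from generation 0).}
#'   \item{death_cap, death_threshold}{at most 30\% of either population dies
#'     per generation; hosts with parasite area above 0.9 die first.}
#'   \item{host_mutation_rate, host_mutation_weights}{5e-3; event weights
#'     add edge 0.25, delete edge 0.25, alter coefficient 0.3, delete protein
#'     0.1, duplicate protein 0.1.}
#'   \item{parasite_mutation_rate, parasite_mutation_weights}{1e-2; retarget
#'     0.5, new coefficient 0.5.}
#'   \item{parasite_self_coef, parasite_detector_coef, effector_parasite_coef}{
#'     0.8 self-replication, +1 onto the host detector, -1 from the host
#'     effector onto the parasite.}
#'   \item{parasite_inoculum}{0.5, the parasite abundance at infection.}
#'   \item{parasite_target_domain}{8; parasite target indices are drawn on
#'     0..7 and resolved per host by modulo over its immune signalling
#'     proteins.}
#'   \item{synchrony}{"synchronous" (infection inside the developmental
#'     window) or "asynchronous" (infection in the 50 steps after it).}
#'   \item{signal_order}{"development-first" (signal on life steps 1-50) or
#'     "development-last" (signal on steps 101-150).}
#'   \item{dev_signal_variant}{"half-angle" reads the signal as
#'     sin(x/2) + 0.5; "half-amplitude" as sin(x)/2 + 0.5.}
#'   \item{snapshot_every}{store population genotype snapshots every K
#'     generations (0 = never).}
#' }
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [load_config()], [run_coevolution()]
#' @examples
#' cfg <- sim_config(generations = 20, resource = "plentiful")
#' cfg$use_coef
#' @export
sim_config <- function(...) {
  cfg <- list(
    host_pop = 500L,
    parasite_pop = 250L,
    burn_in_host_pop = 250L,
    burn_in_parasite_pop = 125L,
    generations = 1000L,
    burn_in_generations = 500L,
    competition_generations = 1000L,
    life_steps = 150L,
    equilibrium_steps = 5L,
    dev_window = 50L,
    use_coef = 0.01,
    initial_active = 0.5,
    resource = "scarce",
    resource_limits = c(scarce = 0.1, plentiful = 1.0),
    death_cap = 0.30,
    death_threshold = 0.9,
    host_mutation_rate = 5e-3,
    host_mutation_weights = c(add_edge = 0.25, delete_edge = 0.25,
                              alter_coefficient = 0.30, delete_protein = 0.10,
                              duplicate_protein = 0.10),
    parasite_mutation_rate = 1e-2,
    parasite_mutation_weights = c(retarget = 0.5, new_coefficient = 0.5),
    parasite_self_coef = 0.8,
    parasite_detector_coef = 1.0,
    effector_parasite_coef = -1.0,
    parasite_inoculum = 0.5,
    parasite_target_domain = 8L,
    synchrony = "asynchronous",
    signal_order = "development-first",
    dev_signal_variant = "half-angle",
    architecture = "independent",
    snapshot_every = 0L,
    seed = NULL
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks ranges and enum values; returns the config blessed as `sim_config`.
#'
#' @param cfg a named list of configuration values.
#' @return the validated `sim_config` object.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  chk_count <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v))
      stop(sprintf("'%s' must be a positive integer", key))
  }
  for (key in c("host_pop", "parasite_pop", "burn_in_host_pop",
                "burn_in_parasite_pop", "generations", "burn_in_generations",
                "competition_generations", "life_steps", "equilibrium_steps",
                "dev_window", "parasite_target_domain"))
    chk_count(key)
  chk_frac <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(sprintf("'%s' must lie in [0, 1]", key))
  }
  for (key in c("death_cap", "death_threshold", "host_mutation_rate",
                "parasite_mutation_rate", "initial_active",
                "parasite_inoculum"))
    chk_frac(key)
  if (cfg$use_coef < 0) stop("'use_coef' must be non-negative")
  if (any(cfg$resource_limits <= 0)) stop("resource limits must be positive")
  chk_enum <- function(key, levels) {
    if (!is.character(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        !cfg[[key]] %in% levels)
      stop(sprintf("'%s' must be one of: %s", key,
                   paste(levels, collapse = ", ")))
  }
  chk_enum("resource", c("scarce", "plentiful", "alternating"))
  chk_enum("synchrony", c("synchronous", "asynchronous"))
  chk_enum("signal_order", c("development-first", "development-last"))
  chk_enum("dev_signal_variant", c("half-angle", "half-amplitude"))
  chk_enum("architecture", c("independent", "shared"))
  wsum <- function(w) abs(sum(w) - 1) < 1e-8
  if (!wsum(cfg$host_mutation_weights) || !wsum(cfg$parasite_mutation_weights))
    stop("mutation event weights must sum to 1")
  if (cfg$parasite_pop > cfg$host_pop)
    stop("parasite population may not exceed host population")
  if (cfg$dev_window * 3L != cfg$life_steps)
    stop("life_steps must equal three developmental windows (50 + 100 split)")
  structure(cfg, class = "sim_config")
}

#' Resource limit in force at a given generation
#'
#' Scarce and plentiful conditions are constant caps (0.1 and 1.0); the
#' alternating condition switches per generation, scarce on even generations
#' and plentiful on odd ones, counting from generation 0.
#'
#' @param cfg a `sim_config`.
#' @param generation integer generation index (0-based).
#' @return the positive cap on total newly activated protein per time-step.
#' @export
resource_limit <- function(cfg, generation = 0L) {
  switch(cfg$resource,
    scarce = unname(cfg$resource_limits[["scarce"]]),
    plentiful = unname(cfg$resource_limits[["plentiful"]]),
    alternating = if (generation %% 2L == 0L)
      unname(cfg$resource_limits[["scarce"]])
    else unname(cfg$resource_limits[["plentiful"]])
  )
}

#' Read a configuration file
#'
#' Loads a JSON file of overrides and merges it onto the model defaults.
#' Unknown keys are rejected; values are validated.
#'
#' @param path path to a JSON object of configuration overrides. An empty
#'   object (`{}`) yields the full default configuration.
#' @return a `sim_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0L) return(sim_config())
  # named vectors arrive as named lists; flatten numeric weight vectors back
  for (key in c("resource_limits", "host_mutation_weights",
                "parasite_mutation_weights")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  do.call(sim_config, raw)
}

#' Write a configuration file
#'
#' @param cfg a `sim_config`.
#' @param path output path; written as JSON, round-trips through
#'   [load_config()] losslessly.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  # named vectors as JSON objects so their names survive the round-trip
  for (key in c("resource_limits", "host_mutation_weights",
                "parasite_mutation_weights"))
    out[[key]] <- as.list(out[[key]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Host-parasite coevolution configuration\n")
  cat(sprintf("  architecture: %s | synchrony: %s | resources: %s | order: %s\n",
              x$architecture, x$synchrony, x$resource, x$signal_order))
  cat(sprintf("  populations: %d hosts / %d parasites; %d generations\n",
              x$host_pop, x$parasite_pop, x$generations))
  cat(sprintf("  life: %d steps (+%d equilibrium), development window %d\n",
              x$life_steps, x$equilibrium_steps, x$dev_window))
  cat(sprintf("  use_coef %.3g; death cap %d%%, threshold %.2g\n",
              x$use_coef, round(100 * x$death_cap), x$death_threshold))
  invisible(x)
}
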