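#' Pulsed developmental input signal
#'
#' The developmental programme the host must track is a periodic pulse,
#' \eqn{\mathrm{sig}(t) = \sin(x(t)/2) + 0.5}, evaluated on the 50 evenly
#' spaced grid points \eqn{x} from 0 to \eqn{8\pi} inclusive — four full
#' pulses over the 50-step developmental window, mimicking periodic
#' developmental events such as segmentation. The alternative reading
#' \eqn{\sin(x)/2 + 0.5} is available as the `"half-amplitude"` variant.
#'
#' @param step_index developmental step, 1 to `dev_window` (vectorized).
#' @param dev_window number of developmental steps (default 50).
#' @param variant `"half-angle"` (default) or `"half-amplitude"`.
#' @return signal values; not clamped to \eqn{[0, 1]} — the signal is an
#'   input and a fitness reference, never a protein concentration.
#' @examples
#' developmental_signal(1)    # 0.5 at x = 0
#' developmental_signal(50)   # 0.5 at x = 8*pi
#' @export
developmental_signal <- function(step_index, dev_window = 50L,
                                 variant = c("half-angle", "half-amplitude")) {
  variant <- match.arg(variant)
  if (any(step_index < 1L | step_index > dev_window))
    stop("step_index out of the developmental window")
  x <- seq(0, 8 * pi, length.out = dev_window)[step_index]
  if (variant == "half-angle") sin(x / 2) + 0.5 else sin(x) / 2 + 0.5
}

#' Equilibrate a host's signalling networks
#'
#' Starting from an active fraction of 0.5 for every protein, integrates the
#' dynamics for five time-steps (no developmental input, no parasite) so
#' host signalling settles before life begins.
#'
#' @param host a `pleio_host`.
#' @param limit resource cap in force.
#' @param cfg a `sim_config` (supplies `use_coef`, step counts, initial
#'   state).
#' @return the equilibrated `network_state`.
#' @export
equilibrate <- function(host, limit = 0.1, cfg = sim_config()) {
  cache <- host$cache
  n <- length(cache$ids)
  res <- run_life_cpp(cache$K, cache$I, as.integer(cache$out_deg),
                      rep(cfg$initial_active, n),
                      as.integer(cfg$equilibrium_steps), limit, cfg$use_coef,
                      0L, numeric(cfg$equilibrium_steps),
                      logical(cfg$equilibrium_steps),
                      0L, 0, 1L, 0, 0L, 0, 0, 1L, 0)
  network_state(host, active = res$states[cfg$equilibrium_steps, ])
}

#' Resolve a parasite's links into a host
#'
#' The infecting parasite joins the host immune network as an extra node
#' with an upregulatory connection of +1 to the immune detector, an up- or
#' downregulatory connection to its target signalling protein, and a
#' self-targeted upregulation of 0.8 (replication). In return the host's
#' immune effector (the sole effector of a shared-effector host) gains a
#' downregulatory connection of -1 onto the parasite. The target is the
#' parasite's target index modulo the number of immune signalling proteins,
#' ordered by protein id, so any parasite resolves on any host.
#'
#' @param host a `pleio_host`.
#' @param parasite a `pleio_parasite`, or `NULL` for a non-disrupting
#'   parasite (detector, self and effector links intact, no target link) as
#'   used in robustness probes.
#' @param cfg a `sim_config`.
#' @return a `parasite_links` list of resolved node indices and coefficients.
#' @export
attach_parasite <- function(host, parasite, cfg = sim_config()) {
  cache <- host$cache
  sig_idx <- cache$idx_immune_signals
  if (length(sig_idx) < 1L)
    stop("host immune network has no signalling protein")
  if (is.null(parasite)) {
    target_idx <- NA_integer_
    target_coef <- 0
    n_links <- 2L
  } else {
    target_idx <- sig_idx[(parasite$target_index %% length(sig_idx)) + 1L]
    target_coef <- parasite$target_coefficient
    n_links <- 3L
  }
  structure(
    list(detector_idx = cache$idx_immune_detector,
         detector_coefficient = cfg$parasite_detector_coef,
         target_idx = target_idx,
         target_coefficient = target_coef,
         self_coefficient = if (is.null(parasite)) cfg$parasite_self_coef
                            else parasite$self_coefficient,
         effector_idx = cache$idx_immune_effector,
         effector_coefficient = cfg$effector_parasite_coef,
         n_links = n_links),
    class = "parasite_links")
}

#' Windows of a signalling schedule
#'
#' Life lasts 150 steps. Under `"development-first"` the developmental
#' signal occupies steps 1-50; under `"development-last"` it occupies steps
#' 101-150 (the reversed-order variant). Synchronous infection starts
#' uniformly at random inside the developmental window; asynchronous
#' infection starts uniformly inside the 50-step window immediately after it
#' (development-first) or inside the first 50 signal-free steps
#' (development-last).
#'
#' @param cfg a `sim_config`.
#' @return list with integer vectors `dev_window` and `infection_window`
#'   (life-step indices, 1-based).
#' @export
schedule_windows <- function(cfg) {
  w <- cfg$dev_window
  L <- cfg$life_steps
  if (cfg$signal_order == "development-first") {
    dev <- seq_len(w)
    inf <- if (cfg$synchrony == "synchronous") dev else (w + 1L):(2L * w)
  } else {
    dev <- (L - w + 1L):L
    inf <- if (cfg$synchrony == "synchronous") dev else seq_len(w)
  }
  list(dev_window = dev, infection_window = inf)
}

#' Simulate one host life
#'
#' Runs the five-step equilibration and then 150 life steps of the
#' resource-capped dynamics. During the developmental window the pulsed
#' signal acts as an external node with a fixed +1 link to the developmental
#' detector. If a parasite is supplied, its links attach from the infection
#' step onward with an inoculum abundance of 0.5, and the trajectory of its
#' abundance is recorded.
#'
#' @param host a `pleio_host`.
#' @param parasite a `pleio_parasite`, `NULL` for no infection, or the
#'   string `"non-disrupting"` for a targetless probe parasite.
#' @param cfg a `sim_config` (schedule, resource condition, constants).
#' @param generation generation index, used only to resolve the alternating
#'   resource condition.
#' @param infection_step life step (1-based) at which infection starts;
#'   `NULL` draws it uniformly from the schedule's infection window. Ignored
#'   when `parasite` is `NULL`.
#' @return a `life_record`: per-protein active-fraction series over the 150
#'   life steps (`states`, steps in rows, proteins in columns named by id),
#'   the equilibration trajectory (`equilibrium_states`), `parasite` series
#'   (NA before infection, NULL if uninfected), `signal` (the 50 signal
#'   values), window and timing bookkeeping, and the derived scalars
#'   `imm_eff_area`, `par_area`, `dev_cost` and `fitness`.
#' @export
simulate_life <- function(host, parasite = NULL, cfg = sim_config(),
                          generation = 0L, infection_step = NULL) {
  cache <- host$cache
  n <- length(cache$ids)
  win <- schedule_windows(cfg)
  limit <- resource_limit(cfg, generation)
  non_disrupting <- identical(parasite, "non-disrupting")
  if (non_disrupting) parasite <- NULL
  infected <- non_disrupting || !is.null(parasite)

  total_steps <- cfg$equilibrium_steps + cfg$life_steps
  dev_active <- logical(total_steps)
  dev_values <- numeric(total_steps)
  dev_steps_abs <- win$dev_window + cfg$equilibrium_steps
  dev_active[dev_steps_abs] <- TRUE
  signal <- developmental_signal(seq_len(cfg$dev_window), cfg$dev_window,
                                 cfg$dev_signal_variant)
  dev_values[dev_steps_abs] <- signal

  links <- NULL
  inf_abs <- 0L
  if (infected) {
    links <- attach_parasite(host, parasite, cfg)
    if (is.null(infection_step))
      infection_step <- if (length(win$infection_window) == 1L)
        win$infection_window else sample(win$infection_window, 1L)
    if (!infection_step %in% seq_len(cfg$life_steps))
      stop("infection_step outside the host life")
    inf_abs <- infection_step + cfg$equilibrium_steps
  }

  res <- run_life_cpp(
    cache$K, cache$I, as.integer(cache$out_deg),
    rep(cfg$initial_active, n), as.integer(total_steps), limit, cfg$use_coef,
    as.integer(cache$idx_dev_detector), dev_values, dev_active,
    as.integer(inf_abs), cfg$parasite_inoculum,
    if (infected) as.integer(links$detector_idx) else 1L,
    if (infected) links$detector_coefficient else 0,
    if (infected && !is.na(links$target_idx)) as.integer(links$target_idx)
      else 0L,
    if (infected && !is.na(links$target_idx)) links$target_coefficient else 0,
    if (infected) links$self_coefficient else 0,
    if (infected) as.integer(links$effector_idx) else 1L,
    if (infected) links$effector_coefficient else 0)

  eq <- cfg$equilibrium_steps
  life_rows <- (eq + 1L):total_steps
  states <- res$states[life_rows, , drop = FALSE]
  colnames(states) <- as.character(cache$ids)
  par_series <- if (infected) res$parasite[life_rows] else NULL

  rec <- structure(
    list(states = states,
         equilibrium_states = res$states[seq_len(eq), , drop = FALSE],
         parasite = par_series,
         signal = signal,
         dev_window = win$dev_window,
         infection_step = if (infected) infection_step else NA_integer_,
         idx_immune_effector = cache$idx_immune_effector,
         idx_dev_effector = cache$idx_dev_effector,
         architecture = host$architecture,
         resource_limit = limit),
    class = "life_record")
  rec$imm_eff_area <- immune_effector_area(rec)
  rec$par_area <- parasite_area(rec)
  rec$dev_cost <- developmental_cost(rec$signal,
                                     rec$states[rec$dev_window,
                                                rec$idx_dev_effector])
  rec$fitness <- host_fitness(rec)
  rec
}

#' Immune effector area
#'
#' Mean active fraction of the immune effector (the sole effector of a
#' shared-effector host) over the 150 life steps — the area under the
#' effector curve normalized to the host lifespan. Constitutive immunity is
#' a fitness cost.
#'
#' @param record a `life_record`.
#' @return a value in \eqn{[0, 1]}.
#' @export
immune_effector_area <- function(record) {
  mean(record$states[, record$idx_immune_effector])
}

#' Parasite area
#'
#' Mean parasite abundance from the infection step to the end of life — the
#' area under the parasite curve normalized to the infection's duration.
#' Zero for uninfected hosts. Doubles as parasite fitness, a proxy for
#' transmission potential.
#'
#' @param record a `life_record`.
#' @return a value in \eqn{[0, 1]}.
#' @export
parasite_area <- function(record) {
  if (is.null(record$parasite) || is.na(record$infection_step)) return(0)
  window <- record$infection_step:nrow(record$states)
  mean(record$parasite[window])
}

#' Developmental cost
#'
#' How badly the developmental effector tracked the input signal over the
#' 50-step developmental window:
#' \deqn{(1 - \mathrm{Corr}(\mathrm{sig}, \mathrm{out})) +
#'       \mathrm{mean}|\mathrm{sig} - \mathrm{out}|}
#' A perfectly tracking effector costs 0. When either series is constant the
#' Pearson correlation is undefined and is taken as 0: a flat output carries
#' no signal-tracking information.
#'
#' @param signal_series the input signal over the developmental window.
#' @param effector_series the developmental effector output, same length.
#' @return a non-negative cost.
#' @export
developmental_cost <- function(signal_series, effector_series) {
  if (length(signal_series) != length(effector_series))
    stop("signal and effector series differ in length")
  r <- if (var(signal_series) == 0 || var(effector_series) == 0) 0
       else cor(signal_series, effector_series)
  (1 - r) + mean(abs(signal_series - effector_series))
}

#' Host fitness
#'
#' \deqn{W = e^{-(\mathrm{Imm.Eff.Area} + \mathrm{Par.Area} +
#'   \mathrm{Dev.Cost})}}
#' Each cost is non-negative, so fitness lies in \eqn{(0, 1]}: a host that
#' mounts no constitutive immune response, clears no-parasite exposure and
#' tracks its developmental signal perfectly has fitness 1.
#'
#' @param record a `life_record`.
#' @return fitness in \eqn{(0, 1]}.
#' @export
host_fitness <- function(record) {
  exp(-(immune_effector_area(record) + parasite_area(record) +
          record$dev_cost))
}

#' Parasite fitness
#'
#' Identical to the parasite area of the infection: the normalized area
#' under the within-host abundance curve.
#'
#' @param record an infected `life_record`.
#' @return fitness in \eqn{[0, 1]}.
#' @export
parasite_fitness <- function(record) {
  if (is.null(record$parasite)) stop("record is uninfected")
  parasite_area(record)
}

#' @export
print.life_record <- function(x, ...) {
  cat(sprintf("<life_record> %s-effector host, %d life steps\n",
              x$architecture, nrow(x$states)))
  cat(sprintf("  infection step: %s\n",
              ifelse(is.na(x$infection_step), "uninfected",
                     x$infection_step)))
  cat(sprintf("  Imm.Eff.Area %.4f | Par.Area %.4f | Dev.Cost %.4f | W %.4f\n",
              x$imm_eff_area, x$par_area, x$dev_cost, x$fitness))
  invisible(x)
}

#' Export a life record as tidy data
#'
#' @param record a `life_record`.
#' @return a long data.frame (step, node, active) covering every protein,
#'   the parasite (when present) and the developmental signal.
#' @export
life_record_table <- function(record) {
  n_steps <- nrow(record$states)
  ids <- colnames(record$states)
  out <- data.frame(
    step = rep(seq_len(n_steps), times = length(ids)),
    node = rep(paste0("protein_", ids), each = n_steps),
    active = as.vector(record$states))
  if (!is.null(record$parasite))
    out <- rbind(out, data.frame(step = seq_len(n_steps), node = "parasite",
                                 active = record$parasite))
  out <- rbind(out, data.frame(step = record$dev_window, node = "dev_signal",
                               active = record$signal))
  out
}
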