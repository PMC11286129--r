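#' Single-knockout robustness of a host's immune response
#'
#' Measures how strongly the evolved immune response relies on individual
#' signalling proteins. The host is infected with a non-disrupting parasite
#' (detector, self-replication and effector links intact, but no target
#' link, so it cannot interfere with host signalling) and lives a full
#' life; each signalling protein is then removed in turn (with all its
#' edges) and the life re-run with identical infection timing. A knockout's
#' score is the mean absolute difference in immune effector activity
#' between the intact and knockout trajectories over the 150 life steps;
#' higher scores mean the network leans harder on that protein, i.e. is
#' less robust. Infection timing is fixed at the midpoint of the schedule's
#' infection window so intact/knockout differences reflect structure, not
#' timing noise.
#'
#' @param host a `pleio_host` with at least one signalling protein.
#' @param cfg a `sim_config` (schedule and resource condition).
#' @param generation generation index for the alternating resource
#'   condition.
#' @return a `robustness_result`: `per_knockout` (named by knocked-out
#'   protein id) and `summary` (their mean).
#' @export
knockout_robustness <- function(host, cfg = sim_config(), generation = 0L) {
  sig_ids <- host$proteins$id[host$proteins$role == "signal"]
  if (length(sig_ids) == 0L) stop("host has no signalling protein to knock out")
  win <- schedule_windows(cfg)
  mid <- win$infection_window[ceiling(length(win$infection_window) / 2)]
  intact <- simulate_life(host, "non-disrupting", cfg, generation,
                          infection_step = mid)
  eff_intact <- intact$states[, intact$idx_immune_effector]
  scores <- vapply(sig_ids, function(id) {
    ko <- host
    ko$proteins <- ko$proteins[ko$proteins$id != id, ]
    ko$edges <- ko$edges[ko$edges$source != id & ko$edges$target != id, ,
                         drop = FALSE]
    ko <- refresh_cache(ko)
    rec <- simulate_life(ko, "non-disrupting", cfg, generation,
                         infection_step = mid)
    mean(abs(eff_intact - rec$states[, rec$idx_immune_effector]))
  }, numeric(1))
  structure(list(per_knockout = setNames(scores, sig_ids),
                 summary = mean(scores)),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result> mean knockout effect %.5f over %d knockouts\n",
              x$summary, length(x$per_knockout)))
  print(round(x$per_knockout, 5))
  invisible(x)
}

#' Most common genotype in a population
#'
#' The modal host under structural equality: identical architecture,
#' protein roster and edge list (coefficients at full precision). Ties are
#' broken by first occurrence.
#'
#' @param hosts a non-empty list of `pleio_host`s.
#' @return the modal `pleio_host`.
#' @export
most_common_genotype <- function(hosts) {
  if (length(hosts) == 0L) stop("empty population")
  keys <- vapply(hosts, canonical_genotype_string, character(1))
  counts <- table(keys)
  winners <- names(counts)[counts == max(counts)]
  first <- min(match(winners, keys))
  hosts[[first]]
}

#' Structural features of an evolved host network
#'
#' \describe{
#'   \item{connectivity}{realized within-network edges divided by the number
#'     of possible within-network connections under the model's edge rules
#'     (same-network ordered pairs, detector-effector pairs excluded,
#'     self-loops on signalling proteins only; see [valid_init_pairs()]).
#'     A shared effector belongs to both networks, so its edges are
#'     within-network.}
#'   \item{size}{protein count; reported size of independent-effector hosts
#'     is reduced by one to offset their 10-versus-9 starting advantage.}
#'   \item{upstream_pleiotropy}{whether any regulatory edge joins an
#'     immune-network protein to a developmental-network protein, excluding
#'     edges incident to a shared effector (those constitute downstream
#'     pleiotropy).}
#'   \item{effector_in_degree}{number of edges into the immune (or shared)
#'     effector.}
#' }
#'
#' @param host a `pleio_host`.
#' @return a one-row data.frame with the four features.
#' @export
network_features <- function(host) {
  p <- host$proteins
  e <- host$edges
  nets <- lapply(setNames(p$network, p$id), protein_networks)
  within <- if (nrow(e)) mapply(function(s, t) {
    length(intersect(nets[[as.character(s)]], nets[[as.character(t)]])) > 0L
  }, e$source, e$target) else logical(0)
  possible <- nrow(valid_init_pairs(p))
  cross <- if (nrow(e)) mapply(function(s, t) {
    ns <- p$network[match(s, p$id)]
    nt <- p$network[match(t, p$id)]
    (ns == "immune" && nt == "developmental") ||
      (ns == "developmental" && nt == "immune")
  }, e$source, e$target) else logical(0)
  eff_id <- p$id[p$role == "effector" & p$network %in% c("immune", "shared")]
  data.frame(
    connectivity = sum(within) / possible,
    size = nrow(p) - (host$architecture == "independent"),
    upstream_pleiotropy = any(cross),
    effector_in_degree = sum(e$target == eff_id))
}

#' Quasi-binomial regression of competition outcomes
#'
#' Models the final proportion of shared-effector hosts in competitive
#' simulations as a logit-link binomial regression on signalling synchrony,
#' resource availability and the length of the burn-in period, with the
#' dispersion parameter estimated from the Pearson residuals
#' (quasi-binomial) and standard errors scaled by its square root.
#' Synchrony is coded with asynchronous as the reference, resources with
#' scarce as the reference, and burn-in enters as a numeric covariate in
#' units of 250 generations.
#'
#' @param data a data.frame with columns `final_shared_fraction` (in
#'   \eqn{[0, 1]}), `synchrony`, `resource` and `burn_in`, as produced by
#'   [run_campaign()].
#' @return a `competition_glm`: `coefficients` table (estimate,
#'   dispersion-adjusted standard error, t value, p value, odds ratio),
#'   `dispersion`, and the underlying `glm` fit.
#' @export
fit_quasibinomial <- function(data) {
  required <- c("final_shared_fraction", "synchrony", "resource", "burn_in")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  y <- data$final_shared_fraction
  if (any(y < 0 | y > 1)) stop("final_shared_fraction must lie in [0, 1]")
  df <- data.frame(
    y = y,
    synchrony = factor(data$synchrony,
                       levels = c("asynchronous", "synchronous")),
    resource = factor(data$resource,
                      levels = c("scarce", "alternating", "plentiful")),
    burn_in_250 = data$burn_in / 250)
  df$synchrony <- droplevels(df$synchrony)
  df$resource <- droplevels(df$resource)
  terms_rhs <- c(
    if (nlevels(df$synchrony) > 1L) "synchrony",
    if (nlevels(df$resource) > 1L) "resource",
    if (length(unique(df$burn_in_250)) > 1L) "burn_in_250")
  if (is.null(terms_rhs)) terms_rhs <- "1"
  fml <- stats::as.formula(paste("y ~", paste(terms_rhs, collapse = " + ")))
  fit <- glm(fml, family = quasibinomial(link = "logit"), data = df)
  if (!fit$converged) warning("quasi-binomial fit did not converge ",
                              "(separated or degenerate design?)")
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1],
                    std_error = co[, 2], t_value = co[, 3],
                    p_value = co[, 4], odds_ratio = exp(co[, 1]),
                    row.names = NULL)
  structure(list(coefficients = out, dispersion = sm$dispersion, fit = fit),
            class = "competition_glm")
}

#' @export
print.competition_glm <- function(x, ...) {
  cat(sprintf("<competition_glm> quasi-binomial, dispersion %.4f\n",
              x$dispersion))
  co <- x$coefficients
  co[, -1] <- round(co[, -1], 4)
  print(co)
  invisible(x)
}

#' Geometric mean fitness
#'
#' \eqn{\exp(\mathrm{mean}(\log w))}: the fitness measure under which
#' between-generation variance is penalized, used to compare populations
#' whose arithmetic means overstate their long-run growth.
#'
#' @param fitness_series positive fitness values.
#' @return the geometric mean.
#' @examples
#' geometric_mean_fitness(c(0.25, 1.0))  # 0.5
#' @export
geometric_mean_fitness <- function(fitness_series) {
  if (any(fitness_series <= 0)) stop("fitness values must be positive")
  exp(mean(log(fitness_series)))
}
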