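#' Network state constructor
#'
#' Every protein carries unit total concentration split into an active
#' fraction \eqn{P^*} and an implicit inactive fraction \eqn{1 - P^*}; only
#' the active fraction regulates targets. A state optionally carries the
#' abundance of an infecting parasite, which the dynamics treat as one more
#' node of the immune network.
#'
#' @param host a `pleio_host`.
#' @param active initial active fraction for every protein (default 0.5), or
#'   a full vector in protein-id order.
#' @param parasite parasite abundance in \eqn{[0, 1]}, or `NULL` when
#'   uninfected.
#' @return a `network_state`: list with `active` (named by protein id) and
#'   `parasite`.
#' @export
network_state <- function(host, active = 0.5, parasite = NULL) {
  ids <- host$cache$ids
  if (length(active) == 1L) active <- rep(active, length(ids))
  stopifnot(length(active) == length(ids), all(active >= 0 & active <= 1))
  structure(list(active = setNames(as.numeric(active), ids),
                 parasite = parasite),
            class = "network_state")
}

#' Raw regulatory deltas for one time-step
#'
#' For each protein \eqn{i} the change in active fraction is the balance of
#' activation by its upregulators, inactivation by its downregulators, and a
#' use cost proportional to its number of outgoing interactions:
#' \deqn{\Delta_i = (1 - P_i^*)\sum_j k_{i,j} P_j^* -
#'       P_i^* \sum_j I_{i,j} P_j^* - \mathrm{UseCoef}\cdot N_i}
#' where \eqn{k_{i,j}} are positive (upregulatory) coefficients of edges
#' \eqn{j \to i}, \eqn{I_{i,j}} the magnitudes of negative ones, and
#' \eqn{N_i} the number of edges leaving \eqn{i}. An infecting parasite is
#' treated as an additional node with its three fixed links and is subject
#' to the same rules, including the use cost on its own outgoing links; the
#' host effector's downregulatory link onto the parasite counts toward the
#' effector's outgoing interactions while infection lasts.
#'
#' @param state a `network_state` covering all host proteins.
#' @param host a `pleio_host`.
#' @param parasite_links links from [attach_parasite()], or `NULL`.
#' @param use_coef per-interaction inactivation cost (default 0.01).
#' @param dev_input value of the external developmental signal acting on the
#'   developmental detector through a fixed +1 link, or `NULL` when outside
#'   the developmental window.
#' @return list with `active` (named deltas) and `parasite` (delta or NULL).
#' @export
regulatory_deltas <- function(state, host, parasite_links = NULL,
                              use_coef = 0.01, dev_input = NULL) {
  cache <- host$cache
  p <- state$active
  if (length(p) != length(cache$ids) ||
      !all(names(p) == as.character(cache$ids)))
    stop("state does not cover the host's proteins")
  up <- as.numeric(cache$K %*% p)
  down <- as.numeric(cache$I %*% p)
  out_deg <- as.numeric(cache$out_deg)
  if (!is.null(dev_input)) {
    di <- cache$idx_dev_detector
    up[di] <- up[di] + dev_input   # fixed +1 link from the signal node
  }
  par_delta <- NULL
  if (!is.null(parasite_links)) {
    v <- state$parasite
    if (is.null(v)) stop("parasite links supplied but state is uninfected")
    up[parasite_links$detector_idx] <-
      up[parasite_links$detector_idx] + parasite_links$detector_coefficient * v
    ti <- parasite_links$target_idx
    if (!is.na(ti)) {
      cf <- parasite_links$target_coefficient
      if (cf >= 0) up[ti] <- up[ti] + cf * v
      else down[ti] <- down[ti] - cf * v
    }
    out_deg[parasite_links$effector_idx] <-
      out_deg[parasite_links$effector_idx] + 1
    eff_act <- p[parasite_links$effector_idx]
    par_delta <- (1 - v) * parasite_links$self_coefficient * v -
      v * abs(parasite_links$effector_coefficient) * eff_act -
      use_coef * parasite_links$n_links
  }
  deltas <- (1 - p) * up - p * down - use_coef * out_deg
  list(active = setNames(deltas, names(p)), parasite = unname(par_delta))
}

#' Apply the resource cap to a set of deltas
#'
#' Resource availability limits the creation of new active protein per
#' time-step. When the sum of positive deltas exceeds the limit, every
#' positive delta is scaled by `limit / sum`, so the total activation equals
#' the limit exactly; negative deltas are untouched. The parasite's
#' replication competes for the same activation budget.
#'
#' @param deltas output of [regulatory_deltas()], or a bare numeric vector.
#' @param limit positive activation budget (0.1 scarce, 1.0 plentiful).
#' @return deltas of the same shape, capped.
#' @export
apply_resource_cap <- function(deltas, limit) {
  stopifnot(limit > 0)
  bare <- is.numeric(deltas)
  d <- if (bare) deltas else c(deltas$active, deltas$parasite)
  pos <- d > 0
  s <- sum(d[pos])
  if (s > limit) d[pos] <- d[pos] * (limit / s)
  if (bare) return(d)
  n <- length(deltas$active)
  out <- list(active = setNames(d[seq_len(n)], names(deltas$active)),
              parasite = if (is.null(deltas$parasite)) NULL else d[n + 1L])
  out
}

#' Advance a network state by one time-step
#'
#' Forward-Euler update with unit time-step: capped deltas are added to the
#' current state and the result is clamped to \eqn{[0, 1]}, protein and
#' parasite alike.
#'
#' @inheritParams regulatory_deltas
#' @param limit resource cap on total activation for the step.
#' @return the next `network_state`.
#' @export
step_state <- function(state, host, parasite_links = NULL, limit = 0.1,
                       use_coef = 0.01, dev_input = NULL) {
  d <- regulatory_deltas(state, host, parasite_links, use_coef, dev_input)
  d <- apply_resource_cap(d, limit)
  state$active <- pmin(1, pmax(0, state$active + d$active))
  if (!is.null(d$parasite))
    state$parasite <- min(1, max(0, state$parasite + d$parasite))
  state
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state>\n")
  print(round(x$active, 4))
  if (!is.null(x$parasite))
    cat(sprintf("parasite abundance: %.4f\n", x$parasite))
  invisible(x)
}
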