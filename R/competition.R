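#' Isolated burn-in evolution for one architecture
#'
#' The first phase of a competitive simulation: a population of hosts of a
#' single architecture (default 250) coevolves with its own parasites
#' (default 125, prevalence 50\%) in isolation for the configured number of
#' burn-in generations.
#'
#' @param architecture `"shared"` or `"independent"`.
#' @param cfg a `sim_config` (`burn_in_host_pop`, `burn_in_parasite_pop`,
#'   `burn_in_generations`).
#' @param seed optional integer seed.
#' @return a `population_history` (the burn-in endpoint populations).
#' @export
run_burn_in <- function(architecture, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hosts <- replicate(cfg$burn_in_host_pop, init_host(architecture),
                     simplify = FALSE)
  parasites <- replicate(cfg$burn_in_parasite_pop, init_parasite(cfg),
                         simplify = FALSE)
  run_coevolution(cfg, seed = NULL, hosts = hosts, parasites = parasites,
                  generations = cfg$burn_in_generations)
}

#' Competition between two burned-in host populations
#'
#' Merges the shared- and independent-effector populations along with their
#' parasite populations into one pool. Hosts of either architecture compete
#' in a single fitness-weighted reproduction market (offspring inherit the
#' parent's architecture); the first reproduction doubles the merged host
#' population and that size is maintained thereafter. The merged parasites
#' infect hosts of either architecture uniformly, so prevalence halves
#' relative to burn-in. The competition ends when one architecture goes
#' extinct or after `cfg$competition_generations` with both extant (a draw).
#'
#' @param shared_state,independent_state `population_history` objects (or
#'   lists with `hosts` and `parasites`) from [run_burn_in()].
#' @param cfg a `sim_config`.
#' @param seed optional integer seed.
#' @return a `competition_result`: `winner` (`"shared"`, `"independent"` or
#'   `"draw"`), `generations` to resolution, and `composition` (fraction of
#'   shared-effector hosts at the start of each generation, beginning at
#'   0.5, plus the final state).
#' @export
run_competition <- function(shared_state, independent_state,
                            cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hosts <- c(shared_state$hosts, independent_state$hosts)
  parasites <- c(shared_state$parasites, independent_state$parasites)
  host_target <- 2L * length(hosts)
  parasite_target <- length(parasites)
  frac_shared <- function(hs)
    mean(vapply(hs, function(h) h$architecture == "shared", logical(1)))
  composition <- frac_shared(hosts)
  winner <- "draw"
  gens <- cfg$competition_generations
  for (g in seq_len(cfg$competition_generations)) {
    gen <- simulate_generation(hosts, parasites, cfg, g - 1L,
                               host_target = host_target,
                               parasite_target = parasite_target)
    hosts <- gen$hosts
    parasites <- gen$parasites
    f <- frac_shared(hosts)
    composition <- c(composition, f)
    if (f == 0 || f == 1) {
      winner <- if (f == 1) "shared" else "independent"
      gens <- g
      break
    }
  }
  structure(list(winner = winner, generations = gens,
                 composition = composition,
                 final_shared_fraction = composition[length(composition)],
                 burn_in_generations = cfg$burn_in_generations,
                 synchrony = cfg$synchrony, resource = cfg$resource,
                 hosts = hosts, parasites = parasites),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf(
    "<competition_result> winner: %s after %d generations (%s, %s, burn-in %d)\n",
    x$winner, x$generations, x$synchrony, x$resource,
    x$burn_in_generations))
  cat(sprintf("  final shared-effector fraction: %.3f\n",
              x$final_shared_fraction))
  invisible(x)
}

#' One full competitive simulation (burn-ins plus competition)
#'
#' Convenience wrapper: burns in a shared-effector and an
#' independent-effector population under the same conditions, then runs the
#' competition.
#'
#' @param cfg a `sim_config`.
#' @param seed optional integer seed for the whole replicate.
#' @return a `competition_result`.
#' @export
run_competitive_simulation <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shared <- run_burn_in("shared", cfg)
  indep <- run_burn_in("independent", cfg)
  run_competition(shared, indep, cfg)
}

#' Campaign of competitive simulations over a condition grid
#'
#' Runs seeded replicates of [run_competitive_simulation()] for every cell
#' of a condition grid (synchrony x resource condition x burn-in length)
#' and returns a tidy results table for regression.
#'
#' @param cfg base `sim_config`; each cell overrides `synchrony`,
#'   `resource` and `burn_in_generations`.
#' @param synchrony,resources,burn_ins condition levels defining the grid.
#' @param replicates replicates per cell.
#' @param seed master seed; per-row seeds are derived deterministically from
#'   it and recorded, so any row can be reproduced in isolation.
#' @return data.frame with one row per replicate: condition labels,
#'   `replicate`, `seed`, `winner`, `generations`, `final_shared_fraction`.
#' @export
run_campaign <- function(cfg = sim_config(),
                         synchrony = c("synchronous", "asynchronous"),
                         resources = c("scarce", "alternating", "plentiful"),
                         burn_ins = c(250L, 500L, 1000L),
                         replicates = 1L, seed = 1L) {
  grid <- expand.grid(synchrony = synchrony, resource = resources,
                      burn_in = burn_ins, replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L)
    return(data.frame(synchrony = character(), resource = character(),
                      burn_in = integer(), replicate = integer(),
                      seed = integer(), winner = character(),
                      generations = integer(),
                      final_shared_fraction = numeric()))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    row_seed <- as.integer((as.numeric(seed) * 10007 + k) %% 2147483647)
    row_cfg <- validate_config(utils::modifyList(unclass(cfg), list(
      synchrony = grid$synchrony[k], resource = grid$resource[k],
      burn_in_generations = as.integer(grid$burn_in[k]))))
    res <- run_competitive_simulation(row_cfg, seed = row_seed)
    rows[[k]] <- data.frame(
      synchrony = grid$synchrony[k], resource = grid$resource[k],
      burn_in = as.integer(grid$burn_in[k]), replicate = grid$replicate[k],
      seed = row_seed, winner = res$winner, generations = res$generations,
      final_shared_fraction = res$final_shared_fraction)
  }
  do.call(rbind, rows)
}
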