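# sample() that never deparses a length-1 x into 1:x
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Assign parasites to hosts
#'
#' Each parasite infects a single, distinct host chosen uniformly at random
#' without replacement; the remaining hosts are uninfected. With the default
#' population sizes (500 hosts, 250 parasites) the infection prevalence is
#' exactly 50\%.
#'
#' @param n_hosts number of hosts.
#' @param n_parasites number of parasites; must not exceed `n_hosts`.
#' @return integer vector of length `n_parasites`: the host index each
#'   parasite infects.
#' @export
assign_infections <- function(n_hosts, n_parasites) {
  if (n_parasites > n_hosts)
    stop("more parasites than hosts: prevalence cannot exceed 1")
  if (n_parasites == 0L) return(integer(0))
  sample.int(n_hosts, n_parasites, replace = FALSE)
}

#' Number of offspring for a parasite
#'
#' Transmission success scales with within-host abundance: one offspring for
#' abundances up to 1/3, two up to 2/3, three above (a partition of the unit
#' interval at thirds).
#'
#' @param abundance final within-host abundance(s) in \eqn{[0, 1]}.
#' @return integer offspring counts.
#' @examples
#' parasite_offspring_count(c(0.2, 0.5, 0.7))  # 1 2 3
#' @export
parasite_offspring_count <- function(abundance) {
  if (any(abundance < 0 | abundance > 1))
    stop("abundance must lie in [0, 1]")
  ifelse(abundance <= 1 / 3, 1L, ifelse(abundance <= 2 / 3, 2L, 3L))
}

#' Select hosts to die this generation
#'
#' Up to 30\% of the host population dies per generation. Hosts that failed
#' to control their infection (parasite area above the death threshold of
#' 0.9) die first; if they exceed the cap, a uniform random subset of
#' exactly the cap dies and the excess returns to the population. If they
#' fall short, the remaining deaths come from a single randomized pass over
#' the survivors, each dying with probability \eqn{1 - W_i/W_{max}}
#' (relative to the fittest survivor, which therefore always survives its
#' visit), until the cap is reached or every survivor has been visited once.
#'
#' @param fitness numeric vector of host fitness values.
#' @param par_area numeric vector of host parasite areas.
#' @param cfg a `sim_config` (`death_cap`, `death_threshold`).
#' @return integer indices of hosts that die.
#' @export
select_host_deaths <- function(fitness, par_area, cfg = sim_config()) {
  n <- length(fitness)
  cap <- floor(cfg$death_cap * n)
  marked <- which(par_area > cfg$death_threshold)
  if (length(marked) >= cap) return(sort(resample(marked, cap)))
  dead <- marked
  alive <- setdiff(seq_len(n), marked)
  if (length(alive) && length(dead) < cap) {
    w_max <- max(fitness[alive])
    p_die <- if (w_max > 0) 1 - fitness[alive] / w_max else rep(0, length(alive))
    visit <- resample(alive, length(alive))
    draws <- runif(length(visit))
    for (k in seq_along(visit)) {
      if (length(dead) >= cap) break
      if (draws[k] < p_die[match(visit[k], alive)]) dead <- c(dead, visit[k])
    }
  }
  sort(dead)
}

#' Select parasites to die this generation
#'
#' Strictly fitness-based: the least fit 30\% (floor) of the parasite
#' population dies, ties broken by stable input order.
#'
#' @param fitness parasite fitness values (their within-host areas).
#' @param cfg a `sim_config`.
#' @return integer indices of parasites that die.
#' @export
select_parasite_deaths <- function(fitness, cfg = sim_config()) {
  n_die <- floor(cfg$death_cap * length(fitness))
  if (n_die == 0L) return(integer(0))
  order(fitness)[seq_len(n_die)]
}

#' Mutate a host genotype
#'
#' Applies exactly one mutation event, drawn by the configured weights:
#' add a regulatory interaction between two random proteins (cross-network
#' allowed, detector-effector forbidden, self-loops only on signalling
#' proteins; 0.25), delete a random interaction (0.25), redraw one
#' coefficient uniformly on \eqn{[-1, 1]} (0.30), delete a signalling
#' protein with its edges (0.10; skipped if its network would lose its last
#' signalling protein), or duplicate a signalling protein with all incoming
#' and outgoing edges (0.10; a self-loop duplicates onto the copy).
#' Detectors and effectors are never deleted or duplicated. Infeasible
#' events (e.g. deleting an edge from an edgeless genotype, or adding an
#' edge that already exists) leave the genotype unchanged.
#'
#' @param host a `pleio_host`.
#' @param cfg a `sim_config`.
#' @return the (possibly) mutated `pleio_host`.
#' @export
mutate_host <- function(host, cfg = sim_config()) {
  w <- cfg$host_mutation_weights
  event <- resample(names(w), 1L, prob = w)
  p <- host$proteins
  e <- host$edges
  changed <- FALSE
  if (event == "add_edge") {
    src <- resample(p$id, 1L)
    tgt <- resample(p$id, 1L)
    if (legal_edge(host, src, tgt) &&
        !any(e$source == src & e$target == tgt)) {
      host$edges <- rbind(e, data.frame(source = src, target = tgt,
                                        coefficient = runif(1, -1, 1)))
      changed <- TRUE
    }
  } else if (event == "delete_edge") {
    if (nrow(e)) {
      host$edges <- e[-sample.int(nrow(e), 1L), , drop = FALSE]
      changed <- TRUE
    }
  } else if (event == "alter_coefficient") {
    if (nrow(e)) {
      host$edges$coefficient[sample.int(nrow(e), 1L)] <- runif(1, -1, 1)
      changed <- TRUE
    }
  } else if (event == "delete_protein") {
    sig <- p[p$role == "signal", ]
    if (nrow(sig)) {
      victim <- sig[sample.int(nrow(sig), 1L), ]
      if (sum(p$role == "signal" & p$network == victim$network) > 1L) {
        host$proteins <- p[p$id != victim$id, ]
        host$edges <- e[e$source != victim$id & e$target != victim$id, ,
                        drop = FALSE]
        changed <- TRUE
      }
    }
  } else if (event == "duplicate_protein") {
    sig <- p[p$role == "signal", ]
    if (nrow(sig)) {
      orig <- sig[sample.int(nrow(sig), 1L), ]
      new_id <- max(p$id) + 1L
      host$proteins <- rbind(p, data.frame(id = new_id, role = orig$role,
                                           network = orig$network))
      out_e <- e[e$source == orig$id, , drop = FALSE]
      if (nrow(out_e)) {
        out_e$source <- new_id
        out_e$target[out_e$target == orig$id] <- new_id
      }
      in_e <- e[e$target == orig$id & e$source != orig$id, , drop = FALSE]
      if (nrow(in_e)) in_e$target <- new_id
      host$edges <- rbind(e, out_e, in_e)
      changed <- TRUE
    }
  }
  if (changed) host <- refresh_cache(host)
  host
}

#' Mutate a parasite genotype
#'
#' One event: redraw the target index uniformly over the fixed index domain
#' (0.5) or redraw the target coefficient uniformly on \eqn{[-1, 1]} (0.5).
#'
#' @param parasite a `pleio_parasite`.
#' @param cfg a `sim_config`.
#' @return the mutated `pleio_parasite`.
#' @export
mutate_parasite <- function(parasite, cfg = sim_config()) {
  w <- cfg$parasite_mutation_weights
  event <- resample(names(w), 1L, prob = w)
  if (event == "retarget")
    parasite$target_index <- sample.int(cfg$parasite_target_domain, 1L) - 1L
  else
    parasite$target_coefficient <- runif(1, -1, 1)
  parasite
}

#' Fitness-weighted host reproduction
#'
#' Survivors persist; offspring parents are drawn with replacement with
#' probability proportional to fitness until the population regains its
#' target size. Each offspring is a direct copy of its parent or, rarely
#' (rate 5e-3), a copy carrying exactly one mutation event.
#'
#' @param hosts list of surviving `pleio_host`s.
#' @param fitness their fitness values.
#' @param target_size population size to restore.
#' @param cfg a `sim_config`.
#' @return list with `hosts` (length `target_size`; survivors first) and
#'   `parent_index` of each offspring.
#' @export
reproduce_hosts <- function(hosts, fitness, target_size, cfg = sim_config()) {
  if (length(hosts) == 0L) stop("host population went extinct")
  n_off <- target_size - length(hosts)
  if (n_off <= 0L)
    return(list(hosts = hosts[seq_len(target_size)], parent_index = integer(0)))
  prob <- if (sum(fitness) > 0) fitness else rep(1, length(fitness))
  parents <- sample.int(length(hosts), n_off, replace = TRUE, prob = prob)
  offspring <- hosts[parents]
  mutate <- runif(n_off) < cfg$host_mutation_rate
  for (k in which(mutate)) offspring[[k]] <- mutate_host(offspring[[k]], cfg)
  list(hosts = c(hosts, offspring), parent_index = parents)
}

#' Rank-ordered parasite reproduction
#'
#' Survivors persist and reproduce in order of fitness, from most to least
#' fit, each contributing as many offspring as its within-host abundance
#' earns ([parasite_offspring_count()]), cycling through the ranking until
#' the population is replenished (the final batch is truncated). Offspring
#' mutate with probability 1e-2.
#'
#' @param parasites list of surviving `pleio_parasite`s.
#' @param fitness their fitness values (within-host areas, also their
#'   abundances for the offspring rule).
#' @param target_size population size to restore.
#' @param cfg a `sim_config`.
#' @return list of `pleio_parasite`s of length `target_size`.
#' @export
reproduce_parasites <- function(parasites, fitness, target_size,
                                cfg = sim_config()) {
  if (length(parasites) == 0L) stop("parasite population went extinct")
  deficit <- target_size - length(parasites)
  if (deficit <= 0L) return(parasites[seq_len(target_size)])
  ranked <- order(-fitness)
  counts <- parasite_offspring_count(pmin(1, pmax(0, fitness)))
  one_pass <- rep(ranked, times = counts[ranked])
  parents <- rep(one_pass, length.out = deficit)
  offspring <- parasites[parents]
  mutate <- runif(deficit) < cfg$parasite_mutation_rate
  for (k in which(mutate))
    offspring[[k]] <- mutate_parasite(offspring[[k]], cfg)
  c(parasites, offspring)
}

# One full generation: infection assignment, life simulation, fitness,
# death, reproduction. Shared by independent coevolution and competition.
# Returns the next populations plus the generation's summary statistics.
simulate_generation <- function(hosts, parasites, cfg, generation,
                                host_target = length(hosts),
                                parasite_target = length(parasites)) {
  n_h <- length(hosts)
  n_p <- length(parasites)
  infected_host <- assign_infections(n_h, n_p)
  host_parasite <- rep(NA_integer_, n_h)
  host_parasite[infected_host] <- seq_len(n_p)

  fitness <- numeric(n_h)
  par_area <- numeric(n_h)
  for (i in seq_len(n_h)) {
    pr <- if (is.na(host_parasite[i])) NULL else parasites[[host_parasite[i]]]
    rec <- simulate_life(hosts[[i]], pr, cfg, generation)
    fitness[i] <- rec$fitness
    par_area[i] <- rec$par_area
  }
  parasite_fit <- par_area[infected_host]

  dead_h <- select_host_deaths(fitness, par_area, cfg)
  infection_deaths <- sum(par_area[dead_h] > cfg$death_threshold)
  surv_h <- setdiff(seq_len(n_h), dead_h)
  dead_p <- select_parasite_deaths(parasite_fit, cfg)
  surv_p <- setdiff(seq_len(n_p), dead_p)

  rep_h <- reproduce_hosts(hosts[surv_h], fitness[surv_h], host_target, cfg)
  next_parasites <- reproduce_parasites(parasites[surv_p],
                                        parasite_fit[surv_p],
                                        parasite_target, cfg)
  list(hosts = rep_h$hosts, parasites = next_parasites,
       stats = data.frame(
         generation = generation,
         mean_host_fitness = mean(fitness),
         var_host_fitness = var(fitness),
         mean_parasite_fitness = mean(parasite_fit),
         host_deaths = length(dead_h),
         infection_deaths = infection_deaths,
         parasite_deaths = length(dead_p),
         prevalence = n_p / n_h))
}

#' Run an independent coevolution simulation
#'
#' A founder population of hosts (default 500) coevolves with a founder
#' population of parasites (default 250) for the configured number of
#' generations. Each generation: parasites are assigned to hosts (50\%
#' prevalence), every host lives its 150-step life, fitness is computed,
#' up to 30\% of each population dies (infection-driven first for hosts,
#' strictly fitness-ranked for parasites), and fitness-weighted
#' reproduction with rare mutation restores both populations exactly.
#'
#' @param cfg a `sim_config`.
#' @param seed optional integer seed; defaults to `cfg$seed`.
#' @param hosts,parasites optional founder populations (lists); generated
#'   from `cfg` when `NULL`.
#' @param generations optional override of `cfg$generations`.
#' @return a `population_history`: `summary` (one row per generation),
#'   `hosts` and `parasites` (final populations), `snapshots` (periodic
#'   genotype copies when `cfg$snapshot_every > 0`), and `config`.
#' @export
run_coevolution <- function(cfg = sim_config(), seed = NULL, hosts = NULL,
                            parasites = NULL, generations = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  if (is.null(generations)) generations <- cfg$generations
  if (is.null(hosts))
    hosts <- replicate(cfg$host_pop, init_host(cfg$architecture),
                       simplify = FALSE)
  if (is.null(parasites))
    parasites <- replicate(cfg$parasite_pop, init_parasite(cfg),
                           simplify = FALSE)
  rows <- vector("list", generations)
  snapshots <- list()
  for (g in seq_len(generations)) {
    gen <- simulate_generation(hosts, parasites, cfg, g - 1L,
                               host_target = length(hosts),
                               parasite_target = length(parasites))
    hosts <- gen$hosts
    parasites <- gen$parasites
    rows[[g]] <- gen$stats
    if (cfg$snapshot_every > 0L && g %% cfg$snapshot_every == 0L)
      snapshots[[as.character(g)]] <- hosts
  }
  structure(list(summary = do.call(rbind, rows), hosts = hosts,
                 parasites = parasites, snapshots = snapshots, config = cfg,
                 seed = seed),
            class = "population_history")
}

#' @export
print.population_history <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("<population_history> %d generations, %d hosts / %d parasites\n",
              n, length(x$hosts), length(x$parasites)))
  if (n) {
    last <- x$summary[n, ]
    cat(sprintf("  final mean host fitness %.4f (var %.4g), parasite %.4f\n",
                last$mean_host_fitness, last$var_host_fitness,
                last$mean_parasite_fitness))
  }
  invisible(x)
}
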