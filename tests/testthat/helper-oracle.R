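# Independent scalar re-implementation of the activation dynamics: plain
# loops over the edge list, no matrices, no shared code with the package's
# vectorized/compiled path. Used as the oracle in equivalence tests.

# Build a bare-bones host object (bypasses roster invariants deliberately,
# so toy networks of any shape can be tested).
toy_host <- function(proteins, edges = NULL, architecture = "independent") {
  if (is.null(edges))
    edges <- data.frame(source = integer(), target = integer(),
                        coefficient = numeric())
  pleionet:::new_host(architecture, proteins, edges)
}

# deltas for one step; active is named by protein id (character names)
oracle_deltas <- function(proteins, edges, active, use_coef = 0.01,
                          dev = NULL, par = NULL) {
  ids <- proteins$id
  deltas <- numeric(length(ids))
  for (k in seq_along(ids)) {
    i <- ids[k]
    up <- 0
    down <- 0
    out_count <- 0
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        cf <- edges$coefficient[r]
        if (edges$target[r] == i) {
          src_act <- active[[as.character(edges$source[r])]]
          if (cf >= 0) up <- up + cf * src_act
          else down <- down + abs(cf) * src_act
        }
        if (edges$source[r] == i) out_count <- out_count + 1
      }
    }
    if (!is.null(dev) && i == dev$target_id) up <- up + 1 * dev$value
    if (!is.null(par)) {
      if (i == par$detector_id) up <- up + par$detector_coef * par$V
      if (!is.na(par$target_id) && i == par$target_id) {
        if (par$target_coef >= 0) up <- up + par$target_coef * par$V
        else down <- down + abs(par$target_coef) * par$V
      }
      if (i == par$effector_id) out_count <- out_count + 1
    }
    a <- active[[as.character(i)]]
    deltas[k] <- (1 - a) * up - a * down - use_coef * out_count
  }
  names(deltas) <- as.character(ids)
  par_delta <- NULL
  if (!is.null(par)) {
    n_links <- if (is.na(par$target_id)) 2 else 3
    par_delta <- (1 - par$V) * par$self_coef * par$V -
      par$V * abs(par$effector_coef) * active[[as.character(par$effector_id)]] -
      use_coef * n_links
  }
  list(active = deltas, parasite = par_delta)
}

oracle_cap <- function(deltas, limit) {
  all_d <- c(deltas$active, deltas$parasite)
  pos_sum <- 0
  for (d in all_d) if (d > 0) pos_sum <- pos_sum + d
  if (pos_sum > limit) {
    scale <- limit / pos_sum
    deltas$active <- ifelse(deltas$active > 0, deltas$active * scale,
                            deltas$active)
    if (!is.null(deltas$parasite) && deltas$parasite > 0)
      deltas$parasite <- deltas$parasite * scale
  }
  deltas
}

oracle_step <- function(proteins, edges, active, limit, use_coef = 0.01,
                        dev = NULL, par = NULL) {
  d <- oracle_cap(oracle_deltas(proteins, edges, active, use_coef, dev, par),
                  limit)
  new_active <- pmin(1, pmax(0, unlist(active)[names(d$active)] + d$active))
  new_V <- if (is.null(par)) NULL
           else min(1, max(0, par$V + d$parasite))
  list(active = as.list(setNames(new_active, names(d$active))), V = new_V)
}

# Full life re-run: 5 equilibrium steps + 150 life steps, developmental
# input over the schedule's window, optional parasite from infection_step.
# parasite: a pleio_parasite, "non-disrupting", or NULL.
oracle_life <- function(host, cfg, generation = 0, infection_step = NA,
                        parasite = NULL) {
  p <- host$proteins
  e <- host$edges
  limit <- if (cfg$resource == "scarce") 0.1
           else if (cfg$resource == "plentiful") 1.0
           else if (generation %% 2 == 0) 0.1 else 1.0
  active <- as.list(setNames(rep(cfg$initial_active, nrow(p)),
                             as.character(sort(p$id))))
  x <- seq(0, 8 * pi, length.out = 50)
  sig <- if (cfg$dev_signal_variant == "half-angle") sin(x / 2) + 0.5
         else sin(x) / 2 + 0.5
  dev_window <- if (cfg$signal_order == "development-first") 1:50 else 101:150
  dev_target <- p$id[p$role == "detector" & p$network == "developmental"]
  imm_detector <- p$id[p$role == "detector" & p$network == "immune"]
  imm_effector <- p$id[p$role == "effector" & p$network %in% c("immune", "shared")]
  imm_signals <- sort(p$id[p$role == "signal" & p$network == "immune"])
  non_disrupting <- identical(parasite, "non-disrupting")
  target_id <- if (non_disrupting || is.null(parasite)) NA_integer_
    else imm_signals[(parasite$target_index %% length(imm_signals)) + 1]
  target_coef <- if (non_disrupting || is.null(parasite)) 0
    else parasite$target_coefficient
  infected <- FALSE
  V <- NA
  n_life <- cfg$life_steps
  states <- matrix(NA_real_, n_life, nrow(p),
                   dimnames = list(NULL, as.character(sort(p$id))))
  par_series <- rep(NA_real_, n_life)
  for (t in 1:(cfg$equilibrium_steps + n_life)) {
    life_t <- t - cfg$equilibrium_steps
    dev <- if (length(dev_target) == 1 && life_t %in% dev_window)
      list(target_id = dev_target, value = sig[match(life_t, dev_window)])
    else NULL
    if (!is.na(infection_step) && life_t == infection_step) {
      infected <- TRUE
      V <- cfg$parasite_inoculum
    }
    par <- if (infected)
      list(V = V, detector_id = imm_detector, detector_coef = 1.0,
           target_id = target_id, target_coef = target_coef,
           self_coef = 0.8, effector_id = imm_effector, effector_coef = -1.0)
    else NULL
    out <- oracle_step(p, e, active, limit, cfg$use_coef, dev, par)
    active <- out$active
    if (infected) V <- out$V
    if (life_t >= 1) {
      states[life_t, ] <- unlist(active)[colnames(states)]
      if (infected) par_series[life_t] <- V
    }
  }
  list(states = states, parasite = par_series, signal = sig,
       imm_effector = as.character(imm_effector))
}

# random toy network of up to max_n proteins with a full role structure
random_toy_host <- function(max_n = 6) {
  n_sig <- sample(1:(max_n - 2), 1)
  roles <- c("detector", rep("signal", n_sig), "effector")
  proteins <- data.frame(id = seq_along(roles), role = roles,
                         network = "immune")
  pairs <- pleionet::valid_init_pairs(proteins)
  keep <- runif(nrow(pairs)) < 0.6
  edges <- data.frame(source = pairs$source[keep], target = pairs$target[keep],
                      coefficient = runif(sum(keep), -1, 1))
  toy_host(proteins, edges)
}
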