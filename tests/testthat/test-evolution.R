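test_that("infection assignment is distinct, complete and uniform", {
  set.seed(8)
  a <- assign_infections(500, 250)
  expect_length(a, 250)
  expect_false(any(duplicated(a)))
  expect_length(assign_infections(10, 0), 0)
  expect_error(assign_infections(5, 6), "prevalence")
  counts <- integer(10)
  for (i in 1:2000) {
    hit <- assign_infections(10, 5)
    counts[hit] <- counts[hit] + 1
  }
  # every host equally likely: expected 1000 each, sd ~ 22
  expect_true(all(abs(counts - 1000) < 110))
})

test_that("parasite offspring counts partition the unit interval at thirds", {
  expect_equal(parasite_offspring_count(0.2), 1L)
  expect_equal(parasite_offspring_count(0.5), 2L)
  expect_equal(parasite_offspring_count(0.7), 3L)
  expect_equal(parasite_offspring_count(c(1 / 3, 2 / 3, 1)), c(1L, 2L, 3L))
  expect_equal(parasite_offspring_count(0), 1L)
  expect_error(parasite_offspring_count(1.2))
})

test_that("host death respects the 30% cap and infection priority", {
  cfg <- sim_config()
  set.seed(14)
  # everyone uncontrolled: exactly 30% die
  dead <- select_host_deaths(rep(0.5, 100), rep(0.95, 100), cfg)
  expect_length(dead, 30)
  # equal fitness, none infected: at most 30% die
  for (i in 1:20) {
    dead <- select_host_deaths(rep(0.4, 100), rep(0, 100), cfg)
    expect_lte(length(dead), 30)
  }
  # the fittest surviving host never dies in the weighted pass
  fit <- c(1, rep(1e-6, 99))
  for (i in 1:30) {
    dead <- select_host_deaths(fit, rep(0, 100), cfg)
    expect_false(1 %in% dead)
  }
  # infection deaths take priority but excess is released
  pa <- c(rep(0.95, 60), rep(0, 40))
  dead <- select_host_deaths(rep(0.5, 100), pa, cfg)
  expect_length(dead, 30)
  expect_true(all(dead <= 60))
})

test_that("parasite death is strictly rank-based with stable ties", {
  cfg <- sim_config()
  fit <- c(0.9, 0.1, 0.5, 0.3, 0.8, 0.2, 0.7, 0.4, 0.6, 1.0)
  expect_setequal(select_parasite_deaths(fit, cfg), c(2, 6, 4))
  expect_equal(select_parasite_deaths(rep(0.5, 10), cfg), 1:3)
  expect_length(select_parasite_deaths(runif(125), cfg), 37)
})

test_that("host mutation events occur at the configured relative rates", {
  set.seed(55)
  cfg <- sim_config()
  base <- init_host("independent")  # has edges and 3 signals per network
  n <- 3000
  events <- character(n)
  for (i in seq_len(n)) {
    m <- mutate_host(base, cfg)
    d_prot <- nrow(m$proteins) - nrow(base$proteins)
    d_edge <- nrow(m$edges) - nrow(base$edges)
    events[i] <- if (d_prot == 1) "duplicate"
      else if (d_prot == -1) "delete_protein"
      else if (d_edge == 1) "add"
      else if (d_edge == -1) "delete_edge"
      else if (!isTRUE(all.equal(m$edges$coefficient,
                                 base$edges$coefficient))) "alter"
      else "noop_or_add_collision"
    if (i %% 250 == 0) validate_host(m)
  }
  freq <- table(factor(events, levels = c("add", "delete_edge", "alter",
                                          "delete_protein", "duplicate",
                                          "noop_or_add_collision"))) / n
  # se at n = 3000 is < 0.01 for each class
  expect_lt(abs(freq[["delete_edge"]] - 0.25), 0.035)
  expect_lt(abs(freq[["alter"]] - 0.30), 0.035)
  expect_lt(abs(freq[["delete_protein"]] - 0.10), 0.025)
  expect_lt(abs(freq[["duplicate"]] - 0.10), 0.025)
  # add-edge draws that hit an existing or illegal pair resolve to no-ops
  expect_lt(abs(freq[["add"]] + freq[["noop_or_add_collision"]] - 0.25), 0.035)
})

test_that("mutation preserves genotype legality under long chains", {
  set.seed(66)
  cfg <- sim_config()
  for (arch in c("independent", "shared")) {
    h <- init_host(arch)
    for (i in 1:1500) {
      h <- mutate_host(h, cfg)
      if (i %% 50 == 0) expect_silent(validate_host(h))
    }
    expect_silent(validate_host(h))
    expect_equal(h$architecture, arch)
    # detectors and effectors survive arbitrary mutation
    expect_equal(sum(h$proteins$role == "detector"), 2L)
    expect_equal(sum(h$proteins$role == "effector"),
                 if (arch == "independent") 2L else 1L)
  }
})

test_that("duplicating a protein copies its incoming, outgoing and self edges", {
  h <- toy_host(
    data.frame(id = 1:4, role = c("detector", "signal", "signal", "effector"),
               network = "immune"),
    data.frame(source = c(1L, 2L, 2L, 3L), target = c(2L, 2L, 4L, 2L),
               coefficient = c(0.5, -0.3, 0.8, 0.2)))
  cfg <- sim_config(host_mutation_weights = c(
    add_edge = 0, delete_edge = 0, alter_coefficient = 0,
    delete_protein = 0, duplicate_protein = 1))
  set.seed(10)
  found_dup2 <- FALSE
  for (i in 1:20) {
    m <- mutate_host(h, cfg)
    new_id <- setdiff(m$proteins$id, h$proteins$id)
    if (m$proteins$role[m$proteins$id == new_id] == "signal" &&
        any(m$edges$source == new_id & m$edges$target == new_id)) {
      # protein 2 was duplicated: copy gets 1->new, new->new, new->4, 3->new
      found_dup2 <- TRUE
      expect_true(any(m$edges$source == 1 & m$edges$target == new_id))
      expect_true(any(m$edges$source == new_id & m$edges$target == 4))
      expect_true(any(m$edges$source == 3 & m$edges$target == new_id))
    }
  }
  expect_true(found_dup2)
})

test_that("fitness-weighted host reproduction restores the population", {
  set.seed(23)
  cfg <- sim_config(host_mutation_rate = 0)
  survivors <- replicate(350, init_host("shared"), simplify = FALSE)
  out <- reproduce_hosts(survivors, runif(350), 500, cfg)
  expect_length(out$hosts, 500)
  expect_length(out$parent_index, 150)

  two <- replicate(2, init_host("shared"), simplify = FALSE)
  out <- reproduce_hosts(two, c(0.9, 0.1), 2002, cfg)
  tab <- tabulate(out$parent_index, 2)
  # 9:1 expected parentage; sd of count ~ 13
  expect_lt(abs(tab[1] / 2000 - 0.9), 0.03)
})

test_that("parasites reproduce greedily in fitness order", {
  set.seed(29)
  cfg <- sim_config(parasite_mutation_rate = 0)
  ps <- replicate(2, init_parasite(cfg), simplify = FALSE)
  ps[[1]]$target_index <- 0L; ps[[2]]$target_index <- 1L
  out <- reproduce_parasites(ps, c(0.2, 1.0), 7, cfg)
  expect_length(out, 7)
  # deficit 5: fitter parasite (abundance 1 -> 3 offspring) fills first,
  # then the weaker (abundance 0.2 -> 1), then cycle back: 3 + 1 + 1
  kids <- vapply(out[3:7], `[[`, integer(1), "target_index")
  expect_equal(kids, c(1L, 1L, 1L, 0L, 1L))

  many <- replicate(88, init_parasite(cfg), simplify = FALSE)
  expect_length(reproduce_parasites(many, runif(88), 125, cfg), 125)
})

test_that("a short coevolution run keeps its population mechanics exact", {
  cfg <- sim_config(host_pop = 30L, parasite_pop = 15L, generations = 6L,
                    synchrony = "synchronous")
  h1 <- run_coevolution(cfg, seed = 5)
  expect_length(h1$hosts, 30)
  expect_length(h1$parasites, 15)
  expect_equal(nrow(h1$summary), 6)
  expect_true(all(h1$summary$prevalence == 0.5))
  expect_true(all(h1$summary$host_deaths <= floor(0.3 * 30)))
  expect_true(all(h1$summary$parasite_deaths == floor(0.3 * 15)))
  h2 <- run_coevolution(cfg, seed = 5)
  expect_identical(h1$summary, h2$summary)
  expect_identical(genotype_hash(most_common_genotype(h1$hosts)),
                   genotype_hash(most_common_genotype(h2$hosts)))
})

test_that("fitness decomposes as exp of the summed cost components", {
  set.seed(61)
  cfg <- sim_config(synchrony = "synchronous")
  for (i in 1:20) {
    h <- init_host(sample(c("shared", "independent"), 1))
    pr <- if (i %% 2) init_parasite(cfg) else NULL
    rec <- simulate_life(h, pr, cfg)
    expect_equal(rec$fitness,
                 exp(-(rec$imm_eff_area + rec$par_area + rec$dev_cost)))
    expect_true(rec$fitness > 0 && rec$fitness <= 1)
    expect_gte(rec$dev_cost, 0)
  }
})
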