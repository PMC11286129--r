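fake_record <- function(effector_series, parasite = NULL,
                        infection_step = NA_integer_, dev_cost = 0) {
  n <- length(effector_series)
  structure(
    list(states = matrix(effector_series, ncol = 1,
                         dimnames = list(NULL, "1")),
         parasite = parasite, infection_step = infection_step,
         idx_immune_effector = 1L, idx_dev_effector = 1L,
         dev_window = seq_len(min(50, n)), dev_cost = dev_cost),
    class = "life_record")
}

test_that("developmental signal follows the pulsed formula on the 0..8pi grid", {
  expect_equal(developmental_signal(1), 0.5)
  expect_equal(developmental_signal(50), sin(4 * pi) + 0.5)
  expect_equal(developmental_signal(50), 0.5, tolerance = 1e-12)
  x13 <- (12 * 8 * pi) / 49
  expect_equal(developmental_signal(13), sin(x13 / 2) + 0.5)
  expect_equal(developmental_signal(13, variant = "half-amplitude"),
               sin(x13) / 2 + 0.5)
  expect_error(developmental_signal(0))
  expect_error(developmental_signal(51))
  # the signal is allowed outside [0,1]
  expect_gt(max(developmental_signal(1:50)), 1)
  expect_lt(min(developmental_signal(1:50)), 0)
})

test_that("equilibration runs five capped steps from the 0.5 start", {
  set.seed(2)
  h0 <- init_host("independent", edge_prob = 0)
  st <- equilibrate(h0)
  expect_equal(unname(st$active), rep(0.5, 10))

  # single +1 self-loop on a signalling protein, scarce cap
  h1 <- toy_host(
    data.frame(id = 1:3, role = c("detector", "signal", "effector"),
               network = "immune"),
    data.frame(source = 2L, target = 2L, coefficient = 1))
  st <- equilibrate(h1, limit = 0.1)
  or <- as.list(c(`1` = 0.5, `2` = 0.5, `3` = 0.5))
  for (s in 1:5) or <- oracle_step(h1$proteins, h1$edges, or, 0.1)$active
  expect_equal(unname(st$active), unname(unlist(or)), tolerance = 1e-12)

  h <- init_host("shared")
  expect_true(all(equilibrate(h)$active >= 0 & equilibrate(h)$active <= 1))
})

test_that("parasite attachment resolves links and modulo targeting", {
  set.seed(4)
  cfg <- sim_config()
  h <- init_host("independent")  # immune signalling ids 2,3,4
  pr <- init_parasite(cfg)
  links <- attach_parasite(h, pr, cfg)
  expect_equal(links$effector_coefficient, -1.0)
  expect_equal(links$detector_coefficient, 1.0)
  expect_equal(links$self_coefficient, 0.8)
  expect_equal(links$n_links, 3L)

  pr$target_index <- 0L
  expect_equal(attach_parasite(h, pr, cfg)$target_idx, 2L)  # lowest-id signal
  pr$target_index <- 5L
  expect_equal(attach_parasite(h, pr, cfg)$target_idx, 4L)  # 5 mod 3 = 2
  # non-disrupting probe keeps all but the target link
  nd <- attach_parasite(h, NULL, cfg)
  expect_true(is.na(nd$target_idx))
  expect_equal(nd$n_links, 2L)
})

test_that("schedule windows partition life and infection lands inside them", {
  for (order in c("development-first", "development-last")) {
    for (sync in c("synchronous", "asynchronous")) {
      cfg <- sim_config(signal_order = order, synchrony = sync)
      win <- schedule_windows(cfg)
      expect_equal(length(win$dev_window), 50L)
      expect_equal(length(win$infection_window), 50L)
      if (sync == "synchronous") {
        expect_identical(win$infection_window, win$dev_window)
      } else {
        expect_length(intersect(win$infection_window, win$dev_window), 0)
      }
      expect_true(all(win$infection_window %in% 1:150))
    }
  }
  cfg <- sim_config(signal_order = "development-last")
  expect_identical(schedule_windows(cfg)$dev_window, 101:150)

  set.seed(12)
  h <- init_host("shared")
  cfg_a <- sim_config(synchrony = "asynchronous")
  steps <- replicate(100, {
    simulate_life(h, init_parasite(cfg_a), cfg_a)$infection_step
  })
  expect_true(all(steps %in% 51:100))
  cfg_s <- sim_config(synchrony = "synchronous")
  steps <- replicate(100, {
    simulate_life(h, init_parasite(cfg_s), cfg_s)$infection_step
  })
  expect_true(all(steps %in% 1:50))
})

test_that("life records carry the expected shapes and determinism", {
  set.seed(21)
  cfg <- sim_config(synchrony = "synchronous")
  h <- init_host("shared")
  rec0 <- simulate_life(h, NULL, cfg)
  expect_null(rec0$parasite)
  expect_true(is.na(rec0$infection_step))
  expect_equal(rec0$par_area, 0)
  expect_equal(nrow(rec0$states), 150L)
  expect_equal(nrow(rec0$equilibrium_states), 5L)

  pr <- init_parasite(cfg)
  set.seed(99); r1 <- simulate_life(h, pr, cfg)
  set.seed(99); r2 <- simulate_life(h, pr, cfg)
  expect_identical(r1$states, r2$states)
  tab <- life_record_table(r1)
  expect_true(all(c("step", "node", "active") %in% names(tab)))
  expect_true("parasite" %in% tab$node)
})

test_that("effector and parasite areas are lifespan- and
           infection-normalized means", {
  expect_equal(immune_effector_area(fake_record(rep(0.5, 150))), 0.5)
  expect_equal(immune_effector_area(fake_record(rep(0, 150))), 0)
  expect_equal(immune_effector_area(fake_record(c(rep(1, 75), rep(0, 75)))),
               0.5)

  expect_equal(parasite_area(fake_record(rep(0, 150))), 0)
  pinned <- fake_record(rep(0, 150),
                        parasite = c(rep(NA, 59), rep(1, 91)),
                        infection_step = 60L)
  expect_equal(parasite_area(pinned), 1)
  # normalization: a constant 0.5 infection scores 0.5 at any infection time
  for (s in c(10L, 120L)) {
    rec <- fake_record(rep(0, 150),
                       parasite = c(rep(NA, s - 1), rep(0.5, 151 - s)),
                       infection_step = s)
    expect_equal(parasite_area(rec), 0.5)
    expect_equal(parasite_fitness(rec), 0.5)
  }
  expect_error(parasite_fitness(fake_record(rep(0, 150))), "uninfected")
})

test_that("developmental cost combines correlation and absolute deviation", {
  sig <- developmental_signal(1:50)
  expect_equal(developmental_cost(sig, sig), 0)
  expect_equal(developmental_cost(sig, rep(0.5, 50)),
               1 + mean(abs(sig - 0.5)))
  # perfectly anti-correlated output: correlation term contributes 2
  s01 <- (sig + 0.5) / 2  # signal rescaled into [0,1]
  anti <- 1 - s01
  expect_equal(developmental_cost(sig, anti), 2 + mean(abs(sig - anti)))
  expect_equal(developmental_cost(rep(0.2, 50), rep(0.2, 50)), 1)  # both flat
  expect_error(developmental_cost(sig, sig[-1]), "length")
})

test_that("host fitness is exp of minus the summed costs and is monotone", {
  expect_equal(host_fitness(fake_record(rep(0, 150))), 1)
  rec <- fake_record(rep(0.5, 150),
                     parasite = c(rep(NA, 49), rep(0.2, 101)),
                     infection_step = 50L, dev_cost = 0.3)
  expect_equal(host_fitness(rec), exp(-1))
  base <- host_fitness(fake_record(rep(0.2, 150), dev_cost = 0.1))
  expect_lt(host_fitness(fake_record(rep(0.3, 150), dev_cost = 0.1)), base)
  expect_lt(host_fitness(fake_record(rep(0.2, 150), dev_cost = 0.2)), base)
  worse_par <- fake_record(rep(0.2, 150),
                           parasite = c(rep(NA, 99), rep(0.4, 51)),
                           infection_step = 100L, dev_cost = 0.1)
  expect_lt(host_fitness(worse_par), base)
})
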