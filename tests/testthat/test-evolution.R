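# The evolutionary loop: pairing, culling, breeding, full runs.

test_that("an all-AllC population gains exactly R per agent per round", {
  cfg <- sim_config(population_size = 10, ticks = 1,
                    initial_mix = c(AllC = 10), rounds_per_encounter = 6,
                    seed = 1)
  pop <- new_population(cfg)
  out <- pair_and_play(pop, cfg)
  expect_equal(out$population$score, rep(3 * 6, 10))
  expect_equal(out$successes + out$failures, 0)
})

test_that("pairing requires an even population and is seed-deterministic", {
  cfg <- quick_config(seed = 1)
  pop <- new_population(cfg)
  odd <- pop; odd$strategy <- odd$strategy[-1]
  expect_error(pair_and_play(odd, cfg), "even")
  set.seed(9); a <- pair_and_play(pop, cfg)
  set.seed(9); b <- pair_and_play(pop, cfg)
  expect_identical(a, b)
})

test_that("culling removes the two lowest scorers and conserves size", {
  cfg <- quick_config(population_size = 4, initial_mix = c(TFT = 4))
  pop <- fixture_population(rep("TFT", 4), score = c(10, 5, 1, 0))
  set.seed(1)
  out <- cull_and_breed(pop, cfg)
  expect_length(out$score, 4)
  expect_true(all(c(10, 5) %in% out$score))
  expect_false(any(c(1, 0) %in% out$score))
  # parent_mean newborns: both offspring start at (10 + 5) / 2
  expect_equal(sort(out$score), c(5, 7.5, 7.5, 10))
  expect_equal(out$mem_len[out$score == 7.5], c(0L, 0L))
})

test_that("degenerate weights make the positive scorer parent 1 surely", {
  # survivors score (7, 0): offspring under parent_mean start at 3.5
  cfg <- quick_config(population_size = 4, initial_mix = c(TFT = 4))
  pop <- fixture_population(rep("TFT", 4), score = c(7, 0, -2, -3))
  set.seed(2)
  out <- cull_and_breed(pop, cfg)
  expect_equal(sort(out$score), c(0, 3.5, 3.5, 7))
})

test_that("newborn_score = 'zero' starts offspring from a zero score", {
  cfg <- quick_config(population_size = 4, initial_mix = c(TFT = 4),
                      newborn_score = "zero")
  pop <- fixture_population(rep("TFT", 4), score = c(10, 5, 1, 0.5))
  set.seed(3)
  out <- cull_and_breed(pop, cfg)
  expect_equal(sort(out$score), c(0, 0, 5, 10))
})

test_that("crossover without mutation permutes parental loci per position", {
  cfg <- quick_config()
  g1 <- list(strategy = "TFT", deception = "None", mutation_prob = 0)
  g2 <- list(strategy = "AllD", deception = "Degradation", mutation_prob = 0)
  set.seed(4)
  for (i in 1:50) {
    off <- crossover_mutate(g1, g2, cfg)
    expect_setequal(c(off[[1]]$strategy, off[[2]]$strategy), c("TFT", "AllD"))
    expect_setequal(c(off[[1]]$deception, off[[2]]$deception),
                    c("None", "Degradation"))
    expect_equal(off[[1]]$mutation_prob + off[[2]]$mutation_prob, 0)
  }
})

test_that("crossover mutation keeps mutation_prob in [0, 1] and deceptions allowed", {
  cfg <- quick_config(allowed_deceptions = c("None", "Corruption"),
                      mutation_sigma = 0.5)
  g <- list(strategy = "TFT", deception = "None", mutation_prob = 1)
  set.seed(5)
  for (i in 1:100) {
    off <- crossover_mutate(g, g, cfg)
    for (o in off) {
      expect_true(o$mutation_prob >= 0 && o$mutation_prob <= 1)
      expect_true(o$deception %in% c("None", "Corruption"))
      expect_true(o$strategy %in% strategy_levels())
    }
  }
})

test_that("run_simulation with ticks = 0 returns the initial census", {
  ts <- run_simulation(quick_config(ticks = 0, seed = 1))
  expect_equal(nrow(ts), 1)
  expect_equal(ts$count_TFT_plain, 4)
  expect_equal(ts$count_AllC_plain, 2)
  expect_equal(sum(ts[1, deceptIPD:::trait_columns()]), 10)
})

test_that("census counts sum to the population size at every tick", {
  ts <- run_simulation(quick_config(ticks = 300, seed = 2,
                                    allowed_deceptions = c("None", "Degradation"),
                                    cost = 0.05))
  counts <- ts[, deceptIPD:::trait_columns()]
  expect_true(all(abs(rowSums(counts) - 10) < 1e-12))
  f <- rowSums(trait_fractions(ts, "six"))
  expect_true(all(abs(f - 1) < 1e-12))
})

test_that("a closed world without deception has all-zero deceiver columns", {
  ts <- run_simulation(quick_config(ticks = 400, seed = 3,
                                    allowed_deceptions = "None", cost = 0))
  dec_cols <- grep("_dec$", names(ts), value = TRUE)
  expect_true(all(ts[, dec_cols] == 0))
  expect_true(all(ts$deception_successes == 0 & ts$deception_failures == 0))
})

test_that("full runs are bit-reproducible from the seed", {
  cfg <- sim_config(ticks = 400, seed = 17, cost = 0.1,
                    allowed_deceptions = c("None", "Corruption"))
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("the engine equals an R-level loop of pair_and_play + cull_and_breed", {
  cfg <- quick_config(ticks = 40, seed = 23, cost = 0.1,
                      allowed_deceptions = c("None", "Degradation"))
  engine <- run_simulation(cfg)
  set.seed(cfg$seed)
  pop <- new_population(cfg)
  for (t in seq_len(cfg$ticks)) {
    pop <- pair_and_play(pop, cfg)$population
    pop <- cull_and_breed(pop, cfg)
  }
  final <- table(factor(strategy_levels()[pop$strategy + 1L],
                        levels = strategy_levels()),
                 factor(ifelse(pop$deception == 0L, "plain", "dec"),
                        levels = c("plain", "dec")))
  engine_final <- engine[nrow(engine), deceptIPD:::trait_columns()]
  for (s in strategy_levels()) {
    expect_equal(unname(engine_final[[paste0("count_", s, "_plain")]]),
                 unname(final[s, "plain"]))
    expect_equal(unname(engine_final[[paste0("count_", s, "_dec")]]),
                 unname(final[s, "dec"]))
  }
})

test_that("exploitative agents displace cooperators in cost-0 corruption runs", {
  # invasion property at the study conditions: deceiving AllD sweeps
  wins <- vapply(1:10, function(s) {
    ts <- run_simulation(corruption_config(cost = 0, seed = 600 + s,
                                           ticks = 3000))
    f <- cooperative_fraction(ts)
    alld <- ts$count_AllD_plain + ts$count_AllD_dec
    tail(alld, 1) > 25 || min(f) < 0.2
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("run CSVs round-trip through write_run_csv / read_run_csv", {
  ts <- run_simulation(quick_config(ticks = 30, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_run_csv(ts, path)
  back <- read_run_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ts), ignore_attr = TRUE)
  expect_equal(population_size(back), 10)
})

test_that("invalid initial mixes are rejected", {
  expect_error(sim_config(population_size = 50,
                          initial_mix = c(TFT = 10, AllC = 10)),
               "sum to population_size")
  expect_error(sim_config(population_size = 49), "%%|even|TRUE")
})
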