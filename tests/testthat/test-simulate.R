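# schedule with maternal-only selection and loss exactly 0.5:
# 1 - (1 - 4/7)/(1 - 1/7) = 0.5
relaxation_config <- function(mode = "deterministic", n_generations = 6,
                              transition_generation = 2, ...) {
  simulation_config(
    arch = genetic_architecture(env_sd = 3),
    pre_schedule = mortality_schedule(1 / 7, 0, rr_maternal = 4,
                                      rr_perinatal = 1, fertility = 6),
    post_schedule = mortality_schedule(0, 0, 1, 1, fertility = 2.5),
    transition_generation = transition_generation,
    n_generations = n_generations,
    initial_freq = 0.10,
    mode = mode, ...
  )
}

test_that("calibrated gain holds the pre-transition frequency constant", {
  cfg <- simulation_config(
    pre_schedule = mortality_schedule(0.15, 0.14, 4, 4),
    post_schedule = mortality_schedule(0.15, 0.14, 4, 4),
    transition_generation = 100, n_generations = 20,
    initial_freq = 0.23
  )
  traj <- deterministic_trajectory(cfg)
  expect_equal(traj$allele_freq, rep(0.23, 20))
  expect_equal(nrow(traj), cfg$n_generations)
})

test_that("relaxation gives the 10% -> 15% -> 22.5% geometric growth", {
  cfg <- relaxation_config()
  expect_equal(cfg$gain, 0.5) # calibrated to the pre-transition schedule
  traj <- deterministic_trajectory(cfg)
  expect_equal(traj$allele_freq[traj$generation <= 2], rep(0.10, 3))
  expect_equal(traj$allele_freq[traj$generation == 3], 0.15)
  expect_equal(traj$allele_freq[traj$generation == 4], 0.225)
  # calendar mapping: transition generation at the transition year
  expect_equal(traj$calendar_year[traj$generation == 2], 1940)
  expect_equal(traj$calendar_year[traj$generation == 3], 1965)
  # frequencies stay in [0, 1] even far past the transition
  long <- deterministic_trajectory(relaxation_config(n_generations = 20))
  expect_true(all(long$allele_freq >= 0 & long$allele_freq <= 1))
  expect_equal(long$allele_freq[20], 1)
})

test_that("post-transition frequency is non-decreasing when loss < gain", {
  traj <- deterministic_trajectory(relaxation_config(n_generations = 10))
  post <- traj$allele_freq[traj$generation >= 2]
  expect_true(all(diff(post) >= 0))
})

test_that("Wright-Fisher runs are seed-reproducible and need pop_size", {
  cfg <- relaxation_config(mode = "wright_fisher", pop_size = 2000,
                           seed = 99)
  t1 <- wright_fisher_trajectory(cfg)
  t2 <- wright_fisher_trajectory(cfg)
  expect_identical(t1$allele_freq, t2$allele_freq)
  expect_identical(t1$mean_bmi, t2$mean_bmi)
  expect_error(
    simulation_config(pre_schedule = mortality_schedule(0.1),
                      post_schedule = mortality_schedule(0.1),
                      transition_generation = 1, n_generations = 2,
                      mode = "wright_fisher", pop_size = 1),
    "pop_size")
})

test_that("neutral Wright-Fisher drifts without trend", {
  cfg <- simulation_config(
    arch = genetic_architecture(env_sd = 3),
    pre_schedule = mortality_schedule(0.15, 0.14, 1, 1),
    post_schedule = mortality_schedule(0.0001, 0.003, 1, 1),
    transition_generation = 5, n_generations = 12,
    initial_freq = 0.10, mode = "wright_fisher", pop_size = 1e4,
    seed = 31
  )
  expect_equal(cfg$gain, 0) # rr = 1 everywhere: no loss to balance
  traj <- wright_fisher_trajectory(cfg)
  # per-generation binomial drift sd: sqrt(p(1-p) / (N L)) per generation
  se <- sqrt(12 * 0.1 * 0.9 / (1e4 * 1000))
  expect_lt(abs(traj$allele_freq[12] - 0.10), 4 * se)
})

test_that("WF replicate mean matches the deterministic one-step recursion", {
  # 10% -> 15% config, one generation after the transition (scaled down
  # here; the acceptance suite runs N = 1e5 x 200 replicates)
  finals <- vapply(1:40, function(s) {
    cfg <- relaxation_config(mode = "wright_fisher", pop_size = 1e4,
                             seed = s, n_generations = 2,
                             transition_generation = 0)
    wright_fisher_trajectory(cfg)$allele_freq[2]
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.15), 3 * se)
})

test_that("adult prevalence is the share-weighted cohort mean", {
  rates <- c(post1945 = 0.20, pre1945 = 0.10)
  expect_equal(adult_prevalence(c(post1945 = 0.10, pre1945 = 0.90), rates),
               0.11)
  expect_equal(adult_prevalence(c(post1945 = 0.50, pre1945 = 0.50), rates),
               0.15)
  expect_equal(adult_prevalence(c(post1945 = 1, pre1945 = 0), rates), 0.20)
  # matrix form: one row per year
  shares <- rbind(c(0.10, 0.90), c(0.50, 0.50))
  colnames(shares) <- names(rates)
  expect_equal(adult_prevalence(shares, rates), c(0.11, 0.15))
  expect_error(adult_prevalence(c(a = 0.5, b = 0.5), rates), "labels")
  expect_error(adult_prevalence(c(post1945 = 0.7, pre1945 = 0.7), rates),
               "sum to 1")
})

test_that("adult prevalence lags the cohort curve and accelerates as elevated cohorts phase in", {
  traj <- deterministic_trajectory(relaxation_config(n_generations = 8))
  series <- adult_prevalence_series(traj, years = seq(1950, 2025, by = 5))
  inc <- diff(series$adult_obesity_prevalence)
  share <- series$post_transition_share
  # share of post-transition cohorts among adults only grows
  expect_true(all(diff(share) >= 0))
  # lag: adult prevalence is flat while no elevated cohort is of adult age
  expect_true(all(abs(inc[share[-1] == 0]) < 1e-12))
  # monotone rise once they arrive
  expect_true(all(inc >= -1e-12))
  # acceleration: increments once elevated cohorts dominate (share >= 1/2)
  # exceed the earliest positive increments, and the second difference is
  # non-negative throughout the phase-in window
  early <- inc[share[-1] > 0 & share[-1] < 0.5]
  late <- inc[share[-1] >= 0.5]
  expect_gt(mean(late), mean(early))
  d2 <- diff(inc[share[-1] > 0])
  expect_true(all(d2 >= -1e-9))
  expect_true(any(d2 > 1e-6))
  # adult prevalence never exceeds the newest cohort's prevalence
  expect_true(all(series$adult_obesity_prevalence <=
                    max(traj$cohort_obesity_prevalence) + 1e-12))
})
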