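test_that("simulation is deterministic given the seed and respects n", {
  cfg <- simulation_config(n_respondents = 8, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$latents, c2$latents)
  expect_equal(c1$study$respondents, c2$study$respondents)

  expect_length(sample_latent(simulation_config(n_respondents = 0, seed = 1)), 0L)

  # adding respondents does not perturb earlier ones
  c3 <- simulate_cohort(simulation_config(n_respondents = 12, seed = 99))
  expect_identical(c3$latents[1:8], c1$latents)
  expect_equal(c3$study$respondents[1:8], c1$study$respondents)
})

test_that("latent draws respect the configured probabilities", {
  cfg0 <- simulation_config(n_respondents = 60, seed = 2,
                            p_nothing_worse_than_dead = 0)
  lat <- sample_latent(cfg0)
  expect_true(all(!vapply(lat, `[[`, logical(1), "nothing_worse_than_dead")))
  expect_true(all(is.finite(vapply(lat, `[[`, numeric(1), "true_dead_utility"))))
  w <- t(vapply(lat, `[[`, numeric(5), "true_weight"))
  expect_equal(rowSums(w), rep(1, 60))
  expect_error(simulation_config(p_nothing_worse_than_dead = 1.5), "0, 1")
})

test_that("noise-free, unrounded responses recover the latent parameters exactly", {
  cfg <- simulation_config(n_respondents = 20, seed = 14,
                           choice_noise_scale = 0, rating_grid = 0)
  cohort <- simulate_cohort(cfg)
  for (i in seq_along(cohort$latents)) {
    lat <- cohort$latents[[i]]
    rec <- cohort$study$respondents[[i]]
    fit <- puf(rec$swing, rec$allocation)
    expect_equal(fit$weights, lat$true_weight, tolerance = 1e-12)
    expect_equal(fit$level2_fraction, lat$true_level2_fraction, tolerance = 1e-12)
  }
  rep <- recovery_report(cfg)
  expect_lt(max(abs(rep$weights$bias)), 1e-12)
  expect_lt(max(rep$level2_fractions$rmse), 1e-12)
})

test_that("respondents with nothing worse than dead answer A once and stop", {
  cfg <- simulation_config(n_respondents = 40, seed = 8, choice_noise_scale = 0,
                           p_nothing_worse_than_dead = 1)
  cohort <- simulate_cohort(cfg)
  for (r in cohort$study$respondents) {
    expect_identical(r$dead_search$choices, "A")
  }
})

test_that("noise-free brackets straddle the latent dead utility", {
  cfg <- simulation_config(n_respondents = 30, seed = 21,
                           choice_noise_scale = 0, rating_grid = 0)
  cohort <- simulate_cohort(cfg)
  for (i in seq_along(cohort$latents)) {
    lat <- cohort$latents[[i]]
    if (lat$nothing_worse_than_dead) next
    rec <- cohort$study$respondents[[i]]
    fit <- puf(rec$swing, rec$allocation)
    rk <- rank_states(fit)
    b <- bracket_from_record(rec$dead_search)
    if (b$classification == "bracketed") {
      expect_gt(rk$utility[b$lower_rank], lat$true_dead_utility)
      expect_lte(rk$utility[b$upper_rank], lat$true_dead_utility)
    } else if (b$classification == "above_mildest") {
      expect_gte(lat$true_dead_utility, rk$utility[b$upper_rank])
    }
  }
})

test_that("rounding to the rating grid keeps weight bias small", {
  rep <- recovery_report(simulation_config(n_respondents = 40, seed = 6,
                                           choice_noise_scale = 0,
                                           rating_grid = 5))
  expect_lt(max(abs(rep$weights$bias)), 0.03)
  expect_lt(rep$weights$rmse[rep$weights$dimension == "overall"], 0.03)
})

test_that("more choice noise does not sharpen the recovered location of dead", {
  rmse_at <- function(scale) {
    recovery_report(simulation_config(n_respondents = 60, seed = 17,
                                      choice_noise_scale = scale,
                                      rating_grid = 0))$dead_utility$rmse
  }
  expect_lte(rmse_at(0.01), rmse_at(0.5))
})

test_that("the below-33333 rate tracks the configured probability", {
  # noise-free: only the never-worse-than-dead subpopulation answers A first
  cfg <- simulation_config(n_respondents = 400, seed = 23,
                           choice_noise_scale = 0,
                           p_nothing_worse_than_dead = 0.24)
  cohort <- simulate_cohort(cfg)
  frac <- mean(vapply(cohort$study$respondents, function(r) {
    bracket_from_record(r$dead_search)$classification == "below_33333"
  }, logical(1)))
  # binomial sd at n = 400 is about 0.021; allow a wide band
  expect_lt(abs(frac - 0.24), 0.07)
})

test_that("full-pipeline social decrements equal the anchored latent means", {
  cfg <- simulation_config(n_respondents = 25, seed = 33,
                           choice_noise_scale = 0, rating_grid = 0)
  cohort <- simulate_cohort(cfg)
  pipeline <- list()
  oracle <- list()
  for (i in seq_along(cohort$latents)) {
    lat <- cohort$latents[[i]]
    rec <- cohort$study$respondents[[i]]
    # pipeline route: elicited responses -> puf -> bracket -> anchor
    fit <- puf(rec$swing, rec$allocation)
    b <- bracket_from_record(rec$dead_search)
    pipeline[[i]] <- anchor_puf(fit, dead_utility(fit, b))
    # oracle route: latent decrements anchored at the latent-search midpoint
    dec <- cbind(`1` = rep(0, 5), `2` = lat$true_weight * lat$true_level2_fraction,
                 `3` = lat$true_weight)
    rownames(dec) <- dims
    lp <- structure(list(decrements = dec), class = "puf")
    rk <- rank_states(lp)
    b2 <- if (lat$nothing_worse_than_dead) {
      run_dead_search(rk, function(s) "A")$bracket
    } else {
      run_dead_search(rk, function(s) {
        if (predict(lp, s) > lat$true_dead_utility) "A" else "B"
      })$bracket
    }
    u_dead <- dead_utility(lp, b2, rk)
    oracle[[i]] <- if (is.na(u_dead)) dec else dec / (1 - u_dead)
  }
  s_pipe <- summarize_decrements(pipeline)
  mean_oracle <- Reduce(`+`, oracle) / length(oracle)
  for (lev in c("2", "3")) {
    expect_equal(s_pipe$mean[s_pipe$level == as.integer(lev)],
                 unname(mean_oracle[, lev]), tolerance = 1e-9)
  }
})
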