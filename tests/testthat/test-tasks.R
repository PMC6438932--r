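test_that("bisection midpoints use round-half-up with implicit lower bound 1", {
  expect_identical(bisection_next(NULL, 243), 122L)  # (1+243)/2
  expect_identical(bisection_next(122, 243), 183L)   # ceil(182.5)
  expect_identical(bisection_next(NULL, 122), 62L)   # ceil(61.5)
  expect_error(bisection_next(10, 11), "exhausted")
  expect_error(bisection_next(50, 40), "lower < upper")
})

test_that("the worked choice sequence B,A,A,A,A brackets dead between ranks 228 and 243", {
  rk <- rank_states(default_puf())
  res <- run_dead_search(rk, pattern_answers(c("B", "A", "A", "A", "A")))
  expect_identical(res$bracket$classification, "bracketed")
  expect_identical(res$bracket$lower_rank, 228L)
  expect_identical(res$bracket$upper_rank, 243L)
  expect_identical(res$record$presented_ranks, c(243L, 122L, 183L, 213L, 228L))
})

test_that("choosing 33333 over dying now stops the search immediately", {
  rk <- rank_states(default_puf())
  res <- run_dead_search(rk, pattern_answers(rep("A", 5)))
  expect_identical(res$bracket$classification, "below_33333")
  expect_length(res$record$choices, 1L)
  expect_identical(res$record$presented_states, "33333")
})

test_that("always preferring dying now walks 243,122,62,32,17 and ends above the mildest", {
  rk <- rank_states(default_puf())
  res <- run_dead_search(rk, pattern_answers(rep("B", 5)))
  expect_identical(res$record$presented_ranks, c(243L, 122L, 62L, 32L, 17L))
  expect_identical(res$bracket$classification, "above_mildest")
  expect_identical(res$bracket$upper_rank, 17L)
})

test_that("every completed five-task search ends with a bracket 15 or 16 ranks wide", {
  rk <- rank_states(default_puf())
  widths <- integer(0)
  for (bits in 0:15) {
    pattern <- c("B", ifelse(bitwAnd(bits, 2^(0:3)) > 0, "A", "B"))
    b <- run_dead_search(rk, pattern_answers(pattern))$bracket
    lower <- if (b$classification == "above_mildest") 1L else b$lower_rank
    widths <- c(widths, b$upper_rank - lower)
  }
  expect_length(widths, 16L)
  expect_true(all(widths %in% c(15L, 16L)))
})

test_that("bracket replay from a stored record matches the live search", {
  rk <- rank_states(random_puf(3))
  for (bits in c(0, 5, 9, 15)) {
    pattern <- c("B", ifelse(bitwAnd(bits, 2^(0:3)) > 0, "A", "B"))
    res <- run_dead_search(rk, pattern_answers(pattern))
    expect_identical(bracket_from_record(res$record), res$bracket)
  }
})

test_that("a noise-free search brackets the latent dead utility", {
  for (seed in 1:8) {
    rp <- random_puf(seed)
    rk <- rank_states(rp)
    set.seed(seed)
    u_star <- runif(1, 0.01, 0.99)
    res <- run_dead_search(rk, function(state) {
      if (predict(rp, state) > u_star) "A" else "B"
    })
    b <- res$bracket
    if (b$classification == "bracketed") {
      expect_gt(rk$utility[b$lower_rank], u_star)
      expect_lte(rk$utility[b$upper_rank], u_star)
    } else if (b$classification == "above_mildest") {
      expect_gte(u_star, rk$utility[b$upper_rank])
      expect_lt(u_star, 1)
    } else {
      expect_lte(u_star, rk$utility[243])
    }
  }
})

test_that("validation pairs never dominate and the first gap exceeds the second", {
  for (seed in 1:25) {
    rp <- random_puf(seed)
    pairs <- generate_validation_pairs(rank_states(rp))
    for (p in pairs) {
      expect_false(dominates(p$option_a, p$option_b))
      expect_false(dominates(p$option_b, p$option_a))
      expect_gte(p$utility_gap, 0)
    }
    expect_gt(pairs[[1]]$utility_gap, pairs[[2]]$utility_gap)
  }
})

test_that("pair-2 gap equals the brute-force minimal non-dominating adjacent gap", {
  for (seed in c(2, 17)) {
    rk <- rank_states(random_puf(seed))
    pairs <- generate_validation_pairs(rk)
    gaps <- vapply(1:242, function(r) {
      a <- rk$state[r]; b <- rk$state[r + 1]
      if (dominates(a, b) || dominates(b, a)) NA_real_
      else rk$utility[r] - rk$utility[r + 1]
    }, numeric(1))
    expect_equal(pairs[[2]]$utility_gap, min(gaps, na.rm = TRUE))
  }
})

test_that("easy pairs present an option A that is crudely less severe than B", {
  cfg <- simulation_config(n_respondents = 40, seed = 5, choice_noise_scale = 0)
  cohort <- simulate_cohort(cfg)
  gap <- vapply(cohort$study$respondents, function(r) {
    p1 <- Filter(function(p) p$task_index == 1, r$pair_choices)[[1]]
    level_sum_score(p1$option_b) - level_sum_score(p1$option_a)
  }, integer(1))
  # quartile-rank targets separate severity by about two level-sum units
  expect_true(all(gap >= 0))
  expect_gt(mean(gap >= 2), 0.5)
  expect_gt(mean(gap), 1.5)
})

test_that("interaction tasks place moderate problems in the opposite-importance dimension", {
  tasks <- generate_interaction_tasks("MO", "AD")
  expect_identical(tasks[[1]]$option_a, list(from = "31111", to = "21111"))
  expect_identical(tasks[[1]]$option_b, list(from = "31112", to = "21112"))
  expect_identical(tasks[[2]]$option_a, list(from = "11113", to = "11112"))
  expect_identical(tasks[[2]]$option_b, list(from = "21113", to = "21112"))

  # swapping most/least swaps the affected digit positions
  swapped <- generate_interaction_tasks("AD", "MO")
  expect_identical(swapped[[1]]$option_a, list(from = "11113", to = "11112"))
  expect_identical(swapped[[1]]$option_b, list(from = "21113", to = "21112"))
  expect_error(generate_interaction_tasks("MO", "MO"), "must differ")
})

test_that("most/least important dimensions come from ranks with rating tie-breaks", {
  ml <- most_least_dimensions(list("PD", c("MO", "AD"), "SC", "UA"),
                              swing = c(90, 70, 60, 100, 95))
  expect_identical(ml$most, "PD")
  expect_identical(ml$least, "UA")
  # tie at the top broken by the higher rating (AD 95 > MO 90)
  ml2 <- most_least_dimensions(list(c("MO", "AD"), "PD", "SC", "UA"),
                               swing = c(90, 70, 60, 80, 95))
  expect_identical(ml2$most, "AD")
  # full tie falls back to the fixed dimension order, keeping most != least
  ml3 <- most_least_dimensions(list(dims))
  expect_identical(ml3$most, "MO")
  expect_identical(ml3$least, "AD")
})

test_that("interaction tallies count on the full respondent denominator", {
  mk <- function(id, t1, t2) {
    ints <- list()
    if (!is.na(t1)) ints <- c(ints, list(interaction_choice(1, t1)))
    if (!is.na(t2)) ints <- c(ints, list(interaction_choice(2, t2)))
    make_record(id = id, interactions = ints)
  }
  recs <- c(
    lapply(1:55, function(i) mk(paste0("a", i), "A", "A")),
    lapply(1:6, function(i) mk(paste0("b", i), "B", "A")),
    lapply(1:14, function(i) mk(paste0("i", i), "indifferent", "B")),
    list(mk("m1", NA, NA))
  )
  tt <- tally_interactions(recs)
  t1 <- tt[tt$task_index == 1, ]
  expect_equal(sum(t1$count), 76)
  expect_equal(t1$count[t1$response == "A"], 55)
  expect_equal(round(t1$percent[t1$response == "A"], 1), 72.4)
  expect_equal(t1$count[t1$response == "missing"], 1)

  empty <- tally_interactions(list())
  expect_true(all(empty$count == 0))

  all_ind <- tally_interactions(lapply(1:4, function(i) mk(paste0("x", i),
                                                           "indifferent",
                                                           "indifferent")))
  expect_equal(all_ind$percent[all_ind$response == "indifferent"], c(100, 100))
})
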