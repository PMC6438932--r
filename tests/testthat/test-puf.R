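test_that("dimension weights are proportional swing ratings summing to 1", {
  expect_equal(unname(dimension_weights(rep(100, 5))), rep(0.2, 5))
  expect_equal(unname(dimension_weights(c(100, 0, 0, 0, 0))), c(1, 0, 0, 0, 0))
  w <- dimension_weights(c(100, 80, 80, 90, 82))
  expect_equal(unname(w), c(100, 80, 80, 90, 82) / 432)
  expect_equal(sum(w), 1)
  expect_error(dimension_weights(rep(0, 5)), "zero")
})

test_that("level-2 decrements follow the configured mapping convention", {
  w <- setNames(rep(0.2, 5), dims)
  # p = 50 is self-dual
  for (m in c("share_of_swing", "remaining_badness")) {
    dec <- level_decrements(w, rep(50, 5), m)
    expect_equal(unname(dec[, "2"]), rep(0.1, 5))
    expect_equal(unname(dec[, "3"]), rep(0.2, 5))
  }
  # p = 100: full swing share vs zero remaining badness
  expect_equal(unname(level_decrements(w, rep(100, 5), "share_of_swing")[, "2"]),
               rep(0.2, 5))
  expect_equal(unname(level_decrements(w, rep(100, 5), "remaining_badness")[, "2"]),
               rep(0, 5))
  # p = 0 under the default: moderate problems cost nothing
  expect_equal(unname(level_decrements(w, rep(0, 5), "share_of_swing")[, "2"]),
               rep(0, 5))
  expect_error(level_decrements(w, rep(50, 5), "inverted"))
})

test_that("state utilities start at 1, lose decrements per level, and hit 0 at 33333", {
  fit <- puf(rep(100, 5), rep(50, 5))
  expect_equal(unname(predict(fit, "11111")), 1)
  expect_equal(unname(predict(fit, "33333")), 0)
  expect_equal(unname(predict(fit, "21111")), 0.9)
  expect_equal(state_utility(fit, "21111"), predict(fit, "21111"))

  for (seed in 1:10) {
    rp <- random_puf(seed)
    expect_equal(unname(predict(rp, "11111")), 1)
    expect_equal(unname(predict(rp, "33333")), 0, tolerance = 1e-12)
    expect_equal(sum(rp$weights), 1, tolerance = 1e-12)
    expect_true(all(rp$decrements[, "2"] >= -1e-15))
    expect_true(all(rp$decrements[, "2"] <= rp$decrements[, "3"] + 1e-15))
  }
})

test_that("worsening one dimension by one level never increases utility", {
  states <- enumerate_states()
  lv <- state_levels(states)
  set.seed(11)
  for (seed in 1:5) {
    rp <- random_puf(sample.int(1e6, 1))
    u <- predict(rp, states)
    for (d in 1:5) {
      can_worsen <- lv[, d] < 3L
      worse <- lv[can_worsen, , drop = FALSE]
      worse[, d] <- worse[, d] + 1L
      worse_codes <- apply(worse, 1, paste, collapse = "")
      expect_true(all(u[worse_codes] <= u[can_worsen] + 1e-12))
    }
  }
})

test_that("dominance implies at least as much utility", {
  states <- enumerate_states()
  set.seed(13)
  rp <- random_puf(99)
  u <- predict(rp, states)
  for (i in 1:300) {
    ab <- sample(states, 2)
    if (dominates(ab[1], ab[2])) {
      expect_true(u[ab[1]] >= u[ab[2]] - 1e-12)
    }
  }
})

test_that("rank_states matches a brute-force sort and breaks ties lexicographically", {
  fit <- puf(rep(100, 5), rep(50, 5))
  rk <- rank_states(fit)
  expect_identical(rk$rank, 1:243)
  expect_identical(rk$state[1], "11111")
  expect_identical(rk$state[243], "33333")
  expect_true(all(diff(rk$utility) <= 1e-12))      # non-increasing
  expect_setequal(rk$state, enumerate_states())    # permutation

  # equal weights, p = 50: "11112" and "21111" tie; lexicographic order wins
  expect_lt(match("11112", rk$state), match("21111", rk$state))

  # oracle: independent sort of enumerate_states by utility then code
  for (seed in c(5, 21)) {
    rp <- random_puf(seed)
    u <- predict(rp, enumerate_states())
    oracle <- names(u)[order(-u, names(u), method = "radix")]
    expect_identical(rank_states(rp)$state, oracle)
  }
})

test_that("puf accessors behave", {
  fit <- puf(c(100, 80, 80, 90, 82), rep(50, 5))
  cf <- coef(fit)
  expect_identical(dim(cf), c(5L, 2L))
  expect_equal(cf[, "3"], fit$weights)
  expect_output(print(fit), "share_of_swing")
  s <- summary(fit)
  expect_equal(s$range, c(0, 1))
})
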