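test_that("adoption and time-to-adoption summaries follow their definitions", {
  res <- list(state = c(2L, 2L, 0L, 1L), t_adopt = c(3L, 5L, NA, NA),
              t_aware = c(1L, 2L, NA, 4L))
  expect_equal(final_adoption(res), 0.5)
  expect_equal(mean_time_to_adoption(res), 4.0)
  expect_equal(final_adoption(list(state = rep(2L, 5), t_adopt = rep(1L, 5))), 1)
  expect_equal(mean_time_to_adoption(list(state = rep(1L, 3),
                                          t_adopt = rep(NA_integer_, 3))),
               NA_real_)
  expect_equal(final_adoption(list(state = rep(0L, 4))), 0)
  expect_error(final_adoption(list(state = integer(0))), "empty")
  # printed headline case: 2044 adopters of 2405
  expect_equal(final_adoption(list(state = rep(c(2L, 0L), c(2044, 361)))),
               2044 / 2405)
})

test_that("conditional mean time-to-adoption matches the geometric oracle", {
  # uniform per-step hazard h over 12 steps: E[T | adopt] by direct sum
  h <- 0.2; T_ <- 12
  pmf <- h * (1 - h)^(0:(T_ - 1))
  exact <- sum((1:T_) * pmf) / sum(pmf)
  set.seed(42)
  nrep <- 200000
  t_adopt <- rep(NA_integer_, nrep)
  alive <- seq_len(nrep)
  for (t in seq_len(T_)) {
    hit <- runif(length(alive)) < h
    t_adopt[alive[hit]] <- t
    alive <- alive[!hit]
  }
  sim <- mean_time_to_adoption(list(t_adopt = t_adopt))
  expect_equal(sim, exact, tolerance = 0.02)
})

test_that("class adoption is an exact stratified recount and permutation invariant", {
  set.seed(31)
  n <- 600
  cls <- sample(1:6, n, replace = TRUE)
  st <- sample(c(0L, 1L, 2L), n, replace = TRUE)
  res <- list(state = st)
  ca <- class_adoption(res, cls)
  for (k in 1:6) expect_equal(ca[k], sum(st == 2 & cls == k) / sum(cls == k))
  perm <- sample(n)
  expect_equal(class_adoption(list(state = st[perm]), cls[perm]), ca)
  expect_error(class_adoption(list(state = st), rep(1L, n)), "empty")
})

test_that("90-10 gap uses linear interpolation between order statistics", {
  expect_equal(gap_90_10(rep(0.7, 6)), 0)
  x <- c(0.6, 0.7, 0.8, 0.9, 1.0, 0.5)
  # type-7 percentiles over 6 points: P10 at order 1.5, P90 at order 5.5
  expect_equal(gap_90_10(x), (0.95 - 0.55) * 100, tolerance = 1e-9)
  for (rep_ in 1:10) {
    v <- runif(6)
    expect_lte(gap_90_10(v), (max(v) - min(v)) * 100 + 1e-12)
  }
  # equal weights reduce the weighted variant to a gap of the same order
  expect_equal(gap_90_10(c(0.5, 0.9), weights = c(1, 1)),
               gap_90_10(c(0.5, 0.9), weights = c(2, 2)))
})

test_that("RDI is the max/min ratio with an infinite degenerate case", {
  expect_equal(rdi(c(0.9, 0.6)), 1.5)
  expect_equal(rdi(rep(0.4, 6)), 1)
  expect_equal(rdi(c(0.868, 0.90, 0.91, 0.88, 0.92, 0.925)), 0.925 / 0.868)
  expect_lt(rdi(c(0.868, 0.90, 0.91, 0.88, 0.92, 0.925)), 1.5)
  expect_equal(rdi(c(0, 0.5)), Inf)
})

test_that("Theil and Atkinson match closed-form hand computations", {
  x <- c(0.9, 0.6); w <- c(1, 1)
  mu <- 0.75
  theil_hand <- 0.5 * (0.9 / mu) * log(0.9 / mu) + 0.5 * (0.6 / mu) * log(0.6 / mu)
  expect_equal(theil_T(x, w), theil_hand, tolerance = 1e-9)
  expect_equal(round(theil_hand, 5), 0.02014)
  atk_hand <- 1 - (0.5 * sqrt(0.9 / mu) + 0.5 * sqrt(0.6 / mu))^2
  expect_equal(atkinson(x, w, 0.5), atk_hand, tolerance = 1e-9)

  expect_equal(theil_T(rep(0.3, 6)), 0)
  expect_equal(atkinson(rep(0.3, 6)), 0)
  # scale invariance
  v <- c(0.2, 0.5, 0.8, 0.4); wt <- c(3, 1, 2, 2)
  expect_equal(theil_T(v * 7, wt), theil_T(v, wt), tolerance = 1e-12)
  expect_equal(atkinson(v * 7, wt), atkinson(v, wt), tolerance = 1e-12)
  # equal weights reduce to the unweighted form
  expect_equal(theil_T(v, rep(2, 4)), theil_T(v), tolerance = 1e-12)
  # mean-preserving spread of two classes increases both indices
  v2 <- c(0.45, 0.55); v3 <- c(0.40, 0.60)
  expect_gt(theil_T(v3), theil_T(v2))
  expect_gt(atkinson(v3), atkinson(v2))
  expect_gte(atkinson(v3), 0); expect_lt(atkinson(v3), 1)
  expect_error(theil_T(c(0.5, 0)), "positive")
  expect_error(atkinson(c(0.5, -0.1)), "positive")
})

test_that("guardrail screening applies the prespecified thresholds", {
  mk <- function(a_min, gap, rdi_) list(a_min = a_min, gap_90_10 = gap, rdi = rdi_)
  g1 <- guardrail_screen(mk(0.868, 5.7, 1.05))
  expect_true(all(g1))
  g2 <- guardrail_screen(mk(0.55, 5.7, 1.05))
  expect_false(g2[["a_min"]]); expect_false(g2[["overall"]])
  g3 <- guardrail_screen(mk(0.868, 5.7, 1.51))
  expect_false(g3[["rdi"]])
  g4 <- guardrail_screen(mk(0.868, 26.0, 1.05))
  expect_false(g4[["gap"]])
  g5 <- guardrail_screen(mk(0.70, 5.7, Inf))
  expect_false(g5[["rdi"]])
})

test_that("the equity report assembles metrics consistently from a result", {
  set.seed(77)
  n <- 1200
  cls <- rep(1:6, each = 200)
  st <- ifelse(runif(n) < c(0.9, 0.8, 0.85, 0.7, 0.95, 0.65)[cls], 2L, 0L)
  rep_ <- equity_report(list(state = st), cls)
  expect_equal(rep_$a_min, min(rep_$class_adoption))
  expect_equal(rep_$rdi, max(rep_$class_adoption) / min(rep_$class_adoption))
  expect_equal(rep_$gap_90_10, gap_90_10(rep_$class_adoption))
  expect_equal(rep_$theil_T, theil_T(rep_$class_adoption, rep_$class_sizes))
  expect_equal(unname(rep_$guardrails[1:3]),
               unname(c(rep_$a_min >= 0.6, rep_$gap_90_10 / 100 <= 0.25,
                        rep_$rdi <= 1.5)))
})

test_that("the synergy index compares a mix against its best single channel", {
  expect_equal(synergy_index(0.931, c(0.943, 0.908)), -1.2, tolerance = 1e-9)
  expect_equal(synergy_index(0.943, c(0.943, 0.908)), 0)
  expect_equal(synergy_index(0.80, c(0.85, 0.90)), -10, tolerance = 1e-9)
  expect_error(synergy_index(0.9, numeric(0)), "single-channel")
})
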