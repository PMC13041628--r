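test_that("percentile intervals follow the linear-interpolation convention", {
  expect_equal(percentile_interval(rep(0.5, 20)), c(0.5, 0.5))
  expect_equal(percentile_interval(1:100), c(3.475, 97.525), tolerance = 1e-9)
  x <- rnorm(31)
  pi_ <- percentile_interval(x)
  expect_lte(pi_[1], median(x)); expect_gte(pi_[2], median(x))
  expect_error(percentile_interval(numeric(0)), "at least one")
})

test_that("rank stability statistics match the Spearman formula", {
  base <- setNames(seq(0.5, by = 0.02, length.out = 15), LETTERS[1:15])
  same <- rank_stability(base, base)
  expect_equal(same$spearman_rho, 1.0)
  expect_equal(same$max_rank_shift, 0)
  expect_true(same$pass)

  rev_ <- rank_stability(base, setNames(rev(unname(base)), names(base)))
  expect_equal(rev_$spearman_rho, -1.0)
  expect_false(rev_$pass)

  # one adjacent swap among 15 distinct values
  swapped <- base
  swapped[c("A", "B")] <- swapped[c("B", "A")]
  st <- rank_stability(base, swapped)
  expect_equal(st$spearman_rho, 1 - 6 * 2 / (15 * (15^2 - 1)), tolerance = 1e-12)
  expect_equal(st$max_rank_shift, 1)
  expect_true(st$pass)

  expect_error(rank_stability(base, base[1:10]), "key sets")
  expect_error(rank_stability(unname(base), base), "named")
})

test_that("scenario runs are deterministic, interval-consistent and control-dominated", {
  set.seed(40)
  pop <- tiny_population(b_step = runif(250, 0.05, 0.25))
  pop$agents$a_tv <- runif(250, 0.2, 1)
  pop$agents$a_dg <- runif(250, 0.1, 0.9)
  pop$agents$class_modal <- rep(1:6, length.out = 250)
  post <- matrix(0, 250, 6); post[cbind(1:250, pop$agents$class_modal)] <- 1
  attr(pop$agents, "posterior") <- post
  pop$task <- "vaccination"
  p <- model_params("vaccination")
  cat_ <- scenario_catalog("vaccination")

  s1 <- run_scenario(pop, cat_$E, p, n_reps = 8, base_seed = 5)
  s2 <- run_scenario(pop, cat_$E, p, n_reps = 8, base_seed = 5)
  expect_equal(s1$adoption$reps, s2$adoption$reps, tolerance = 1e-15)
  expect_lte(s1$adoption$lower, s1$adoption$mean)
  expect_gte(s1$adoption$upper, s1$adoption$mean)

  # n_reps = 1 collapses the interval onto the point
  s3 <- run_scenario(pop, cat_$B, p, n_reps = 1, base_seed = 9)
  expect_equal(s3$adoption$lower, s3$adoption$mean)
  expect_equal(s3$adoption$upper, s3$adoption$mean)

  # background-only control is dominated by every media scenario
  m_A <- run_scenario(pop, cat_$A, p, n_reps = 25, base_seed = 11)$adoption$mean
  for (id in c("B", "C", "D", "E", "H", "J")) {
    m_id <- run_scenario(pop, cat_[[id]], p, n_reps = 25, base_seed = 11)$adoption$mean
    expect_gte(m_id, m_A)
  }

  # agent degree targets feed network regeneration under the I-O policy
  pop$agents$degree_target <- rep(4L, 250)
  s4 <- run_scenario(pop, cat_$J, p, n_reps = 3, base_seed = 2)
  expect_equal(s4$network_policy, "regenerate")
  s5 <- run_scenario(pop, cat_$J, p, n_reps = 3, base_seed = 2)
  expect_equal(s4$adoption$reps, s5$adoption$reps, tolerance = 1e-15)
})

test_that("a variant identical to the baseline is perfectly rank-stable", {
  set.seed(50)
  pop <- tiny_population(b_step = runif(150, 0.05, 0.25))
  pop$agents$a_tv <- runif(150, 0.2, 1)
  pop$agents$a_dg <- runif(150, 0.1, 0.9)
  pop$agents$class_modal <- rep(1:6, 25)
  post <- matrix(0, 150, 6); post[cbind(1:150, pop$agents$class_modal)] <- 1
  attr(pop$agents, "posterior") <- post
  pop$task <- "vaccination"
  pop$net_seed <- 1L
  p <- model_params("vaccination")
  catalog <- scenario_catalog("vaccination")[c("A", "B", "E")]
  run_means <- function(prm) vapply(catalog, function(spec)
    run_scenario(pop, spec, prm, n_reps = 5, base_seed = 3)$adoption$mean,
    numeric(1))
  st <- rank_stability(run_means(p), run_means(p))
  expect_equal(st$spearman_rho, 1)
  expect_equal(st$max_rank_shift, 0)
})

test_that("the sensitivity suite reports stability for every requested axis", {
  set.seed(70)
  pop <- tiny_population(b_step = runif(120, 0.05, 0.3))
  pop$agents$a_tv <- runif(120, 0.2, 1)
  pop$agents$class_modal <- rep(1:6, 20)
  post <- matrix(0, 120, 6); post[cbind(1:120, pop$agents$class_modal)] <- 1
  attr(pop$agents, "posterior") <- post
  pop$task <- "vaccination"
  pop$net_seed <- 9L
  pop$agents$degree_target <- rep(4L, 120)
  p <- model_params("vaccination")
  sens <- sensitivity_suite(pop, p, axes = c("tau", "network_seeds"),
                            n_reps = 4, base_seed = 2,
                            catalog = scenario_catalog("vaccination")[c("A", "B", "J")])
  expect_setequal(names(sens), c("tau", "network_seeds"))
  for (s in sens) {
    expect_true(is.finite(s$spearman_rho))
    expect_gte(s$spearman_rho, -1); expect_lte(s$spearman_rho, 1)
    expect_gte(s$max_rank_shift, 0)
  }
  expect_length(attr(sens, "baseline"), 3)
})

test_that("summaries serialize to JSON and tidy CSV", {
  set.seed(60)
  pop <- tiny_population(b_step = runif(60, 0.1, 0.3))
  pop$agents$class_modal <- rep(1:6, 10)
  post <- matrix(0, 60, 6); post[cbind(1:60, pop$agents$class_modal)] <- 1
  attr(pop$agents, "posterior") <- post
  pop$task <- "vaccination"
  p <- model_params("vaccination")
  summ <- run_catalog(pop, p, scenario_catalog("vaccination")[c("A", "B")],
                      n_reps = 4, base_seed = 8)
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_summaries(summ, jf, cf)
  back <- jsonlite::read_json(jf)
  expect_equal(length(back), 2)
  expect_equal(back$A$n_reps, 4)
  tidy <- read.csv(cf)
  expect_setequal(unique(tidy$metric),
                  c("a_min", "gap_90_10", "rdi", "theil_T", "atkinson"))
  expect_equal(nrow(tidy), 2 * 4 * 5)
})
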