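test_that("Gower distance matches hand computations and is a bounded semimetric", {
  spec <- list(numeric = c(age = 10), categorical = c("sex"))
  a <- list(age = 2, sex = "F"); b <- list(age = 7, sex = "F")
  expect_equal(gower_distance(a, a, spec), 0)
  expect_equal(gower_distance(a, b, spec), (0.5 + 0) / 2)
  expect_equal(gower_distance(a, b, spec), gower_distance(b, a, spec))

  spec4 <- list(numeric = setNames(numeric(0), character(0)),
                categorical = c("v1", "v2", "v3", "v4"))
  x <- list(v1 = "a", v2 = "a", v3 = "a", v4 = "a")
  y <- list(v1 = "b", v2 = "b", v3 = "b", v4 = "b")
  expect_equal(gower_distance(x, y, spec4), 1)

  expect_error(gower_distance(list(age = 1), list(age = 2),
                              list(numeric = c(age = 0), categorical = character(0))),
               "range")
  expect_error(gower_distance(list(a = 1), list(b = 2),
                              list(numeric = c(a = 1), categorical = "b")),
               "missing")
})

test_that("Gower cross-distances agree with cluster::daisy", {
  skip_if_not_installed("cluster")
  set.seed(21)
  df <- data.frame(age = runif(12, 60, 90),
                   sex = sample(c("F", "M"), 12, TRUE),
                   inc = sample(1:4, 12, TRUE))
  df$sex <- factor(df$sex); df$inc <- factor(df$inc)
  D_ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  df2 <- data.frame(age = df$age, sex = as.character(df$sex),
                    inc = as.character(df$inc), stringsAsFactors = FALSE)
  spec <- gower_spec(df2, "age", c("sex", "inc"))
  D <- campaignsim:::gower_cross(df2, df2, spec)
  expect_equal(unname(D), unname(D_ref), tolerance = 1e-9)
})

test_that("nearest-neighbor matching equals the exhaustive-search oracle", {
  set.seed(33)
  mk <- function(n) data.frame(
    id = seq_len(n),
    age = runif(n, 55, 95),
    sex = sample(c("F", "M"), n, TRUE),
    edu = sample(1:4, n, TRUE),
    stringsAsFactors = FALSE)
  recipients <- mk(20); donors <- mk(30)
  spec <- gower_spec(rbind(recipients, donors), "age", c("sex", "edu"))
  map <- match_donors(recipients, donors, spec, chunk = 7L)
  for (i in seq_len(20)) {
    d_all <- vapply(seq_len(30), function(j)
      gower_distance(recipients[i, ], donors[j, ], spec), numeric(1))
    expect_equal(unname(map[i]), which.min(d_all))  # which.min = lowest id on ties
    expect_equal(attr(map, "distance")[i], min(d_all), tolerance = 1e-12)
  }
  # a recipient identical to one donor maps to it at distance 0
  recipients[3, c("age", "sex", "edu")] <- donors[17, c("age", "sex", "edu")]
  map2 <- match_donors(recipients, donors, spec)
  expect_equal(unname(map2[3]), 17)
  expect_equal(attr(map2, "distance")[3], 0)
  # single donor: everyone maps to it
  map3 <- match_donors(recipients, donors[5, , drop = FALSE], spec)
  expect_true(all(map3 == 1))
  expect_error(match_donors(recipients, donors[0, ], spec), "empty donor")
})

test_that("synthetic survey honors class sizes, determinism and configured moments", {
  cfg <- population_config("vaccination")
  s1 <- generate_synthetic_survey(cfg, seed = 91)
  expect_equal(nrow(s1$recipients), 2405)
  expect_equal(tabulate(s1$true_class, 6), c(534L, 430L, 420L, 400L, 376L, 245L))
  s2 <- generate_synthetic_survey(cfg, seed = 91)
  expect_identical(s1$donors, s2$donors)
  expect_identical(s1$recipients, s2$recipients)

  # class-conditional channel-use means on the donor table within +/-0.02
  d <- s1$donors
  for (k in 1:6) {
    sel <- d$true_class == k
    expect_lt(abs(mean(d$a_tv[sel]) - cfg$tv_shape[k, 1] / sum(cfg$tv_shape[k, ])),
              0.02)
    expect_lt(abs(mean(d$a_dg[sel]) - cfg$dg_shape[k, 1] / sum(cfg$dg_shape[k, ])),
              0.02)
  }
  # media-profile ordering: classes 1 and 5 TV-dominant, class 6 digital-dominant
  mtv <- tapply(d$a_tv, d$true_class, mean)
  mdg <- tapply(d$a_dg, d$true_class, mean)
  expect_true(all(mtv[c(1, 5)] > mdg[c(1, 5)]))
  expect_gt(mdg[6], mtv[6])

  # population mean baseline propensity near the calibration target
  expect_lt(abs(mean(s1$recipients$baseline_propensity) - 0.848), 0.02)
  # class-conditional uptake means match the centered configuration (3 sigma)
  for (k in 1:6) {
    sel <- s1$recipients$true_class == k
    se <- sqrt(var(s1$recipients$baseline_propensity[sel]) / sum(sel))
    expect_lt(abs(mean(s1$recipients$baseline_propensity[sel]) -
                    cfg$class_uptake_mean[k]), 3 * se + 0.002)
  }

  # screening task: 5 nonresponses dropped, mean near its target
  cfg_s <- population_config("screening")
  s3 <- generate_synthetic_survey(cfg_s, seed = 91)
  expect_equal(nrow(s3$recipients), 2400)
  expect_lt(abs(mean(s3$recipients$baseline_propensity) - 0.744), 0.02)

  expect_error(population_config("vaccination", class_sizes = c(600, 430, 420, 400, 310, 245)),
               "within")
  expect_error(population_config("vaccination", class_sizes = c(534, 430, 420, 400, 376, 240)),
               "sum|within")
})

test_that("hazard conversion has the stated closed form and round-trips", {
  expect_equal(annual_to_step_hazard(0, 12), 0)
  expect_equal(annual_to_step_hazard(0.5, 1), 0.5)
  h <- annual_to_step_hazard(0.848, 12)
  expect_equal(h, 1 - (1 - 0.848)^(1 / 12), tolerance = 1e-12)
  expect_equal(h, 0.1453, tolerance = 1e-4)
  q <- runif(50)
  expect_equal(1 - (1 - annual_to_step_hazard(q, 12))^12, q, tolerance = 1e-12)
  expect_error(annual_to_step_hazard(1, 12), "0, 1")
})

test_that("agents inherit matched attributes and vanish-media propagates", {
  cfg <- population_config("vaccination")
  s <- generate_synthetic_survey(cfg, seed = 17)
  matched <- match_survey(s)
  expect_equal(nrow(matched), 2405)
  # media block really comes from the matched donor
  i <- 25
  expect_equal(matched$a_tv[i], s$donors$a_tv[matched$donor_id[i]])

  post <- matrix(1 / 6, nrow(matched), 6)
  asg <- structure(list(posterior = post,
                        modal_class = rep(1L, nrow(matched))),
                   class = "lca_assignment")
  agents <- build_agents(matched, asg, "vaccination")
  expect_equal(nrow(agents), 2405)
  expect_false(anyDuplicated(agents$id) > 0)
  expect_equal(agents$b_step, annual_to_step_hazard(matched$baseline_propensity, 12))
  expect_equal(agents$degree_target,
               degree_from_social_activity(matched$social_activity_freq))
  # social activity 5 maps to degree target 10 under the default table
  if (any(matched$social_activity_freq == 5))
    expect_true(all(agents$degree_target[matched$social_activity_freq == 5] == 10))

  # all-zero channel use gives zero media exposure in every scenario
  agents0 <- agents
  agents0$a_tv <- agents0$a_dg <- agents0$a_pr <- 0
  attr(agents0, "posterior") <- post
  p <- model_params("vaccination")
  for (spec in scenario_catalog("vaccination"))
    expect_equal(agent_exposure(spec, agents0, p), rep(0, nrow(agents0)))

  expect_error(build_agents(matched[1:10, ], asg, "vaccination"), "align")
})

test_that("agent tables round-trip through CSV", {
  cfg <- population_config("vaccination", n = 2405L)
  s <- generate_synthetic_survey(cfg, seed = 3)
  matched <- match_survey(s)[1:40, ]
  post <- matrix(runif(240), 40, 6); post <- post / rowSums(post)
  asg <- structure(list(posterior = post, modal_class = max.col(post)),
                   class = "lca_assignment")
  agents <- build_agents(matched, asg, "vaccination")
  path <- tempfile(fileext = ".csv")
  write_agents_csv(agents, path)
  back <- read_agents_csv(path)
  expect_equal(back$b_step, agents$b_step, tolerance = 1e-12)
  expect_equal(attr(back, "posterior"), unname(post), tolerance = 1e-12)
})
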