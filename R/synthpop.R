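#' Configuration of the synthetic matched survey population
#'
#' Defines the study conditions the simulator assumes: six media/social
#' latent classes with fixed sizes, class-conditional channel-use (Beta)
#' distributions, class-conditional baseline annual uptake propensities
#' whose size-weighted mean equals the task target, ordinal social-activity
#' distributions driving offline degree targets, class-conditional
#' demographics used for Gower matching, and categorical indicator items
#' for the latent class model.
#'
#' Defaults: 2405 recipients in classes of sizes (534, 430, 420, 400, 376,
#' 245); for the screening task 5 random recipients are dropped (emulating
#' survey nonresponse, N = 2400). Classes 1 and 5 are television-dominant
#' (channel use Beta(8,2) TV / Beta(2,6) digital), class 6 digital-dominant
#' (reversed), classes 2--4 mixed (Beta(4,4)/Beta(4,4)); print is Beta(2,8)
#' everywhere. Baseline annual uptake class means are spread +/-0.10 around
#' the task target (0.848 vaccination, 0.744 screening) with class 6 lowest
#' for vaccination and class 1 lowest for screening, then centered so the
#' size-weighted mean hits the target exactly.
#'
#' @param task `"vaccination"` or `"screening"`.
#' @param n recipient count before nonresponse (default 2405).
#' @param class_sizes integer vector of 6 class sizes summing to `n`, each
#'   within `[245, 534]`.
#' @param n_donor donor pool size (drawn with class probabilities
#'   proportional to `class_sizes`, wider age range).
#' @param n_nonresponse recipients dropped at random for the screening task.
#' @param uptake_target population mean annual uptake propensity.
#' @param uptake_offsets per-class offsets (before centering) around the
#'   target.
#' @param beta_concentration concentration of the Beta draws for baseline
#'   propensities.
#' @param horizon number of monthly simulation steps (used to convert
#'   annual propensities to per-step hazards).
#' @return a list of class `"population_config"`.
#' @export
population_config <- function(task = c("vaccination", "screening"),
                              n = 2405L,
                              class_sizes = c(534L, 430L, 420L, 400L, 376L, 245L),
                              n_donor = 3000L,
                              n_nonresponse = 5L,
                              uptake_target = NULL,
                              uptake_offsets = NULL,
                              beta_concentration = 30,
                              horizon = 12L) {
  task <- match.arg(task)
  if (length(class_sizes) != 6L) stop("exactly 6 class sizes required")
  if (any(class_sizes < 245L) || any(class_sizes > 534L))
    stop("class sizes must lie within [245, 534]")
  if (sum(class_sizes) != n) stop("class sizes must sum to n")
  if (is.null(uptake_target))
    uptake_target <- if (task == "vaccination") 0.848 else 0.744
  if (is.null(uptake_offsets)) {
    uptake_offsets <- if (task == "vaccination")
      c(0.10, 0.05, 0.02, -0.02, -0.05, -0.10)   # class 6 lowest
    else
      c(-0.10, -0.05, -0.02, 0.02, 0.05, 0.10)   # class 1 lowest
  }
  wts <- class_sizes / sum(class_sizes)
  offsets <- uptake_offsets - sum(wts * uptake_offsets)  # center to target
  class_uptake_mean <- uptake_target + offsets

  # channel-use Beta shapes per class (rows) and channel
  tv_shape <- rbind(c(8, 2), c(4, 4), c(4, 4), c(4, 4), c(8, 2), c(2, 6))
  dg_shape <- rbind(c(2, 6), c(4, 4), c(4, 4), c(4, 4), c(2, 6), c(8, 2))
  pr_shape <- matrix(rep(c(2, 8), each = 6), 6, 2)

  social_activity_probs <- rbind(
    c(0.15, 0.25, 0.30, 0.20, 0.10),
    c(0.10, 0.20, 0.30, 0.25, 0.15),
    c(0.10, 0.20, 0.35, 0.25, 0.10),
    c(0.15, 0.20, 0.30, 0.25, 0.10),
    c(0.05, 0.15, 0.30, 0.30, 0.20),
    c(0.20, 0.30, 0.30, 0.15, 0.05))

  # eight 3-category indicator items; one peak category per class and item
  indicator_items <- c("tv_news", "tv_program", "smartphone_use", "sns_use",
                       "messaging_use", "print_news", "digital_confidence",
                       "community_meeting")
  indicator_peaks <- rbind(
    c(3, 3, 1, 1, 1, 2, 1, 2),   # class 1: TV-heavy, low digital
    c(2, 2, 2, 2, 2, 2, 2, 2),   # class 2: mixed
    c(2, 3, 2, 1, 2, 3, 2, 3),   # class 3: mixed, print/social leaning
    c(3, 2, 2, 2, 3, 1, 2, 1),   # class 4: mixed, messaging leaning
    c(3, 3, 1, 2, 1, 3, 1, 3),   # class 5: TV-heavy, socially active
    c(1, 1, 3, 3, 3, 1, 3, 1))   # class 6: digital-dominant
  indicator_peak_prob <- 0.75

  # classes are strongly demographically structured (age, schooling, income,
  # rurality gradients), which is what makes nearest-neighbor matching on
  # sociodemographics informative about a record's media/social segment
  demographics <- list(
    age_mean = c(79, 70, 74, 68, 76, 66), age_sd = 3,
    donor_age_shift = -4, donor_age_sd = 4.5,
    recipient_age_range = c(65, 95), donor_age_range = c(55, 95),
    p_female = c(0.70, 0.55, 0.60, 0.45, 0.75, 0.40),
    education_probs = rbind(
      c(0.70, 0.20, 0.08, 0.02), c(0.10, 0.55, 0.25, 0.10),
      c(0.25, 0.25, 0.40, 0.10), c(0.05, 0.25, 0.55, 0.15),
      c(0.55, 0.30, 0.10, 0.05), c(0.02, 0.08, 0.35, 0.55)),
    income_probs = rbind(
      c(0.65, 0.25, 0.08, 0.02), c(0.15, 0.50, 0.25, 0.10),
      c(0.30, 0.30, 0.30, 0.10), c(0.08, 0.27, 0.50, 0.15),
      c(0.45, 0.35, 0.15, 0.05), c(0.03, 0.12, 0.35, 0.50)),
    region_probs = rbind(
      c(0.15, 0.25, 0.60), c(0.55, 0.30, 0.15), c(0.35, 0.40, 0.25),
      c(0.65, 0.25, 0.10), c(0.25, 0.25, 0.50), c(0.80, 0.15, 0.05)))

  structure(list(task = task, n = as.integer(n),
                 class_sizes = as.integer(class_sizes),
                 n_donor = as.integer(n_donor),
                 n_nonresponse = as.integer(n_nonresponse),
                 uptake_target = uptake_target,
                 class_uptake_mean = class_uptake_mean,
                 beta_concentration = beta_concentration,
                 tv_shape = tv_shape, dg_shape = dg_shape, pr_shape = pr_shape,
                 social_activity_probs = social_activity_probs,
                 indicator_items = indicator_items,
                 indicator_peaks = indicator_peaks,
                 indicator_peak_prob = indicator_peak_prob,
                 demographics = demographics,
                 horizon = as.integer(horizon)),
            class = "population_config")
}

sample_per_class <- function(classes, probs, values = seq_len(ncol(probs))) {
  out <- integer(length(classes))
  for (k in seq_len(nrow(probs))) {
    sel <- classes == k
    if (any(sel)) out[sel] <- sample(values, sum(sel), replace = TRUE, prob = probs[k, ])
  }
  out
}

trunc_norm <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

#' Generate a synthetic matched-survey population
#'
#' Draws a donor pool (media-panel-like records: demographics, channel-use
#' levels, digital literacy, social activity, categorical indicator items)
#' and a recipient pool (health-survey-like records: demographics, baseline
#' annual uptake propensity and a Bernoulli observed uptake indicator),
#' both with six latent classes as configured. Recipient class sizes are
#' honored exactly; for the screening task `n_nonresponse` random
#' recipients are dropped afterwards. Byte-identical output under a fixed
#' seed.
#'
#' @param config a [population_config()].
#' @param seed integer seed.
#' @return list of class `"synthetic_survey"` with `donors`, `recipients`
#'   (each carrying a `true_class` column -- generator truth, available
#'   only for synthetic data), and the `config`.
#' @export
generate_synthetic_survey <- function(config, seed) {
  stopifnot(inherits(config, "population_config"))
  set.seed(seed)
  dm <- config$demographics

  # ---- donor pool (media panel emulation, aged >= 55) ----
  nd <- config$n_donor
  dclass <- sample(1:6, nd, replace = TRUE, prob = config$class_sizes)
  donors <- data.frame(
    id = seq_len(nd),
    true_class = dclass,
    age = round(trunc_norm(nd, dm$age_mean[dclass] + dm$donor_age_shift,
                           dm$donor_age_sd, dm$donor_age_range[1], dm$donor_age_range[2])),
    sex = ifelse(runif(nd) < dm$p_female[dclass], "F", "M"),
    education = sample_per_class(dclass, dm$education_probs),
    income = sample_per_class(dclass, dm$income_probs),
    region = c("urban", "suburban", "rural")[sample_per_class(dclass, dm$region_probs)],
    a_tv = rbeta(nd, config$tv_shape[dclass, 1], config$tv_shape[dclass, 2]),
    a_dg = rbeta(nd, config$dg_shape[dclass, 1], config$dg_shape[dclass, 2]),
    a_pr = rbeta(nd, config$pr_shape[dclass, 1], config$pr_shape[dclass, 2]),
    social_activity_freq = sample_per_class(dclass, config$social_activity_probs),
    stringsAsFactors = FALSE)
  donors$digital_literacy <- pmin(pmax(donors$a_dg + rnorm(nd, 0, 0.1), 0), 1)
  for (j in seq_along(config$indicator_items)) {
    peaks <- config$indicator_peaks[dclass, j]
    pk <- config$indicator_peak_prob
    probs <- matrix((1 - pk) / 2, nd, 3)
    probs[cbind(seq_len(nd), peaks)] <- pk
    u <- runif(nd)
    cum1 <- probs[, 1]; cum2 <- probs[, 1] + probs[, 2]
    donors[[config$indicator_items[j]]] <- 1L + (u > cum1) + (u > cum2)
  }

  # ---- recipient pool (health survey emulation, aged >= 65) ----
  nr <- config$n
  rclass <- rep(1:6, times = config$class_sizes)
  m <- config$class_uptake_mean[rclass]
  nu <- config$beta_concentration
  prop <- pmin(pmax(rbeta(nr, m * nu, (1 - m) * nu), 0.01), 0.99)
  recipients <- data.frame(
    id = seq_len(nr),
    true_class = rclass,
    age = round(trunc_norm(nr, dm$age_mean[rclass], dm$age_sd,
                           dm$recipient_age_range[1], dm$recipient_age_range[2])),
    sex = ifelse(runif(nr) < dm$p_female[rclass], "F", "M"),
    education = sample_per_class(rclass, dm$education_probs),
    income = sample_per_class(rclass, dm$income_probs),
    region = c("urban", "suburban", "rural")[sample_per_class(rclass, dm$region_probs)],
    baseline_propensity = prop,
    observed_uptake = as.integer(runif(nr) < prop),
    stringsAsFactors = FALSE)

  if (config$task == "screening" && config$n_nonresponse > 0L) {
    drop <- sample(nr, config$n_nonresponse)
    recipients <- recipients[-drop, , drop = FALSE]
    recipients$id <- seq_len(nrow(recipients))
    rownames(recipients) <- NULL
  }

  structure(list(donors = donors, recipients = recipients,
                 true_class = recipients$true_class, config = config,
                 seed = seed),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("Synthetic matched survey (%s): %d recipients, %d donors, 6 classes\n",
              x$config$task, nrow(x$recipients), nrow(x$donors)))
  cat("  recipient class sizes:", paste(tabulate(x$true_class, 6), collapse = " "), "\n")
  cat(sprintf("  mean baseline propensity: %.3f (target %.3f)\n",
              mean(x$recipients$baseline_propensity), x$config$uptake_target))
  invisible(x)
}

#' Match recipients to donors and transfer the media block
#'
#' Runs one-to-one nearest-neighbor Gower matching with replacement on the
#' shared sociodemographic covariates (age, sex, education, income, region,
#' equally weighted) and copies the donor's media block (channel-use
#' levels, digital literacy, social activity, indicator items) onto each
#' recipient.
#'
#' @param survey a `"synthetic_survey"` (or a list with `donors` and
#'   `recipients` data frames exposing the matching covariates).
#' @return the recipient data frame augmented with `donor_id`,
#'   `match_distance` and the donor media columns.
#' @export
match_survey <- function(survey) {
  donors <- survey$donors
  recipients <- survey$recipients
  spec <- gower_spec(rbind(donors[, "age", drop = FALSE],
                           recipients[, "age", drop = FALSE]),
                     numeric_vars = "age",
                     categorical_vars = c("sex", "education", "income", "region"))
  map <- match_donors(recipients, donors, spec)
  media_cols <- c("a_tv", "a_dg", "a_pr", "digital_literacy",
                  "social_activity_freq", survey$config$indicator_items)
  out <- cbind(recipients,
               donor_id = donors$id[map],
               match_distance = attr(map, "distance"),
               donors[map, media_cols, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Convert an annual uptake probability to a per-step hazard
#'
#' Returns `1 - (1 - q)^(1/T)`, the constant per-step hazard that
#' compounds back to the annual probability over `T` steps.
#'
#' @param q_annual annual probability in `[0, 1)`.
#' @param T number of steps per year (12 monthly steps by default).
#' @return per-step hazard in `[0, 1)`.
#' @export
annual_to_step_hazard <- function(q_annual, T = 12L) {
  if (any(q_annual < 0) || any(q_annual >= 1))
    stop("q_annual must lie in [0, 1)")
  if (T < 1L) stop("T must be >= 1")
  1 - (1 - q_annual)^(1 / T)
}

#' Instantiate agents from a matched recipient table
#'
#' Each matched recipient becomes one agent: the channel-use vector and
#' degree target come from the matched donor attributes, the per-step
#' baseline adoption hazard from the recipient's annual baseline
#' propensity, and the class membership (posterior vector plus modal
#' class) from a latent-class assignment.
#'
#' @param matched recipient table augmented by [match_survey()].
#' @param assignment an `"lca_assignment"` aligned with the table rows.
#' @param task `"vaccination"` or `"screening"`.
#' @param horizon steps per year for the hazard conversion.
#' @param degree_map mapping from ordinal social activity to offline degree
#'   targets, see [degree_from_social_activity()].
#' @return a data frame of agents (one row per agent) with the posterior
#'   matrix in attribute `"posterior"`.
#' @export
build_agents <- function(matched, assignment, task, horizon = 12L,
                         degree_map = c(2L, 4L, 6L, 8L, 10L)) {
  if (nrow(matched) != nrow(assignment$posterior))
    stop("assignment rows do not align with the recipient table")
  agents <- data.frame(
    id = matched$id,
    class_modal = assignment$modal_class,
    a_tv = matched$a_tv, a_dg = matched$a_dg, a_pr = matched$a_pr,
    b_step = annual_to_step_hazard(matched$baseline_propensity, horizon),
    baseline_propensity = matched$baseline_propensity,
    observed_uptake = matched$observed_uptake,
    degree_target = degree_from_social_activity(matched$social_activity_freq,
                                                table = degree_map),
    task = task,
    stringsAsFactors = FALSE)
  if (anyDuplicated(agents$id)) stop("agent ids must be unique")
  attr(agents, "posterior") <- assignment$posterior
  agents
}
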