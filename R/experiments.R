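#' Monte Carlo scenario run
#'
#' Runs `n_reps` replications of one scenario. Under the `"fixed"` network
#' policy (scenarios A--H) the population's network pair is reused across
#' replications; under `"regenerate"` (I--O) both layers are regenerated
#' at the start of each replication to reflect structural uncertainty.
#' Replication `r` uses seed `base_seed + r`, so seed-matched runs of
#' different scenarios or parameter variants share common random numbers.
#'
#' @param population a `"campaign_population"`.
#' @param spec a `"scenario_spec"`.
#' @param params a [model_params()].
#' @param n_reps number of Monte Carlo replications.
#' @param base_seed base of the replication seed stream.
#' @param network_policy `"fixed"` or `"regenerate"`; defaults to the
#'   scenario's group policy.
#' @return an object of class `"scenario_summary"` with means, 95%
#'   percentile intervals (2.5th--97.5th) and per-replication vectors for
#'   final adoption, mean time to adoption and awareness, plus mean
#'   class-level adoption and mean equity metrics.
#' @export
run_scenario <- function(population, spec, params, n_reps = 100L,
                         base_seed = 1L, network_policy = NULL) {
  if (is.null(network_policy))
    network_policy <- if (spec$regenerate_networks) "regenerate" else "fixed"
  network_policy <- match.arg(network_policy, c("fixed", "regenerate"))
  modal <- population$agents$class_modal
  adoption <- tta <- awareness <- numeric(n_reps)
  class_mat <- matrix(NA_real_, n_reps, 6L)
  eq_mat <- matrix(NA_real_, n_reps, 5L,
                   dimnames = list(NULL, c("a_min", "gap_90_10", "rdi",
                                           "theil_T", "atkinson")))
  # regenerated layers are memoized per replication seed so seed-matched
  # runs (other scenarios, parameter variants) reuse the same networks:
  # common random numbers across the portfolio comparison
  cache <- population$net_cache
  pop_r <- population
  for (r in seq_len(n_reps)) {
    if (network_policy == "regenerate") {
      net_seed <- base_seed + 100000L + r
      key <- paste0("n", net_seed)
      if (!is.null(cache) && !is.null(cache[[key]])) {
        pop_r$net <- cache[[key]]
      } else {
        pop_r$net <- build_layers(population$agents$degree_target, seed = net_seed)
        if (!is.null(cache)) cache[[key]] <- pop_r$net
      }
    }
    res <- run_simulation(pop_r, spec, params, seed = base_seed + r)
    adoption[r] <- final_adoption(res)
    tta[r] <- mean_time_to_adoption(res)
    awareness[r] <- mean(res$state >= 1L)
    eq <- equity_report(res, modal)
    class_mat[r, ] <- eq$class_adoption
    eq_mat[r, ] <- c(eq$a_min, eq$gap_90_10, eq$rdi, eq$theil_T, eq$atkinson)
  }
  summ <- function(x) {
    pi_ <- percentile_interval(x[!is.na(x)])
    list(mean = mean(x, na.rm = TRUE), lower = pi_[1], upper = pi_[2], reps = x)
  }
  structure(list(scenario = spec$id, name = spec$name, task = params$task,
                 n_reps = as.integer(n_reps), base_seed = base_seed,
                 network_policy = network_policy,
                 adoption = summ(adoption),
                 time_to_adoption = summ(tta),
                 awareness = summ(awareness),
                 class_adoption_mean = colMeans(class_mat),
                 equity_mean = colMeans(eq_mat),
                 equity_reps = eq_mat),
            class = "scenario_summary")
}

#' Run the full scenario catalog
#'
#' @param population a `"campaign_population"`.
#' @param params a [model_params()].
#' @param catalog scenario list (default [scenario_catalog()] for the
#'   population's task).
#' @param n_reps replications per scenario.
#' @param base_seed replication seed base (shared across scenarios for
#'   common random numbers).
#' @return named list of `"scenario_summary"` objects with a tidy
#'   data-frame view in attribute `"table"`.
#' @export
run_catalog <- function(population, params,
                        catalog = scenario_catalog(population$task),
                        n_reps = 100L, base_seed = 1L) {
  out <- lapply(catalog, function(spec)
    run_scenario(population, spec, params, n_reps = n_reps,
                 base_seed = base_seed))
  tab <- do.call(rbind, lapply(out, function(s) data.frame(
    scenario = s$scenario, name = s$name,
    adoption = s$adoption$mean,
    adoption_lo = s$adoption$lower, adoption_hi = s$adoption$upper,
    tta = s$time_to_adoption$mean,
    awareness = s$awareness$mean,
    a_min = s$equity_mean[["a_min"]],
    gap_90_10 = s$equity_mean[["gap_90_10"]],
    rdi = s$equity_mean[["rdi"]],
    stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  attr(out, "table") <- tab
  out
}

#' Empirical percentile interval
#'
#' @param samples numeric vector.
#' @param lo,hi percentile bounds (default 2.5 and 97.5).
#' @return numeric `(lower, upper)` using linear interpolation between
#'   order statistics.
#' @export
percentile_interval <- function(samples, lo = 2.5, hi = 97.5) {
  if (length(samples) == 0L) stop("need at least one sample")
  unname(quantile(samples, c(lo, hi) / 100, type = 7))
}

#' Rank stability between a baseline and a variant scenario ordering
#'
#' @param baseline,variant named numeric vectors of mean adoption per
#'   scenario (same key sets).
#' @param rho_min,max_shift heuristic stability benchmarks (`rho >= 0.90`
#'   and `max |rank change| <= 1` by default).
#' @return an object of class `"stability_result"` with `spearman_rho`,
#'   `max_rank_shift` and the benchmark verdict `pass`.
#' @export
rank_stability <- function(baseline, variant, rho_min = 0.90, max_shift = 1) {
  if (is.null(names(baseline)) || is.null(names(variant)))
    stop("vectors must be named by scenario")
  if (!setequal(names(baseline), names(variant)))
    stop("scenario key sets differ")
  variant <- variant[names(baseline)]
  rho <- cor(baseline, variant, method = "spearman")
  shift <- max(abs(rank(baseline, ties.method = "average") -
                     rank(variant, ties.method = "average")))
  structure(list(spearman_rho = unname(rho), max_rank_shift = unname(shift),
                 pass = rho >= rho_min && shift <= max_shift,
                 baseline = baseline, variant = variant),
            class = "stability_result")
}

#' Sensitivity suite over the prespecified robustness axes
#'
#' Reruns all scenarios under each variant configuration and reports rank
#' stability of the scenario ordering by mean final adoption against the
#' baseline, with common random numbers. Axes: `"link"` (logistic instead
#' of clipped-linear), `"weight_allocation"` (media-centric `beta_m = 1.5,
#' beta_s = 0.1`; social-centric `beta_m = 0.5, beta_s = 0.4`), `"tau"`
#' (reinforcement threshold 1 instead of 2), `"network_seeds"`
#' (alternative random seeds for both network layers).
#'
#' @param population a `"campaign_population"`.
#' @param params baseline (calibrated) [model_params()].
#' @param axes subset of the four axis names.
#' @param n_reps replications per scenario and variant.
#' @param base_seed seed base shared between baseline and variants.
#' @param catalog scenario list.
#' @return named list of `"stability_result"` objects (axis
#'   `weight_allocation` yields two entries), with the baseline mean
#'   vector in attribute `"baseline"`.
#' @export
sensitivity_suite <- function(population, params,
                              axes = c("link", "weight_allocation", "tau",
                                       "network_seeds"),
                              n_reps = 25L, base_seed = 1L,
                              catalog = scenario_catalog(population$task)) {
  axes <- match.arg(axes, several.ok = TRUE)
  mean_vec <- function(pop, prm, seed_off = 0L) {
    vapply(catalog, function(spec)
      run_scenario(pop, spec, prm, n_reps = n_reps,
                   base_seed = base_seed + seed_off)$adoption$mean,
      numeric(1))
  }
  baseline <- mean_vec(population, params)
  out <- list()
  if ("link" %in% axes) {
    prm <- params; prm$link <- "logistic"
    out$link <- rank_stability(baseline, mean_vec(population, prm))
  }
  if ("weight_allocation" %in% axes) {
    prm <- params; prm$beta_m <- 1.5; prm$beta_s <- 0.1
    out$weight_media_centric <- rank_stability(baseline, mean_vec(population, prm))
    prm <- params; prm$beta_m <- 0.5; prm$beta_s <- 0.4
    out$weight_social_centric <- rank_stability(baseline, mean_vec(population, prm))
  }
  if ("tau" %in% axes) {
    prm <- params; prm$tau <- 1L
    out$tau <- rank_stability(baseline, mean_vec(population, prm))
  }
  if ("network_seeds" %in% axes) {
    pop2 <- population
    pop2$net <- build_layers(population$agents$degree_target,
                             seed = population$net_seed + 555L)
    out$network_seeds <- rank_stability(baseline,
                                        mean_vec(pop2, params, seed_off = 333L))
  }
  attr(out, "baseline") <- baseline
  out
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("Scenario %s (%s, %s): %d reps, networks %s\n",
              x$scenario, x$name, x$task, x$n_reps, x$network_policy))
  cat(sprintf("  adoption %.3f [%.3f, %.3f] | TTA %.2f mo | awareness %.3f\n",
              x$adoption$mean, x$adoption$lower, x$adoption$upper,
              x$time_to_adoption$mean, x$awareness$mean))
  cat(sprintf("  A_min %.3f | 90-10 gap %.1f pp | RDI %.3f\n",
              x$equity_mean[["a_min"]], x$equity_mean[["gap_90_10"]],
              x$equity_mean[["rdi"]]))
  invisible(x)
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Rank stability: Spearman rho = %.4f, max rank shift = %g -> %s\n",
              x$spearman_rho, x$max_rank_shift,
              if (x$pass) "stable" else "NOT stable"))
  invisible(x)
}

#' Adoption-curve plot for scenario summaries
#'
#' @param x a `"scenario_summary"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scenario_summary <- function(x, ...) {
  reps <- x$adoption$reps
  graphics::hist(reps, breaks = "FD",
                 main = sprintf("Scenario %s final adoption (%d reps)",
                                x$scenario, x$n_reps),
                 xlab = "Final adoption proportion", ...)
  graphics::abline(v = x$adoption$mean, lwd = 2)
  invisible(x)
}
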