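#' Simulation engine parameters
#'
#' Defaults are the calibrated values for each task (`alpha` 1.15 with
#' `w_bg` 0.12 for vaccination; 1.03 with 0.10 for screening) and the
#' configured behavioral weights: social-awareness weight `omega_a = 0.30`,
#' media adoption weight `beta_m = 1.0`, social-reinforcement weight
#' `beta_s = 0.20` with threshold `tau = 2` adopted neighbors, over a
#' 12-step monthly horizon. The link maps the linear predictor to a
#' probability: `"clipped_linear"` clips to `[0, 1]`; `"logistic"` uses
#' `plogis(gamma0 + gamma1 * L)` with `gamma1 = 4`, `gamma0 = -2`, chosen
#' so both links give 0.5 at `L = 0.5` with matching slope there.
#'
#' Within-phase updates are sequential by default (agents are visited in a
#' fresh random permutation and newly changed states are visible to
#' later-visited agents); `sequential = FALSE` evaluates a phase
#' synchronously from the phase-start state.
#'
#' @param task `"vaccination"` or `"screening"` (sets `alpha`/`w_bg`
#'   defaults).
#' @param alpha baseline propensity multiplier.
#' @param w_bg background exposure weight.
#' @param omega_a social-awareness (spillover) weight.
#' @param beta_m media weight in the adoption predictor.
#' @param beta_s social-reinforcement weight.
#' @param tau adopted-neighbor threshold activating reinforcement.
#' @param link `"clipped_linear"` or `"logistic"`.
#' @param gamma0,gamma1 logistic link coefficients.
#' @param horizon number of monthly steps.
#' @param sequential logical; sequential within-phase updating.
#' @param personalization `"posterior"` (default) or `"modal"` class
#'   weighting for class-dependent scenarios.
#' @return a list of class `"model_params"`.
#' @export
model_params <- function(task = c("vaccination", "screening"),
                         alpha = NULL, w_bg = NULL,
                         omega_a = 0.30, beta_m = 1.0, beta_s = 0.20,
                         tau = 2L, link = c("clipped_linear", "logistic"),
                         gamma0 = -2, gamma1 = 4,
                         horizon = 12L, sequential = TRUE,
                         personalization = c("posterior", "modal")) {
  task <- match.arg(task)
  link <- match.arg(link)
  if (is.null(alpha)) alpha <- if (task == "vaccination") 1.15 else 1.03
  if (is.null(w_bg)) w_bg <- if (task == "vaccination") 0.12 else 0.10
  stopifnot(alpha >= 0, w_bg >= 0, omega_a >= 0, beta_m >= 0, beta_s >= 0,
            tau >= 1, horizon >= 1)
  structure(list(task = task, alpha = alpha, w_bg = w_bg, omega_a = omega_a,
                 beta_m = beta_m, beta_s = beta_s, tau = as.integer(tau),
                 link = link, gamma0 = gamma0, gamma1 = gamma1,
                 horizon = as.integer(horizon), sequential = sequential,
                 personalization = match.arg(personalization)),
            class = "model_params")
}

link_probability <- function(L, params) {
  if (params$link == "clipped_linear") pmin(pmax(L, 0), 1)
  else plogis(params$gamma0 + params$gamma1 * L)
}

#' Per-agent media exposure term of a scenario
#'
#' Computes `sum_c m_c * W_c * a_c` over the three channels, where the
#' weights are resolved per agent (class-personalized for K/L) and `m_c`
#' equals the loss-framing multiplier `k_neg` for TV and digital in
#' scenarios M--O and 1 otherwise (print and background are never framed).
#'
#' @param spec a `"scenario_spec"`.
#' @param agents agent data frame from [build_agents()] (posterior matrix
#'   in attribute `"posterior"`).
#' @param params a [model_params()] (personalization mode).
#' @return numeric vector, one exposure term per agent.
#' @export
agent_exposure <- function(spec, agents, params) {
  posterior <- attr(agents, "posterior")
  W <- effective_agent_weights(spec, posterior, agents$class_modal,
                               mode = params$personalization)
  if (!is.matrix(W)) W <- matrix(W, nrow(agents), 3, byrow = TRUE)
  m <- if (spec$framed) c(spec$k_neg, spec$k_neg, 1) else c(1, 1, 1)
  m[1] * W[, 1] * agents$a_tv + m[2] * W[, 2] * agents$a_dg +
    m[3] * W[, 3] * agents$a_pr
}

#' Awareness transition probability
#'
#' Linear predictor `W_BG + exposure + omega_a * frac_aware_neighbors`
#' passed through the link. `exposure` is the media term from
#' [agent_exposure()] (already including any framing multiplier).
#'
#' @param exposure media exposure term(s).
#' @param frac_aware_neighbors fraction of union-neighborhood members that
#'   are aware (adopters count as aware); 0 for isolated agents.
#' @param params a [model_params()].
#' @param w_bg background weight override (defaults to the params value).
#' @return probability in `[0, 1]` (vectorized).
#' @export
awareness_probability <- function(exposure, frac_aware_neighbors, params,
                                  w_bg = params$w_bg) {
  link_probability(w_bg + exposure + params$omega_a * frac_aware_neighbors,
                   params)
}

#' Adoption transition probability (conditional on awareness)
#'
#' Linear predictor `alpha * b_step + beta_m * exposure + beta_s *
#' I(n_adopted_neighbors >= tau) * frac_adopted_neighbors` through the
#' link: the social-reinforcement term is a complex-contagion component
#' that activates only once at least `tau` neighbors have adopted, and
#' influences adoption but not awareness.
#'
#' @param b_step per-step baseline adoption hazard.
#' @param exposure media exposure term(s).
#' @param n_adopted_neighbors count of adopted union-neighbors.
#' @param frac_adopted_neighbors adopted fraction of the union
#'   neighborhood (0 for isolated agents).
#' @param params a [model_params()].
#' @return probability in `[0, 1]` (vectorized).
#' @export
adoption_probability <- function(b_step, exposure, n_adopted_neighbors,
                                 frac_adopted_neighbors, params) {
  reinf <- ifelse(n_adopted_neighbors >= params$tau, frac_adopted_neighbors, 0)
  link_probability(params$alpha * b_step + params$beta_m * exposure +
                     params$beta_s * reinf, params)
}

engine_call <- function(net, exposure, b_step, params, n_steps, t_start,
                        init_state, init_t_aware, init_t_adopt) {
  .engine_run(net$n, net$adj_ptr, net$adj_nbr,
              as.numeric(exposure), as.numeric(b_step),
              params$alpha, params$w_bg, params$omega_a,
              params$beta_m, params$beta_s, params$tau,
              if (params$link == "clipped_linear") 0L else 1L,
              params$gamma0, params$gamma1,
              as.integer(n_steps), as.integer(t_start),
              isTRUE(params$sequential),
              as.integer(init_state), as.integer(init_t_aware),
              as.integer(init_t_adopt))
}

#' Run one scenario replication
#'
#' Simulates the full horizon from an all-unaware start: at every monthly
#' step, awareness is updated first (background + media + social
#' spillover) over a fresh random agent permutation, then adoption
#' conditional on awareness (baseline propensity + media + threshold
#' reinforcement). Adoption is absorbing. Deterministic given `(seed,
#' inputs)`.
#'
#' @param population a `"campaign_population"` (see [build_population()])
#'   or a list with elements `agents` and `net`.
#' @param spec a `"scenario_spec"`.
#' @param params a [model_params()].
#' @param seed integer seed (optional; the current RNG state is used when
#'   `NULL`).
#' @return an object of class `"sim_result"` with integer vectors
#'   `t_aware` and `t_adopt` (`NA` = never), the final `state` vector, and
#'   the scenario id, task and seed.
#' @export
run_simulation <- function(population, spec, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agents <- population$agents
  n <- nrow(agents)
  exposure <- agent_exposure(spec, agents, params)
  res <- engine_call(population$net, exposure, agents$b_step, params,
                     n_steps = params$horizon, t_start = 1L,
                     init_state = rep(0L, n),
                     init_t_aware = rep(NA_integer_, n),
                     init_t_adopt = rep(NA_integer_, n))
  structure(list(t_aware = res$t_aware, t_adopt = res$t_adopt,
                 state = res$state, scenario = spec$id,
                 task = params$task, seed = seed, n = n),
            class = "sim_result")
}

#' Advance a simulation state by one step
#'
#' Low-level single-step interface (used, for example, to compare the
#' engine against exact Markov-chain enumeration on tiny graphs).
#'
#' @param state integer vector of agent states (0/1/2).
#' @param population population or list with `agents` and `net`.
#' @param spec scenario.
#' @param params parameters.
#' @param t the step label recorded for transitions (default 1).
#' @return list with updated `state`, `t_aware`, `t_adopt`.
#' @export
sim_step <- function(state, population, spec, params, t = 1L) {
  agents <- population$agents
  exposure <- agent_exposure(spec, agents, params)
  engine_call(population$net, exposure, agents$b_step, params,
              n_steps = 1L, t_start = as.integer(t),
              init_state = state,
              init_t_aware = ifelse(state >= 1L, 0L, NA_integer_),
              init_t_adopt = ifelse(state == 2L, 0L, NA_integer_))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Scenario %s (%s): %d agents, %.1f%% adopted, %.1f%% ever aware\n",
              x$scenario, x$task, x$n, 100 * mean(x$state == 2),
              100 * mean(x$state >= 1)))
  invisible(x)
}
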