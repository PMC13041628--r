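#' The 15 prespecified campaign scenarios
#'
#' Builds the scenario catalog A--O for one task:
#' \itemize{
#' \item A: background-only control (no paid media).
#' \item B/C/D: single-channel TV / digital / print at weight 0.10.
#' \item E/F/G: two-channel fixed-sum mixes (0.05 + 0.05).
#' \item H: integrated three-channel mix (0.033 each).
#' \item I/J: low- (0.025 + 0.025) and high-budget (0.200 + 0.200)
#'   variants of the TV + digital mix.
#' \item K: equity-focused reweighting -- the lowest-baseline uptake class
#'   (class 6 for vaccination, class 1 for screening) receives `0.10 +
#'   delta` on one channel; all other classes get symmetric `0.05 -
#'   delta/10` on TV and digital, preserving a class-average TV + digital
#'   budget of exactly 0.10.
#' \item L: class-tailored portfolios -- classes 1 and 5 TV-only (0.10),
#'   class 6 digital-only (0.10), classes 2--4 mixed (0.05 + 0.05).
#' \item M/N/O: loss-framing variants of B/C/E with the TV and digital
#'   exposure terms multiplied by `k_neg`.
#' }
#' Networks are held fixed across replications for A--H and regenerated per
#' replication for I--O.
#'
#' @param task `"vaccination"` or `"screening"`.
#' @param delta equity-reweighting intensity for scenario K, one of 0.02
#'   (default, main analysis) or 0.05 (higher-intensity variant).
#' @param k_neg loss-framing multiplier applied to scenarios M--O (default
#'   1.0; dose-response grids come from [framing_grid()]).
#' @return named list of 15 `"scenario_spec"` objects.
#' @export
scenario_catalog <- function(task = c("vaccination", "screening"),
                             delta = 0.02, k_neg = 1.0) {
  task <- match.arg(task)
  base <- list(
    A = c(0.000, 0.000, 0.000), B = c(0.100, 0.000, 0.000),
    C = c(0.000, 0.100, 0.000), D = c(0.000, 0.000, 0.100),
    E = c(0.050, 0.050, 0.000), F = c(0.050, 0.000, 0.050),
    G = c(0.000, 0.050, 0.050), H = c(0.033, 0.033, 0.033),
    I = c(0.025, 0.025, 0.000), J = c(0.200, 0.200, 0.000),
    M = c(0.100, 0.000, 0.000), N = c(0.000, 0.100, 0.000),
    O = c(0.050, 0.050, 0.000))
  names_ <- c(A = "Control", B = "TV-only", C = "Digital-only",
              D = "Print-only", E = "TV + digital", F = "TV + print",
              G = "Digital + print", H = "All channels", I = "Low-budget",
              J = "High-budget", K = "Equity-focused reweighting",
              L = "Class-tailored channel portfolios",
              M = "TV (loss framing)", N = "Digital (loss framing)",
              O = "TV + digital (loss framing)")
  w_bg <- if (task == "vaccination") 0.12 else 0.10
  out <- list()
  for (id in c(LETTERS[1:15])) {
    spec <- list(id = id, name = unname(names_[id]), task = task,
                 w_bg = w_bg, delta = delta,
                 k_neg = if (id %in% c("M", "N", "O")) k_neg else 1.0,
                 framed = id %in% c("M", "N", "O"),
                 class_dependent = id %in% c("K", "L"),
                 regenerate_networks = id %in% LETTERS[9:15])
    if (!spec$class_dependent) spec$weights <- base[[id]]
    class(spec) <- "scenario_spec"
    out[[id]] <- spec
  }
  out
}

#' Loss-framing intensity grids
#'
#' @param task `"vaccination"` or `"screening"`.
#' @return the ordered `k_neg` grid for the task: vaccination
#'   `(0.95, 1.00, 1.05, 1.10)`, screening `(1.05, 1.10, 1.15, 1.20)`.
#' @export
framing_grid <- function(task = c("vaccination", "screening")) {
  task <- match.arg(task)
  if (task == "vaccination") c(0.95, 1.00, 1.05, 1.10) else c(1.05, 1.10, 1.15, 1.20)
}

#' Channel weights of a scenario for one latent class
#'
#' Resolves the (W_TV, W_DG, W_Print) triple, including the class-dependent
#' rules of scenarios K and L. The loss-framing multiplier is not applied
#' here; it enters the exposure term (see [agent_exposure()]).
#'
#' @param spec a `"scenario_spec"`.
#' @param class_k latent class in `1..6`.
#' @param task task override (defaults to the spec's task).
#' @return numeric triple `(W_TV, W_DG, W_Print)`.
#' @export
weights_for <- function(spec, class_k, task = spec$task) {
  if (class_k < 1 || class_k > 6) stop("class must lie in 1..6")
  if (!spec$class_dependent) return(spec$weights)
  if (spec$id == "K") {
    delta <- spec$delta
    if (!isTRUE(all.equal(delta, 0.02)) && !isTRUE(all.equal(delta, 0.05)))
      stop("delta must be 0.02 or 0.05")
    target_class <- if (task == "vaccination") 6L else 1L
    if (class_k == target_class) {
      if (task == "vaccination") c(0.00, 0.10 + delta, 0.00)
      else c(0.10 + delta, 0.00, 0.00)
    } else {
      c(0.05 - delta / 10, 0.05 - delta / 10, 0.00)
    }
  } else {  # L
    if (class_k %in% c(1L, 5L)) c(0.10, 0.00, 0.00)
    else if (class_k == 6L) c(0.00, 0.10, 0.00)
    else c(0.05, 0.05, 0.00)
  }
}

#' Per-agent effective channel weights
#'
#' Class-personalized weight resolution: in `"modal"` mode the weights of
#' the agent's modal class; in `"posterior"` mode (the default used in the
#' simulations) the posterior-probability-weighted average of the class
#' weights, which propagates classification uncertainty. The two modes
#' coincide for class-independent scenarios and one-hot posteriors.
#'
#' @param spec a `"scenario_spec"`.
#' @param posterior numeric vector of length 6 (one agent) or an `N x 6`
#'   matrix.
#' @param modal modal class (vector), used in `"modal"` mode.
#' @param mode `"posterior"` or `"modal"`.
#' @return weight triple, or an `N x 3` matrix for matrix input.
#' @export
effective_agent_weights <- function(spec, posterior, modal = NULL,
                                    mode = c("posterior", "modal")) {
  mode <- match.arg(mode)
  W <- t(vapply(1:6, function(k) weights_for(spec, k), numeric(3)))  # 6 x 3
  if (is.matrix(posterior)) {
    if (mode == "posterior") return(posterior %*% W)
    return(W[modal, , drop = FALSE])
  }
  if (mode == "posterior") as.vector(posterior %*% W) else W[modal, ]
}

#' Validate scenario budget invariants
#'
#' Checks that all weights are non-negative; that the fixed-budget
#' scenarios B--H (and the framing bases M--O at `k_neg = 1`) sum to 0.10
#' within rounding (`[0.099, 0.101]`); that scenario K's unweighted
#' class-average TV + digital budget equals 0.10 exactly; and that
#' scenario L spends 0.10 in every class. I and J are intentional budget
#' variants and are flagged, not failed.
#'
#' @param catalog a scenario catalog (list) or a single `"scenario_spec"`.
#' @return data frame report with one row per scenario; attribute
#'   `"ok"` is `TRUE` when no violations were found.
#' @export
validate_budget <- function(catalog) {
  if (inherits(catalog, "scenario_spec")) catalog <- list(catalog)
  rows <- lapply(catalog, function(spec) {
    id <- spec$id
    exempt <- id %in% c("A", "I", "J")
    if (!spec$class_dependent) {
      s <- sum(spec$weights)
      ok <- all(spec$weights >= 0) && (exempt || (s >= 0.099 && s <= 0.101))
      note <- if (exempt && id != "A") "intentional budget variant" else ""
      data.frame(scenario = id, budget = s, ok = ok, note = note,
                 stringsAsFactors = FALSE)
    } else {
      W <- t(vapply(1:6, function(k) weights_for(spec, k), numeric(3)))
      per_class <- rowSums(W[, 1:2, drop = FALSE])
      avg <- mean(per_class)
      ok <- all(W >= 0) && abs(avg - 0.10) <= 1e-9
      data.frame(scenario = id, budget = avg, ok = ok,
                 note = "class-average TV + digital budget",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$ok)
  out
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s (%s, %s)\n", x$id, x$name, x$task))
  if (x$class_dependent) {
    W <- t(vapply(1:6, function(k) weights_for(x, k), numeric(3)))
    colnames(W) <- c("W_TV", "W_DG", "W_PR")
    rownames(W) <- paste0("class", 1:6)
    print(round(W, 3))
  } else {
    cat(sprintf("  W_TV=%.3f W_DG=%.3f W_PR=%.3f\n",
                x$weights[1], x$weights[2], x$weights[3]))
  }
  if (x$framed) cat(sprintf("  loss framing k_neg=%.2f (TV/digital only)\n", x$k_neg))
  cat(sprintf("  W_BG=%.2f | networks %s\n", x$w_bg,
              if (x$regenerate_networks) "regenerated per replication" else "fixed"))
  invisible(x)
}
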