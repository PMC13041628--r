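#' Final adoption proportion
#'
#' @param result a `"sim_result"` (or any list with a `state` vector).
#' @return proportion of agents in the adopted state at the end of the
#'   horizon.
#' @export
final_adoption <- function(result) {
  if (length(result$state) == 0L) stop("empty simulation result")
  mean(result$state == 2L)
}

#' Mean time to adoption among adopters
#'
#' @param result a `"sim_result"`.
#' @return arithmetic mean of the adoption step over adopters only, in
#'   months; `NA` when nobody adopted.
#' @export
mean_time_to_adoption <- function(result) {
  t <- result$t_adopt[!is.na(result$t_adopt)]
  if (length(t) == 0L) return(NA_real_)
  mean(t)
}

#' Class-level adoption proportions
#'
#' @param result a `"sim_result"`.
#' @param modal_classes integer vector of modal class labels `1..6`.
#' @return numeric vector of length 6 (class order fixed).
#' @export
class_adoption <- function(result, modal_classes) {
  if (length(modal_classes) != length(result$state))
    stop("class labels do not align with the result")
  sizes <- tabulate(modal_classes, nbins = 6L)
  if (any(sizes == 0L)) stop("empty latent class")
  adopted <- tabulate(modal_classes[result$state == 2L], nbins = 6L)
  adopted / sizes
}

#' 90-10 gap of class-level adoption
#'
#' Difference between the 90th and 10th percentiles of the class-level
#' adoption values, in percentage points. Percentiles use linear
#' interpolation between order statistics (the convention under which the
#' percentiles of `1..100` at 2.5/97.5 are 3.475 and 97.525); an optional
#' class-size-weighted variant interpolates the weighted empirical
#' quantile function.
#'
#' @param class_adoption numeric vector of class-level proportions.
#' @param weights optional class sizes for the weighted variant; default
#'   unweighted across the class values.
#' @return gap in percentage points.
#' @export
gap_90_10 <- function(class_adoption, weights = NULL) {
  if (length(class_adoption) < 2L) stop("need at least two classes")
  if (is.null(weights)) {
    q <- quantile(class_adoption, c(0.10, 0.90), type = 7, names = FALSE)
  } else {
    q <- weighted_quantile(class_adoption, weights, c(0.10, 0.90))
  }
  (q[2] - q[1]) * 100
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2)$y
}

#' Relative disparity index
#'
#' @param class_adoption numeric vector of class-level proportions.
#' @return ratio of maximum to minimum class-level adoption; `Inf` when
#'   the minimum is zero (reported, and failed by the guardrail screen).
#' @export
rdi <- function(class_adoption) {
  mn <- min(class_adoption)
  if (mn == 0) return(Inf)
  max(class_adoption) / mn
}

#' Theil T inequality index
#'
#' `sum_k w_k (x_k / mu) log(x_k / mu)` with population-share weights
#' `w_k = n_k / N` and `mu = sum_k w_k x_k`. Zero iff all values are
#' equal; scale invariant.
#'
#' @param values positive class-level values.
#' @param weights class sizes (equal weights when `NULL`).
#' @return non-negative index.
#' @export
theil_T <- function(values, weights = NULL) {
  if (any(values <= 0)) stop("Theil T requires strictly positive values")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights <= 0)) stop("weights must be positive")
  w <- weights / sum(weights)
  mu <- sum(w * values)
  r <- values / mu
  sum(w * r * log(r))
}

#' Atkinson inequality index
#'
#' `1 - [sum_k w_k (x_k / mu)^(1 - eps)]^(1 / (1 - eps))` with
#' population-share weights; the default inequality aversion is
#' `epsilon = 0.5`. Zero iff all values are equal; bounded in `[0, 1)`.
#'
#' @param values positive class-level values.
#' @param weights class sizes (equal weights when `NULL`).
#' @param epsilon inequality-aversion parameter in `(0, 1)`.
#' @return index in `[0, 1)`.
#' @export
atkinson <- function(values, weights = NULL, epsilon = 0.5) {
  if (any(values <= 0)) stop("Atkinson requires strictly positive values")
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights <= 0)) stop("weights must be positive")
  w <- weights / sum(weights)
  mu <- sum(w * values)
  1 - sum(w * (values / mu)^(1 - epsilon))^(1 / (1 - epsilon))
}

#' Class-level equity report for one simulation result
#'
#' Bundles the class adoption vector with the five distributional metrics:
#' minimum class adoption (A_min), 90-10 gap (unweighted over the six
#' class values by default), relative disparity index, and the
#' descriptive Theil T and Atkinson A_0.5 (class-size weighted by
#' default), plus the guardrail verdicts.
#'
#' @param result a `"sim_result"`.
#' @param modal_classes modal class labels `1..6` per agent.
#' @param thresholds guardrail thresholds `(a_min, gap, rdi)`; see
#'   [guardrail_screen()].
#' @return an object of class `"equity_report"`.
#' @export
equity_report <- function(result, modal_classes,
                          thresholds = c(a_min = 0.60, gap = 0.25, rdi = 1.5)) {
  ca <- class_adoption(result, modal_classes)
  sizes <- tabulate(modal_classes, nbins = 6L)
  pos <- all(ca > 0)
  rep_ <- structure(list(
    class_adoption = ca,
    class_sizes = sizes,
    a_min = min(ca),
    gap_90_10 = gap_90_10(ca),
    rdi = rdi(ca),
    theil_T = if (pos) theil_T(ca, sizes) else NA_real_,
    atkinson = if (pos) atkinson(ca, sizes, 0.5) else NA_real_,
    thresholds = thresholds), class = "equity_report")
  rep_$guardrails <- guardrail_screen(rep_, thresholds)
  rep_
}

#' Screen an equity report against the planning guardrails
#'
#' Prespecified planning benchmarks: minimum class adoption `>= 0.60`,
#' 90-10 gap `<= 25` percentage points, relative disparity index
#' `<= 1.5`. Theil T and Atkinson are descriptive and are not screened.
#'
#' @param report an `"equity_report"` (or list with `a_min`, `gap_90_10`
#'   in percentage points, and `rdi`).
#' @param thresholds named vector `(a_min, gap, rdi)`; `gap` is on the
#'   proportion scale (0.25 = 25 percentage points).
#' @return named logical vector `(a_min, gap, rdi, overall)`.
#' @export
guardrail_screen <- function(report,
                             thresholds = c(a_min = 0.60, gap = 0.25, rdi = 1.5)) {
  v <- c(a_min = report$a_min >= thresholds[["a_min"]],
         gap = report$gap_90_10 / 100 <= thresholds[["gap"]],
         rdi = is.finite(report$rdi) && report$rdi <= thresholds[["rdi"]])
  c(v, overall = all(v))
}

#' Synergy index of a mixed-channel strategy
#'
#' @param mix_adoption adoption under the mixed strategy.
#' @param single_adoptions adoption under the component single-channel
#'   strategies.
#' @return `(mix - max(singles)) * 100`, in percentage points; negative
#'   values indicate dilution relative to the best single channel.
#' @export
synergy_index <- function(mix_adoption, single_adoptions) {
  if (length(single_adoptions) == 0L) stop("need at least one single-channel value")
  (mix_adoption - max(single_adoptions)) * 100
}

#' @export
print.equity_report <- function(x, ...) {
  cat("Class adoption:", paste(sprintf("%.3f", x$class_adoption), collapse = " "), "\n")
  cat(sprintf("A_min %.3f | 90-10 gap %.1f pp | RDI %s | Theil %.5f | Atkinson %.5f\n",
              x$a_min, x$gap_90_10,
              if (is.finite(x$rdi)) sprintf("%.3f", x$rdi) else "Inf",
              x$theil_T, x$atkinson))
  g <- x$guardrails
  cat(sprintf("Guardrails: a_min %s, gap %s, rdi %s -> %s\n",
              ifelse(g[["a_min"]], "pass", "FAIL"),
              ifelse(g[["gap"]], "pass", "FAIL"),
              ifelse(g[["rdi"]], "pass", "FAIL"),
              ifelse(g[["overall"]], "PASS", "FAIL")))
  invisible(x)
}
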