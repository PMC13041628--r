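#' Fit a latent class model to categorical indicator data
#'
#' Fits a finite mixture of independent multinomials ("latent class
#' analysis") by the EM algorithm, restarted from `n_starts` random
#' initializations; the start with the highest log-likelihood is returned.
#' Class-conditional item-response probabilities are floored at `rho_floor`
#' and renormalized each M step to avoid degenerate zero cells.
#'
#' @param data integer matrix or data frame, one row per respondent, one
#'   column per item; entries are category codes `1..M_j`.
#' @param K number of latent classes.
#' @param n_starts number of random EM initializations (Dirichlet(1) draws
#'   for the mixing proportions and every item-response row).
#' @param seed optional seed set before the random starts.
#' @param tol EM convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations per start.
#' @param rho_floor lower bound applied to item-response probabilities.
#' @return an object of class `"lca"` with components
#'   `K`, `mixing_proportions`, `item_response` (per item, a `K x M_j`
#'   matrix), `log_likelihood`, `n_params`, `aic`, `bic`, `entropy_R2`,
#'   `N`, `ll_trace` (log-likelihood path of the winning start) and
#'   `converged`.
#' @examples
#' x <- cbind(sample(1:2, 50, TRUE), sample(1:3, 50, TRUE))
#' m <- fit_lca(x, K = 2, n_starts = 3, seed = 1)
#' summary(m)
#' @export
fit_lca <- function(data, K, n_starts = 10, seed = NULL, tol = 1e-8,
                    max_iter = 1000, rho_floor = 1e-6) {
  x <- as.matrix(data)
  storage.mode(x) <- "integer"
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty indicator data")
  if (anyNA(x) || any(x < 1L)) stop("entries must be positive integer category codes")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  N <- nrow(x); J <- ncol(x)
  if (K < 1L || K > N) stop("K must lie in 1..N")
  M <- apply(x, 2L, max)

  # collapse to unique response patterns; EM cost scales with patterns, not N
  key <- apply(x, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  pat <- x[first, , drop = FALSE]
  w <- as.vector(table(key)[key[first]])
  U <- nrow(pat)
  if (K > U) stop("degenerate model: K exceeds the number of distinct response patterns")

  if (!is.null(seed)) set.seed(seed)

  class_logdens <- function(rho) {
    logf <- matrix(0, U, K)
    for (j in seq_len(J)) logf <- logf + t(log(rho[[j]]))[pat[, j], , drop = FALSE]
    logf
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    pi_k <- rdirichlet1(K)
    rho <- lapply(seq_len(J), function(j) {
      r <- t(replicate(K, rdirichlet1(M[j]), simplify = "matrix"))
      if (K == 1L) r <- matrix(r, 1L, M[j])
      r
    })
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      a <- class_logdens(rho) + rep(log(pmax(pi_k, 1e-300)), each = U)
      mx <- a[cbind(seq_len(U), max.col(a, ties.method = "first"))]
      e <- exp(a - mx)
      rs <- rowSums(e)
      ll <- sum(w * (mx + log(rs)))
      post <- e / rs
      trace <- c(trace, ll)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
      ll_prev <- ll
      # M step
      wp <- post * w
      nk <- colSums(wp)
      pi_k <- nk / N
      for (j in seq_len(J)) {
        cnt <- matrix(0, M[j], K)
        agg <- rowsum(wp, pat[, j])
        cnt[as.integer(rownames(agg)), ] <- agg
        r <- t(cnt) / pmax(nk, 1e-300)
        r <- pmax(r, rho_floor)
        rho[[j]] <- r / rowSums(r)
      }
    }
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, pi = pi_k, rho = rho, trace = trace,
                   converged = converged, post = post)
    }
  }

  item_names <- colnames(x)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  names(best$rho) <- item_names
  n_params <- (K - 1L) + K * sum(M - 1L)
  out <- structure(list(
    K = K,
    mixing_proportions = best$pi,
    item_response = best$rho,
    log_likelihood = best$ll,
    n_params = n_params,
    aic = -2 * best$ll + 2 * n_params,
    bic = -2 * best$ll + n_params * log(N),
    N = N,
    M = M,
    item_names = item_names,
    ll_trace = best$trace,
    converged = best$converged,
    n_starts = n_starts
  ), class = "lca")
  # posterior on the fitting data, expanded back from patterns
  full_post <- best$post[match(key, key[first]), , drop = FALSE]
  out$entropy_R2 <- entropy_R2(full_post)
  out
}

rdirichlet1 <- function(d) {
  g <- stats::rgamma(d, 1)
  g / sum(g)
}

#' Posterior class membership and modal assignment
#'
#' @param object a fitted `"lca"` model.
#' @param newdata categorical matrix with the same items (columns) and
#'   category ranges as the fitting data.
#' @param ... unused.
#' @return a list of class `"lca_assignment"` with `posterior` (`N x K`,
#'   rows sum to 1) and `modal_class` (argmax per row, ties to the lowest
#'   class index).
#' @export
predict.lca <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "integer"
  J <- length(object$item_response)
  if (ncol(x) != J) stop("model items do not match data items")
  for (j in seq_len(J)) {
    if (any(x[, j] < 1L | x[, j] > object$M[j]))
      stop("category codes outside the model's range for item ", j)
  }
  N <- nrow(x); K <- object$K
  a <- matrix(rep(log(pmax(object$mixing_proportions, 1e-300)), each = N), N, K)
  for (j in seq_len(J)) a <- a + t(log(object$item_response[[j]]))[x[, j], , drop = FALSE]
  mx <- a[cbind(seq_len(N), max.col(a, ties.method = "first"))]
  e <- exp(a - mx)
  rs <- rowSums(e)
  if (any(!is.finite(rs) | rs <= 0)) stop("zero total posterior density for some row")
  posterior <- e / rs
  structure(list(posterior = posterior,
                 modal_class = max.col(posterior, ties.method = "first")),
            class = "lca_assignment")
}

#' Entropy-based classification quality of a posterior matrix
#'
#' Computes `1 - sum(-p log p) / (N log K)`, i.e. 1 minus the total Shannon
#' entropy of the posterior rows relative to its maximum. By convention the
#' value is 1 when `K = 1` (classification is trivially certain).
#'
#' @param posterior `N x K` matrix of class-membership probabilities.
#' @return a number in `[0, 1]`; 1 for one-hot rows, 0 for uniform rows.
#' @export
entropy_R2 <- function(posterior) {
  posterior <- as.matrix(posterior)
  K <- ncol(posterior)
  if (K == 1L) return(1)
  p <- posterior[posterior > 0]
  ent <- -sum(p * log(p))
  1 - ent / (nrow(posterior) * log(K))
}

#' Select a latent class model by BIC
#'
#' Returns the model with the minimum BIC; ties are broken toward the
#' smaller class count. AIC and entropy are reported alongside in the
#' comparison table attached as attribute `"comparison"`.
#'
#' @param models list of `"lca"` fits over a range of `K`.
#' @return the selected `"lca"` model.
#' @export
select_lca <- function(models) {
  if (length(models) == 0L) stop("empty model list")
  ks <- vapply(models, function(m) m$K, integer(1))
  bic <- vapply(models, function(m) m$bic, numeric(1))
  ord <- order(bic, ks)
  best <- models[[ord[1L]]]
  attr(best, "comparison") <- data.frame(
    K = ks,
    loglik = vapply(models, function(m) m$log_likelihood, numeric(1)),
    n_params = vapply(models, function(m) m$n_params, numeric(1)),
    aic = vapply(models, function(m) m$aic, numeric(1)),
    bic = bic,
    entropy = vapply(models, function(m) m$entropy_R2, numeric(1))
  )
  best
}

#' Align latent class labels to reference labels
#'
#' Class labels in a mixture are arbitrary. This relabels a fitted
#' assignment so that classes match a reference labeling as closely as
#' possible, by greedy matching on the modal-class confusion matrix
#' (largest cell first).
#'
#' @param assignment an `"lca_assignment"`.
#' @param reference integer vector of reference labels `1..K`, same length
#'   as the assignment.
#' @return the relabeled `"lca_assignment"`, with the label map in
#'   attribute `"label_map"` (`label_map[k]` is the new label of fitted
#'   class `k`).
#' @export
align_lca_classes <- function(assignment, reference) {
  K <- ncol(assignment$posterior)
  if (length(reference) != nrow(assignment$posterior))
    stop("reference length does not match assignment")
  conf <- matrix(0, K, K)
  for (i in seq_along(reference))
    conf[assignment$modal_class[i], reference[i]] <- conf[assignment$modal_class[i], reference[i]] + 1
  map <- integer(K)
  used_r <- used_c <- rep(FALSE, K)
  for (step in seq_len(K)) {
    conf2 <- conf
    conf2[used_r, ] <- -1
    conf2[, used_c] <- -1
    idx <- which(conf2 == max(conf2), arr.ind = TRUE)[1L, ]
    map[idx[1L]] <- idx[2L]
    used_r[idx[1L]] <- TRUE
    used_c[idx[2L]] <- TRUE
  }
  posterior <- assignment$posterior
  new_post <- posterior
  new_post[, map] <- posterior
  out <- structure(list(posterior = new_post,
                        modal_class = map[assignment$modal_class]),
                   class = "lca_assignment")
  attr(out, "label_map") <- map
  out
}

#' @export
print.lca <- function(x, ...) {
  cat(sprintf("Latent class model: K = %d classes, N = %d, %d items\n",
              x$K, x$N, length(x$item_response)))
  cat(sprintf("  logLik %.2f | AIC %.2f | BIC %.2f | entropy %.3f\n",
              x$log_likelihood, x$aic, x$bic, x$entropy_R2))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$mixing_proportions),
                                     collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.lca <- function(object, ...) {
  print(object)
  cat("\nItem-response probabilities (rows = classes):\n")
  for (j in seq_along(object$item_response)) {
    cat(" ", object$item_names[j], "\n")
    print(round(object$item_response[[j]], 3))
  }
  invisible(object)
}

#' @export
logLik.lca <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params,
            nobs = object$N, class = "logLik")
}

#' @export
coef.lca <- function(object, ...) {
  list(mixing_proportions = object$mixing_proportions,
       item_response = object$item_response)
}
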