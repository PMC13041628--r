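#' Write and read agent tables as CSV
#'
#' Column dictionary: `id`, `class_modal` (1..6), `a_tv`/`a_dg`/`a_pr`
#' (channel-use levels in `[0,1]`), `b_step` (per-step baseline hazard),
#' `baseline_propensity` (annual), `observed_uptake` (0/1),
#' `degree_target`, `task`, and the posterior membership columns
#' `post_1..post_6`.
#'
#' @param agents agent data frame from [build_agents()] (posterior matrix
#'   in attribute `"posterior"`).
#' @param path output CSV path.
#' @export
write_agents_csv <- function(agents, path) {
  post <- attr(agents, "posterior")
  out <- cbind(agents, setNames(as.data.frame(post), paste0("post_", 1:6)))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_agents_csv
#' @export
read_agents_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  post_cols <- paste0("post_", 1:6)
  post <- as.matrix(x[, post_cols])
  agents <- x[, setdiff(names(x), post_cols)]
  attr(agents, "posterior") <- unname(post)
  agents
}

#' Serialize a scenario catalog to YAML
#'
#' Writes every scenario's resolved per-class weight table plus the
#' framing, budget and network-policy settings for audit.
#'
#' @param catalog list from [scenario_catalog()].
#' @param path output YAML path.
#' @export
catalog_to_yaml <- function(catalog, path) {
  ser <- lapply(catalog, function(spec) {
    W <- t(vapply(1:6, function(k) weights_for(spec, k), numeric(3)))
    list(id = spec$id, name = spec$name, task = spec$task,
         w_bg = spec$w_bg, k_neg = spec$k_neg, delta = spec$delta,
         regenerate_networks = spec$regenerate_networks,
         class_weights = lapply(seq_len(6), function(k)
           list(class = k, w_tv = W[k, 1], w_dg = W[k, 2], w_pr = W[k, 3])))
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Write per-replication simulation output as CSV
#'
#' @param result a `"sim_result"`.
#' @param agents the agent table of the simulated population.
#' @param path output CSV path.
#' @export
write_sim_csv <- function(result, agents, path) {
  write.csv(data.frame(id = agents$id, class = agents$class_modal,
                       t_aware = result$t_aware, t_adopt = result$t_adopt),
            path, row.names = FALSE)
  invisible(path)
}

#' Write scenario summaries as JSON and tidy equity metrics as CSV
#'
#' @param summaries list from [run_catalog()].
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_summaries <- function(summaries, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    ser <- lapply(summaries, function(s) list(
      scenario = s$scenario, name = s$name, task = s$task, n_reps = s$n_reps,
      adoption = list(mean = s$adoption$mean, lower = s$adoption$lower,
                      upper = s$adoption$upper),
      time_to_adoption = list(mean = s$time_to_adoption$mean),
      awareness = list(mean = s$awareness$mean),
      equity = as.list(s$equity_mean)))
    jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(summaries, function(s) {
      m <- s$equity_reps
      do.call(rbind, lapply(colnames(m), function(metric)
        data.frame(scenario = s$scenario, task = s$task,
                   replication = seq_len(nrow(m)), metric = metric,
                   value = m[, metric], stringsAsFactors = FALSE)))
    }))
    rownames(rows) <- NULL
    write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(summaries)
}

#' Write a latent-class model summary
#'
#' @param model an `"lca"` fit (or a [select_lca()] result, whose
#'   comparison table is included).
#' @param path output path; format by extension (`.json` or `.csv`).
#' @export
write_lca_summary <- function(model, path) {
  info <- list(K = model$K, loglik = model$log_likelihood,
               n_params = model$n_params, aic = model$aic, bic = model$bic,
               entropy = model$entropy_R2,
               mixing_proportions = model$mixing_proportions)
  if (grepl("\\.json$", path)) {
    if (!is.null(attr(model, "comparison")))
      info$comparison <- attr(model, "comparison")
    jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(K = info$K, loglik = info$loglik, n_params = info$n_params,
                     aic = info$aic, bic = info$bic, entropy = info$entropy,
                     t(setNames(info$mixing_proportions, paste0("pi_", seq_len(model$K)))))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
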