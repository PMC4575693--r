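#' Run the full analysis pipeline and write a report bundle
#'
#' Executes, in order: pairwise variable computation, frequency and
#' correlation statistics, discriminant model fit, cross-validation,
#' prediction of unexamined pairs, topology summaries and (when
#' directions are available) laminar correlations. All tables are written
#' as TSV and all test results as JSON; `run_info.json` records seed,
#' package version and input digests so runs are reproducible.
#'
#' @param data list with elements `parcellation`, `table` and optionally
#'   `hierarchy` (named level vector) and `directions` (data.frame) — the
#'   shape returned by [synthetic_connectome()], [synthetic_cat_fixture()]
#'   and [load_fixture()]
#' @param out_dir output directory (created if needed)
#' @param thresholds posterior thresholds for prediction/cross-validation
#' @param theta headline threshold reported in the summary
#' @param seed seed for the cross-validation cycles
#' @param n_cycles cross-validation cycles (default 200)
#' @return invisibly, a list with every computed object
#' @export
run_all <- function(data, out_dir, thresholds = seq(0.60, 0.90, by = 0.05),
                    theta = 0.75, seed = 20140726, n_cycles = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  json <- function(x, name) jsonlite::write_json(
    x, file.path(out_dir, name), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  as_list <- function(rt) rt[c("statistic", "z", "p_value", "n", "method")]

  parc <- data$parcellation
  pv <- pair_variables(parc, hierarchy = data$hierarchy)
  pvs <- join_status(pv, data$table)
  tsv(pvs, "variables.tsv")

  stats <- list()
  freq <- list()
  for (v in c("delta_dist", "abs_type", "abs_level")) {
    rf <- tryCatch(relative_frequencies(pvs, v), error = function(e) NULL)
    cp <- tryCatch(cumulative_percentages(pvs, v), error = function(e) NULL)
    if (is.null(rf) || nrow(rf) < 3) next
    freq[[v]] <- merge(rf, cp[c("value", "cum_pct")], by = "value",
                       all.x = TRUE)
    tsv(freq[[v]], paste0("frequencies_", v, ".tsv"))
    stats[[paste0("relfreq_", v)]] <- as_list(
      spearman_test(rf$rel_freq, rf$value))
  }
  ok_t <- !is.na(pvs$abs_type); ok_l <- !is.na(pvs$abs_level)
  stats$dist_vs_abs_type <- as_list(
    spearman_test(pvs$delta_dist[ok_t], pvs$abs_type[ok_t]))
  if (any(ok_l)) {
    stats$dist_vs_abs_level <- as_list(
      spearman_test(pvs$delta_dist[ok_l], pvs$abs_level[ok_l]))
    ok_b <- ok_t & ok_l
    stats$type_vs_level <- as_list(
      spearman_test(pvs$delta_type[ok_b], pvs$delta_level[ok_b]))
  }
  json(stats, "stats.json")

  grid <- build_grid(pvs)
  tsv(grid, "lda_grid.tsv")
  cases <- construct_cases(grid)
  model <- fit_lda(cases)
  json(list(weights = as.list(model$weights), bias = model$bias,
            standardized_coefficients = as.list(model$standardized_coefficients),
            class_means = apply(model$class_means, 1, as.list),
            n = as.list(model$n)),
       "lda_model.json")
  cv <- cross_validate(cases, thresholds, n_cycles = n_cycles, seed = seed)
  json(c(cv["summary"], cv[c("n_cycles", "holdout", "seed", "redraws")]),
       "crossval.json")
  predictions <- predict_unknown(model, pvs, thresholds)
  tsv(predictions, "predictions.tsv")
  write_matrix_tsv(prediction_status_matrix(predictions, pvs),
                   file.path(out_dir, "prediction_status_matrix.tsv"))

  summ <- node_summaries(data$table, parc, pv)
  tsv(summ, "node_summaries.tsv")
  topo <- list(
    degree_type = lapply(degree_type_correlations(summ, parc), as_list),
    range_trends = {
      rt <- connection_range_trends(summ, parc)
      list(by_type = rt$by_type, jt_short = as_list(rt$jt_short),
           jt_long = as_list(rt$jt_long))
    }
  )
  if (any(!is.na(parc$areas$module))) {
    mc <- module_comparisons(parc)
    topo$modules <- list(
      hub_vs_nonhub = as_list(mc$hub_vs_nonhub),
      medians_hub = as.list(mc$medians_hub),
      kruskal = as_list(mc$kruskal),
      posthoc = mc$posthoc,
      jt_trend = as_list(mc$jt_trend),
      medians_module = as.list(mc$medians_module))
  }
  json(topo, "topology.json")
  rob <- robustness_scan(summ, parc)
  tsv(rob, "robustness.tsv")

  lam <- NULL
  if (!is.null(data$directions) && nrow(data$directions) >= 3) {
    lam <- direction_correlations(data$directions, pv)
    json(list(vs_delta_type = as_list(lam$vs_delta_type),
              vs_delta_level = as_list(lam$vs_delta_level),
              n_used = lam$n_used), "laminar.json")
  }

  json(list(seed = seed, thresholds = thresholds, theta = theta,
            package_version = as.character(utils::packageVersion("connectopred")),
            n_areas = nrow(parc$areas),
            status_counts = as.list(status_counts(data$table)),
            n_predictions_at_theta = n_decided(predictions, theta),
            q_max_significant = attr(rob, "q_max_significant"),
            timestamp = format(Sys.time(), tz = "UTC")),
       "run_info.json")

  invisible(list(pairs = pvs, frequencies = freq, stats = stats,
                 grid = grid, cases = cases, model = model, cv = cv,
                 predictions = predictions, summaries = summ,
                 topology = topo, robustness = rob, laminar = lam))
}
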