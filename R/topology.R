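#' Per-area connectome summaries
#'
#' For every area: in-, out- and total degree over present projections;
#' weighted degree with ordinal strengths mapped to weights 1 (sparse),
#' 10 (intermediate) and 100 (dense), reflecting the roughly exponential
#' spread of real projection densities; per-strength projection counts;
#' the proportions of its present projections that are short range
#' (border distance 1-2) and long range (distance 4-5); and the numbers
#' of examined and unexamined ordered pairs the area takes part in.
#'
#' @param table an (unbinarized) [projection_table()]
#' @param parcellation the matching [parcellation()]
#' @param pairs pair-variables table (default recomputed)
#' @param unknown_areas area set over which unexamined pairs are counted
#'   (default: the typed areas, matching the restriction of the degree
#'   analyses)
#' @return data.frame, one row per area
#' @export
node_summaries <- function(table, parcellation,
                           pairs = pair_variables(parcellation),
                           unknown_areas = typed_areas(parcellation)) {
  areas <- attr(table, "areas")
  pres <- table[table$status != "absent", ]
  wts <- c(sparse = 1, intermediate = 10, dense = 100, present = 1)
  dist_of <- setNames(pairs$delta_dist,
                      paste(pairs$source, pairs$target, sep = "\r"))
  pd <- dist_of[paste(pres$source, pres$target, sep = "\r")]

  one <- function(a) {
    out_i <- pres$source == a
    in_i <- pres$target == a
    inv <- out_i | in_i
    d <- pd[inv]; d <- d[!is.na(d)]
    n_pres <- sum(inv)
    if (n_pres == 0)
      message("area ", a, ": no present projections; range proportions NA")
    data.frame(
      area = a,
      in_degree = sum(in_i), out_degree = sum(out_i),
      degree = n_pres,
      weighted_degree = sum(wts[pres$status[inv]]),
      n_sparse = sum(pres$status[inv] == "sparse"),
      n_intermediate = sum(pres$status[inv] == "intermediate"),
      n_dense = sum(pres$status[inv] == "dense"),
      prop_short = if (length(d)) mean(d %in% 1:2) else NA_real_,
      prop_long = if (length(d)) mean(d %in% 4:5) else NA_real_,
      n_examined = sum(table$source == a | table$target == a),
      n_unknown = NA_integer_
    )
  }
  res <- do.call(rbind, lapply(areas, one))
  # unexamined ordered pairs between each area and the rest of the
  # unknown-universe, both directions
  in_u <- table$source %in% unknown_areas & table$target %in% unknown_areas
  for (i in seq_len(nrow(res))) {
    a <- res$area[i]
    if (!a %in% unknown_areas) { res$n_unknown[i] <- NA_integer_; next }
    n_known <- sum(in_u & (table$source == a | table$target == a))
    res$n_unknown[i] <- 2L * (length(unknown_areas) - 1L) - n_known
  }
  rownames(res) <- NULL
  res
}

#' Rank correlations of node degree measures with structural type
#'
#' Spearman correlations, over typed areas, of degree, weighted degree
#' and each per-strength projection count against structural type.
#'
#' @param summaries a [node_summaries()] result
#' @param parcellation the matching [parcellation()]
#' @param exclude area names to drop (e.g. the hub areas)
#' @return named list of `rank_test` objects: degree, weighted_degree,
#'   n_sparse, n_intermediate, n_dense, n_examined
#' @export
degree_type_correlations <- function(summaries, parcellation, exclude = NULL) {
  df <- merge(summaries, parcellation$areas[c("name", "structural_type")],
              by.x = "area", by.y = "name")
  n_untyped <- sum(is.na(df$structural_type))
  if (n_untyped) message(n_untyped, " untyped area(s) excluded")
  df <- df[!is.na(df$structural_type) & !df$area %in% exclude, ]
  measures <- c("degree", "weighted_degree", "n_sparse", "n_intermediate",
                "n_dense", "n_examined")
  setNames(lapply(measures, function(m)
    spearman_test(df[[m]], df$structural_type)), measures)
}

#' Structural-type comparisons across modules and the hub set
#'
#' Compares structural types between hub and non-hub areas (Wilcoxon
#' rank-sum), across the four functional modules (Kruskal-Wallis with
#' Bonferroni-corrected pairwise post hocs), and along the stated module
#' order visual -> auditory -> somatosensory-motor -> fronto-limbic
#' (Jonckheere-Terpstra, expected decreasing).
#'
#' @param parcellation a [parcellation()] with `module` and `hub` columns
#' @param module_order module order for the trend test
#' @return list: hub_vs_nonhub, medians_hub, kruskal, posthoc (data.frame),
#'   jt_trend, medians_module, n_areas
#' @export
module_comparisons <- function(parcellation,
    module_order = MODULE_LEVELS) {
  a <- parcellation$areas
  a <- a[!is.na(a$structural_type) & !is.na(a$module), ]
  dropped <- nrow(parcellation$areas) - nrow(a)
  if (dropped) message(dropped, " area(s) without type or module excluded")
  groups <- split(a$structural_type, factor(a$module, levels = module_order))
  hub <- a$structural_type[!is.na(a$hub) & a$hub]
  nonhub <- a$structural_type[is.na(a$hub) | !a$hub]
  ph <- pairwise_wilcoxon(groups)
  list(
    hub_vs_nonhub = wilcoxon_rank_sum(hub, nonhub),
    medians_hub = c(hub = median(hub), nonhub = median(nonhub)),
    kruskal = kruskal_wallis(groups),
    posthoc = bonferroni(ph),
    jt_trend = jonckheere_terpstra(groups, alternative = "decreasing"),
    medians_module = vapply(groups, median, 0),
    n_areas = nrow(a)
  )
}

#' Aggregate connection-range profiles by structural type
#'
#' Means of the per-area short- and long-range proportions for each
#' structural type, with Jonckheere-Terpstra trend tests across types
#' 1..5 (short-range proportions expected to increase with type,
#' long-range to decrease).
#'
#' @inheritParams degree_type_correlations
#' @return list: by_type (data.frame of means), jt_short, jt_long
#' @export
connection_range_trends <- function(summaries, parcellation) {
  df <- merge(summaries, parcellation$areas[c("name", "structural_type")],
              by.x = "area", by.y = "name")
  df <- df[!is.na(df$structural_type) & !is.na(df$prop_short), ]
  g_short <- split(df$prop_short, factor(df$structural_type, levels = 1:5))
  g_long <- split(df$prop_long, factor(df$structural_type, levels = 1:5))
  by_type <- data.frame(
    structural_type = 1:5,
    n = lengths(g_short),
    mean_prop_short = vapply(g_short, function(x) mean(x), 0),
    mean_prop_long = vapply(g_long, function(x) mean(x), 0),
    row.names = NULL
  )
  list(by_type = by_type,
       jt_short = jonckheere_terpstra(g_short, "increasing"),
       jt_long = jonckheere_terpstra(g_long, "decreasing"))
}

#' Robustness of the degree-type correlation to undersampling
#'
#' If the unexamined pairs of every area were examined and a proportion
#' `q` of them found present, each area's degree would grow by
#' `q * n_unknown`. The scan recomputes the Spearman correlation of this
#' augmented degree with structural type over a grid of `q` and reports
#' the largest `q` at which the correlation stays significant.
#' Augmented degrees are left fractional (`q * n_unknown` is an
#' expectation).
#'
#' @inheritParams degree_type_correlations
#' @param alpha two-tailed significance level (default 0.05)
#' @param q_grid proportions of unknown projections assumed present
#' @return data.frame (q, rho, p_value) with attribute
#'   `q_max_significant`
#' @export
robustness_scan <- function(summaries, parcellation, alpha = 0.05,
                            q_grid = seq(0, 1, by = 0.01), exclude = NULL) {
  if (!length(q_grid)) stop("empty q grid")
  df <- merge(summaries, parcellation$areas[c("name", "structural_type")],
              by.x = "area", by.y = "name")
  df <- df[!is.na(df$structural_type) & !is.na(df$n_unknown) &
             !df$area %in% exclude, ]
  res <- lapply(q_grid, function(q) {
    st <- spearman_test(df$degree + q * df$n_unknown, df$structural_type)
    data.frame(q = q, rho = st$statistic, p_value = st$p_value)
  })
  out <- do.call(rbind, res)
  sig <- out$q[out$p_value < alpha]
  attr(out, "q_max_significant") <- if (length(sig)) max(sig) else NA_real_
  attr(out, "alpha") <- alpha
  out
}
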