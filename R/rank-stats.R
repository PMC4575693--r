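#' @name rank_stats
#' @title Ordinal statistics for projection analyses
#' @description Rank-based tests used throughout the pipeline. All tests
#'   use average ranks for ties and a two-tailed significance level;
#'   results are returned as `rank_test` objects with fields `statistic`,
#'   `z`, `p_value`, `n` and `method`.
NULL

rank_test <- function(statistic, z = NA_real_, p_value, n, method,
                      estimate = NULL) {
  structure(list(statistic = statistic, z = z, p_value = p_value,
                 n = n, method = method, estimate = estimate),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, z = %.3g, p = %.4g, n = %s\n",
              x$method, x$statistic, x$z, x$p_value, toString(x$n)))
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho as the Pearson correlation of average ranks. For n up to
#' `exact_max` the two-tailed p-value is obtained by exhaustive
#' permutation of one rank vector (valid under ties, unlike the classical
#' exact null tables); for larger n a t-approximation with n-2 degrees of
#' freedom is used.
#'
#' @param x,y equal-length ordinal vectors (n >= 3)
#' @param exact_max largest n for which the exact permutation p is
#'   computed (default 8; 8! = 40,320 permutations)
#' @return a `rank_test` (statistic = rho)
#' @export
spearman_test <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0)
    stop("spearman_test: zero variance in an input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_perms(n)
    rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  rank_test(rho, p_value = p, n = n, method = "Spearman rank correlation")
}

#' Wilcoxon rank-sum test (two groups)
#'
#' Reports the rank sum W of the first group and the tie-corrected
#' standardized z. For small samples (combined n up to `exact_max`) the
#' two-tailed p-value comes from exhaustive enumeration of all group
#' assignments (valid under ties); otherwise from the normal
#' approximation.
#'
#' @param group1,group2 non-empty ordinal vectors
#' @param exact_max largest combined n for the exact enumeration p
#'   (default 8)
#' @return a `rank_test` (statistic = W, the group-1 rank sum)
#' @export
wilcoxon_rank_sum <- function(group1, group2, exact_max = 8L) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  stopifnot(length(group1) > 0, length(group2) > 0)
  n1 <- length(group1); n2 <- length(group2); N <- n1 + n2
  r <- rank(c(group1, group2))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(c(group1, group2))
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (v <= 0) {
    warning("all observations identical; test degenerate")
    return(rank_test(W, 0, 1, c(n1, n2), "Wilcoxon rank sum"))
  }
  z <- (W - mu) / sqrt(v)
  if (N <= exact_max) {
    sets <- combn(N, n1)
    Ws <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  rank_test(W, z, p, c(n1, n2), "Wilcoxon rank sum")
}

#' Kruskal-Wallis test across several groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H,
#' chi-square p on k-1 df) returning a `rank_test`.
#'
#' @param groups list of >= 2 non-empty ordinal vectors
#' @return a `rank_test` (statistic = H)
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0)) stop("kruskal_wallis: empty group")
  if (length(unique(unlist(groups))) == 1) {
    warning("all observations identical; H = 0")
    return(rank_test(0, p_value = 1, n = lengths(groups),
                     method = sprintf("Kruskal-Wallis (df = %d)",
                                      length(groups) - 1L)))
  }
  kt <- kruskal.test(groups)
  rank_test(unname(kt$statistic), p_value = kt$p.value,
            n = lengths(groups),
            method = sprintf("Kruskal-Wallis (df = %d)", kt$parameter))
}

#' Bonferroni adjustment for a family of rank tests
#'
#' Divides the family-wise alpha by the number of comparisons. The
#' denominator is exposed because correction families can legitimately be
#' larger than the reported set of comparisons.
#'
#' @param tests list of `rank_test` objects (e.g. pairwise post hocs)
#' @param alpha family-wise two-tailed level (default 0.05)
#' @param m correction denominator (default: number of tests)
#' @return data.frame with p, corrected alpha, and significance decisions
#' @export
bonferroni <- function(tests, alpha = 0.05, m = length(tests)) {
  p <- vapply(tests, `[[`, 0, "p_value")
  data.frame(
    comparison = names(tests) %||% seq_along(tests),
    p_value = p, alpha_corrected = alpha / m, significant = p < alpha / m
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Wilcoxon post hoc tests
#'
#' All pairwise [wilcoxon_rank_sum()] comparisons among named groups,
#' for use after a significant [kruskal_wallis()].
#'
#' @param groups named list of ordinal vectors
#' @return named list of `rank_test` objects (names `a vs b`)
#' @export
pairwise_wilcoxon <- function(groups) {
  stopifnot(!is.null(names(groups)))
  pairs <- combn(names(groups), 2, simplify = FALSE)
  res <- lapply(pairs, function(p) wilcoxon_rank_sum(groups[[p[1]]], groups[[p[2]]]))
  names(res) <- vapply(pairs, paste, "", collapse = " vs ")
  res
}

# raw JT: over ordered group pairs i < j, pairs (u, v) with u < v plus
# half the ties; with two groups this is the Mann-Whitney U count
jt_count <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    jt <- jt + sum(outer(groups[[i]], groups[[j]], "<")) +
      0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
  }
  jt
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' Tests for a monotone trend across k >= 3 groups given in a stated
#' order. The raw statistic counts, over all ordered group pairs i < j,
#' the pairs of observations (u in group i, v in group j) with u < v,
#' plus half the ties. The reported statistic is the standardized z under
#' the null mean and the no-tie variance; the sign of z follows the
#' observed trend direction. The two-tailed p-value comes from exhaustive
#' enumeration of group assignments for combined n up to `exact_max`, and
#' from the normal approximation otherwise.
#'
#' @param groups ordered list of >= 3 ordinal vectors
#' @param alternative expected direction, recorded in the method label
#'   only (the statistic's sign is observed, not imposed)
#' @param exact_max largest combined n for the exact enumeration p
#'   (default 8)
#' @return a `rank_test` (statistic = z; `estimate` holds the raw JT count)
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing"),
                                exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (length(groups) < 3)
    stop("jonckheere_terpstra needs >= 3 ordered groups; ",
         "use wilcoxon_rank_sum for two groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0)) stop("jonckheere_terpstra: empty group")
  jt <- jt_count(groups)
  ni <- lengths(groups); N <- sum(ni)
  mu <- (N^2 - sum(ni^2)) / 4
  v <- (N^2 * (2 * N + 3) - sum(ni^2 * (2 * ni + 3))) / 72
  z <- (jt - mu) / sqrt(v)
  if (N <= exact_max) {
    jts <- jt_assignment_distribution(unlist(groups), ni)
    p <- mean(abs(jts - mu) >= abs(jt - mu) - 1e-12)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  rank_test(z, z, p, ni,
            sprintf("Jonckheere-Terpstra (%s)", alternative), estimate = jt)
}

# JT counts over every distinct assignment of the pooled observations to
# groups of the given sizes (all equally likely under the null)
jt_assignment_distribution <- function(pool, sizes) {
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1) return(list(list(pool[avail])))
    out <- list()
    for (p in combn(avail, sizes[1], simplify = FALSE)) {
      rest <- recurse(setdiff(avail, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(pool[p]), r)))
    }
    out
  }
  vapply(recurse(seq_along(pool), sizes), jt_count, 0)
}

#' Cumulative percentage of present projections over a variable
#'
#' For each value of the chosen anatomical variable, the number of
#' present projections found up to and including that value, divided by
#' the total number of present projections, times 100. Absent and unknown
#' pairs play no role.
#'
#' @param pairs pair-variables table with a binarized `status` column
#'   (see [join_status()])
#' @param variable one of `"delta_dist"`, `"abs_type"`, `"abs_level"`
#' @return data.frame: value, n_present, cum_pct (non-decreasing, ends at 100)
#' @export
cumulative_percentages <- function(pairs,
    variable = c("delta_dist", "abs_type", "abs_level")) {
  variable <- match.arg(variable)
  v <- pairs[[variable]][pairs$status == "present"]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no present projections with ", variable, " defined")
  tab <- table(v)
  data.frame(
    variable = variable,
    value = as.integer(names(tab)),
    n_present = as.integer(tab),
    cum_pct = 100 * cumsum(as.integer(tab)) / length(v),
    row.names = NULL
  )
}

#' Relative frequency of present projections over a variable
#'
#' For each value of the chosen variable: the number of present
#' projections divided by the number of *examined* (absent + present)
#' projections at that value. Unknown pairs are excluded from numerator
#' and denominator; value classes with no examined pairs are omitted with
#' a warning.
#'
#' @inheritParams cumulative_percentages
#' @return data.frame: value, n_present, n_absent, rel_freq
#' @export
relative_frequencies <- function(pairs,
    variable = c("delta_dist", "abs_type", "abs_level")) {
  variable <- match.arg(variable)
  df <- pairs[pairs$status %in% c("present", "absent") &
                !is.na(pairs[[variable]]), ]
  values <- sort(unique(pairs[[variable]][!is.na(pairs[[variable]])]))
  np <- vapply(values, function(v)
    sum(df[[variable]] == v & df$status == "present"), 0L)
  na_ <- vapply(values, function(v)
    sum(df[[variable]] == v & df$status == "absent"), 0L)
  empty <- np + na_ == 0L
  if (any(empty))
    warning("no examined projections at ", variable, " = ",
            toString(values[empty]), "; row(s) omitted")
  data.frame(
    variable = variable,
    value = values[!empty],
    n_present = np[!empty],
    n_absent = na_[!empty],
    rel_freq = (np / (np + na_))[!empty],
    row.names = NULL
  )
}
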