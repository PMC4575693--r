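#' Co-occurrence-normalized grid over (|type difference|, border distance)
#'
#' Not all combinations of the two predictors can occur equally often in a
#' given parcellation (small type differences at short distances are
#' frequent; extreme combinations are rare). The grid therefore normalizes
#' the observed numbers of absent and present projections per combination
#' by the maximally possible number of co-occurrences of that combination
#' among ordered typed-area pairs, yielding percentages
#' `pct_absent` and `pct_present`. Their sum is at most 100; the
#' remainder is the share of pairs never examined.
#'
#' @param pairs pair-variables table with binarized `status`
#'   (see [join_status()])
#' @return data.frame of class `lda_grid`: abs_type, delta_dist,
#'   n_possible, n_absent, n_present, pct_absent, pct_present
#' @export
build_grid <- function(pairs) {
  df <- pairs[!is.na(pairs$abs_type) & !is.na(pairs$delta_dist), ]
  key <- interaction(df$abs_type, df$delta_dist, drop = FALSE)
  cells <- unique(df[c("abs_type", "delta_dist")])
  cells <- cells[order(cells$abs_type, cells$delta_dist), ]
  count <- function(sub) {
    k <- paste(sub$abs_type, sub$delta_dist)
    tab <- table(factor(k, levels = paste(cells$abs_type, cells$delta_dist)))
    as.integer(tab)
  }
  n_possible <- count(df)
  n_absent <- count(df[df$status == "absent", ])
  n_present <- count(df[df$status == "present", ])
  if (any(n_possible == 0 & (n_absent > 0 | n_present > 0)))
    stop("observed projections in a combination with zero possible pairs")
  out <- data.frame(
    abs_type = cells$abs_type, delta_dist = cells$delta_dist,
    n_possible = n_possible, n_absent = n_absent, n_present = n_present,
    pct_absent = 100 * n_absent / n_possible,
    pct_present = 100 * n_present / n_possible,
    row.names = NULL
  )
  class(out) <- c("lda_grid", "data.frame")
  out
}

# nearest integer, halves up ("n = %" leaves fractional counts unspecified)
round_half_up <- function(x) floor(x + 0.5)

#' Expand a normalized grid into discriminant-analysis cases
#'
#' Per grid cell, creates `round(pct_absent)` cases labelled absent and
#' `round(pct_present)` cases labelled present (halves rounded up), each
#' carrying the cell's predictor values. This re-weights the examined
#' projections by how thoroughly each region of the predictor space was
#' sampled.
#'
#' @param grid an [build_grid()] result
#' @return data.frame: abs_type, delta_dist, label (factor absent/present)
#' @export
construct_cases <- function(grid) {
  n_a <- round_half_up(grid$pct_absent)
  n_p <- round_half_up(grid$pct_present)
  idx <- rep(seq_len(nrow(grid)), n_a + n_p)
  label <- unlist(Map(function(a, p) rep(c("absent", "present"), c(a, p)),
                      n_a, n_p), use.names = FALSE)
  data.frame(
    abs_type = grid$abs_type[idx],
    delta_dist = grid$delta_dist[idx],
    label = factor(label, levels = c("absent", "present")),
    cell = idx
  )
}

#' Fit the two-class linear discriminant model
#'
#' Classic LDA with shared (pooled, bias-corrected) within-class
#' covariance and uniform class priors. With two Gaussian classes of
#' common covariance S and means m0 (absent), m1 (present), the posterior
#' probability of presence is `plogis(w.x + b)` with
#' `w = solve(S, m1 - m0)` and `b = -w.(m1 + m0)/2` (uniform priors
#' contribute no offset). Standardized coefficients are reported as
#' magnitudes `|w_j| * s_j`, with `s_j` the pooled within-class standard
#' deviation of predictor j.
#'
#' @param cases a [construct_cases()] result (or any data.frame with
#'   numeric predictors and a two-level `label` factor with levels
#'   `absent`, `present`)
#' @param predictors predictor column names (default the two used by the
#'   connectome model)
#' @return object of class `connectome_lda`
#' @export
fit_lda <- function(cases, predictors = c("abs_type", "delta_dist")) {
  X <- as.matrix(cases[predictors])
  y <- cases$label
  if (nlevels(droplevels(y)) < 2) stop("fit_lda: one class is empty")
  m0 <- colMeans(X[y == "absent", , drop = FALSE])
  m1 <- colMeans(X[y == "present", , drop = FALSE])
  n0 <- sum(y == "absent"); n1 <- sum(y == "present")
  S <- ((n0 - 1) * cov_or_zero(X[y == "absent", , drop = FALSE]) +
        (n1 - 1) * cov_or_zero(X[y == "present", , drop = FALSE])) /
       (n0 + n1 - 2)
  if (rcond_sym(S) < 1e-12)
    S <- S + diag(1e-8 * sum(diag(S)), ncol(S))
  if (rcond_sym(S) < 1e-12)
    stop(sprintf("pooled covariance singular (rcond = %.3g)", rcond_sym(S)))
  w <- solve(S, m1 - m0)
  b <- -sum(w * (m1 + m0) / 2)
  structure(list(
    class_means = rbind(absent = m0, present = m1),
    pooled_covariance = S,
    weights = w, bias = b,
    standardized_coefficients = abs(w) * sqrt(diag(S)),
    priors = c(absent = 0.5, present = 0.5),
    predictors = predictors,
    n = c(absent = n0, present = n1)
  ), class = "connectome_lda")
}

cov_or_zero <- function(X) {
  if (nrow(X) < 2) matrix(0, ncol(X), ncol(X)) else stats::cov(X)
}

rcond_sym <- function(S) {
  ev <- abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (max(ev) == 0) 0 else min(ev) / max(ev)
}

#' @export
print.connectome_lda <- function(x, ...) {
  cat("two-class linear discriminant model (uniform priors)\n")
  cat("  weights:", toString(sprintf("%s = %.4f", x$predictors, x$weights)), "\n")
  cat("  standardized coefficients:",
      toString(sprintf("%s = %.3f", x$predictors,
                       x$standardized_coefficients)), "\n")
  cat("  cases:", toString(sprintf("%s = %d", names(x$n), x$n)), "\n")
  invisible(x)
}

#' Posterior probability of projection presence
#'
#' @param object a [fit_lda()] model
#' @param newdata data.frame containing the model's predictor columns
#' @param ... unused
#' @return numeric vector of posterior probabilities in (0, 1)
#' @export
predict.connectome_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictors])
  plogis(drop(X %*% object$weights) + object$bias)
}

#' Threshold rule for posterior classification
#'
#' @param posterior posterior presence probabilities
#' @param theta classification threshold in (0.5, 1): `present` if
#'   posterior >= theta, `absent` if posterior <= 1 - theta, otherwise
#'   `unclassified`
#' @return character vector of decisions
#' @export
classify_posterior <- function(posterior, theta) {
  stopifnot(theta > 0.5, theta < 1)
  out <- rep("unclassified", length(posterior))
  out[posterior >= theta] <- "present"
  out[posterior <= 1 - theta] <- "absent"
  out[is.na(posterior)] <- NA
  out
}

#' Holdout cross-validation of the discriminant model
#'
#' Repeatedly holds out a random 10% of the constructed cases, refits on
#' the remainder and classifies the held-out cases at each threshold.
#' Unclassified cases are excluded from the accuracy denominators.
#'
#' @param cases a [construct_cases()] result
#' @param thresholds posterior thresholds (default 0.60 to 0.90 by 0.05)
#' @param n_cycles number of cycles (default 200)
#' @param holdout held-out fraction (default 0.10)
#' @param seed RNG seed (logged in the result)
#' @param max_redraws cap on re-drawn degenerate holdouts
#' @return object of class `connectome_cv`: per-threshold means and SDs of
#'   accuracy for predicted-present, predicted-absent and overall, and the
#'   mean number of classified test cases
#' @export
cross_validate <- function(cases, thresholds = seq(0.60, 0.90, by = 0.05),
                           n_cycles = 200, holdout = 0.10,
                           seed = 20140726, max_redraws = 1000) {
  set.seed(seed)
  n <- nrow(cases)
  n_test <- max(1L, round(holdout * n))
  acc <- array(NA_real_, c(n_cycles, length(thresholds), 4),
               dimnames = list(NULL, sprintf("%.2f", thresholds),
                               c("present", "absent", "overall", "n_classified")))
  redraws <- 0L
  for (cy in seq_len(n_cycles)) {
    repeat {
      test_idx <- sample.int(n, n_test)
      train <- cases[-test_idx, ]
      if (nlevels(droplevels(train$label)) == 2) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) stop("too many degenerate holdout draws")
    }
    model <- fit_lda(train)
    post <- predict(model, cases[test_idx, ])
    truth <- as.character(cases$label[test_idx])
    for (ti in seq_along(thresholds)) {
      dec <- classify_posterior(post, thresholds[ti])
      cls <- dec != "unclassified"
      acc[cy, ti, "n_classified"] <- sum(cls)
      if (any(dec == "present"))
        acc[cy, ti, "present"] <- mean(truth[dec == "present"] == "present")
      if (any(dec == "absent"))
        acc[cy, ti, "absent"] <- mean(truth[dec == "absent"] == "absent")
      if (any(cls))
        acc[cy, ti, "overall"] <- mean(truth[cls] == dec[cls])
    }
  }
  summ <- data.frame(
    theta = thresholds,
    acc_present_mean = colMeans(acc[, , "present"], na.rm = TRUE),
    acc_present_sd = apply(acc[, , "present"], 2, sd, na.rm = TRUE),
    acc_absent_mean = colMeans(acc[, , "absent"], na.rm = TRUE),
    acc_absent_sd = apply(acc[, , "absent"], 2, sd, na.rm = TRUE),
    acc_overall_mean = colMeans(acc[, , "overall"], na.rm = TRUE),
    acc_overall_sd = apply(acc[, , "overall"], 2, sd, na.rm = TRUE),
    n_classified_mean = colMeans(acc[, , "n_classified"]),
    row.names = NULL
  )
  structure(list(summary = summ, n_cycles = n_cycles, holdout = holdout,
                 seed = seed, redraws = redraws),
            class = "connectome_cv")
}

#' @export
print.connectome_cv <- function(x, ...) {
  cat(sprintf("cross-validation: %d cycles, %.0f%% holdout, seed %d\n",
              x$n_cycles, 100 * x$holdout, x$seed))
  print(format(x$summary, digits = 3))
  invisible(x)
}

#' Predict the status of unexamined projections
#'
#' Applies the fitted posterior to every unknown-status ordered pair with
#' defined predictors and records the decision at each threshold. Pairs
#' with undefined predictors are left out (no prediction possible).
#'
#' @param model a [fit_lda()] model
#' @param pairs pair-variables table with binarized `status`
#' @param thresholds posterior thresholds (default 0.60 to 0.90 by 0.05)
#' @return data.frame of class `prediction_matrix`: source, target,
#'   abs_type, delta_dist, posterior, and one decision column per
#'   threshold (`decision_0.75`, ...)
#' @export
predict_unknown <- function(model, pairs,
                            thresholds = seq(0.60, 0.90, by = 0.05)) {
  unk <- pairs[pairs$status == "unknown" &
                 !is.na(pairs$abs_type) & !is.na(pairs$delta_dist), ]
  out <- unk[c("source", "target", "abs_type", "delta_dist")]
  out$posterior <- predict(model, unk)
  for (th in thresholds)
    out[[sprintf("decision_%.2f", th)]] <- classify_posterior(out$posterior, th)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  class(out) <- c("prediction_matrix", "data.frame")
  out
}

#' Count decided predictions at a threshold
#' @param predictions a [predict_unknown()] result
#' @param theta threshold present in the prediction matrix
#' @return number of pairs decided present or absent at `theta`
#' @export
n_decided <- function(predictions, theta) {
  col <- sprintf("decision_%.2f", theta)
  stopifnot(col %in% names(predictions))
  sum(predictions[[col]] != "unclassified")
}

#' Status-code matrix combining known statuses and predictions
#'
#' Mirrors the published connectivity-matrix figure semantics: known
#' statuses pass through; unexamined pairs carry the prediction made at
#' the most conservative threshold they survived, or `unclassified`;
#' pairs without predictors stay `unknown`.
#'
#' @param predictions a [predict_unknown()] result
#' @param pairs pair-variables table with binarized `status`
#' @return character matrix (rows = sources, columns = targets) with codes
#'   `known-absent`, `known-present`, `pred-absent@t`, `pred-present@t`,
#'   `unclassified`, `unknown`
#' @export
prediction_status_matrix <- function(predictions, pairs) {
  areas <- sort(unique(c(pairs$source, pairs$target)))
  m <- matrix(NA_character_, length(areas), length(areas),
              dimnames = list(areas, areas))
  known <- pairs$status != "unknown"
  m[cbind(pairs$source[known], pairs$target[known])] <-
    paste0("known-", pairs$status[known])
  m[cbind(pairs$source[!known], pairs$target[!known])] <- "unknown"
  ths <- attr(predictions, "thresholds")
  code <- rep("unclassified", nrow(predictions))
  for (th in sort(ths)) {  # ascending: most conservative surviving wins
    dec <- predictions[[sprintf("decision_%.2f", th)]]
    sel <- dec != "unclassified"
    code[sel] <- sprintf("pred-%s@%.2f", dec[sel], th)
  }
  m[cbind(predictions$source, predictions$target)] <- code
  m
}
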