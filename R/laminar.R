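#' Correlate laminar projection directions with type and level differences
#'
#' Projection directions summarize laminar origin/termination patterns as
#' an ordinal code: ascending = 1, lateral = 2, descending = 3. With this
#' coding a hierarchy built from the directions yields a *positive*
#' correlation of direction with level difference, and projections from
#' more- to less-differentiated areas (positive type difference) being
#' descending drives a *negative* correlation with type difference.
#' Reversing the coding exactly negates every correlation.
#'
#' Directions classified as unreliable in the source data are included by
#' default (their assigned category is still the best available
#' information); set `include_unreliable = FALSE` to drop them.
#'
#' @param directions data.frame with columns `source`, `target`,
#'   `direction` (one of `ascending`/`lateral`/`descending` or the codes
#'   `A`/`L`/`D`) and optionally `reliable` (logical)
#' @param pairs pair-variables table (for `delta_type`, `delta_level`)
#' @param include_unreliable keep unreliable classifications? (default TRUE)
#' @return list: vs_delta_type, vs_delta_level (`rank_test` objects),
#'   n_skipped_type, n_skipped_level (projections lacking the variable)
#' @export
direction_correlations <- function(directions, pairs,
                                   include_unreliable = TRUE) {
  dmap <- c(A = 1, L = 2, D = 3, ascending = 1, lateral = 2, descending = 3)
  stopifnot(all(directions$direction %in% names(dmap)))
  if (!include_unreliable && "reliable" %in% names(directions))
    directions <- directions[directions$reliable, ]
  key <- paste(directions$source, directions$target, sep = "\r")
  pkey <- paste(pairs$source, pairs$target, sep = "\r")
  m <- match(key, pkey)
  if (anyNA(m)) stop("direction record for unknown area pair")
  code <- unname(dmap[directions$direction])
  dt <- pairs$delta_type[m]
  dl <- pairs$delta_level[m]
  n_skip_t <- sum(is.na(dt)); n_skip_l <- sum(is.na(dl))
  if (n_skip_t) message(n_skip_t, " projection(s) without delta_type skipped")
  if (n_skip_l) message(n_skip_l, " projection(s) without delta_level skipped")
  list(
    vs_delta_type = spearman_test(code[!is.na(dt)], dt[!is.na(dt)]),
    vs_delta_level = spearman_test(code[!is.na(dl)], dl[!is.na(dl)]),
    n_skipped_type = n_skip_t,
    n_skipped_level = n_skip_l,
    n_used = length(code)
  )
}
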