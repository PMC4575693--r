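#' Configuration for the synthetic connectome generator
#'
#' The generator emulates the statistical structure the analyses assume:
#' a connected planar-like parcellation, structural types varying
#' gradually in space, projection existence decreasing monotonically in
#' both border distance and absolute type difference (logistic model),
#' ordinal strengths favouring dense projections at short distances, a
#' large unknown-status mask, and type-correlated hierarchy levels from
#' which projection directions derive.
#'
#' @param n_areas number of areas (>= 9; default 64)
#' @param adjacency_model `"random-geometric"` (unit square, threshold
#'   radius, regenerated towards a border-distance range of about 1..6 as
#'   in real whole-cortex parcellations; the default) or `"grid"`
#'   (4-neighbour lattice)
#' @param type_field_smoothness kernel bandwidth of the spatial type
#'   field, in units of the typical inter-area spacing (default 1.5)
#' @param beta0,beta_dist,beta_type existence model
#'   `P(present) = plogis(beta0 - beta_dist * dist - beta_type * |dtype|)`
#'   (defaults 2.0, 0.6, 0.8)
#' @param unknown_rate probability an ordered pair is never examined
#'   (default 0.67)
#' @param strength_decay distance decay of ordinal strength: conditional
#'   on presence, strength s in 1..3 has weight
#'   `exp(strength_decay * (3 - dist) * (s - 1))` (default 0.5)
#' @param level_scale,hierarchy_noise hierarchy levels on the designated
#'   subset are `max(0, round((6 - type) * level_scale + noise))` with
#'   `noise ~ N(0, hierarchy_noise)` (defaults 1, 0.5)
#' @param direction_flip_rate probability a projection direction is
#'   re-assigned at random (default 0.10)
#' @param seed RNG seed (default 20140726)
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_areas = 64,
                             adjacency_model = c("random-geometric", "grid"),
                             type_field_smoothness = 1.5,
                             beta0 = 2.0, beta_dist = 0.6, beta_type = 0.8,
                             unknown_rate = 0.67,
                             strength_decay = 0.5,
                             level_scale = 1, hierarchy_noise = 0.5,
                             direction_flip_rate = 0.10,
                             seed = 20140726) {
  adjacency_model <- match.arg(adjacency_model)
  stopifnot(n_areas >= 9,
            unknown_rate >= 0, unknown_rate <= 1,
            direction_flip_rate >= 0, direction_flip_rate <= 1,
            type_field_smoothness > 0)
  structure(as.list(environment()), class = "generator_config")
}

# smooth spatial random field quantized to types 1..5
smooth_types <- function(coords, smoothness) {
  n <- nrow(coords)
  spacing <- sqrt(prod(apply(coords, 2, function(v) diff(range(v)))) / n)
  h <- smoothness * spacing
  d2 <- as.matrix(stats::dist(coords))^2
  w <- exp(-d2 / (2 * h^2))
  f <- drop(w %*% rnorm(n)) / rowSums(w)
  as.integer(cut(f, quantile(f, probs = seq(0, 1, 0.2)),
                 include.lowest = TRUE, labels = FALSE))
}

geometric_graph <- function(n, radius) {
  coords <- cbind(x = runif(n), y = runif(n))
  adj <- as.matrix(stats::dist(coords)) <= radius
  diag(adj) <- FALSE
  list(coords = coords, adj = adj)
}

#' Generate a synthetic parcellation
#'
#' Builds a connected adjacency graph (grid or random-geometric) and
#' assigns structural types 1..5 by quantile-binning a spatially smoothed
#' Gaussian random field, so that types change gradually across the sheet
#' and every type recurs in several places.
#'
#' @param config a [generator_config()]
#' @return a [parcellation()] (with generator coordinates in `$coords`)
#' @export
generate_parcellation <- function(config) {
  set.seed(config$seed)
  n <- config$n_areas
  if (config$adjacency_model == "grid") {
    nr <- floor(sqrt(n)); nc <- ceiling(n / nr)
    row <- ((seq_len(n) - 1) %/% nc) + 1
    col <- ((seq_len(n) - 1) %% nc) + 1
    coords <- cbind(x = col, y = row)
    adj <- abs(outer(row, row, "-")) + abs(outer(col, col, "-")) == 1
  } else {
    # dense enough that border distances span roughly 1..6, as in real
    # whole-cortex parcellations
    radius <- 2.1 * sqrt(log(n) / (pi * n))
    best <- NULL
    for (attempt in seq_len(100)) {
      g <- geometric_graph(n, radius)
      gr <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
      if (igraph::components(gr)$no == 1) {
        best <- g
        if (igraph::diameter(gr) <= 6) break
      }
    }
    if (is.null(best)) stop("could not generate a connected parcellation")
    coords <- best$coords; adj <- best$adj
  }
  nm <- sprintf("a%02d", seq_len(n))
  dimnames(adj) <- list(nm, nm)
  areas <- data.frame(name = nm,
                      structural_type = smooth_types(coords, config$type_field_smoothness))
  parcellation(areas, adj, coords = coords)
}

# conditional ordinal strength: dense favoured at short distances
draw_strengths <- function(d, decay) {
  vapply(d, function(di) {
    w <- exp(decay * (3 - di) * (0:2))
    sample(c("sparse", "intermediate", "dense"), 1, prob = w / sum(w))
  }, "")
}

assign_directions <- function(delta_level, flip_rate) {
  dir <- ifelse(delta_level < 0, "ascending",
                ifelse(delta_level > 0, "descending", "lateral"))
  flip <- runif(length(dir)) < flip_rate
  dir[flip] <- vapply(dir[flip], function(d)
    sample(setdiff(c("ascending", "lateral", "descending"), d), 1), "")
  dir
}

#' Generate synthetic projections, hierarchy levels and directions
#'
#' For each ordered pair of areas, presence follows the logistic
#' existence model in border distance and absolute type difference;
#' present projections receive an ordinal strength favouring dense at
#' short range; the whole status is then masked to unknown independently
#' at the configured rate (missing completely at random). Hierarchy
#' levels anti-correlated with type are assigned on a designated
#' module-like subset (the third of areas in one corner of the sheet),
#' and directions for present projections within that subset derive from
#' the level difference with flip noise.
#'
#' @param parcellation a [generate_parcellation()] result
#' @param config a [generator_config()]
#' @return list of class `synthetic_connectome`: `parcellation` (with
#'   levels filled in), `table` ([projection_table()]), `directions`
#'   (data.frame), `hierarchy` (named vector), `config`
#' @export
generate_projections <- function(parcellation, config) {
  set.seed(config$seed + 1L)
  pv <- pair_variables(parcellation)
  a <- pv$abs_type
  a[is.na(a)] <- mean(a, na.rm = TRUE)
  p <- plogis(config$beta0 - config$beta_dist * pv$delta_dist -
                config$beta_type * a)
  present <- rbinom(nrow(pv), 1, p) == 1
  examined <- runif(nrow(pv)) >= config$unknown_rate
  status <- rep("absent", nrow(pv))
  status[present] <- draw_strengths(pv$delta_dist[present],
                                    config$strength_decay)
  rec <- data.frame(source = pv$source, target = pv$target,
                    status = status)[examined, ]
  table <- projection_table(rec, parcellation$areas$name)

  # module-like subset in one corner of the sheet gets hierarchy levels
  ord <- order(rowSums(parcellation$coords))
  subset_idx <- ord[seq_len(ceiling(config$n_areas / 3))]
  sub <- parcellation$areas$name[subset_idx]
  ty <- parcellation$areas$structural_type[subset_idx]
  lev <- pmax(0, round((6 - ty) * config$level_scale +
                         rnorm(length(ty), 0, config$hierarchy_noise)))
  lev[is.na(ty)] <- NA
  parcellation$areas$hierarchy_level[subset_idx] <- as.integer(lev)
  hierarchy <- setNames(as.integer(lev), sub)

  bt <- binarize(table)
  vis <- bt[bt$status == "present" & bt$source %in% sub & bt$target %in% sub, ]
  dl <- hierarchy[vis$source] - hierarchy[vis$target]
  keep <- !is.na(dl)
  directions <- data.frame(
    source = vis$source[keep], target = vis$target[keep],
    direction = assign_directions(dl[keep], config$direction_flip_rate),
    reliable = runif(sum(keep)) > 0.15,
    row.names = NULL
  )
  structure(list(parcellation = parcellation, table = table,
                 directions = directions, hierarchy = hierarchy,
                 config = config),
            class = "synthetic_connectome")
}

#' One-call synthetic connectome
#' @param config a [generator_config()]
#' @return a `synthetic_connectome` (see [generate_projections()])
#' @export
synthetic_connectome <- function(config = generator_config()) {
  generate_projections(generate_parcellation(config), config)
}

#' @export
print.synthetic_connectome <- function(x, ...) {
  print(x$parcellation); print(x$table)
  cat("directions:", nrow(x$directions), "classified projections\n")
  invisible(x)
}
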