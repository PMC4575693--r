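#' Synthetic stand-in for the cat corticocortical collation
#'
#' Generates a single deterministic dataset with the published study
#' dimensions of the cat connectivity collation: 65 areas on a connected
#' planar-like parcellation whose border distances span 1..6; structural
#' types on 49 areas; four functional modules covering 53 areas (48 of
#' them typed) named along the decreasing-type gradient
#' visual -> auditory -> somatosensory-motor -> fronto-limbic; 11
#' hub-module areas; 1,400 known directed projections of which 954 link
#' typed area pairs (218 absent, 736 present, i.e. the collation's 77%
#' present share among examined pairs); hierarchy levels on a 22-area
#' visual-like subset; and laminar directions for the present projections
#' inside that subset. Known-pair sample sizes are constructive inputs
#' (quota sampling weighted by the logistic existence model); all
#' *statistics* of the dataset are emergent.
#'
#' This is synthetic data: it mimics the collation's sampling depth and
#' assumed generative structure, not its actual area names or measured
#' projections.
#'
#' @param seed RNG seed (default 20140726); the shipped fixture under
#'   `inst/extdata/` was written with the default
#' @param n_examined_typed,n_present_typed,n_known_total quota sample
#'   sizes (defaults 954, 736, 1400)
#' @return a `synthetic_connectome` list (see [generate_projections()])
#' @export
synthetic_cat_fixture <- function(seed = 20140726,
                                  n_examined_typed = 954,
                                  n_present_typed = 736,
                                  n_known_total = 1400) {
  set.seed(seed)
  n <- 65L
  cfg <- generator_config(n_areas = n, adjacency_model = "random-geometric",
                          level_scale = 2, hierarchy_noise = 0.7, seed = seed)

  # connected geometric parcellation with border-distance range exactly 1..6
  radius <- 1.7 * sqrt(log(n) / (pi * n))
  for (attempt in seq_len(500)) {
    g <- geometric_graph(n, radius)
    gr <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
    if (igraph::components(gr)$no == 1 && igraph::diameter(gr) == 6) break
    if (attempt == 500) stop("no suitable parcellation found")
  }
  nm <- sprintf("a%02d", seq_len(n))
  dimnames(g$adj) <- list(nm, nm)
  types <- smooth_types(g$coords, cfg$type_field_smoothness)

  # 12 areas outside the module partition (11 of them untyped), 5 further
  # untyped module areas: 49 typed, 53 in modules, 48 typed module areas
  nonmodule <- sample(n, 12)
  untyped <- c(sample(nonmodule, 11), sample(setdiff(seq_len(n), nonmodule), 5))
  types[untyped] <- NA

  km <- kmeans(g$coords, centers = 4, nstart = 5)
  med_type <- vapply(1:4, function(k)
    median(types[km$cluster == k], na.rm = TRUE), 0)
  module <- MODULE_LEVELS[match(km$cluster, order(med_type, decreasing = TRUE))]
  module[nonmodule] <- NA

  areas <- data.frame(name = nm, structural_type = types, module = module)
  parc <- parcellation(areas, g$adj, coords = g$coords)

  # quota-sampled projection statuses: examination effort favours short
  # distances, presence follows the logistic existence model
  pv <- pair_variables(parc)
  typed_pair <- !is.na(pv$abs_type)
  p_model <- plogis(cfg$beta0 - cfg$beta_dist * pv$delta_dist -
                      cfg$beta_type * ifelse(typed_pair, pv$abs_type,
                                             mean(pv$abs_type, na.rm = TRUE)))
  w_exam <- exp(-0.35 * pv$delta_dist)

  idx_typed <- which(typed_pair)
  exam_t <- sample(idx_typed, n_examined_typed, prob = w_exam[idx_typed])
  pres_t <- sample(exam_t, n_present_typed, prob = p_model[exam_t])

  idx_unty <- which(!typed_pair)
  exam_u <- sample(idx_unty, n_known_total - n_examined_typed,
                   prob = w_exam[idx_unty])
  pres_u <- exam_u[rbinom(length(exam_u), 1, p_model[exam_u]) == 1]

  exam <- c(exam_t, exam_u)
  pres <- c(pres_t, pres_u)
  status <- setNames(rep("absent", length(exam)), exam)
  status[as.character(pres)] <- draw_strengths(pv$delta_dist[pres],
                                               cfg$strength_decay)
  rec <- data.frame(source = pv$source[exam], target = pv$target[exam],
                    status = unname(status))
  table <- projection_table(rec, nm)

  # hierarchy levels for the 22 typed areas nearest the visual centroid
  vis_centroid <- colMeans(g$coords[which(module == "visual"), , drop = FALSE])
  d_cen <- sqrt(colSums((t(g$coords) - vis_centroid)^2))
  sub_idx <- order(d_cen + ifelse(is.na(types), Inf, 0))[1:22]
  lev <- pmax(0, round((6 - types[sub_idx]) * cfg$level_scale +
                         rnorm(22, 0, cfg$hierarchy_noise)))
  parc$areas$hierarchy_level[sub_idx] <- as.integer(lev)
  hierarchy <- setNames(as.integer(lev), nm[sub_idx])

  bt <- binarize(table)
  sub <- nm[sub_idx]
  vis <- bt[bt$status == "present" & bt$source %in% sub & bt$target %in% sub, ]
  dl <- hierarchy[vis$source] - hierarchy[vis$target]
  directions <- data.frame(
    source = vis$source, target = vis$target,
    direction = assign_directions(unname(dl), cfg$direction_flip_rate),
    reliable = runif(nrow(vis)) > 0.15,
    row.names = NULL
  )

  # hub flag: the 11 highest-degree module areas
  deg <- table(c(bt$source[bt$status == "present"],
                 bt$target[bt$status == "present"]))
  degree <- setNames(rep(0L, n), nm)
  degree[names(deg)] <- as.integer(deg)
  in_mod <- !is.na(parc$areas$module)
  hubs <- names(sort(degree[in_mod], decreasing = TRUE))[1:11]
  parc$areas$hub <- ifelse(!in_mod, NA, parc$areas$name %in% hubs)

  structure(list(parcellation = parc, table = table,
                 directions = directions, hierarchy = hierarchy,
                 config = cfg),
            class = "synthetic_connectome")
}

#' Write a synthetic connectome as the package's TSV fixture formats
#'
#' Produces `<prefix>_connectivity.tsv` (ordinal matrix),
#' `<prefix>_adjacency.tsv`, `<prefix>_areas.tsv` (per-area attributes)
#' and `<prefix>_directions.tsv`.
#'
#' @param x a `synthetic_connectome`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix (default `"synthetic_cat"`)
#' @return invisibly, the written paths
#' @export
write_fixture <- function(x, dir, prefix = "synthetic_cat") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(what) file.path(dir, paste0(prefix, "_", what, ".tsv"))
  write_connectivity(x$table, path("connectivity"))
  write_matrix_tsv(x$parcellation$adjacency + 0L, path("adjacency"))
  write.table(x$parcellation$areas[c("name", "structural_type",
                                     "hierarchy_level", "module", "hub")],
              path("areas"), sep = "\t", quote = FALSE, row.names = FALSE)
  dirs <- x$directions
  dirs$direction <- c(ascending = "A", lateral = "L",
                      descending = "D")[dirs$direction]
  dirs$reliable <- as.integer(dirs$reliable)
  write.table(dirs, path("directions"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(vapply(c("connectivity", "adjacency", "areas", "directions"),
                   path, ""))
}

#' Load a TSV fixture written by [write_fixture()]
#'
#' @param dir directory holding the fixture (default: the fixture shipped
#'   with the package)
#' @param prefix file-name prefix (default `"synthetic_cat"`)
#' @return list: `parcellation`, `table`, `directions`, `hierarchy`
#' @export
load_fixture <- function(dir = system.file("extdata", package = "connectopred"),
                         prefix = "synthetic_cat") {
  path <- function(what) file.path(dir, paste0(prefix, "_", what, ".tsv"))
  areas <- read.delim(path("areas"), na.strings = "NA")
  areas$name <- as.character(areas$name)
  adj <- read_adjacency(path("adjacency"))
  parc <- parcellation(areas, adj)
  table <- load_connectivity(path("connectivity"), areas = areas$name)
  dirs <- read.delim(path("directions"))
  dirs$source <- as.character(dirs$source)
  dirs$target <- as.character(dirs$target)
  dirs$reliable <- dirs$reliable == 1
  lev <- !is.na(areas$hierarchy_level)
  list(parcellation = parc, table = table, directions = dirs,
       hierarchy = setNames(as.integer(areas$hierarchy_level[lev]),
                            areas$name[lev]))
}
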