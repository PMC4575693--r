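#' Border distances between all pairs of areas
#'
#' The border distance between two areas is the minimum number of area
#' borders that must be crossed to travel between them on the cortical
#' sheet, i.e. the unweighted shortest-path length in the parcellation
#' adjacency graph.
#'
#' @param parcellation a [parcellation()]
#' @return symmetric integer matrix of distances (0 on the diagonal);
#'   pairs in different graph components are `NA`, with a warning listing
#'   the components
#' @export
border_distances <- function(parcellation) {
  g <- igraph::graph_from_adjacency_matrix(parcellation$adjacency,
                                           mode = "undirected")
  d <- igraph::distances(g)
  if (any(is.infinite(d))) {
    comp <- igraph::components(g)
    warning("adjacency graph is disconnected; components: ",
            paste(vapply(seq_len(comp$no), function(i)
              toString(names(comp$membership)[comp$membership == i]), ""),
              collapse = " | "))
    d[is.infinite(d)] <- NA
  }
  storage.mode(d) <- "integer"
  d
}

#' Structural type difference for directed pairs
#'
#' `delta_type = type(source) - type(target)`: positive when the
#' projection runs from a more differentiated (higher type) to a less
#' differentiated area. Antisymmetric in its arguments.
#'
#' @param parcellation a [parcellation()]
#' @param source,target area names (vectorized)
#' @return integer vector; NA where either area lacks a type
#' @export
type_difference <- function(parcellation, source, target) {
  ty <- setNames(parcellation$areas$structural_type, parcellation$areas$name)
  unname(ty[source] - ty[target])
}

#' Hierarchical level difference for directed pairs
#'
#' `delta_level = level(source) - level(target)` in a named hierarchy.
#' Hierarchies are inputs, never computed here.
#'
#' @param source,target area names (vectorized)
#' @param hierarchy named integer vector mapping area name to level
#' @return integer vector; NA for areas absent from the hierarchy
#' @export
level_difference <- function(source, target, hierarchy) {
  unname(hierarchy[source] - hierarchy[target])
}

#' Pairwise anatomical variables for all ordered area pairs
#'
#' Builds the long-format table of border distance, structural type
#' difference and hierarchical level difference (plus absolute values)
#' over every ordered pair of distinct areas. Pairs lacking a required
#' attribute carry NA in the corresponding column and are excluded
#' per-analysis downstream, never globally.
#'
#' @param parcellation a [parcellation()]
#' @param hierarchy named integer vector of levels, or NULL to use the
#'   parcellation's `hierarchy_level` column
#' @return data.frame: source, target, delta_dist, delta_type,
#'   delta_level, abs_type, abs_level
#' @export
pair_variables <- function(parcellation, hierarchy = NULL) {
  nm <- parcellation$areas$name
  if (is.null(hierarchy))
    hierarchy <- setNames(parcellation$areas$hierarchy_level, nm)
  d <- border_distances(parcellation)
  grid <- expand.grid(target = nm, source = nm, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, c("source", "target")]
  out <- data.frame(
    source = grid$source,
    target = grid$target,
    delta_dist = d[cbind(grid$source, grid$target)],
    delta_type = type_difference(parcellation, grid$source, grid$target),
    delta_level = level_difference(grid$source, grid$target, hierarchy)
  )
  out$abs_type <- abs(out$delta_type)
  out$abs_level <- abs(out$delta_level)
  rownames(out) <- NULL
  out
}
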