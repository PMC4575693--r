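#' Construct a parcellation
#'
#' A parcellation bundles the named cortical areas with their per-area
#' attributes and the symmetric border-adjacency relation. Adjacency encodes
#' which areas share a common border on the cortical sheet; it is the graph
#' on which border distances are computed.
#'
#' @param areas data.frame with column `name` (unique, case-sensitive
#'   abbreviations) and optional columns `structural_type` (ordinal 1-5,
#'   NA allowed), `hierarchy_level` (non-negative integer, NA allowed),
#'   `module` (one of `r toString(MODULE_LEVELS)`, NA allowed) and `hub`
#'   (logical, NA allowed).
#' @param adjacency logical or 0/1 matrix with dimnames equal to the area
#'   names; must be symmetric with an empty diagonal.
#' @param coords optional numeric matrix of 2-D area coordinates (used by
#'   the synthetic generator; not required for any analysis).
#' @return object of class `parcellation`: list with elements `areas`
#'   (data.frame) and `adjacency` (logical matrix).
#' @export
parcellation <- function(areas, adjacency, coords = NULL) {
  stopifnot(is.data.frame(areas), "name" %in% names(areas))
  areas$name <- as.character(areas$name)
  if (anyDuplicated(areas$name))
    stop("duplicate area names: ",
         toString(unique(areas$name[duplicated(areas$name)])))
  for (col in c("structural_type", "hierarchy_level")) {
    if (!col %in% names(areas)) areas[[col]] <- NA_integer_
    areas[[col]] <- as.integer(areas[[col]])
  }
  bad <- !is.na(areas$structural_type) & !areas$structural_type %in% 1:5
  if (any(bad))
    stop("structural_type outside 1..5 for: ", toString(areas$name[bad]))
  if (!"module" %in% names(areas)) areas$module <- NA_character_
  if (!"hub" %in% names(areas)) areas$hub <- NA
  areas$hub <- as.logical(areas$hub)

  adjacency <- as.matrix(adjacency)
  mode(adjacency) <- "logical"
  if (is.null(dimnames(adjacency)))
    dimnames(adjacency) <- list(areas$name, areas$name)
  if (!identical(rownames(adjacency), areas$name) ||
      !identical(colnames(adjacency), areas$name))
    stop("adjacency dimnames must equal the area names, in order")
  if (!isSymmetric(unname(adjacency)))
    stop("adjacency matrix must be symmetric")
  if (any(diag(adjacency), na.rm = TRUE))
    stop("self-adjacency is not allowed")
  adjacency[is.na(adjacency)] <- FALSE
  diag(adjacency) <- FALSE

  structure(list(areas = areas, adjacency = adjacency, coords = coords),
            class = "parcellation")
}

MODULE_LEVELS <- c("visual", "auditory", "somatosensory-motor", "fronto-limbic")

#' @export
print.parcellation <- function(x, ...) {
  n <- nrow(x$areas)
  cat("parcellation:", n, "areas,", sum(x$adjacency) / 2, "border adjacencies\n")
  cat("  typed:", sum(!is.na(x$areas$structural_type)),
      " levelled:", sum(!is.na(x$areas$hierarchy_level)),
      " in modules:", sum(!is.na(x$areas$module)), "\n")
  invisible(x)
}

#' Names of areas carrying a structural type
#' @param parcellation a [parcellation()]
#' @return character vector
#' @export
typed_areas <- function(parcellation) {
  parcellation$areas$name[!is.na(parcellation$areas$structural_type)]
}

#' Apply symmetric adjacency edits to a parcellation
#'
#' Each edit adds or removes one border adjacency; additions and removals
#' are applied to both triangles of the matrix. Removing an absent
#' adjacency (or adding a present one) warns but does not fail, so edit
#' lists are idempotent.
#'
#' @param parcellation a [parcellation()]
#' @param edits list of edits, each `list(op = "add"|"remove", a = , b = )`,
#'   e.g. as returned by [cat_adjacency_edits()] or [read_adjacency_edits()].
#' @return the edited parcellation
#' @export
apply_adjacency_edits <- function(parcellation, edits) {
  adj <- parcellation$adjacency
  for (e in edits) {
    stopifnot(e$op %in% c("add", "remove"))
    for (nm in c(e$a, e$b))
      if (!nm %in% rownames(adj))
        stop("adjacency edit references unknown area: ", nm)
    val <- e$op == "add"
    if (adj[e$a, e$b] == val)
      warning(sprintf("edit %s (%s, %s) is a no-op", e$op, e$a, e$b))
    adj[e$a, e$b] <- adj[e$b, e$a] <- val
  }
  parcellation$adjacency <- adj
  parcellation
}

#' Default border-adjacency corrections for the cat parcellation
#'
#' The published spatial adjacency matrix for the 65-area cat parcellation
#' disagrees with the published cortical map in a few places; these edits
#' reconcile the two (two removals around area 17, and added borders for
#' areas 18, CGa, SVA, SIV and 4g).
#'
#' @return list of edits suitable for [apply_adjacency_edits()]
#' @export
cat_adjacency_edits <- function() {
  rm_ <- function(a, b) list(op = "remove", a = a, b = b)
  add <- function(a, b) list(op = "add", a = a, b = b)
  list(
    rm_("17", "CGp"), rm_("17", "RS"),
    add("18", "20a"), add("18", "20b"),
    add("CGa", "17"), add("CGa", "4"), add("CGa", "6m"),
    add("SVA", "18"), add("SVA", "20b"), add("SVA", "RS"),
    add("SIV", "Ig"), add("4g", "6m")
  )
}

#' Read adjacency edits from a JSON config
#'
#' @param path JSON file: array of objects with fields `op`, `a`, `b`
#' @return list of edits
#' @export
read_adjacency_edits <- function(path) {
  edits <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(edits, function(e) list(op = e$op, a = e$a, b = e$b))
}
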