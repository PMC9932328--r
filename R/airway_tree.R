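#' Airway tree model
#'
#' A branch graph with centerlines and per-branch attributes, stored as a
#' tibble (one row per branch) so it can be manipulated with ordinary dplyr
#' verbs. Required columns:
#' \describe{
#'   \item{id}{character or integer branch identifier, unique}
#'   \item{parent}{identifier of the parent branch, `NA` for the root
#'     (trachea)}
#'   \item{centerline}{list-column of n x 3 numeric matrices, points in mm,
#'     ordered from the proximal to the distal end}
#' }
#' Optional columns carry the airway generation (`generation`, trachea = 1),
#' the lobe label (`lobe`), and geometry — either ground truth from a
#' phantom generator (`lumen_diameter_mm`, `wall_thickness_mm`) or measured
#' values attached by [measure_tree()].
#'
#' @param branches a data frame with at least `id`, `parent`, `centerline`.
#' @return the validated tibble with class `airway_tree` prepended.
#' @export
airway_tree <- function(branches) {
  branches <- tibble::as_tibble(branches)
  req <- c("id", "parent", "centerline")
  miss <- setdiff(req, names(branches))
  if (length(miss)) {
    stop("airway_tree is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(branches$id)) stop("duplicate branch ids", call. = FALSE)
  known <- !is.na(branches$parent)
  if (any(known & !(branches$parent %in% branches$id))) {
    stop("parent ids refer to unknown branches", call. = FALSE)
  }
  bad_cl <- !vapply(branches$centerline, function(m) {
    is.matrix(m) && ncol(m) == 3 && nrow(m) >= 2 && !anyNA(m)
  }, logical(1))
  if (any(bad_cl)) {
    stop("each centerline must be an n x 3 matrix with n >= 2", call. = FALSE)
  }
  class(branches) <- c("airway_tree", class(tibble::tibble()))
  branches
}

tree_children <- function(tree) {
  split(tree$id[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
}

#' Label airway generations breadth-first from the trachea
#'
#' The trachea carries generation 1, the main stem bronchi 2, lobar bronchi
#' 3, segmental bronchi 4, and so on; every child is one generation deeper
#' than its parent, so trifurcations increment all children equally.
#'
#' @param tree an [airway_tree()].
#' @return the tree with a `generation` column (re)computed.
#' @export
label_generations <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  roots <- tree$id[is.na(tree$parent)]
  if (length(roots) != 1L) {
    stop("tree must have exactly one root (trachea); found ", length(roots),
         call. = FALSE)
  }
  gen <- stats::setNames(rep(NA_integer_, nrow(tree)), tree$id)
  kids <- tree_children(tree)
  frontier <- roots
  g <- 1L
  while (length(frontier)) {
    gen[frontier] <- g
    frontier <- unlist(kids[frontier], use.names = FALSE)
    g <- g + 1L
    if (g > nrow(tree) + 1L) stop("cycle detected in airway tree", call. = FALSE)
  }
  if (anyNA(gen)) {
    stop("branches unreachable from the root (cycle or detached subgraph): ",
         paste(names(gen)[is.na(gen)], collapse = ", "), call. = FALSE)
  }
  tree$generation <- unname(gen[tree$id])
  tree
}

#' Assign lobe labels by inheritance from labelled lobar entry branches
#'
#' The six lobar entry bronchi are labelled (by the phantom ground truth or
#' by the user); every descendant inherits its lobar ancestor's label. The
#' trachea and main stem bronchi are labelled as non-lobar airways. Deep
#' branches (generation >= 4) with no labelled ancestor are marked
#' `"unassigned"` and flagged, which excludes them from lobar aggregates.
#'
#' @param tree an [airway_tree()] with generations labelled.
#' @param lobar_entry_labels named character vector: names are branch ids of
#'   the lobar entries, values are region names (typically RUL, RML, RLL,
#'   LUL, LLi, LLL).
#' @return the tree with `lobe` and logical `lobe_unassigned` columns.
#' @export
assign_lobes <- function(tree, lobar_entry_labels) {
  stopifnot(inherits(tree, "airway_tree"))
  if (!"generation" %in% names(tree)) tree <- label_generations(tree)
  if (is.null(names(lobar_entry_labels)) || anyNA(names(lobar_entry_labels))) {
    stop("lobar_entry_labels must be named by branch id", call. = FALSE)
  }
  unknown <- setdiff(names(lobar_entry_labels), tree$id)
  if (length(unknown)) {
    stop("lobar entry ids not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lobe <- stats::setNames(rep(NA_character_, nrow(tree)), tree$id)
  lobe[names(lobar_entry_labels)] <- unname(lobar_entry_labels)
  parent <- stats::setNames(tree$parent, tree$id)
  # propagate down in generation order so parents are resolved first
  ord <- order(tree$generation)
  for (i in ord) {
    id <- tree$id[i]
    if (is.na(lobe[id]) && !is.na(parent[id]) && !is.na(lobe[parent[id]])) {
      lobe[id] <- lobe[parent[id]]
    }
  }
  gen <- stats::setNames(tree$generation, tree$id)
  airway_label <- ifelse(
    gen == 1L, "trachea",
    ifelse(gen == 2L & is.na(lobe), "main", NA_character_)
  )
  unassigned <- is.na(lobe) & is.na(airway_label)
  lobe[unassigned] <- "unassigned"
  lobe[!is.na(airway_label)] <- airway_label[!is.na(airway_label)]
  tree$lobe <- unname(lobe[tree$id])
  tree$lobe_unassigned <- unname(unassigned[tree$id])
  if (any(tree$lobe_unassigned)) {
    warning(sum(tree$lobe_unassigned),
            " branch(es) have no labelled lobar ancestor; marked unassigned",
            call. = FALSE)
  }
  tree
}

#' Serialize an airway tree to JSON
#'
#' Centerline points in mm, topology, labels and any per-branch geometry
#' are written; [read_airway_tree()] restores them.
#'
#' @param tree an [airway_tree()].
#' @param path destination JSON file.
#' @return invisibly, `path`.
#' @export
write_airway_tree <- function(tree, path) {
  stopifnot(inherits(tree, "airway_tree"))
  plain <- as.data.frame(tree)
  plain$centerline <- lapply(tree$centerline, function(m) unclass(m))
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_airway_tree
#' @export
read_airway_tree <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- tibble::as_tibble(raw)
  raw$centerline <- lapply(raw$centerline, function(m) {
    matrix(as.numeric(m), ncol = 3)
  })
  airway_tree(raw)
}
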