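#' Seed-space geometry
#'
#' A seed space describes the grey-matter domain tractography is seeded from:
#' cortical surface vertices and/or subcortical voxels, with an undirected
#' adjacency graph (used for contiguous random parcellations), hemisphere
#' labels, an optional exclusion mask (e.g. the non-cortical medial wall) and
#' an optional left/right homologue pairing used for symmetry analyses.
#'
#' @param seed_ids Character or integer vector of unique seed identifiers.
#' @param kind Per-seed kind, `"surface-vertex"` or `"volume-voxel"`
#'   (recycled if scalar).
#' @param hemisphere Per-seed hemisphere, one of `"left"`, `"right"`,
#'   `"midline"` (recycled if scalar).
#' @param edges Two-column integer matrix of undirected adjacency edges
#'   (1-based seed indices). Each edge may be listed once; the graph is
#'   treated as symmetric.
#' @param exclusion Logical vector, `TRUE` for seeds excluded from analysis.
#'   Defaults to all `FALSE`.
#' @param homologue Integer vector mapping each seed to its contralateral
#'   counterpart (`NA` where unmapped). Must be an involution across
#'   hemispheres on its domain.
#' @param coordinates Optional n_seeds x 3 matrix of mm positions (used by the
#'   synthetic generator for seed--target distances and by volume export).
#' @param grid_shape,affine Optional voxel grid (3 integers) and 4x4
#'   voxel-to-mm affine for volume-voxel seeds; required by [export_maps()]
#'   when exporting volume seed maps.
#' @return An object of class `tractica_seed_space`.
#' @seealso [target_space()], [make_toy_spaces()]
#' @export
seed_space <- function(seed_ids, kind = "surface-vertex", hemisphere = "midline",
                       edges = NULL, exclusion = NULL, homologue = NULL,
                       coordinates = NULL, grid_shape = NULL, affine = NULL) {
  n <- length(seed_ids)
  if (n < 1L) stop("seed space needs at least one seed")
  if (anyDuplicated(seed_ids)) stop("seed_ids must be unique")
  kind <- rep_len(as.character(kind), n)
  if (!all(kind %in% c("surface-vertex", "volume-voxel")))
    stop("kind must be 'surface-vertex' or 'volume-voxel'")
  hemisphere <- rep_len(as.character(hemisphere), n)
  if (!all(hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be 'left', 'right' or 'midline'")
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n))
      stop("adjacency edges reference seeds outside 1..", n)
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    # canonical undirected form: i < j, unique
    edges <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                          pmax(edges[, 1L], edges[, 2L])))
  }
  if (is.null(exclusion)) exclusion <- rep(FALSE, n)
  exclusion <- as.logical(exclusion)
  if (length(exclusion) != n || anyNA(exclusion))
    stop("exclusion must be logical of length n_seeds without NA")
  if (!is.null(homologue)) {
    homologue <- as.integer(homologue)
    if (length(homologue) != n) stop("homologue must have length n_seeds")
    dom <- which(!is.na(homologue))
    if (any(homologue[dom] < 1L | homologue[dom] > n))
      stop("homologue references seeds outside 1..", n)
    if (!all(homologue[homologue[dom]] == dom, na.rm = TRUE))
      stop("homologue map must be an involution on its domain")
    same <- hemisphere[dom] == hemisphere[homologue[dom]] &
      hemisphere[dom] != "midline"
    if (any(same))
      stop("homologue map must pair seeds across hemispheres")
  }
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n || ncol(coordinates) != 3L ||
        !all(is.finite(coordinates)))
      stop("coordinates must be a finite n_seeds x 3 matrix")
  }
  structure(list(
    n_seeds = n, seed_ids = seed_ids, kind = kind, hemisphere = hemisphere,
    edges = edges, exclusion = exclusion, homologue = homologue,
    coordinates = coordinates, grid_shape = grid_shape, affine = affine
  ), class = "tractica_seed_space")
}

#' Target-space voxel grid
#'
#' The whole-brain voxel grid streamline visitation counts are recorded on.
#' Targets are (a subset of) the voxels of a 3-D grid with a voxel-to-mm
#' affine; coordinates are in mm.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param target_ids Optional ids, defaults to linear voxel indices of the
#'   full grid.
#' @param coordinates Optional n_targets x 3 mm positions; derived from the
#'   grid when absent.
#' @return An object of class `tractica_target_space`.
#' @export
target_space <- function(grid_shape, affine, target_ids = NULL,
                         coordinates = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (is.null(target_ids)) target_ids <- seq_len(prod(grid_shape))
  if (anyDuplicated(target_ids)) stop("target_ids must be unique")
  m <- length(target_ids)
  if (is.null(coordinates)) {
    vox <- arrayInd(seq_len(prod(grid_shape)), grid_shape)[target_ids, ,
                                                           drop = FALSE]
    coordinates <- t(affine[1:3, , drop = FALSE] %*%
                       rbind(t(vox) - 1, 1))
  }
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != m || ncol(coordinates) != 3L ||
      !all(is.finite(coordinates)))
    stop("coordinates must be a finite n_targets x 3 matrix")
  structure(list(
    n_targets = m, grid_shape = grid_shape, affine = affine,
    target_ids = target_ids, coordinates = coordinates
  ), class = "tractica_target_space")
}

#' @export
print.tractica_seed_space <- function(x, ...) {
  cat("<tractica_seed_space> ", x$n_seeds, " seeds (",
      sum(x$hemisphere == "left"), " L / ", sum(x$hemisphere == "right"),
      " R / ", sum(x$hemisphere == "midline"), " midline), ",
      nrow(x$edges), " adjacency edges, ", sum(x$exclusion), " excluded\n",
      sep = "")
  invisible(x)
}

#' @export
print.tractica_target_space <- function(x, ...) {
  cat("<tractica_target_space> ", x$n_targets, " targets on a ",
      paste(x$grid_shape, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

# adjacency list (both directions) for BFS-based operations
adjacency_list <- function(space) {
  adj <- vector("list", space$n_seeds)
  e <- space$edges
  if (nrow(e) > 0L) {
    from <- c(e[, 1L], e[, 2L])
    to <- c(e[, 2L], e[, 1L])
    adj_split <- split(to, factor(from, levels = seq_len(space$n_seeds)))
    adj <- lapply(adj_split, as.integer)
  }
  adj
}

# connected components of the subgraph induced by `keep` (logical)
graph_components <- function(space, keep = !space$exclusion) {
  adj <- adjacency_list(space)
  comp <- integer(space$n_seeds)
  cur <- 0L
  for (s in which(keep)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      nb <- nb[keep[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
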