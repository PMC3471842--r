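# Icosahedral rotation group and symmetry-axis direction sets.
#
# Orientation convention (fixed, "222" setting): the three mutually
# perpendicular two-fold axes lie on the coordinate axes, so the twelve
# five-fold axes point along the cyclic permutations of (0, +/-1, +/-phi)
# with phi the golden ratio. This matches the common icosahedral
# reconstruction convention; all downstream results are covariant with the
# choice.

.icodiff_cache <- new.env(parent = emptyenv())

# Rodrigues rotation matrix about unit axis u by angle theta
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)   # column-major: K %*% x = u x x
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * tcrossprod(u)
}

# nearest orthonormal matrix (polar projection); keeps products of products
# from drifting
.orthonormalize <- function(R) {
  s <- svd(R)
  s$u %*% t(s$v)
}

.build_group <- function() {
  phi <- (1 + sqrt(5)) / 2
  g5 <- rotation_about(c(0, 1, phi), 2 * pi / 5)
  g2 <- rotation_about(c(0, 0, 1), pi)
  gens <- list(g5, g2)
  ops <- list(diag(3))
  keys <- new.env(parent = emptyenv())
  key_of <- function(R) paste(sprintf("%.6f", round(R, 6) + 0), collapse = ",")
  assign(key_of(diag(3)), TRUE, envir = keys)
  frontier <- ops
  while (length(frontier) > 0) {
    nxt <- list()
    for (a in frontier) for (g in gens) {
      p <- .orthonormalize(g %*% a)
      k <- key_of(p)
      if (!exists(k, envir = keys, inherits = FALSE)) {
        assign(k, TRUE, envir = keys)
        ops[[length(ops) + 1L]] <- p
        nxt[[length(nxt) + 1L]] <- p
      }
    }
    frontier <- nxt
  }
  if (length(ops) != 60L)
    stop("internal error: icosahedral group closure produced ",
         length(ops), " elements")
  ops
}

#' The icosahedral rotation group
#'
#' Returns the 60 proper rotations of the icosahedron as a list of 3x3
#' orthonormal matrices (determinant +1), in the fixed 222 orientation with
#' two-fold axes along the coordinate axes. The list is closed under
#' composition and inversion and contains the identity.
#'
#' @return List of 60 3x3 rotation matrices.
#' @export
icosahedral_group <- function() {
  if (is.null(.icodiff_cache$group)) .icodiff_cache$group <- .build_group()
  .icodiff_cache$group
}

# smallest k with R^k = I (icosahedral elements have order 1,2,3 or 5)
rotation_order <- function(R, tol = 1e-8) {
  P <- R
  for (k in 1:5) {
    if (max(abs(P - diag(3))) < tol) return(k)
    P <- P %*% R
  }
  stop("matrix is not a finite-order icosahedral rotation")
}

# unit rotation axis of a non-identity rotation (eigenvector of eigenvalue 1)
rotation_axis <- function(R) {
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  u <- Re(e$vectors[, i])
  u / sqrt(sum(u^2))
}

#' Symmetry-axis direction sets
#'
#' The unit direction set of the icosahedral axes of a given order, in the
#' same orientation convention as [icosahedral_group()]: 12 directions for
#' the five-fold axes, 20 for the three-fold axes, 30 for the two-fold axes
#' (antipodal pairs counted separately, so each direction marks one vertex /
#' face / edge of the icosahedron).
#'
#' @param order axis order; one of 2, 3, 5.
#' @return An object of class `axis_set`: list with `order` and a K x 3
#'   matrix `directions` of unit vectors, sorted lexicographically.
#' @export
axis_directions <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || !order %in% c(2, 3, 5))
    stop("`order` must be one of 2, 3 or 5")
  order <- as.integer(order)
  slot <- paste0("axes", order)
  if (!is.null(.icodiff_cache[[slot]])) return(.icodiff_cache[[slot]])
  ops <- icosahedral_group()
  dirs <- matrix(numeric(0), 0, 3)
  for (R in ops) {
    if (max(abs(R - diag(3))) < 1e-8) next
    if (rotation_order(R) != order) next
    u <- rotation_axis(R)
    for (v in list(u, -u)) {
      if (nrow(dirs) == 0 ||
          min(colSums((t(dirs) - v)^2)) > 1e-10)
        dirs <- rbind(dirs, v)
    }
  }
  expected <- c(`2` = 30L, `3` = 20L, `5` = 12L)[as.character(order)]
  if (nrow(dirs) != expected)
    stop("internal error: found ", nrow(dirs), " axes of order ", order)
  dirs <- dirs[order(round(dirs[, 1], 9), round(dirs[, 2], 9),
                     round(dirs[, 3], 9)), , drop = FALSE]
  dimnames(dirs) <- NULL
  out <- structure(list(order = order, directions = dirs), class = "axis_set")
  .icodiff_cache[[slot]] <- out
  out
}

#' @export
print.axis_set <- function(x, ...) {
  cat(sprintf("<axis_set> order %d, %d directions\n",
              x$order, nrow(x$directions)))
  invisible(x)
}

#' Export an axis set as a plain-text table
#'
#' Writes one row per direction: `order x y z`, tab-separated.
#'
#' @param axes an `axis_set` from [axis_directions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_axis_set <- function(axes, path) {
  stopifnot(inherits(axes, "axis_set"))
  df <- data.frame(order = axes$order,
                   x = axes$directions[, 1],
                   y = axes$directions[, 2],
                   z = axes$directions[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Icosahedrally average a map
#'
#' Replaces the map by the mean of its 60 rotated copies, with trilinear
#' resampling about the grid center voxel. Voxels rotated outside the grid
#' contribute the edge-padding value 0 (phantoms keep density away from the
#' edges, so this only affects the extreme corners). The result is invariant
#' under any further group rotation up to interpolation error, and the
#' operation is idempotent at the same tolerance.
#'
#' @param map a [map3d] (cubic grid; rotation center at the grid center).
#' @return The symmetrized [map3d].
#' @export
symmetrize <- function(map) {
  if (!is_map3d(map)) stop("`map` must be a map3d (cubic grid)")
  n <- grid_size(map)
  ctr <- center_index(n)
  co <- grid_coords(n, 1)            # voxel units
  acc <- numeric(n^3)
  for (R in icosahedral_group()) {
    rc <- co %*% R                   # rows x^T R = (R^T x)^T; group is
    acc <- acc + interp_trilinear(map$data,      # closed under transpose
                                  rc[, 1] + ctr, rc[, 2] + ctr, rc[, 3] + ctr)
  }
  map3d(array(acc / 60, dim = c(n, n, n)), map$voxel_size)
}
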