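#' Per-channel particle coordinates
#'
#' Bundles the k per-channel coordinate lists that form the marginals of
#' the matching problem. Coordinates are rows of a numeric matrix with 2
#' or 3 columns, interpreted as 0-based (row, col and optionally plane)
#' positions in
#' the declared unit. Optionally, explicit distance matrices for adjacent
#' channel pairs override Euclidean distances (e.g. when an upstream
#' segmentation defines its own particle-to-particle distances).
#'
#' @param coords list of k numeric matrices (n_j x d, d in {2, 3}); empty
#'   channels are allowed as 0-row matrices.
#' @param unit "px" or "nm".
#' @param pixel_size_nm physical pixel size, required context when
#'   converting between units (may be NA if never converted).
#' @param dist_matrices optional list of length k - 1; element j is the
#'   n_j x n_{j+1} distance matrix for channels (j, j+1), or NULL to use
#'   Euclidean distances.
#' @return an object of class `point_cloud_set`.
#' @export
point_cloud_set <- function(coords, unit = c("px", "nm"),
                            pixel_size_nm = NA_real_,
                            dist_matrices = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.list(coords), length(coords) >= 2)
  coords <- lapply(coords, function(x) {
    x <- as.matrix(x)
    if (nrow(x) == 0 && ncol(x) == 0) x <- matrix(numeric(0), 0, 2)
    storage.mode(x) <- "double"
    x
  })
  dims <- vapply(coords, ncol, integer(1))
  if (length(unique(dims)) != 1) {
    stop("all channels must share dimensionality; got ",
         paste(dims, collapse = ", "))
  }
  if (!dims[1] %in% c(2L, 3L)) {
    stop("coordinates must be 2- or 3-dimensional")
  }
  k <- length(coords)
  if (!is.null(dist_matrices)) {
    stopifnot(is.list(dist_matrices), length(dist_matrices) == k - 1)
    for (j in seq_len(k - 1)) {
      D <- dist_matrices[[j]]
      if (is.null(D)) next
      D <- as.matrix(D)
      if (!all(dim(D) == c(nrow(coords[[j]]), nrow(coords[[j + 1]])))) {
        stop("distance matrix for pair (", j, ",", j + 1,
             ") has wrong shape")
      }
      if (any(D < 0)) {
        stop("distance matrix for pair (", j, ",", j + 1,
             ") has negative entries")
      }
      dist_matrices[[j]] <- D
    }
  }
  structure(
    list(k = k, coords = coords,
         counts = vapply(coords, nrow, integer(1)),
         dim = dims[1], unit = unit, pixel_size_nm = pixel_size_nm,
         dist_matrices = dist_matrices),
    class = "point_cloud_set")
}

#' @export
print.point_cloud_set <- function(x, ...) {
  cat("point_cloud_set: ", x$k, " channels (",
      paste(channel_letters(x$k), collapse = ","), "), ",
      x$dim, "D, unit = ", x$unit, "\n", sep = "")
  cat("  counts:", paste(x$counts, collapse = ", "), "\n")
  if (!is.null(x$dist_matrices)) cat("  explicit distance matrices supplied\n")
  invisible(x)
}

#' Distance matrix for an adjacent channel pair
#'
#' Returns the user-supplied matrix when present, else Euclidean
#' distances between the two coordinate lists, in the cloud's unit.
#'
#' @param clouds a [point_cloud_set()].
#' @param pair index j of the adjacent pair (j, j+1).
#' @return numeric matrix of shape n_j x n_{j+1}.
#' @export
pairwise_distances <- function(clouds, pair) {
  stopifnot(inherits(clouds, "point_cloud_set"))
  j <- as.integer(pair)
  if (j < 1 || j >= clouds$k) {
    stop("pair must index an adjacent channel pair (j, j+1) with 1 <= j < k")
  }
  if (!is.null(clouds$dist_matrices) && !is.null(clouds$dist_matrices[[j]])) {
    return(clouds$dist_matrices[[j]])
  }
  euclidean_cross(clouds$coords[[j]], clouds$coords[[j + 1]])
}

euclidean_cross <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(0), nrow(a), nrow(b)))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# restrict a cloud set to given particle indices per channel, remembering
# the original indices (used by Mode I leftover matching)
subset_clouds <- function(clouds, keep) {
  stopifnot(length(keep) == clouds$k)
  coords <- Map(function(x, idx) x[idx, , drop = FALSE], clouds$coords, keep)
  dm <- clouds$dist_matrices
  if (!is.null(dm)) {
    for (j in seq_len(clouds$k - 1)) {
      if (!is.null(dm[[j]])) {
        dm[[j]] <- dm[[j]][keep[[j]], keep[[j + 1]], drop = FALSE]
      }
    }
  }
  out <- point_cloud_set(coords, unit = clouds$unit,
                         pixel_size_nm = clouds$pixel_size_nm,
                         dist_matrices = dm)
  out$orig_index <- keep
  out
}

# restrict to a contiguous channel span, keeping orig channel numbering
span_clouds <- function(clouds, span) {
  idx <- span[1]:span[2]
  dm <- NULL
  if (!is.null(clouds$dist_matrices)) {
    dm <- clouds$dist_matrices[idx[-length(idx)]]
  }
  out <- point_cloud_set(clouds$coords[idx], unit = clouds$unit,
                         pixel_size_nm = clouds$pixel_size_nm,
                         dist_matrices = dm)
  out$orig_index <- clouds$orig_index[idx]
  out$span_offset <- span[1] - 1L
  out
}
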