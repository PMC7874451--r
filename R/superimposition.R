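#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid, the standard size measure removed by Procrustes superimposition
#' and restored when working in form space.
#'
#' @param coords numeric k x 3 matrix of landmark coordinates (mm).
#' @return Centroid size, in the units of \code{coords}.
#' @export
centroid_size <- function(coords) {
  coords <- as_coord_matrix(coords)
  cs <- sqrt(sum(center_config(coords)^2))
  if (cs == 0) stop("degenerate configuration: all landmarks identical (zero centroid size)")
  cs
}

#' Symmetry map over landmark indices
#'
#' Pairs each left-side landmark index with its homologous right-side index;
#' midline landmarks are self-paired. Applying the map twice is the identity,
#' and pairs plus midline must partition \code{1:k}.
#'
#' @param pairs integer matrix with two columns (left index, right index).
#' @param midline integer vector of self-paired midline indices (may be empty).
#' @param k total number of landmarks.
#' @return An object of class \code{symmetry_map} with elements \code{pairs},
#'   \code{midline}, \code{k} and the full index permutation \code{perm}.
#' @export
symmetry_map <- function(pairs, midline = integer(0), k) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  midline <- as.integer(midline)
  idx <- c(pairs[, 1L], pairs[, 2L], midline)
  if (length(idx) != k || !setequal(idx, seq_len(k)) || anyDuplicated(idx))
    stop("symmetry map must partition 1:k into pairs and midline indices")
  perm <- seq_len(k)
  perm[pairs[, 1L]] <- pairs[, 2L]
  perm[pairs[, 2L]] <- pairs[, 1L]
  if (!identical(perm[perm], seq_len(k)))
    stop("symmetry map is not an involution")
  structure(list(pairs = pairs, midline = midline, k = k, perm = perm),
            class = "symmetry_map")
}

#' Reflect and relabel a configuration
#'
#' Mirrors a configuration across the midsagittal plane (x = 0) and swaps the
#' rows of paired left/right landmarks so that the reflected copy is a valid
#' configuration with the original labelling. Midline landmarks keep their
#' slot. This is the standard construction used to extract the symmetric
#' component of a bilaterally symmetric structure.
#'
#' @param coords k x 3 landmark matrix.
#' @param map a \code{\link{symmetry_map}} for the same k.
#' @return k x 3 matrix of the reflected, relabelled configuration.
#' @export
reflect_relabel <- function(coords, map) {
  coords <- as_coord_matrix(coords)
  if (!inherits(map, "symmetry_map")) stop("`map` must be a symmetry_map")
  if (nrow(coords) != map$k)
    stop("configuration has ", nrow(coords), " landmarks but map expects ", map$k)
  out <- coords[map$perm, , drop = FALSE]
  out[, 1L] <- -out[, 1L]
  dimnames(out) <- dimnames(coords)
  out
}

# Optimal rotation (det +1) taking X onto Y, both assumed centered.
# Reflections are never produced here; they enter only via reflect_relabel().
opa_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3L] <- -u[, 3L]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of a set of landmark configurations: each
#' configuration is centered, scaled to unit centroid size and rotated onto
#' the current mean shape; the mean is then re-estimated, renormalized to
#' unit centroid size, and the cycle repeats until the mean moves by less
#' than \code{tol}. Rotations are restricted to proper rotations
#' (determinant +1), so reflections can only enter through
#' \code{\link{reflect_relabel}}.
#'
#' With \code{include_reflections = TRUE} the superimposed set contains, for
#' each input, both the original and its reflected relabelled copy (2n items
#' in total), which is the prerequisite for
#' \code{\link{symmetric_component}}.
#'
#' @param configs a list of k x 3 matrices, or a k x 3 x n array.
#' @param include_reflections logical; superimpose each configuration
#'   together with its reflected relabelled copy.
#' @param map a \code{\link{symmetry_map}}; required when
#'   \code{include_reflections} is \code{TRUE}.
#' @param tol convergence tolerance on the root-mean-square displacement of
#'   the mean shape between iterations.
#' @param max_iter maximum number of GPA iterations.
#' @return Object of class \code{procrustes_result}: \code{shapes}
#'   (k x 3 x n array of shape coordinates for the original configurations),
#'   \code{reflected} (matching array for the reflected copies, or NULL),
#'   \code{mean_shape}, \code{centroid_sizes} (mm), \code{iterations},
#'   \code{converged}, and \code{objective} (the residual dispersion around
#'   the mean at each iteration, non-increasing for a healthy fit).
#' @export
gpa <- function(configs, include_reflections = FALSE, map = NULL,
                tol = 1e-10, max_iter = 100L) {
  configs <- as_config_list(configs)
  n <- length(configs)
  if (n < 1L) stop("need at least one configuration")
  k <- nrow(configs[[1L]])
  if (any(vapply(configs, nrow, 0L) != k)) stop("all configurations must share k")
  if (include_reflections) {
    if (is.null(map)) stop("include_reflections = TRUE requires a symmetry map")
    configs <- c(configs, lapply(configs, reflect_relabel, map = map))
  }
  m <- length(configs)

  sizes <- numeric(m)
  X <- vector("list", m)
  for (i in seq_len(m)) {
    ci <- center_config(configs[[i]])
    sizes[i] <- sqrt(sum(ci^2))
    if (sizes[i] == 0) stop("configuration ", i, " has zero centroid size")
    X[[i]] <- ci / sizes[i]
  }

  mean_shape <- X[[1L]]
  iterations <- 0L
  converged <- FALSE
  objective <- numeric(0)
  if (m == 1L) {
    converged <- TRUE
    iterations <- 1L
  } else {
    for (it in seq_len(max_iter)) {
      for (i in seq_len(m)) X[[i]] <- X[[i]] %*% opa_rotation(X[[i]], mean_shape)
      new_mean <- center_config(Reduce(`+`, X) / m)
      new_mean <- new_mean / sqrt(sum(new_mean^2))
      # residual dispersion around the freshly rotated-to mean
      objective <- c(objective,
                     sum(vapply(X, function(x) sum((x - mean_shape)^2), 0)))
      delta <- sqrt(mean((new_mean - mean_shape)^2))
      mean_shape <- new_mean
      iterations <- it
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      warning("GPA did not converge in ", max_iter,
              " iterations; returning partial result")
  }

  shapes <- array(unlist(X[seq_len(n)], use.names = FALSE), dim = c(k, 3L, n),
                  dimnames = list(NULL, c("x", "y", "z"), names(configs)[seq_len(n)]))
  reflected <- NULL
  if (include_reflections)
    reflected <- array(unlist(X[n + seq_len(n)], use.names = FALSE), dim = c(k, 3L, n))
  structure(list(shapes = shapes, reflected = reflected, mean_shape = mean_shape,
                 centroid_sizes = sizes[seq_len(n)], iterations = iterations,
                 converged = converged, objective = objective),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat("Generalized Procrustes Analysis\n")
  cat("  configurations:", dim(x$shapes)[3L],
      if (!is.null(x$reflected)) "(+ reflected relabelled copies)" else "", "\n")
  cat("  landmarks:     ", dim(x$shapes)[1L], "\n")
  cat("  iterations:    ", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  mean centroid size:", format(mean(x$centroid_sizes)), "mm\n")
  invisible(x)
}

#' Symmetric component of superimposed configurations
#'
#' For each original configuration, the landmark-wise average of its
#' superimposed shape and its superimposed reflected relabelled copy. The
#' result discards left-right asymmetry and is the input to all downstream
#' shape statistics in a bilateral-symmetry analysis.
#'
#' @param result a \code{procrustes_result} fitted with
#'   \code{include_reflections = TRUE}.
#' @return k x 3 x n array of symmetric-component shape coordinates.
#' @export
symmetric_component <- function(result) {
  if (!inherits(result, "procrustes_result")) stop("`result` must be a procrustes_result")
  if (is.null(result$reflected))
    stop("GPA was run without reflections; symmetric component undefined")
  (result$shapes + result$reflected) / 2
}

#' Procrustes distance between superimposed shapes
#'
#' Euclidean norm of the coordinate-wise difference between two shapes that
#' are already in a common superimposition frame. At the small shape
#' distances typical of dense facial data this linear surrogate agrees with
#' the full Procrustes (chord) distance to third order.
#'
#' @param a,b k x 3 shape coordinate matrices in the same frame.
#' @return Dimensionless Procrustes distance.
#' @export
procrustes_distance <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  if (!all(dim(a) == dim(b))) stop("shape dimensions differ")
  sqrt(sum((a - b)^2))
}

#' Form coordinates (shape times centroid size)
#'
#' Restores size to Procrustes shape coordinates by multiplying every
#' coordinate by the configuration's centroid size, yielding form
#' coordinates in mm with centroid at the origin.
#'
#' @param shape k x 3 shape coordinate matrix (unit centroid size).
#' @param size centroid size in mm; must be positive.
#' @return k x 3 form coordinate matrix (mm).
#' @export
to_form <- function(shape, size) {
  if (length(size) != 1L || !is.finite(size) || size <= 0)
    stop("`size` must be a single positive number")
  as_coord_matrix(shape) * size
}

center_config <- function(x) {
  x - matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE)
}

# coerce to a plain numeric k x 3 matrix, with validation
as_coord_matrix <- function(x) {
  if (inherits(x, "landmark_configuration")) x <- x$coords
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  if (nrow(x) < 3L) stop("need at least 3 landmarks")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("coordinates contain non-finite values")
  x
}

as_config_list <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    n <- dim(configs)[3L]
    configs <- lapply(seq_len(n), function(i) configs[, , i])
  }
  if (is.matrix(configs)) configs <- list(configs)
  lapply(configs, as_coord_matrix)
}
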