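#' Anchor set of five facial landmarks
#'
#' The five anchoring landmarks digitized on every face, in fixed order:
#' right exocanthus, left exocanthus, pronasale, right cheilion, left
#' cheilion. The fixed order is what lets a template be aligned to any
#' subject without further labelling.
#'
#' @param coords 5 x 3 numeric matrix (mm), rows in the fixed anchor order.
#' @return Object of class \code{anchor_set}.
#' @export
anchor_set <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != 5L || ncol(coords) != 3L)
    stop("anchor set must be exactly 5 points x 3 coordinates")
  if (!all(is.finite(coords))) stop("anchor coordinates must be finite")
  if (points_collinear(coords)) stop("anchor points are collinear or coincident")
  rownames(coords) <- c("exocanthion_r", "exocanthion_l", "pronasale",
                        "cheilion_r", "cheilion_l")
  structure(list(coords = coords), class = "anchor_set")
}

points_collinear <- function(x, tol = 1e-8) {
  xc <- center_config(x)
  d <- svd(xc, nu = 0, nv = 0)$d
  d[2L] <= tol * max(d[1L], tol)
}

#' Read five anchor landmarks from CSV
#'
#' CSV with columns x,y,z and five rows in the fixed anchor order.
#'
#' @param path CSV path.
#' @return An \code{\link{anchor_set}}.
#' @export
read_anchors <- function(path) {
  conf <- read_configuration(path)
  anchor_set(conf$coords)
}

#' Least-squares similarity transform between point sets
#'
#' Closed-form (SVD-based) estimate of the rotation, uniform scale and
#' translation minimizing the sum of squared residuals mapping \code{source}
#' onto \code{target}. Reflections are excluded: the rotation always has
#' determinant +1.
#'
#' @param source,target \code{\link{anchor_set}} objects or n x 3 matrices in
#'   one-to-one row correspondence (n >= 3, non-collinear).
#' @return Object of class \code{similarity_transform} with fields
#'   \code{scale}, \code{rotation} (3 x 3), \code{translation} (length 3) and
#'   \code{rss} (residual sum of squares).
#' @export
similarity_align_anchors <- function(source, target) {
  X <- if (inherits(source, "anchor_set")) source$coords else as_coord_matrix(source)
  Y <- if (inherits(target, "anchor_set")) target$coords else as_coord_matrix(target)
  if (!all(dim(X) == dim(Y))) stop("point sets must have matching dimensions")
  if (points_collinear(X) || points_collinear(Y))
    stop("degenerate configuration: points collinear or coincident")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- X - rep(mx, each = nrow(X)); Yc <- Y - rep(my, each = nrow(Y))
  s <- svd(crossprod(Xc, Yc))
  d <- rep(1, 3L)
  if (det(s$u %*% t(s$v)) < 0) d[3L] <- -1
  R <- s$v %*% diag(d) %*% t(s$u)              # maps source onto target
  scale <- sum(s$d * d) / sum(Xc^2)
  trans <- as.numeric(my - scale * R %*% mx)
  fitted <- scale * Xc %*% t(R) + rep(my, each = nrow(X))
  out <- structure(list(scale = scale, rotation = R, translation = trans,
                        rss = sum((fitted - Y)^2)),
                   class = "similarity_transform")
  validate_similarity(out)
  out
}

validate_similarity <- function(tf) {
  RtR <- crossprod(tf$rotation)
  if (max(abs(RtR - diag(3))) > 1e-10 || abs(det(tf$rotation) - 1) > 1e-10)
    stop("internal error: rotation is not a proper orthogonal matrix")
  if (tf$scale <= 0) stop("similarity scale must be positive")
  invisible(tf)
}

#' Apply a similarity transform to points
#'
#' @param tf a \code{similarity_transform}.
#' @param points n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_similarity <- function(tf, points) {
  points <- as.matrix(points)
  tf$scale * points %*% t(tf$rotation) +
    rep(tf$translation, each = nrow(points))
}

#' Thin-plate-spline warp in 3D
#'
#' Fits the 3D thin-plate spline with kernel U(r) = r (the standard 3D
#' choice) plus an affine part through the control-point pairs, then
#' evaluates the interpolant at the query points. The interpolant is exact
#' at the control points and reproduces any affine map with zero bending.
#'
#' @param control_src n x 3 source control points (n >= 5, non-coplanar,
#'   rows distinct).
#' @param control_dst n x 3 destination control points.
#' @param queries m x 3 points to warp.
#' @return m x 3 matrix of warped query points.
#' @export
tps_warp <- function(control_src, control_dst, queries) {
  S <- as_coord_matrix(control_src)
  D <- as_coord_matrix(control_dst)
  Q <- as.matrix(queries)
  n <- nrow(S)
  if (!all(dim(S) == dim(D))) stop("control point sets must match in size")
  if (n < 5L) stop("need at least 5 control points for a 3D TPS")
  dups <- as.matrix(stats::dist(S))
  diag(dups) <- Inf
  if (min(dups) < 1e-9)
    stop("TPS system singular: duplicate control points")
  P <- cbind(1, S)
  if (qr(P)$rank < 4L)
    stop("TPS affine part degenerate: control points are coplanar")
  K <- as.matrix(stats::dist(S))            # U(r) = r
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(D, matrix(0, 4L, 3L))
  coefs <- tryCatch(solve(L, rhs),
                    error = function(e) stop("TPS system is ill-conditioned: ", conditionMessage(e)))
  coefs <- coefs + solve(L, rhs - L %*% coefs)   # one step of iterative refinement
  W <- coefs[seq_len(n), , drop = FALSE]
  A <- coefs[n + 1:4, , drop = FALSE]
  # U(|q - s_i|) per control, differencing first to avoid cancellation
  U <- matrix(0, nrow(Q), n)
  for (i in seq_len(n))
    U[, i] <- sqrt((Q[, 1L] - S[i, 1L])^2 + (Q[, 2L] - S[i, 2L])^2 +
                     (Q[, 3L] - S[i, 3L])^2)
  out <- cbind(1, Q) %*% A + U %*% W
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Closest points on a triangle mesh
#'
#' Projects each query point to its nearest point on the mesh surface using
#' exact point-to-triangle distances (barycentric clamping). Ties between
#' equidistant triangles are broken toward the lowest triangle index.
#'
#' @param points m x 3 matrix of query points.
#' @param mesh a \code{\link{surface_mesh}}.
#' @return List with \code{points} (m x 3 projected coordinates),
#'   \code{distance} (m), and \code{face} (m, winning triangle index).
#' @export
project_to_mesh <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  P <- as.matrix(points)
  V <- mesh$vertices
  A <- V[mesh$faces[, 1L], , drop = FALSE]
  B <- V[mesh$faces[, 2L], , drop = FALSE]
  C <- V[mesh$faces[, 3L], , drop = FALSE]
  E0 <- B - A
  E1 <- C - A

  m <- nrow(P)
  nf <- nrow(A)
  out <- matrix(0, m, 3L)
  dist <- numeric(m)
  face <- integer(m)
  for (i in seq_len(m)) {
    p <- P[i, ]
    AP <- -sweep(A, 2L, p)
    BP <- -sweep(B, 2L, p)
    CP <- -sweep(C, 2L, p)
    d1 <- rowSums(E0 * AP); d2 <- rowSums(E1 * AP)
    d3 <- rowSums(E0 * BP); d4 <- rowSums(E1 * BP)
    d5 <- rowSums(E0 * CP); d6 <- rowSums(E1 * CP)
    vc <- d1 * d4 - d3 * d2
    vb <- d5 * d2 - d1 * d6
    va <- d3 * d6 - d5 * d4

    # region classification (first matching region wins, in the
    # vertex / edge / interior order of the standard algorithm)
    region <- integer(nf)
    claim <- function(cond, id) {
      sel <- region == 0L & cond
      region[sel] <<- id
      invisible(NULL)
    }
    claim(d1 <= 0 & d2 <= 0, 1L)                       # vertex A
    claim(d3 >= 0 & d4 <= d3, 2L)                      # vertex B
    claim(vc <= 0 & d1 >= 0 & d3 <= 0, 3L)             # edge AB
    claim(d6 >= 0 & d5 <= d6, 4L)                      # vertex C
    claim(vb <= 0 & d2 >= 0 & d6 <= 0, 5L)             # edge AC
    claim(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, 6L) # edge BC
    claim(rep(TRUE, nf), 7L)                           # interior

    v <- numeric(nf); w <- numeric(nf)
    sel <- region == 2L; v[sel] <- 1
    sel <- region == 3L; v[sel] <- d1[sel] / (d1[sel] - d3[sel])
    sel <- region == 4L; w[sel] <- 1
    sel <- region == 5L; w[sel] <- d2[sel] / (d2[sel] - d6[sel])
    sel <- region == 6L
    if (any(sel)) {
      wb <- (d4[sel] - d3[sel]) / ((d4[sel] - d3[sel]) + (d5[sel] - d6[sel]))
      v[sel] <- 1 - wb; w[sel] <- wb
    }
    sel <- region == 7L
    if (any(sel)) {
      denom <- va[sel] + vb[sel] + vc[sel]
      v[sel] <- vb[sel] / denom; w[sel] <- vc[sel] / denom
    }

    Q <- A + v * E0 + w * E1
    d2q <- rowSums(sweep(Q, 2L, p)^2)
    j <- which.min(d2q)   # which.min returns the lowest index on ties
    out[i, ] <- Q[j, ]
    dist[i] <- sqrt(d2q[j])
    face[i] <- j
  }
  list(points = out, distance = dist, face = face)
}

#' Map a quasi-landmark template onto a target mesh
#'
#' The transparent mapping pipeline: (1) similarity-align the template's five
#' anchor landmarks to the subject's digitized anchors; (2) thin-plate-spline
#' warp all template landmarks using the five anchor pairs as controls;
#' (3) project every warped landmark to the closest point on the target
#' surface. The output preserves template ordering, so landmark i corresponds
#' across subjects. Structures not covered by the template (hair, ears) are
#' excluded by construction.
#'
#' @param template a \code{\link{make_template}}-style template object.
#' @param mesh target \code{\link{surface_mesh}}.
#' @param anchors subject \code{\link{anchor_set}} in the fixed order.
#' @param gate_mm registration gate: if any aligned anchor lies farther than
#'   this from the mesh surface the mapping is treated as failed (default 30).
#' @param project logical; set \code{FALSE} to skip the surface-projection
#'   step (useful for diagnostics).
#' @param subject_id,stage,group metadata for the returned configuration.
#' @return A \code{\link{landmark_configuration}} with k = template size.
#' @export
map_template <- function(template, mesh, anchors, gate_mm = 30,
                         project = TRUE,
                         subject_id = NA, stage = NA, group = NA) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!inherits(anchors, "anchor_set")) anchors <- anchor_set(anchors)
  src_anchors <- template$coords[template$anchor_indices, , drop = FALSE]
  tf <- similarity_align_anchors(src_anchors, anchors$coords)
  aligned <- apply_similarity(tf, template$coords)
  aligned_anchors <- aligned[template$anchor_indices, , drop = FALSE]

  gap <- project_to_mesh(anchors$coords, mesh)$distance
  if (any(gap > gate_mm))
    stop("registration failure: anchor ", which.max(gap), " lies ",
         format(max(gap), digits = 4), " mm from the mesh surface (gate ",
         gate_mm, " mm)")

  warped <- tps_warp5(aligned_anchors, anchors$coords, aligned)
  if (project) warped <- project_to_mesh(warped, mesh)$points
  landmark_configuration(warped, subject_id, stage, group)
}

# TPS with exactly 5 controls: the generic solver requires non-coplanarity,
# which five digitized facial anchors satisfy in practice; if they are
# numerically coplanar fall back to the affine least-squares map.
tps_warp5 <- function(src, dst, queries) {
  ok <- qr(cbind(1, src))$rank == 4L
  if (ok) return(tps_warp(src, dst, queries))
  B <- stats::lm.fit(cbind(1, src), dst)$coefficients
  cbind(1, as.matrix(queries)) %*% B
}

#' Write / read a template to CSV + JSON
#'
#' The template is stored as a coordinates CSV next to a JSON file holding
#' anchor indices, region labels, symmetry pairs and triangulation.
#'
#' @param template template object.
#' @param prefix path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}.
#' @return Invisibly, the two paths.
#' @export
write_template <- function(template, prefix) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  write_configuration(template$coords, csv)
  meta <- list(anchor_indices = template$anchor_indices,
               region_labels = as.character(template$region_labels),
               symmetry_pairs = template$symmetry$pairs,
               symmetry_midline = template$symmetry$midline,
               faces = template$faces)
  jsonlite::write_json(meta, json, auto_unbox = FALSE, digits = NA)
  invisible(c(csv, json))
}

#' @rdname write_template
#' @export
read_template <- function(prefix) {
  coords <- read_configuration(paste0(prefix, ".csv"))$coords
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  k <- nrow(coords)
  structure(list(coords = coords,
                 anchor_indices = as.integer(meta$anchor_indices),
                 region_labels = factor(meta$region_labels,
                                        levels = c("buccal", "temporal", "labial",
                                                   "nasal", "other")),
                 symmetry = symmetry_map(matrix(as.integer(meta$symmetry_pairs), ncol = 2),
                                         as.integer(meta$symmetry_midline), k),
                 faces = matrix(as.integer(meta$faces), ncol = 3)),
            class = "quasi_template")
}
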