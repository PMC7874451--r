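#' Surface mesh constructor
#'
#' A triangle mesh with vertices in mm. Face indices are stored 1-based (the
#' R convention); PLY's 0-based and OBJ's 1-based indices are converted at
#' the file boundary.
#'
#' @param vertices numeric v x 3 matrix (mm).
#' @param faces integer f x 3 matrix of vertex indices (1-based).
#' @param colors optional v x 3 integer matrix of RGB values in 0..255.
#' @return Object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L)
    stop("mesh needs >= 3 vertices with 3 coordinates each")
  if (!all(is.finite(vertices))) stop("mesh vertices contain non-finite values")
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
          faces[, 2L] == faces[, 3L]))
    stop("degenerate face: repeated vertex index within a triangle")
  if (!is.null(colors)) {
    colors <- matrix(as.integer(colors), ncol = 3L)
    if (nrow(colors) != nrow(vertices)) stop("colors must match vertex count")
    if (any(colors < 0L) || any(colors > 255L)) stop("colors must be in 0..255")
  }
  structure(list(vertices = vertices, faces = faces, colors = colors),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces",
      if (!is.null(x$colors)) "(with vertex colors)" else "", "\n")
  invisible(x)
}

#' Read a surface mesh (ASCII PLY or OBJ)
#'
#' Parses ASCII PLY (vertex x,y,z with optional red/green/blue) and Wavefront
#' OBJ (v/f records only). Vertex order is preserved exactly as in the file:
#' for quasi-landmark data, ordering *is* the correspondence. Binary PLY is
#' rejected explicitly rather than misread.
#'
#' @param path path to a \code{.ply} or \code{.obj} file.
#' @return A \code{\link{surface_mesh}}.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format '.", ext, "' (expected ASCII PLY or OBJ)"))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ply")
    stop("malformed PLY header at line 1: missing 'ply' magic")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY header: no end_header")
  header <- trimws(lines[2:(end - 1L)])
  fmt <- grep("^format ", header, value = TRUE)
  if (length(fmt) != 1L) stop("malformed PLY header: missing format line")
  if (!grepl("^format ascii", fmt))
    stop("unsupported PLY dialect: only 'format ascii 1.0' is read (got '", fmt, "')")

  n_vertex <- n_face <- NA_integer_
  vertex_props <- character(0)
  current <- ""
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1L]]
    if (tok[1L] == "element") {
      current <- tok[2L]
      if (current == "vertex") n_vertex <- as.integer(tok[3L])
      if (current == "face") n_face <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && current == "vertex" && tok[2L] != "list") {
      vertex_props <- c(vertex_props, tok[3L])
    }
  }
  if (is.na(n_vertex) || is.na(n_face))
    stop("malformed PLY header: vertex/face element counts missing")
  need <- c("x", "y", "z")
  if (!all(need %in% vertex_props))
    stop("malformed PLY header: vertex element lacks x,y,z properties")

  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_vertex + n_face)
    stop("truncated PLY: expected ", n_vertex + n_face, " data lines, found ", length(body))

  vparse <- strsplit(trimws(body[seq_len(n_vertex)]), "\\s+")
  npc <- length(vertex_props)
  vnum <- vapply(vparse, function(v) {
    if (length(v) < npc) rep(NA_real_, npc) else as.numeric(v[seq_len(npc)])
  }, numeric(npc))
  vnum <- t(vnum)
  if (anyNA(vnum)) {
    bad <- which(apply(vnum, 1L, anyNA))[1L]
    stop("malformed PLY vertex record at data line ", bad)
  }
  verts <- vnum[, match(need, vertex_props), drop = FALSE]
  colors <- NULL
  if (all(c("red", "green", "blue") %in% vertex_props))
    colors <- vnum[, match(c("red", "green", "blue"), vertex_props), drop = FALSE]

  fparse <- strsplit(trimws(body[n_vertex + seq_len(n_face)]), "\\s+")
  faces <- t(vapply(fparse, function(f) {
    v <- suppressWarnings(as.integer(f))
    if (anyNA(v) || v[1L] != 3L || length(v) < 4L)
      return(rep(NA_integer_, 3L))
    v[2:4]
  }, integer(3L)))
  if (anyNA(faces)) {
    bad <- which(apply(faces, 1L, anyNA))[1L]
    stop("malformed PLY face record at data line ", n_vertex + bad,
         " (only triangles with a leading count of 3 are supported)")
  }
  surface_mesh(verts, faces + 1L, colors)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines)
  flines <- grep("^f\\s", lines)
  if (length(vlines) == 0L) stop("OBJ file has no vertex records")
  verts <- t(vapply(strsplit(trimws(lines[vlines]), "\\s+"), function(v) {
    as.numeric(v[2:4])
  }, numeric(3L)))
  if (anyNA(verts))
    stop("malformed OBJ vertex record at line ", vlines[which(apply(is.na(verts), 1, any))[1L]])
  faces <- t(vapply(strsplit(trimws(lines[flines]), "\\s+"), function(f) {
    # strip texture/normal references: "f 1/2/3 ..." -> vertex index only
    idx <- suppressWarnings(as.integer(sub("/.*$", "", f[-1L])))
    if (length(idx) != 3L || anyNA(idx)) rep(NA_integer_, 3L) else idx
  }, integer(3L)))
  if (anyNA(faces))
    stop("malformed OBJ face record at line ",
         flines[which(apply(is.na(faces), 1, any))[1L]],
         " (only triangular faces are supported)")
  surface_mesh(verts, faces)
}

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @param path output path.
#' @param digits number of significant digits for vertex coordinates.
#' @return Invisibly, \code{path}.
#' @export
write_mesh <- function(mesh, path, digits = 9L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  has_col <- !is.null(mesh$colors)
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(v)),
              "property float x", "property float y", "property float z",
              if (has_col) c("property uchar red", "property uchar green",
                             "property uchar blue"),
              paste("element face", nrow(mesh$faces)),
              "property list uchar int vertex_indices",
              "end_header")
  vtxt <- apply(format(v, digits = digits, trim = TRUE, scientific = FALSE), 1L,
                paste, collapse = " ")
  if (has_col)
    vtxt <- paste(vtxt, apply(mesh$colors, 1L, paste, collapse = " "))
  ftxt <- paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L)
  writeLines(c(header, vtxt, ftxt), path)
  invisible(path)
}

#' Export a per-vertex scalar field as a colored ASCII PLY heatmap
#'
#' Maps a scalar field (e.g. per-landmark displacement magnitude, R-squared
#' or -log10 p) to vertex colors and writes an ASCII PLY. Values are min-max
#' normalized over the finite entries unless an explicit \code{range} is
#' given; missing values are rendered neutral gray.
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @param scalars numeric vector, one value per vertex; NA allowed.
#' @param path output path.
#' @param palette a palette name understood by \code{\link[grDevices]{hcl.colors}}
#'   (e.g. "Viridis", "Blue-Red 3").
#' @param range optional length-2 numeric; scalars are clamped to it and its
#'   endpoints map to the palette endpoints.
#' @param na_color color used for missing scalars (default neutral gray).
#' @return Invisibly, \code{path}.
#' @export
write_colored_mesh <- function(mesh, scalars, path, palette = "Viridis",
                               range = NULL, na_color = "gray50") {
  stopifnot(inherits(mesh, "surface_mesh"))
  scalars <- as.numeric(scalars)
  if (length(scalars) != nrow(mesh$vertices))
    stop("scalars length (", length(scalars), ") must equal vertex count (",
         nrow(mesh$vertices), ")")
  ok <- is.finite(scalars)
  ramp <- grDevices::hcl.colors(256L, palette)
  if (is.null(range)) {
    range <- if (any(ok)) range(scalars[ok]) else c(0, 1)
  }
  span <- diff(range)
  u <- if (span > 0) pmin(pmax((scalars - range[1L]) / span, 0), 1) else rep(0.5, length(scalars))
  idx <- 1L + as.integer(round(u * 255))
  idx[!ok] <- 1L
  cols <- t(grDevices::col2rgb(ramp[idx]))
  if (any(!ok))
    cols[!ok, ] <- matrix(grDevices::col2rgb(na_color)[, 1L],
                          sum(!ok), 3L, byrow = TRUE)
  write_mesh(surface_mesh(mesh$vertices, mesh$faces, cols), path)
}

#' Export a binary significance mask as a two-color PLY
#'
#' Significant vertices are drawn in pink on a neutral gray face, the usual
#' convention for marking regions with p below the chosen alpha.
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @param significant logical vector, one entry per vertex.
#' @param path output path.
#' @param sig_color,bg_color colors for significant / non-significant vertices.
#' @return Invisibly, \code{path}.
#' @export
write_mask_mesh <- function(mesh, significant, path,
                            sig_color = "#FF69B4", bg_color = "gray80") {
  significant <- as.logical(significant)
  if (length(significant) != nrow(mesh$vertices))
    stop("mask length must equal vertex count")
  pal <- t(grDevices::col2rgb(c(bg_color, sig_color)))
  cols <- pal[significant + 1L, , drop = FALSE]
  write_mesh(surface_mesh(mesh$vertices, mesh$faces, cols), path)
}

#' Landmark configuration constructor
#'
#' One subject-stage observation: k ordered quasi-landmarks in mm plus
#' subject/stage/group labels. Row order encodes landmark correspondence
#' across subjects and is never permuted by I/O.
#'
#' @param coords k x 3 numeric matrix (mm).
#' @param subject_id subject identifier.
#' @param stage treatment-stage label (e.g. "T0").
#' @param group group label (e.g. "extraction").
#' @return Object of class \code{landmark_configuration}.
#' @export
landmark_configuration <- function(coords, subject_id = NA_character_,
                                   stage = NA_character_, group = NA_character_) {
  coords <- as_coord_matrix(coords)
  structure(list(coords = coords, subject_id = as.character(subject_id),
                 stage = as.character(stage), group = as.character(group)),
            class = "landmark_configuration")
}

#' Read / write a landmark configuration CSV
#'
#' Plain CSV with header \code{x,y,z} (mm), one row per landmark, in template
#' order.
#'
#' @param path CSV path.
#' @param subject_id,stage,group metadata attached to the configuration
#'   (typically from the design table).
#' @return \code{read_configuration}: a \code{\link{landmark_configuration}}.
#' @export
read_configuration <- function(path, subject_id = NA, stage = NA, group = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("configuration CSV must have columns x,y,z: ", path)
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df[, c("x", "y", "z")])), ncol = 3L))
  bad <- which(!is.finite(m))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    stop("non-finite or non-numeric coordinate at row ", row, " of ", path)
  }
  landmark_configuration(m, subject_id, stage, group)
}

#' @rdname read_configuration
#' @param conf a \code{landmark_configuration} or bare k x 3 matrix.
#' @export
write_configuration <- function(conf, path) {
  coords <- if (inherits(conf, "landmark_configuration")) conf$coords else as_coord_matrix(conf)
  df <- data.frame(x = coords[, 1L], y = coords[, 2L], z = coords[, 3L])
  utils::write.csv(format(df, digits = 12L, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a study design table
#'
#' CSV with header \code{subject_id,stage,group[,file]}. Stages are restricted
#' to the declared ordered set; the group must be constant within subject and
#' each (subject, stage) may appear only once.
#'
#' @param path CSV path.
#' @param stages ordered character vector of admissible stage labels.
#' @return A \code{data.frame} with factor \code{stage} (ordered levels) and
#'   \code{group}, of class \code{c("design_table","data.frame")}.
#' @export
read_design <- function(path, stages = c("T0", "T1", "T2")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (nrow(df) == 0L) stop("no observations in design table: ", path)
  validate_design(df, stages)
}

validate_design <- function(df, stages = c("T0", "T1", "T2")) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("subject_id", "stage", "group")
  if (!all(need %in% names(df)))
    stop("design table must have columns subject_id, stage, group")
  if (nrow(df) == 0L) stop("no observations in design table")
  if (!all(df$stage %in% stages))
    stop("unknown stage label(s): ",
         paste(unique(setdiff(df$stage, stages)), collapse = ", "))
  key <- paste(df$subject_id, df$stage)
  if (anyDuplicated(key))
    stop("duplicate (subject, stage) observation: ", key[duplicated(key)][1L])
  ng <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  if (any(ng > 1L))
    stop("group varies within subject: ", names(ng)[ng > 1L][1L])
  df$stage <- factor(df$stage, levels = stages)
  df$group <- factor(df$group)
  class(df) <- c("design_table", "data.frame")
  df
}
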