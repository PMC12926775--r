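# Surface mesh graph and ROI mask containers. Vertex indices are 0-based
# everywhere (the FreeSurfer label-file convention), so label files need no
# index shift on read or write.

#' Construct a surface mesh graph
#'
#' A light-weight undirected graph over surface vertices with an optional
#' parcellation, supporting connected-component cluster extraction and
#' parcel lookup.
#'
#' @param n_vertices Number of vertices on the mesh.
#' @param edges Two-column matrix of 0-based vertex index pairs (undirected).
#' @param parcel_of Optional character vector of length `n_vertices` giving
#'   the parcel name of each vertex.
#' @return An object of class `mesh_graph`.
#' @export
mesh_graph <- function(n_vertices, edges, parcel_of = NULL) {
  cs_assert(is_count(n_vertices, min = 1), "n_vertices must be a positive integer")
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  }
  cs_assert(ncol(edges) == 2, "edges must have two columns")
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  cs_assert(all(edges >= 0) && all(edges < n_vertices),
            "edge endpoints must be 0-based indices below n_vertices")
  cs_assert(all(edges[, 1] != edges[, 2]), "self-loops are not allowed")
  if (!is.null(parcel_of)) {
    cs_assert(length(parcel_of) == n_vertices,
              "parcel_of must have one entry per vertex")
    parcel_of <- as.character(parcel_of)
  }
  structure(list(n_vertices = as.integer(n_vertices), edges = edges,
                 parcel_of = parcel_of),
            class = "mesh_graph")
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat(sprintf("Mesh graph: %d vertices, %d edges", x$n_vertices, nrow(x$edges)))
  if (!is.null(x$parcel_of)) {
    cat(sprintf(", %d parcels", length(unique(x$parcel_of))))
  }
  cat("\n")
  invisible(x)
}

#' Build a rectangular grid mesh
#'
#' A convenience mesh with 4-neighbour connectivity, used by the synthetic
#' module and in examples. Vertices are numbered row-major, 0-based.
#'
#' @param nrow,ncol Grid dimensions.
#' @param parcel_of Optional parcel names (length `nrow * ncol`).
#' @return A [mesh_graph()].
#' @export
make_grid_mesh <- function(nrow, ncol, parcel_of = NULL) {
  cs_assert(is_count(nrow) && is_count(ncol), "grid dimensions must be positive integers")
  idx <- function(r, c) (r - 1L) * ncol + (c - 1L)  # 0-based
  h <- cbind(rep(seq_len(nrow), each = ncol - 1L),
             rep(seq_len(ncol - 1L), times = nrow))
  v <- cbind(rep(seq_len(nrow - 1L), each = ncol),
             rep(seq_len(ncol), times = nrow - 1L))
  edges <- rbind(
    if (ncol > 1) cbind(idx(h[, 1], h[, 2]), idx(h[, 1], h[, 2] + 1L)),
    if (nrow > 1) cbind(idx(v[, 1], v[, 2]), idx(v[, 1] + 1L, v[, 2]))
  )
  mesh_graph(nrow * ncol, edges, parcel_of = parcel_of)
}

#' Read / write a mesh as TSV
#'
#' The edge table has columns `v1` and `v2` (0-based); the optional
#' parcellation table has columns `vertex` and `parcel`.
#'
#' @param path Edge TSV path.
#' @param n_vertices Number of mesh vertices (indices in the file must be
#'   below this).
#' @param parcellation_path Optional parcellation TSV path.
#' @return For `read_mesh_tsv`, a [mesh_graph()].
#' @export
read_mesh_tsv <- function(path, n_vertices, parcellation_path = NULL) {
  cs_assert(file.exists(path), "mesh file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  cs_assert(all(c("v1", "v2") %in% names(tab)), "mesh TSV needs columns v1, v2")
  parcel_of <- NULL
  if (!is.null(parcellation_path)) {
    parcel_of <- read_parcellation_tsv(parcellation_path, n_vertices)
  }
  mesh_graph(n_vertices, as.matrix(tab[c("v1", "v2")]), parcel_of = parcel_of)
}

#' @rdname read_mesh_tsv
#' @param mesh A `mesh_graph`.
#' @export
write_mesh_tsv <- function(mesh, path, parcellation_path = NULL) {
  cs_assert(inherits(mesh, "mesh_graph"), "mesh must be a mesh_graph")
  utils::write.table(data.frame(v1 = mesh$edges[, 1], v2 = mesh$edges[, 2]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(parcellation_path) && !is.null(mesh$parcel_of)) {
    utils::write.table(
      data.frame(vertex = seq_len(mesh$n_vertices) - 1L, parcel = mesh$parcel_of),
      parcellation_path, sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

read_parcellation_tsv <- function(path, n_vertices) {
  cs_assert(file.exists(path), "parcellation file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character"))
  cs_assert(all(c("vertex", "parcel") %in% names(tab)),
            "parcellation TSV needs columns vertex, parcel")
  cs_assert(all(tab$vertex >= 0 & tab$vertex < n_vertices),
            "parcellation vertex indices out of range")
  parcel_of <- rep(NA_character_, n_vertices)
  parcel_of[tab$vertex + 1L] <- tab$parcel
  parcel_of
}

#' Construct an ROI mask
#'
#' A named set of 0-based vertex indices on a shared mesh, with a free-form
#' provenance record (thresholds, parcels, cluster sizes used to build it).
#'
#' @param name Mask name (`"core"`, `"control"`, or custom).
#' @param vertices Integer vector of 0-based vertex indices.
#' @param source Optional named list recording how the mask was derived.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, vertices, source = list()) {
  vertices <- sort(unique(as.integer(vertices)))
  cs_assert(length(vertices) > 0, "an ROI mask cannot be empty")
  cs_assert(all(vertices >= 0), "vertex indices must be non-negative (0-based)")
  structure(list(name = as.character(name), vertices = vertices, source = source),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask '%s': %d vertices\n", x$name, length(x$vertices)))
  invisible(x)
}

#' Read a FreeSurfer label file
#'
#' Label files are plain text: a comment line, a count line, then one row per
#' vertex (`index x y z value`). Vertex indices are 0-based.
#'
#' @param path Path to the label file.
#' @param name Name for the resulting mask (defaults to the file stem).
#' @return An [roi_mask()].
#' @export
read_label_mask <- function(path, name = NULL) {
  cs_assert(file.exists(path), "label file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cs_assert(length(lines) >= 2, "label file %s is truncated", path)
  body_start <- if (startsWith(trimws(lines[1]), "#")) 2L else 1L
  count <- suppressWarnings(as.integer(trimws(lines[body_start])))
  cs_assert(!is.na(count) && count >= 0, "label file %s: bad count line", path)
  rows <- lines[seq.int(body_start + 1L, length.out = length(lines) - body_start)]
  if (length(rows) != count) {
    cs_abort("label file %s declares %d vertices but has %d rows",
             path, count, length(rows))
  }
  vertices <- vapply(strsplit(trimws(rows), "[[:space:]]+"),
                     function(f) as.integer(f[1]), integer(1))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  roi_mask(name, vertices, source = list(file = path))
}

#' Write an ROI mask as a FreeSurfer label file
#'
#' Coordinates are written as zeros (only the vertex index set is meaningful
#' for this package); `values` fills the fifth column, e.g. with W-scores.
#'
#' @param mask An `roi_mask`.
#' @param path Output path.
#' @param values Optional numeric vector (per mask vertex) for the value
#'   column; defaults to 0.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path, values = NULL) {
  cs_assert(inherits(mask, "roi_mask"), "mask must be an roi_mask")
  n <- length(mask$vertices)
  if (is.null(values)) values <- rep(0, n)
  cs_assert(length(values) == n, "values must match the mask size")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#!ascii label, mask '%s' (%d vertices)", mask$name, n), con)
  writeLines(as.character(n), con)
  writeLines(sprintf("%d  0.000  0.000  0.000 %.10g", mask$vertices, values), con)
  invisible(path)
}
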