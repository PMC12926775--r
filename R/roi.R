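# Individualized ROI construction from a W-score map on a surface mesh:
# core-atrophy masks from thresholded, cluster-filtered atrophic vertices and
# a sensorimotor control mask with atrophic vertices removed.

#' Threshold a W-score map
#'
#' Returns exactly the (0-based) vertices whose W-score is strictly below
#' `threshold`.
#'
#' @param wmap A [compute_wscores()] result or a plain numeric vector of
#'   W-scores indexed by vertex (0-based positions).
#' @param threshold W-score threshold (default -2).
#' @return Integer vector of 0-based vertex indices.
#' @export
threshold_wmap <- function(wmap, threshold = -2) {
  w <- if (inherits(wmap, "wscore_map")) wmap$w else as.numeric(wmap)
  cs_assert(is_number(threshold) || identical(threshold, -Inf),
            "threshold must be a number")
  which(!is.na(w) & w < threshold) - 1L
}

#' Extract clusters of atrophic vertices
#'
#' Finds connected components of the subgraph induced by `vertices` on the
#' mesh, then keeps components of size at least `min_size` whose majority
#' parcel is in `allowed_parcels` (when given). This rule is the reproducible
#' stand-in for manual cluster curation: the anatomical selection criteria
#' become explicit configuration recorded in each mask's provenance.
#'
#' @param vertices Integer vector of 0-based vertex indices (e.g. from
#'   [threshold_wmap()]).
#' @param mesh A [mesh_graph()].
#' @param min_size Minimum cluster size (default 1).
#' @param allowed_parcels Optional character vector of parcel names; a
#'   cluster survives only if its most frequent parcel is listed.
#' @return A list of [roi_mask()] objects, largest first; empty list when no
#'   cluster survives.
#' @export
extract_clusters <- function(vertices, mesh, min_size = 1,
                             allowed_parcels = NULL) {
  cs_assert(inherits(mesh, "mesh_graph"), "mesh must be a mesh_graph")
  vertices <- sort(unique(as.integer(vertices)))
  if (length(vertices) == 0) return(list())
  cs_assert(all(vertices >= 0 & vertices < mesh$n_vertices),
            "vertices must lie on the mesh")
  keep_edge <- mesh$edges[, 1] %in% vertices & mesh$edges[, 2] %in% vertices
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(mesh$edges[keep_edge, 1]),
                   to = as.character(mesh$edges[keep_edge, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(vertices))
  )
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(vertices)]
  clusters <- split(vertices, membership)
  clusters <- clusters[order(-lengths(clusters))]
  out <- list()
  for (cl in clusters) {
    if (length(cl) < min_size) next
    majority <- NA_character_
    if (!is.null(mesh$parcel_of)) {
      tab <- sort(table(mesh$parcel_of[cl + 1L]), decreasing = TRUE)
      if (length(tab) > 0) majority <- names(tab)[1]
    }
    if (!is.null(allowed_parcels) && !(majority %in% allowed_parcels)) next
    out[[length(out) + 1L]] <- roi_mask(
      sprintf("cluster%02d", length(out) + 1L), cl,
      source = list(kind = "cluster", size = length(cl),
                    majority_parcel = majority, min_size = min_size,
                    allowed_parcels = allowed_parcels)
    )
  }
  out
}

#' Build the individualized core-atrophy ROI
#'
#' Thresholds the W-score map at `threshold` (strict `<`), extracts connected
#' clusters, applies the size/parcel selection rule, and unions the surviving
#' clusters into one mask.
#'
#' @inheritParams extract_clusters
#' @param wmap W-score map (vertex-indexed).
#' @param threshold Core W-score threshold (default -2).
#' @return An [roi_mask()] named `"core"`.
#' @export
make_core_roi <- function(wmap, mesh, threshold = -2, min_size = 1,
                          allowed_parcels = NULL) {
  atrophic <- threshold_wmap(wmap, threshold)
  clusters <- extract_clusters(atrophic, mesh, min_size = min_size,
                               allowed_parcels = allowed_parcels)
  if (length(clusters) == 0) {
    cs_abort("no cluster of atrophic vertices (W < %g) survives min_size = %d%s",
             threshold, min_size,
             if (is.null(allowed_parcels)) "" else " and the parcel filter")
  }
  roi_mask("core", unlist(lapply(clusters, `[[`, "vertices")),
           source = list(kind = "core", threshold = threshold,
                         min_size = min_size, allowed_parcels = allowed_parcels,
                         cluster_sizes = vapply(clusters, function(m)
                           length(m$vertices), integer(1))))
}

#' Build the sensorimotor control ROI
#'
#' Starts from the vertices of the named parcels (pre/postcentral gyri by
#' default, i.e. primary motor and somatosensory cortex) and removes any
#' vertex with W strictly below `exclusion`, so that the control region
#' contains minimal baseline atrophy. Vertices with `W == exclusion` are
#' kept.
#'
#' @param mesh A [mesh_graph()] with a parcellation.
#' @param wmap W-score map (vertex-indexed).
#' @param parcels Parcel names forming the control region.
#' @param exclusion W-score removal threshold (default -0.25; strict `<`).
#' @return An [roi_mask()] named `"control"`.
#' @export
make_control_roi <- function(mesh, wmap, parcels = c("precentral", "postcentral"),
                             exclusion = -0.25) {
  cs_assert(inherits(mesh, "mesh_graph"), "mesh must be a mesh_graph")
  cs_assert(!is.null(mesh$parcel_of), "mesh has no parcellation")
  missing <- setdiff(parcels, unique(mesh$parcel_of))
  if (length(missing) > 0) {
    cs_abort("parcel(s) not present in the parcellation: %s",
             paste(missing, collapse = ", "))
  }
  w <- if (inherits(wmap, "wscore_map")) wmap$w else as.numeric(wmap)
  candidates <- which(mesh$parcel_of %in% parcels) - 1L
  kept <- candidates[!(w[candidates + 1L] < exclusion)]
  if (length(kept) == 0) {
    cs_abort(paste0("control ROI is empty: all %d vertices of parcels {%s} have ",
                    "W < %g; consider different parcels"),
             length(candidates), paste(parcels, collapse = ", "), exclusion)
  }
  roi_mask("control", kept,
           source = list(kind = "control", parcels = parcels,
                         exclusion = exclusion,
                         n_candidates = length(candidates),
                         n_removed = length(candidates) - length(kept)))
}

#' Mean thickness over an ROI
#'
#' Unweighted arithmetic mean of the vertex thickness values inside the mask
#' (mirroring how published cluster-scanning analyses average all vertices
#' within an ROI boundary). An area-weighted mean is available when vertex
#' areas are supplied, but is off by default.
#'
#' @param thickness_map Numeric vector of per-vertex thickness (mm), indexed
#'   by 0-based vertex position.
#' @param mask An [roi_mask()].
#' @param vertex_area Optional per-vertex areas for a weighted mean.
#' @return Mean thickness in mm.
#' @export
roi_mean_thickness <- function(thickness_map, mask, vertex_area = NULL) {
  cs_assert(inherits(mask, "roi_mask"), "mask must be an roi_mask")
  cs_assert(max(mask$vertices) < length(thickness_map),
            "thickness map does not cover the mask (mask vertex %d, map length %d)",
            max(mask$vertices), length(thickness_map))
  vals <- thickness_map[mask$vertices + 1L]
  if (is.null(vertex_area)) return(mean(vals))
  wts <- vertex_area[mask$vertices + 1L]
  sum(vals * wts) / sum(wts)
}
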