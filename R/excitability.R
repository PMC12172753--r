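#' MEP-weighted excitability map
#'
#' A muscle's cortical representation: a subset of template vertices with
#' non-negative interpolated MEP weights.
#'
#' @param surface the template [tri_surface].
#' @param vertex_ids integer vector of (unique, 1-based) vertex indices.
#' @param mep numeric vector of non-negative weights, one per vertex.
#' @param muscle_label,intensity_condition optional metadata.
#' @return an object of class `excitability_map`.
#' @export
excitability_map <- function(surface, vertex_ids, mep, muscle_label = NA,
                             intensity_condition = NA) {
  vertex_ids <- as.integer(vertex_ids)
  if (anyDuplicated(vertex_ids)) stop("vertex_ids must be unique")
  if (length(mep) != length(vertex_ids))
    stop("one weight per vertex required")
  if (any(mep < 0)) stop("MEP weights must be non-negative")
  if (length(vertex_ids) &&
      (min(vertex_ids) < 1L || max(vertex_ids) > nrow(surface$vertices)))
    stop("vertex_ids out of range")
  structure(list(surface = surface, vertex_ids = vertex_ids,
                 mep = as.numeric(mep), muscle_label = muscle_label,
                 intensity_condition = intensity_condition),
            class = "excitability_map")
}

#' @export
print.excitability_map <- function(x, ...) {
  cat("excitability_map:", length(x$vertex_ids), "vertices",
      if (!is.na(x$muscle_label)) paste0("(", x$muscle_label, ")"), "\n")
  invisible(x)
}

#' Interpolate stimulation amplitudes onto mesh vertices
#'
#' Spreads MEP amplitudes from stimulation vertices onto the surrounding
#' surface: every vertex within geodesic radius `radius_mm` of at least one
#' stimulation vertex receives the inverse-distance-weighted mean of those
#' amplitudes; stimulation vertices keep their own amplitude exactly
#' (amplitudes of stimulations landing on the same vertex are averaged
#' first); vertices reached by no stimulation are excluded from the map.
#'
#' @param stims data.frame with `vertex_id` (template vertices) and `mep_uv`.
#' @param surface the template [tri_surface].
#' @param radius_mm geodesic search radius (mm).
#' @param muscle_label,intensity_condition metadata carried into the map.
#' @return an [excitability_map].
#' @export
interpolate_to_vertices <- function(stims, surface, radius_mm = 5,
                                    muscle_label = NA,
                                    intensity_condition = NA) {
  if (nrow(stims) == 0L) stop("empty stimulation set")
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  amp <- tapply(stims$mep_uv, stims$vertex_id, mean)
  src <- as.integer(names(amp))
  amp <- as.numeric(amp)
  d <- geodesic_distances(surface, src) # sources x vertices
  reach <- d <= radius_mm
  keep <- which(colSums(reach) > 0)
  vals <- vapply(keep, function(j) {
    within <- which(reach[, j])
    dj <- d[within, j]
    if (any(dj == 0)) return(mean(amp[within[dj == 0]]))
    w <- 1 / dj
    sum(w * amp[within]) / sum(w)
  }, 0)
  excitability_map(surface, keep, vals, muscle_label, intensity_condition)
}

#' MEP-weighted centroid of an excitability map
#'
#' The weighted mean position `sum(MEP_i * v_i) / sum(MEP_i)` over the map's
#' vertices.
#'
#' @param map an [excitability_map].
#' @return numeric 3-vector (mm).
#' @export
map_centroid <- function(map) {
  w <- map$mep
  if (sum(w) <= 0) stop("undefined centroid: all weights are zero")
  v <- map$surface$vertices[map$vertex_ids, , drop = FALSE]
  as.numeric(colSums(v * w) / sum(w))
}

# triangles of the surface whose three vertices all belong to the vertex set
complete_triangles <- function(surface, vertex_ids) {
  inmap <- logical(nrow(surface$vertices))
  inmap[vertex_ids] <- TRUE
  f <- surface$faces
  which(inmap[f[, 1]] & inmap[f[, 2]] & inmap[f[, 3]])
}

# Heron area per face (semi-perimeter product form, radicand clipped at 0)
heron_areas <- function(surface, face_idx) {
  f <- surface$faces[face_idx, , drop = FALSE]
  v <- surface$vertices
  el <- function(i, j) sqrt(rowSums((v[f[, i], , drop = FALSE] -
                                       v[f[, j], , drop = FALSE])^2))
  l1 <- el(1, 2); l2 <- el(2, 3); l3 <- el(3, 1)
  s <- (l1 + l2 + l3) / 2
  sqrt(pmax(s * (s - l1) * (s - l2) * (s - l3), 0))
}

# mean of the three vertex weights per face, given a per-vertex weight lookup
face_mean_weight <- function(surface, face_idx, vertex_ids, weights) {
  wfull <- rep(NA_real_, nrow(surface$vertices))
  wfull[vertex_ids] <- weights
  f <- surface$faces[face_idx, , drop = FALSE]
  (wfull[f[, 1]] + wfull[f[, 2]] + wfull[f[, 3]]) / 3
}

#' MEP-weighted area of an excitability map
#'
#' Sum, over every surface triangle whose three vertices belong to the map,
#' of the triangle's Heron area multiplied by the mean MEP weight of its
#' vertices (units weight x mm^2). With all weights equal to one this is the
#' geometric area of the mapped patch.
#'
#' @param map an [excitability_map].
#' @param unit_weights if `TRUE`, ignore the MEP weights (geometric area).
#' @return weighted area; 0 (with a warning) when no triangle is complete in
#'   the map.
#' @export
area_size <- function(map, unit_weights = FALSE) {
  tri <- complete_triangles(map$surface, map$vertex_ids)
  if (length(tri) == 0L) {
    warning("no complete triangle in map; size is 0")
    return(0)
  }
  a <- heron_areas(map$surface, tri)
  if (unit_weights) return(sum(a))
  mw <- face_mean_weight(map$surface, tri, map$vertex_ids, map$mep)
  sum(mw * a)
}

#' Overlap between two excitability maps
#'
#' Intersection-over-union of two muscles' cortical representations on the
#' same template surface. Triangle sets are the triangles complete in each
#' map; the intersection is the triangles complete in both, the union those
#' complete in at least one. In `"geometric"` mode (default) every triangle
#' counts with its Heron area alone; in `"weighted"` mode each triangle's
#' area is multiplied by a MEP weight derived from the max-normalised maps
#' (the mean of the two muscles' mean vertex weights where both are present,
#' the available muscle's weight elsewhere).
#'
#' @param map_k,map_l [excitability_map]s on the same template surface.
#' @param mode `"geometric"` or `"weighted"`.
#' @return overlap in `[0, 1]`.
#' @export
map_overlap <- function(map_k, map_l, mode = c("geometric", "weighted")) {
  mode <- match.arg(mode)
  surf <- map_k$surface
  if (!identical(dim(surf$vertices), dim(map_l$surface$vertices)) ||
      !identical(surf$faces, map_l$surface$faces))
    stop("maps must live on the same template surface")
  tk <- complete_triangles(surf, map_k$vertex_ids)
  tl <- complete_triangles(surf, map_l$vertex_ids)
  uni <- union(tk, tl)
  if (length(uni) == 0L) stop("undefined overlap: empty union")
  inter <- intersect(tk, tl)
  a <- heron_areas(surf, uni)
  if (mode == "geometric") {
    w <- rep(1, length(uni))
  } else {
    wk <- face_mean_weight(surf, uni, map_k$vertex_ids,
                           map_k$mep / max(map_k$mep))
    wl <- face_mean_weight(surf, uni, map_l$vertex_ids,
                           map_l$mep / max(map_l$mep))
    w <- ifelse(!is.na(wk) & !is.na(wl), (wk + wl) / 2,
                ifelse(is.na(wk), wl, wk))
  }
  sum(w * a * (uni %in% inter)) / sum(w * a)
}

#' Muscle-pair grouping skeleton
#'
#' Enumerates the 28 unordered pairs of the eight canonical muscles,
#' partitioned into hand-hand, hand-forearm, and forearm-forearm groups, and
#' flags the synergistic pairs: FDI-APB, FDI-FPB, APB-FPB within the hand;
#' EDC-ECR and FDS-FCR within the forearm; and EDC/FDS paired with each of
#' FDI, APB, FPB, ADM across hand and forearm.
#'
#' @param labels the eight canonical muscle labels (any order).
#' @return data.frame with columns `muscle_k`, `muscle_l`, `pair_group`,
#'   `synergistic` (28 rows).
#' @export
pair_grouping <- function(labels = muscle_labels()) {
  unknown <- setdiff(labels, muscle_labels())
  if (length(unknown))
    stop("unknown muscle label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(labels)) stop("duplicate muscle labels")
  if (length(labels) != 8L) stop("expected the 8 canonical muscle labels")
  pairs <- utils::combn(labels, 2)
  k <- pairs[1, ]; l <- pairs[2, ]
  grp <- function(m) ifelse(m %in% HAND_MUSCLES, "hand", "forearm")
  gk <- grp(k); gl <- grp(l)
  pair_group <- ifelse(gk == "hand" & gl == "hand", "hand-hand",
                       ifelse(gk == "forearm" & gl == "forearm",
                              "forearm-forearm", "hand-forearm"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  syn_hh <- c(key("FDI", "APB"), key("FDI", "FPB"), key("APB", "FPB"))
  syn_ff <- c(key("EDC", "ECR"), key("FDS", "FCR"))
  syn_hf <- as.vector(outer(c("EDC", "FDS"), c("FDI", "APB", "FPB", "ADM"),
                            key))
  synergistic <- key(k, l) %in% c(syn_hh, syn_ff, syn_hf)
  data.frame(muscle_k = k, muscle_l = l, pair_group = pair_group,
             synergistic = synergistic, stringsAsFactors = FALSE)
}

#' Pairwise overlap table for a set of maps
#'
#' Computes [map_overlap()] for the 28 muscle pairs and joins the
#' [pair_grouping()] columns.
#'
#' @param maps named list of eight [excitability_map]s (names are muscle
#'   labels).
#' @param mode overlap weighting mode, see [map_overlap()].
#' @return data.frame with `muscle_k`, `muscle_l`, `overlap`, `pair_group`,
#'   `synergistic`, `mode`.
#' @export
overlap_table <- function(maps, mode = c("geometric", "weighted")) {
  mode <- match.arg(mode)
  tab <- pair_grouping(names(maps))
  tab$overlap <- vapply(seq_len(nrow(tab)), function(i)
    map_overlap(maps[[tab$muscle_k[i]]], maps[[tab$muscle_l[i]]], mode), 0)
  tab$mode <- mode
  tab[, c("muscle_k", "muscle_l", "overlap", "pair_group", "synergistic",
          "mode")]
}
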