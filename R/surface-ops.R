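#' Project a stimulation event onto the nearest surface vertex
#'
#' Nearest-vertex (Euclidean) projection of the coil position; coil
#' orientation is deliberately not used. Ties are broken by the lowest vertex
#' index.
#'
#' @param event a stimulation event (one row of an event table, or any list
#'   with `x_mm`, `y_mm`, `z_mm`), or a numeric 3-vector.
#' @param surface a [tri_surface].
#' @return 1-based vertex index.
#' @export
project_event_to_vertex <- function(event, surface) {
  if (nrow(surface$vertices) == 0L) stop("empty surface")
  p <- if (is.numeric(event) && length(event) == 3L) event else
    c(event$x_mm, event$y_mm, event$z_mm)
  if (length(p) != 3L || anyNA(p)) stop("event must carry a 3-vector position")
  d2 <- (surface$vertices[, 1] - p[1])^2 + (surface$vertices[, 2] - p[2])^2 +
    (surface$vertices[, 3] - p[3])^2
  which.min(d2) # which.min returns the first (lowest-index) minimum
}

#' Restrict vertex indices to an atlas region
#'
#' Keeps the indices whose atlas label equals `region` (by default the left
#' precentral gyrus, i.e. primary motor cortex), preserving order. Masking can
#' be disabled with `enabled = FALSE`, in which case the input is returned
#' unchanged (the whole-cortex analysis variant).
#'
#' @param vertex_ids integer vector of 1-based vertex indices.
#' @param surface a [tri_surface] with atlas labels.
#' @param region atlas label to keep.
#' @param enabled if `FALSE`, no masking is performed.
#' @return filtered vertex indices.
#' @export
mask_to_region <- function(vertex_ids, surface, region = "precentral L",
                           enabled = TRUE) {
  if (!enabled) return(vertex_ids)
  if (is.null(surface$atlas_labels)) stop("surface has no atlas labels")
  if (!any(surface$atlas_labels == region))
    warning("region '", region, "' labels no vertex of this surface")
  vertex_ids[surface$atlas_labels[vertex_ids] == region]
}

# z-scored curvature (zero vector when curvature is constant)
zscore_curv <- function(curv) {
  s <- sd(curv)
  if (!is.finite(s) || s == 0) return(rep(0, length(curv)))
  (curv - mean(curv)) / s
}

#' Warp a subject vertex to the template surface
#'
#' Finds, for a subject vertex, the template vertex minimising the sum of the
#' great-circle distance between their unit-sphere registration coordinates
#' and a curvature-mismatch penalty,
#' `arccos(clip(s . t, -1, 1)) + lambda_curv * |c_s - c_t|`,
#' where curvatures are z-scored within each surface so that both terms are
#' dimensionless. Ties are broken by the lowest template vertex index.
#'
#' @param source_vertex 1-based vertex index on the subject surface.
#' @param subject,template [tri_surface]s with sphere registrations (and
#'   curvature when `lambda_curv > 0`).
#' @param lambda_curv non-negative weight of the curvature penalty.
#' @return 1-based template vertex index.
#' @export
warp_vertex <- function(source_vertex, subject, template, lambda_curv = 1) {
  warp_vertices(source_vertex, subject, template, lambda_curv)
}

#' Warp several subject vertices to the template surface
#'
#' Vectorised form of [warp_vertex()].
#'
#' @inheritParams warp_vertex
#' @param source_vertices integer vector of subject vertex indices.
#' @return integer vector of template vertex indices.
#' @export
warp_vertices <- function(source_vertices, subject, template,
                          lambda_curv = 1) {
  if (is.null(subject$sphere) || is.null(template$sphere))
    stop("both surfaces need a sphere registration to warp")
  if (lambda_curv < 0) stop("lambda_curv must be non-negative")
  use_curv <- lambda_curv > 0
  if (use_curv && (is.null(subject$curvature) || is.null(template$curvature)))
    stop("curvature required on both surfaces when lambda_curv > 0")
  s <- subject$sphere[source_vertices, , drop = FALSE]
  tt <- template$sphere
  dots <- pmin(pmax(s %*% t(tt), -1), 1)
  cost <- acos(dots)
  if (use_curv) {
    cs <- zscore_curv(subject$curvature)[source_vertices]
    ct <- zscore_curv(template$curvature)
    cost <- cost + lambda_curv * abs(outer(cs, ct, "-"))
  }
  as.integer(apply(cost, 1, which.min))
}

#' Warp a stimulation set to the template surface
#'
#' Carries a set of (subject vertex, MEP amplitude) pairs to template
#' vertices via [warp_vertices()]; amplitudes are unchanged. Input rows are
#' expected to be already masked and MEP-positive.
#'
#' @param stims data.frame with columns `vertex_id` (1-based subject vertex)
#'   and `mep_uv`; further columns are carried through.
#' @inheritParams warp_vertex
#' @return the input data.frame with `vertex_id` replaced by template indices.
#' @export
warp_events <- function(stims, subject, template, lambda_curv = 1) {
  if (nrow(stims) == 0L) return(stims)
  uniq <- sort(unique(stims$vertex_id))
  mapped <- warp_vertices(uniq, subject, template, lambda_curv)
  stims$vertex_id <- mapped[match(stims$vertex_id, uniq)]
  stims
}
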