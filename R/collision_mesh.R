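# Mesh-to-mesh contact backend. The AABB tree is built once per mesh in its
# body frame; at query time the opposing mesh is posed into the tree frame, so
# a rocking femur never forces a tree rebuild.

#' Build an axis-aligned bounding-box tree over a mesh
#'
#' Recursive median split of the dominant box axis; every leaf encloses
#' exactly one triangle.
#'
#' @param mesh `pf_mesh` (coordinates as given; build in the body frame and
#'   pose the probe for moving bodies).
#' @return Object of class `pf_aabb_tree` holding the compiled tree handle and
#'   the source mesh.
#' @export
build_aabb_tree <- function(mesh) {
  stopifnot(inherits(mesh, "pf_mesh"))
  ptr <- cpp_aabb_build(mesh$vertices, mesh$faces)
  structure(list(ptr = ptr, mesh = mesh), class = "pf_aabb_tree")
}

#' Inspect the nodes of an AABB tree
#'
#' Returns the node table (box bounds, child links, leaf triangle ids) for
#' structural checks; indices are 1-based with 0 meaning "none".
#' @param tree `pf_aabb_tree`.
#' @export
aabb_nodes <- function(tree) {
  stopifnot(inherits(tree, "pf_aabb_tree"))
  cpp_aabb_nodes(tree$ptr)
}

#' Depth of an AABB tree (edges on the longest root-leaf path)
#' @param tree `pf_aabb_tree`.
#' @export
aabb_depth <- function(tree) cpp_aabb_depth(tree$ptr)

#' Collision candidates for an axis-aligned probe box
#'
#' @param tree `pf_aabb_tree`.
#' @param box_min,box_max probe box corners (length-3).
#' @return sorted integer vector of candidate triangle ids; a superset of the
#'   triangles whose own boxes intersect the probe.
#' @export
query_candidates <- function(tree, box_min, box_max) {
  stopifnot(inherits(tree, "pf_aabb_tree"))
  cpp_aabb_query(tree$ptr, as.numeric(box_min), as.numeric(box_max))
}

#' Cast a ray against a mesh tree
#' @param tree `pf_aabb_tree`; `origin`, `direction` length-3.
#' @return list with `hit` (triangle id, 0 if none), `t`, `normal`.
#' @export
ray_mesh <- function(tree, origin, direction) {
  cpp_ray_mesh(tree$ptr, as.numeric(origin), as.numeric(direction))
}

#' Detect mesh-to-mesh contact patches
#'
#' Finds triangle-pair intersections between the posed meshes by dual
#' traversal of mesh A's AABB tree, chains the intersection segments into
#' contour(s), and reports one contact patch per contour: averaged contact
#' point (length-weighted contour centroid), area-weighted average normal of
#' the penetrated A faces (oriented from surface A toward body B), and the
#' maximum indentation (deepest B vertex below A's surface along the patch
#' normal). An open (non-chainable) contour triggers a warning and falls back
#' to the deepest-point contact of that contour; near-coplanar triangle pairs
#' are resolved by a deterministic 1e-9 m normal jitter of body B.
#'
#' @param treeA `pf_aabb_tree` of the reference surface (femur), built in its
#'   body frame.
#' @param poseA,poseB poses `list(x =, q =)` of bodies A and B.
#' @param meshB `pf_mesh` of body B (patella button) in its body frame.
#' @param twistA,twistB optional `list(v =, w =)` world linear velocity and
#'   body angular velocity; needed for the approach rate `delta_dot`.
#' @param episodes optional episode-state environment from
#'   [contact_episodes()]; latches `delta_dot0` per contact episode.
#' @param commit update the episode state (TRUE at accepted steps only).
#' @return list of contact patches (classed `pf_contact_patch`): `point`,
#'   `normal` (world frame), `delta`, `delta_dot`, `delta_dot0`, `contour`,
#'   `closed`.
#' @export
mesh_contacts <- function(treeA, poseA, meshB, poseB,
                          twistA = NULL, twistB = NULL,
                          episodes = NULL, commit = FALSE) {
  stopifnot(inherits(treeA, "pf_aabb_tree"), inherits(meshB, "pf_mesh"))
  RA <- quat_to_mat(poseA$q); RB <- quat_to_mat(poseB$q)
  # pose B vertices into A's frame
  VBw <- meshB$vertices %*% t(RB)
  VBw <- sweep(VBw, 2, poseB$x, "+")
  VBa <- sweep(VBw, 2, poseA$x) %*% RA
  bcen <- drop(crossprod(RA, colMeans(VBw) - poseA$x))
  res <- cpp_mesh_contacts(treeA$ptr, VBa, meshB$faces, meshB$face_normals,
                           bcen)
  if (isTRUE(res$coplanar)) {
    VBa2 <- sweep(VBa, 2, c(0, 0, 1e-9), "+")  # deterministic normal jitter
    res <- cpp_mesh_contacts(treeA$ptr, VBa2, meshB$faces,
                             meshB$face_normals, bcen)
  }
  if (res$n_patches == 0) {
    if (!is.null(episodes) && commit) episodes_end_all(episodes)
    return(list())
  }
  out <- vector("list", res$n_patches)
  for (i in seq_len(res$n_patches)) {
    p <- res$patches[[i]]
    if (!isTRUE(p$closed))
      warning("open contact contour; falling back to deepest-point contact")
    pt_w <- drop(RA %*% p$point) + poseA$x
    n_w <- drop(RA %*% p$normal)
    delta_dot <- 0
    if (!is.null(twistA) && !is.null(twistB)) {
      vA <- twistA$v + drop(RA %*% cross3(twistA$w,
                                          drop(crossprod(RA, pt_w - poseA$x))))
      vB <- twistB$v + drop(RB %*% cross3(twistB$w,
                                          drop(crossprod(RB, pt_w - poseB$x))))
      delta_dot <- -sum((vB - vA) * n_w)
    }
    dd0 <- if (!is.null(episodes))
      episode_delta_dot0(episodes, i, p$delta, delta_dot, commit) else NA_real_
    out[[i]] <- structure(list(point = pt_w, normal = n_w, delta = p$delta,
                               delta_dot = delta_dot, delta_dot0 = dd0,
                               contour = p$contour, closed = isTRUE(p$closed),
                               n_segments = p$n_segments),
                          class = "pf_contact_patch")
  }
  if (!is.null(episodes) && commit)
    episodes_keep_active(episodes, seq_len(res$n_patches))
  out
}

#' Dump contact contours as OBJ polylines (debug aid)
#' @param patches list of `pf_contact_patch`.
#' @param path output OBJ path (`l` line records).
#' @export
write_contours_obj <- function(patches, path) {
  con <- file(path, "w")
  on.exit(close(con))
  off <- 0L
  for (p in patches) {
    pts <- p$contour
    writeLines(sprintf("v %.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
    ns <- nrow(pts) / 2
    writeLines(sprintf("l %d %d", off + 2 * seq_len(ns) - 1,
                       off + 2 * seq_len(ns)), con)
    off <- off + nrow(pts)
  }
  invisible(path)
}
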