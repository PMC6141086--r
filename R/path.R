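#' World-space path of a muscle element
#'
#' Transforms the element's path nodes to world coordinates and applies each
#' wrap cylinder (at most one per span, between consecutive nodes).  The
#' result is a piecewise path of straight segments and helical arcs whose
#' total length is the muscle-tendon path length.
#'
#' @param model A `skeletal_model`.
#' @param poses Segment poses from [forward_kinematics()].
#' @param muscle A muscle element of `model` (or its name).
#' @return List with `points` (ordered list of `list(xyz, owner)` world
#'   points: nodes plus engaged tangent points, tangent points owned by the
#'   wrap cylinder's segment), `length` (m), `engaged` (logical per wrap),
#'   and `wrap_results` (raw [wrap_over_cylinder()] outputs per span).
#' @export
compute_path <- function(model, poses, muscle) {
  if (is.character(muscle)) {
    muscle <- model$muscles[[muscle]] %||%
      stop("unknown muscle '", muscle, "'", call. = FALSE)
  }
  nodes_w <- lapply(muscle$nodes, function(nd)
    list(xyz = world_point(poses, nd$segment, nd$point), owner = nd$segment))
  wrap_by_span <- list()
  for (w in muscle$wraps) wrap_by_span[[as.character(w$between[1])]] <- w

  points <- list(nodes_w[[1]])
  total <- 0
  engaged <- logical(0)
  wrap_results <- list()
  for (i in seq_len(length(nodes_w) - 1L)) {
    a <- nodes_w[[i]]; b <- nodes_w[[i + 1L]]
    w <- wrap_by_span[[as.character(i)]]
    if (is.null(w)) {
      total <- total + vnorm(b$xyz - a$xyz)
    } else {
      res <- tryCatch(
        wrap_over_cylinder(a$xyz, b$xyz, w, poses[[w$segment]]),
        error = function(e) stop("muscle '", muscle$name, "': ",
                                 conditionMessage(e), call. = FALSE))
      total <- total + res$length
      engaged <- c(engaged, res$engaged)
      wrap_results[[length(wrap_results) + 1L]] <- res
      if (res$engaged) {
        points <- c(points, list(list(xyz = res$t1, owner = w$segment),
                                 list(xyz = res$t2, owner = w$segment)))
      }
    }
    points <- c(points, list(b))
  }
  list(points = points, length = total, engaged = engaged,
       wrap_results = wrap_results, name = muscle$name)
}

#' Muscle-tendon path length
#'
#' @inheritParams compute_path
#' @return Length in m.
#' @export
muscle_length <- function(model, poses, muscle) {
  compute_path(model, poses, muscle)$length
}

#' Line of action of a muscle across a joint
#'
#' Muscle paths are straight where they cross a joint (a wrap surface belongs
#' to one side or the other), so the line of action is the unit vector along
#' the straight path piece crossing the joint, oriented from the distal-side
#' point toward the proximal-side point (the direction in which the muscle
#' pulls on the distal body), anchored at the distal-side point.
#'
#' @param model A `skeletal_model`.
#' @param poses Segment poses from [forward_kinematics()].
#' @param muscle A muscle element of `model` (or its name).
#' @param joint Name of the joint crossed.
#' @return List with `u` (unit 3-vector, world), `anchor` (world 3-vector,
#'   distal-side point), `proximal_point`, and the crossing point owners.
#' @export
line_of_action <- function(model, poses, muscle, joint) {
  path <- compute_path(model, poses, muscle)
  distal <- distal_segments(model, joint)
  owners <- vapply(path$points, `[[`, "", "owner")
  is_distal <- owners %in% distal
  if (!any(is_distal) || all(is_distal)) {
    stop("muscle '", path$name, "' does not span joint '", joint, "'",
         call. = FALSE)
  }
  k <- which(is_distal)[1]
  if (k == 1L) {
    stop("muscle '", path$name, "' path starts distal to joint '", joint,
         "'; expected origin on the proximal side", call. = FALSE)
  }
  prox <- path$points[[k - 1L]]$xyz
  dist <- path$points[[k]]$xyz
  list(u = unitv(prox - dist), anchor = dist, proximal_point = prox,
       proximal_owner = owners[k - 1L], distal_owner = owners[k])
}

# Does the muscle span the joint (nodes on both sides of the cut)?
muscle_spans_joint <- function(model, muscle, joint) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  distal <- distal_segments(model, joint)
  owners <- vapply(muscle$nodes, `[[`, "", "segment")
  any(owners %in% distal) && any(!(owners %in% distal))
}
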