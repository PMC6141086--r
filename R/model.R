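#' Build a skeletal model from a configuration document
#'
#' Constructs a validated rigid-body lower-limb model from a structured
#' configuration (a YAML file path or an already-parsed list).  The model is
#' a tree of segments connected by ball (3-dof) and hinge (1-dof) joints,
#' rooted at a floating-base segment (conventionally the pelvis, carrying 6
#' base dofs), with muscle elements (origin-to-insertion node chains, optional
#' via points and single-cylinder wrapping surfaces, constant strength),
#' a skin-marker protocol, and optional patella couplers that slave a patella
#' segment's pose to the knee flexion angle without adding dofs.
#'
#' All coordinates are in meters in the owning segment's frame; frames are
#' right-handed; masses in kg; strengths in N.  Gravity defaults to
#' `c(0, 0, -9.81)` m/s^2 (world z up).
#'
#' @param config Path to a YAML model file, or a list with elements
#'   `segments`, `joints`, `muscles`, `markers`, and optionally `couplers`,
#'   `gravity`, `subject_mass`, `subject_height`, `femur_frame`.
#' @return An object of class `skeletal_model`.
#' @examples
#' mdl <- make_toy_model("planar-2seg")
#' n_dof(mdl)
#' @export
build_model <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))

  segs <- list()
  for (s in config$segments) {
    inertia <- parse_inertia(s$inertia)
    seg <- list(
      name = s$name,
      mass = as.numeric(s$mass %||% 0),
      mass_fraction = if (!is.null(s$mass_fraction)) as.numeric(s$mass_fraction) else NULL,
      com_local = as.numeric(s$com %||% c(0, 0, 0)),
      inertia_local = inertia,
      length = as.numeric(s$length %||% 1),
      parent_joint = NULL
    )
    if (seg$mass < 0) {
      stop("segment '", s$name, "': mass must be >= 0", call. = FALSE)
    }
    if (max(abs(inertia - t(inertia))) > 1e-12) {
      stop("segment '", s$name, "': inertia tensor must be symmetric", call. = FALSE)
    }
    if (min(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      stop("segment '", s$name, "': inertia tensor must be positive semidefinite",
           call. = FALSE)
    }
    if (seg$length <= 0) {
      stop("segment '", s$name, "': length must be > 0", call. = FALSE)
    }
    segs[[s$name]] <- seg
  }
  if (length(segs) == 0L) stop("model has no segments", call. = FALSE)

  need_segment <- function(name, where) {
    if (is.null(segs[[name]])) {
      stop(where, ": unresolved segment reference '", name, "'", call. = FALSE)
    }
    name
  }

  joints <- list()
  for (j in config$joints) {
    kind <- match.arg(j$kind, c("ball", "hinge"))
    jt <- list(
      name = j$name,
      kind = kind,
      parent_segment = need_segment(j$parent, paste0("joint '", j$name, "'")),
      child_segment = need_segment(j$child, paste0("joint '", j$name, "'")),
      location_in_parent = as.numeric(j$location_in_parent %||% c(0, 0, 0)),
      location_in_child = as.numeric(j$location_in_child %||% c(0, 0, 0)),
      hinge_axis = NULL,
      dof_names = j$dof_names
    )
    if (kind == "hinge") {
      ax <- as.numeric(j$axis)
      if (abs(vnorm(ax) - 1) > 1e-9) ax <- unitv(ax)
      jt$hinge_axis <- ax
    }
    if (is.null(jt$dof_names)) {
      jt$dof_names <- if (kind == "ball") {
        paste0(j$name, c("_rx", "_ry", "_rz"))
      } else {
        paste0(j$name, "_angle")
      }
    }
    joints[[j$name]] <- jt
    if (!is.null(segs[[jt$child_segment]]$parent_joint)) {
      stop("segment '", jt$child_segment, "' has more than one parent joint",
           call. = FALSE)
    }
    segs[[jt$child_segment]]$parent_joint <- j$name
  }

  couplers <- list()
  for (cp in config$couplers %||% list()) {
    tab <- do.call(rbind, lapply(cp$table, as.numeric))
    if (ncol(tab) != 7L) {
      stop("coupler table rows must be (angle, tx, ty, tz, rx, ry, rz)",
           call. = FALSE)
    }
    if (any(diff(tab[, 1]) <= 0)) {
      stop("coupler table angles must be strictly increasing", call. = FALSE)
    }
    couplers[[cp$segment]] <- list(
      knee_joint = cp$knee_joint,
      segment = need_segment(cp$segment, "coupler"),
      table = tab
    )
    if (is.null(joints[[cp$knee_joint]])) {
      stop("coupler: unresolved joint reference '", cp$knee_joint, "'",
           call. = FALSE)
    }
  }

  muscles <- list()
  for (m in config$muscles %||% list()) {
    nodes <- lapply(m$nodes, function(nd) {
      list(segment = need_segment(nd$segment, paste0("muscle '", m$name, "'")),
           point = as.numeric(nd$point))
    })
    if (length(nodes) < 2L) {
      stop("muscle '", m$name, "' needs at least 2 path nodes", call. = FALSE)
    }
    wraps <- lapply(m$wraps %||% list(), function(w) {
      ax <- as.numeric(w$axis)
      list(between = as.integer(w$between),
           segment = need_segment(w$segment, paste0("muscle '", m$name, "' wrap")),
           center = as.numeric(w$center),
           axis = unitv(ax),
           radius = as.numeric(w$radius),
           side = as.numeric(w$side %||% 1))
    })
    for (w in wraps) {
      if (w$radius <= 0) {
        stop("muscle '", m$name, "': wrap radius must be > 0", call. = FALSE)
      }
      if (length(w$between) != 2L || w$between[2] != w$between[1] + 1L ||
          w$between[1] < 1L || w$between[2] > length(nodes)) {
        stop("muscle '", m$name, "': wrap 'between' must name consecutive nodes",
             call. = FALSE)
      }
    }
    strength <- as.numeric(m$strength)
    if (!is.finite(strength) || strength <= 0) {
      stop("muscle '", m$name, "': strength must be > 0", call. = FALSE)
    }
    muscles[[m$name]] <- list(name = m$name,
                              group = m$group %||% m$name,
                              nodes = nodes, wraps = wraps,
                              strength = strength)
  }

  markers <- list()
  for (mk in config$markers %||% list()) {
    markers[[mk$name]] <- list(
      name = mk$name,
      segment = need_segment(mk$segment, paste0("marker '", mk$name, "'")),
      point = as.numeric(mk$point),
      weight = as.numeric(mk$weight %||% 1),
      bony = isTRUE(mk$bony),
      optimize = as.logical(mk$optimize %||% c(FALSE, FALSE, FALSE))
    )
    if (!is.finite(markers[[mk$name]]$weight) || markers[[mk$name]]$weight < 0) {
      stop("marker '", mk$name, "': weight must be finite and >= 0", call. = FALSE)
    }
  }
  if (length(markers) > 0) {
    w_bony <- vapply(markers, function(m) if (m$bony) m$weight else Inf, 0)
    w_other <- vapply(markers, function(m) if (!m$bony) m$weight else 0, 0)
    if (min(w_bony) < max(w_other)) {
      stop("marker protocol: bony-landmark weights must be >= other weights",
           call. = FALSE)
    }
  }

  model <- structure(list(
    name = config$name %||% "model",
    segments = segs,
    joints = joints,
    couplers = couplers,
    muscles = muscles,
    markers = markers,
    gravity = as.numeric(config$gravity %||% c(0, 0, -9.81)),
    subject_mass = as.numeric(config$subject_mass %||% sum(vapply(segs, `[[`, 0, "mass"))),
    subject_height = as.numeric(config$subject_height %||% 1.75),
    femur_frame = config$femur_frame
  ), class = "skeletal_model")

  model$root <- find_root(model)
  model$dofs <- dof_layout(model)
  model$order <- topo_order(model)
  model
}

parse_inertia <- function(x) {
  if (is.null(x)) return(diag(3) * 0)
  x <- unlist(x)
  if (length(x) == 3L) return(diag(as.numeric(x)))
  matrix(as.numeric(x), 3, 3, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

find_root <- function(model) {
  coupled <- names(model$couplers)
  roots <- names(model$segments)[vapply(model$segments, function(s)
    is.null(s$parent_joint), TRUE)]
  roots <- setdiff(roots, coupled)
  if (length(roots) != 1L) {
    stop("joint graph must be a tree with exactly one root segment (found ",
         length(roots), ")", call. = FALSE)
  }
  roots
}

# Segments in parent-before-child order (root first); detects cycles.
topo_order <- function(model) {
  children <- lapply(model$segments, function(s) character(0))
  for (j in model$joints) {
    children[[j$parent_segment]] <- c(children[[j$parent_segment]], j$child_segment)
  }
  for (cp in model$couplers) {
    parent <- model$joints[[cp$knee_joint]]$child_segment
    children[[parent]] <- c(children[[parent]], cp$segment)
  }
  ord <- character(0)
  visit <- function(s, trail) {
    if (s %in% trail) stop("cyclic joint graph at segment '", s, "'", call. = FALSE)
    ord <<- c(ord, s)
    for (ch in children[[s]]) visit(ch, c(trail, s))
  }
  visit(model$root, character(0))
  if (length(ord) != length(model$segments)) {
    stop("joint graph is not a tree rooted at '", model$root,
         "': unreachable segments ",
         paste(setdiff(names(model$segments), ord), collapse = ", "),
         call. = FALSE)
  }
  ord
}

# Generalized-coordinate layout: 6 floating-base dofs (world xyz translation
# of the root origin, then intrinsic XYZ Euler angles), then each joint's
# dofs in tree order.
dof_layout <- function(model) {
  nm <- c(paste0(model$root, c("_tx", "_ty", "_tz", "_rx", "_ry", "_rz")))
  joint_of <- rep(NA_character_, 6)
  idx <- list()
  ord_segs <- topo_order(model)
  for (s in ord_segs) {
    jn <- model$segments[[s]]$parent_joint
    if (is.null(jn)) next
    j <- model$joints[[jn]]
    k <- length(nm)
    nd <- if (j$kind == "ball") 3L else 1L
    idx[[jn]] <- (k + 1L):(k + nd)
    nm <- c(nm, j$dof_names[seq_len(nd)])
    joint_of <- c(joint_of, rep(jn, nd))
  }
  list(names = nm, n = length(nm), joint_dofs = idx, joint_of = joint_of)
}

#' Number of generalized coordinates of a model
#'
#' @param model A `skeletal_model`.
#' @return Integer dof count (6 floating-base + joint dofs).
#' @export
n_dof <- function(model) model$dofs$n

#' Names of the generalized coordinates
#' @param model A `skeletal_model`.
#' @return Character vector of dof names in `q` order.
#' @export
dof_names <- function(model) model$dofs$names

#' @export
print.skeletal_model <- function(x, ...) {
  cat("<skeletal_model> '", x$name, "'\n", sep = "")
  cat("  segments:", length(x$segments), " joints:", length(x$joints),
      " muscles:", length(x$muscles), " markers:", length(x$markers), "\n")
  cat("  dofs:", x$dofs$n, " root:", x$root,
      " subject:", x$subject_mass, "kg /", x$subject_height, "m\n")
  invisible(x)
}

#' Total mass of all model segments
#' @param model A `skeletal_model`.
#' @return Mass in kg.
#' @export
total_mass <- function(model) sum(vapply(model$segments, `[[`, 0, "mass"))

#' Body weight of the modelled subject
#' @param model A `skeletal_model`.
#' @return Weight in N (`subject_mass * |gravity|`).
#' @export
body_weight <- function(model) model$subject_mass * vnorm(model$gravity)

# Segment names strictly distal to (on the child side of) a joint's cut.
distal_segments <- function(model, joint) {
  j <- model$joints[[joint]]
  if (is.null(j)) stop("unknown joint '", joint, "'", call. = FALSE)
  children <- lapply(model$segments, function(s) character(0))
  for (jj in model$joints) {
    children[[jj$parent_segment]] <- c(children[[jj$parent_segment]], jj$child_segment)
  }
  for (cp in model$couplers) {
    parent <- model$joints[[cp$knee_joint]]$child_segment
    children[[parent]] <- c(children[[parent]], cp$segment)
  }
  out <- character(0)
  gather <- function(s) {
    out <<- c(out, s)
    for (ch in children[[s]]) gather(ch)
  }
  gather(j$child_segment)
  out
}
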