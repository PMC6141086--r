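#' Weighted least-squares inverse kinematics for one frame
#'
#' Finds the posture minimizing the weighted sum of squared distances
#' between measured markers and the model's virtual markers, by a damped
#' Gauss-Newton (Levenberg-Marquardt) iteration with a finite-difference
#' Jacobian.  Markers with missing samples (any `NA` coordinate) are dropped
#' for the frame.
#'
#' @param model A `skeletal_model` with a marker protocol.
#' @param markers Named list or 3 x n matrix of measured world positions (m).
#' @param q_init Starting coordinates (warm start from the previous frame in
#'   trial processing).
#' @param tol Convergence tolerance on the objective decrease (default
#'   1e-14).
#' @param max_iter Iteration cap (default 100).
#' @return List with `q`, `objective` (weighted SSE, m^2), `residuals`
#'   (per-marker distance, m), `iterations`.
#' @export
solve_frame_ik <- function(model, markers, q_init = rep(0, n_dof(model)),
                           tol = 1e-14, max_iter = 100L) {
  if (is.matrix(markers)) {
    markers <- stats::setNames(lapply(seq_len(ncol(markers)),
                                      function(j) markers[, j]),
                               colnames(markers))
  }
  use <- intersect(names(model$markers), names(markers))
  use <- use[vapply(use, function(mn) !anyNA(markers[[mn]]), TRUE)]
  nd <- n_dof(model)
  if (3L * length(use) < nd) {
    stop("underdetermined pose: ", length(use), " usable markers give ",
         3L * length(use), " constraints for ", nd, " dofs", call. = FALSE)
  }
  w <- sqrt(vapply(use, function(mn) model$markers[[mn]]$weight, 0))
  meas <- unlist(lapply(use, function(mn) markers[[mn]]))

  res_fun <- function(q) {
    poses <- forward_kinematics(model, q)
    vm <- unlist(lapply(use, function(mn)
      world_point(poses, model$markers[[mn]]$segment, model$markers[[mn]]$point)))
    rep(w, each = 3L) * (vm - meas)
  }

  q <- q_init
  r <- res_fun(q)
  obj <- sum(r^2)
  mu <- 1e-8
  h <- 1e-6
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    J <- matrix(0, length(r), nd)
    for (d in seq_len(nd)) {
      qp <- q; qp[d] <- q[d] + h
      J[, d] <- (res_fun(qp) - r) / h
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (try in 1:40) {
      d <- tryCatch(solve(JtJ + mu * diag(nd), -g), error = function(e) NULL)
      if (!is.null(d)) {
        qn <- q + as.numeric(d)
        rn <- res_fun(qn)
        on <- sum(rn^2)
        if (on < obj) {
          gain <- obj - on
          q <- qn; r <- rn; obj <- on
          mu <- max(mu / 5, 1e-12)
          improved <- TRUE
          if (gain < tol * max(1e-12, obj) || sum(d^2) < 1e-24) it <- max_iter
          break
        }
      }
      mu <- mu * 10
    }
    if (!improved) {
      sv <- svd(J, nu = 0, nv = 0)$d
      if (length(sv) && sv[length(sv)] < 1e-8 * sv[1]) {
        stop("underdetermined pose: marker set does not observe all dofs ",
             "(rank-deficient IK Jacobian)", call. = FALSE)
      }
      break
    }
  }
  dist <- sqrt(colSums(matrix(r / rep(w, each = 3L), 3L)^2))
  names(dist) <- use
  list(q = q, objective = obj, residuals = dist, iterations = it)
}

#' Inverse kinematics over a trial
#'
#' Solves [solve_frame_ik()] frame by frame, warm-starting each frame from
#' the previous solution.
#'
#' @param model A `skeletal_model`.
#' @param marker_series Named list: marker name -> frames x 3 matrix (m).
#' @param q_init Starting coordinates for the first frame.
#' @return List with `qs` (frames x dofs matrix) and `objective` (per-frame
#'   weighted SSE).
#' @export
solve_ik_trial <- function(model, marker_series, q_init = rep(0, n_dof(model))) {
  nfr <- nrow(marker_series[[1]])
  qs <- matrix(0, nfr, n_dof(model),
               dimnames = list(NULL, dof_names(model)))
  obj <- numeric(nfr)
  q <- q_init
  for (k in seq_len(nfr)) {
    frame <- lapply(marker_series, function(m) m[k, ])
    sol <- solve_frame_ik(model, frame, q_init = q)
    q <- sol$q
    qs[k, ] <- q
    obj[k] <- sol$objective
  }
  list(qs = qs, objective = obj)
}

#' Calibrate segment lengths and marker placements against a trial
#'
#' Minimizes the cumulative weighted error between measured and virtual
#' markers over the trial, jointly over per-segment length scale factors,
#' the local coordinates of markers whose protocol entries allow
#' optimization, and the per-frame postures (solved by nested inverse
#' kinematics).  Optionally constrains the model's hip joint centre to the
#' Harrington pelvis regression recomputed from the current ASIS/PSIS
#' marker placements at every outer step.
#'
#' The outer problem is solved by Gauss-Newton on the stacked (IK-optimal)
#' marker residuals with a finite-difference Jacobian over the calibration
#' parameters.
#'
#' @param model A roughly (height-)scaled `skeletal_model`.
#' @param marker_series Named list: marker -> frames x 3 matrix (filtered).
#' @param opts List: `scale_segments` (character, default: all segments
#'   owning markers), `frames` (indices used for calibration, default: up to
#'   20 evenly spaced), `max_iter` (outer iterations, default 30; 0 returns
#'   the initial model and residuals unchanged), `tol` (objective decrease,
#'   default 1e-10), `constrain_hjc` (NULL, or a list with `hip_joint`,
#'   `leg_length`, and marker names `rasi`, `lasi`, `rpsi`, `lpsi`,
#'   `side`).
#' @return List with `model` (calibrated), `factors` (named length scales),
#'   `marker_offsets`, `qs` (calibration-frame postures), `residual_report`
#'   (per-marker RMS residual, mm), `objective`.
#' @export
optimize_marker_params <- function(model, marker_series, opts = list()) {
  nfr_all <- nrow(marker_series[[1]])
  frames <- opts$frames %||%
    unique(round(seq(1, nfr_all, length.out = min(20L, nfr_all))))
  scale_segments <- opts$scale_segments %||%
    unique(vapply(model$markers, `[[`, "", "segment"))
  max_iter <- opts$max_iter %||% 30L
  tol <- opts$tol %||% 1e-10

  free_marker <- list()
  for (mk in model$markers) {
    if (any(mk$optimize)) free_marker[[mk$name]] <- which(mk$optimize)
  }
  n_sc <- length(scale_segments)
  n_mk <- sum(lengths(free_marker))
  theta <- c(rep(1, n_sc), rep(0, n_mk))

  apply_theta <- function(th) {
    factors <- as.list(th[seq_len(n_sc)])
    names(factors) <- scale_segments
    m2 <- scale_model(model, list(factors = factors,
                                  target_mass = model$subject_mass,
                                  target_height = model$subject_height,
                                  fat_fraction = 0.2, ref_fat_fraction = 0.2))
    i <- n_sc
    for (mn in names(free_marker)) {
      for (ax in free_marker[[mn]]) {
        i <- i + 1L
        m2$markers[[mn]]$point[ax] <- m2$markers[[mn]]$point[ax] + th[i]
      }
    }
    if (!is.null(opts$constrain_hjc)) m2 <- apply_hjc_constraint(m2, opts$constrain_hjc)
    m2
  }

  sub_series <- lapply(marker_series, function(m) m[frames, , drop = FALSE])
  q_store <- NULL
  stacked_residuals <- function(th) {
    m2 <- apply_theta(th)
    ik <- solve_ik_trial(m2, sub_series,
                         q_init = if (is.null(q_store)) rep(0, n_dof(m2)) else q_store[1, ])
    q_store <<- ik$qs
    res <- lapply(seq_along(frames), function(k) {
      poses <- forward_kinematics(m2, ik$qs[k, ])
      unlist(lapply(names(m2$markers), function(mn) {
        mk <- m2$markers[[mn]]
        sqrt(mk$weight) *
          (world_point(poses, mk$segment, mk$point) - sub_series[[mn]][k, ])
      }))
    })
    unlist(res)
  }

  r <- stacked_residuals(theta)
  obj <- sum(r^2)
  if (max_iter > 0L) {
    h <- 1e-6
    for (it in seq_len(max_iter)) {
      J <- matrix(0, length(r), length(theta))
      for (d in seq_along(theta)) {
        tp <- theta; tp[d] <- theta[d] + h
        J[, d] <- (stacked_residuals(tp) - r) / h
      }
      mu <- 1e-10 * max(diag(crossprod(J)))
      improved <- FALSE
      for (try in 1:30) {
        d <- tryCatch(solve(crossprod(J) + mu * diag(length(theta)),
                            -crossprod(J, r)), error = function(e) NULL)
        if (!is.null(d)) {
          tn <- theta + as.numeric(d)
          if (all(tn[seq_len(n_sc)] > 0)) {
            rn <- stacked_residuals(tn)
            if (sum(rn^2) < obj) {
              gain <- obj - sum(rn^2)
              theta <- tn; r <- rn; obj <- sum(rn^2)
              improved <- TRUE
              if (gain < tol * max(1, obj)) it <- max_iter
              break
            }
          }
        }
        mu <- mu * 10
      }
      if (!improved || it >= max_iter) break
    }
  }

  m_final <- apply_theta(theta)
  ik <- solve_ik_trial(m_final, sub_series)
  per_marker <- marker_residual_report(m_final, sub_series, ik$qs)
  factors <- stats::setNames(theta[seq_len(n_sc)], scale_segments)
  offs <- theta[-seq_len(n_sc)]
  list(model = m_final, factors = factors, marker_offsets = offs,
       qs = ik$qs, residual_report = per_marker, objective = obj)
}

# RMS residual per marker over frames, in mm.
marker_residual_report <- function(model, marker_series, qs) {
  nfr <- nrow(qs)
  acc <- stats::setNames(numeric(length(model$markers)), names(model$markers))
  for (k in seq_len(nfr)) {
    poses <- forward_kinematics(model, qs[k, ])
    for (mn in names(model$markers)) {
      mk <- model$markers[[mn]]
      d <- world_point(poses, mk$segment, mk$point) - marker_series[[mn]][k, ]
      acc[mn] <- acc[mn] + sum(d^2)
    }
  }
  sqrt(acc / nfr) * 1000
}

# Recompute the hip joint centre from the (current) ASIS/PSIS local marker
# placements via the Harrington regression and pin the hip joint's
# location-in-pelvis to it.
apply_hjc_constraint <- function(model, cfg) {
  mk <- function(nm) model$markers[[cfg[[nm]]]]$point
  rasi <- mk("rasi"); lasi <- mk("lasi")
  rpsi <- mk("rpsi"); lpsi <- mk("lpsi")
  asis_mid <- (rasi + lasi) / 2
  psis_mid <- (rpsi + lpsi) / 2
  z_right <- unitv(rasi - lasi)
  x_ant_raw <- asis_mid - psis_mid
  x_ant <- unitv(x_ant_raw - sum(x_ant_raw * z_right) * z_right)
  y_sup <- cross3(z_right, x_ant)
  pw <- vnorm(rasi - lasi)
  pd <- vnorm(asis_mid - psis_mid)
  hjc <- harrington_hjc(pw, pd, cfg$leg_length, side = cfg$side %||% "right")
  loc <- asis_mid + hjc[1] * x_ant + hjc[2] * y_sup + hjc[3] * z_right
  model$joints[[cfg$hip_joint]]$location_in_parent <- loc
  model
}
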