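#' Femur-based reporting frame for hip contact forces
#'
#' Builds the orthonormal axes of the instrumented-implant-style femur frame
#' from the model's `femur_frame` block: origin at the hip joint centre, the
#' proximo-distal (PD) axis along the mechanical femur axis (knee centre to
#' hip centre, pointing proximally), the antero-posterior (AP) axis the
#' anterior reference direction orthogonalized against PD, and the
#' medio-lateral (ML) axis completing a right-handed triad.
#'
#' @param model A `skeletal_model` whose `femur_frame` block names the femur
#'   segment, `hip_point` and `knee_point` (local m), and `anterior_local`
#'   (local direction).
#' @param poses Segment poses from [forward_kinematics()].
#' @return 3x3 matrix whose columns are the world AP, ML, PD unit axes.
#' @export
femur_frame_axes <- function(model, poses) {
  ff <- model$femur_frame
  if (is.null(ff)) stop("model has no femur_frame block", call. = FALSE)
  seg <- ff$segment
  hip <- world_point(poses, seg, as.numeric(ff$hip_point))
  knee <- world_point(poses, seg, as.numeric(ff$knee_point))
  pd <- unitv(hip - knee)
  ant <- as.numeric(poses[[seg]]$R %*% as.numeric(ff$anterior_local))
  ap <- unitv(ant - sum(ant * pd) * pd)
  ml <- cross3(pd, ap)
  cbind(AP = ap, ML = ml, PD = pd)
}

#' Hip contact force from the limb free-body balance
#'
#' Evaluates the single-limb force balance
#' `HCF + F_inertial + F_gravity + GRF + sum_i F_i = 0`,
#' where `F_i = f_i u_i` are the forces of the muscle elements crossing the
#' hip (line of action `u_i`, recruitment force `f_i`), and reports the
#' articular contact force in the femur-based frame, normalized to body
#' weight.
#'
#' @param model A `skeletal_model`.
#' @param poses Segment poses for the frame.
#' @param muscle_forces Named vector of muscle forces (N) for all elements
#'   crossing the hip (others ignored).
#' @param free_body One frame of [limb_free_body()] output.
#' @param hip_joint Hip joint name.
#' @return List with `hcf_world` (N), `hcf_femur` (AP/ML/PD components, BW),
#'   `total_bw`, `mf_hip` (world N, summed muscle force), `lines` (per
#'   crossing muscle: `u`, `anchor`, `f`).
#' @export
joint_contact_force <- function(model, poses, muscle_forces, free_body,
                                hip_joint) {
  crossing <- names(model$muscles)[vapply(names(model$muscles), function(mn)
    muscle_spans_joint(model, mn, hip_joint), TRUE)]
  mf <- c(0, 0, 0)
  lines <- list()
  for (mn in crossing) {
    if (is.na(muscle_forces[mn])) {
      stop("no recruitment force available for hip-crossing muscle '",
           mn, "'", call. = FALSE)
    }
    loa <- line_of_action(model, poses, mn, hip_joint)
    mf <- mf + muscle_forces[mn] * loa$u
    lines[[mn]] <- list(u = loa$u, anchor = loa$anchor,
                        f = unname(muscle_forces[mn]))
  }
  hcf_w <- -(free_body$F_inertial + free_body$F_gravity +
               free_body$GRF_sum + mf)
  bw <- body_weight(model)
  ax <- femur_frame_axes(model, poses)
  comp <- as.numeric(t(ax) %*% hcf_w) / bw
  names(comp) <- c("AP", "ML", "PD")
  list(hcf_world = hcf_w, hcf_femur = comp,
       total_bw = sqrt(sum(comp^2)), mf_hip = mf, lines = lines)
}
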