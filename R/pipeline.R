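#' Pipeline configuration
#'
#' @param filter List: `enabled` (default TRUE), `cutoff` Hz (default 5),
#'   `order` (default 2) — the zero-phase low-pass applied to markers and
#'   GRF.
#' @param recruitment A [recruitment_config()].
#' @param hip_joint Hip joint name (default `"hip_r"`).
#' @param constrained_dofs Dof names whose moment equilibrium the muscles
#'   must satisfy; `NULL` (default) selects all joint dofs of joints spanned
#'   by at least one muscle.  Unconstrained joint moments and the base
#'   wrench are reported as ideal residuals.
#' @param grf_threshold Stance/plate assignment threshold, N (default 20).
#' @param calibrate `NULL`, or options for [optimize_marker_params()] run
#'   before inverse kinematics.
#' @param flag_thresholds Thresholds for [flag_suspect_muscles()].
#' @param seed Seed recorded in the manifest (the deterministic stages do
#'   not consume randomness).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = list(enabled = TRUE, cutoff = 5, order = 2),
                            recruitment = recruitment_config(),
                            hip_joint = "hip_r",
                            constrained_dofs = NULL,
                            grf_threshold = 20,
                            calibrate = NULL,
                            flag_thresholds = list(),
                            seed = 1L) {
  structure(list(filter = filter, recruitment = recruitment,
                 hip_joint = hip_joint, constrained_dofs = constrained_dofs,
                 grf_threshold = grf_threshold, calibrate = calibrate,
                 flag_thresholds = flag_thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Constrained dof default: all joint dofs of joints spanned by >= 1 muscle.
default_constrained_dofs <- function(model) {
  out <- character(0)
  for (jn in names(model$joints)) {
    spanned <- any(vapply(names(model$muscles), function(mn)
      muscle_spans_joint(model, mn, jn), TRUE))
    if (spanned) {
      out <- c(out, model$dofs$names[model$dofs$joint_dofs[[jn]]])
    }
  }
  out
}

# The full per-trial computation shared by run_pipeline() and the synthetic
# generator's reference-HCF stage.
pipeline_core <- function(model, trial, config = pipeline_config()) {
  rate <- trial$rate
  markers <- trial$markers
  grf <- trial$grf
  if (isTRUE(config$filter$enabled)) {
    fc <- list(cutoff = config$filter$cutoff %||% 5,
               order = config$filter$order %||% 2)
    markers <- lapply(markers, lowpass_zero_phase, rate = rate, config = fc)
    grf <- lapply(grf, function(pl) {
      pl$force <- lowpass_zero_phase(pl$force, rate, fc)
      pl
    })
  }

  calib <- NULL
  if (!is.null(config$calibrate)) {
    calib <- optimize_marker_params(model, markers, config$calibrate)
    model <- calib$model
  }

  ik <- solve_ik_trial(model, markers)
  qs <- ik$qs
  dd <- differentiate_q(qs, rate)
  loads <- grf_to_loads(grf, threshold = config$grf_threshold)
  nl <- inverse_dynamics(model, qs, dd$qd, dd$qdd, loads)
  fb <- limb_free_body(model, qs, dd$qd, dd$qdd, loads, config$hip_joint)
  events <- detect_gait_events(grf[[1]]$force[, 3],
                               threshold = config$grf_threshold)

  cdofs <- config$constrained_dofs %||% default_constrained_dofs(model)
  mus <- names(model$muscles)
  strengths <- vapply(model$muscles, `[[`, 0, "strength")
  nfr <- nrow(qs)
  frames <- vector("list", nfr)
  hcf_femur <- matrix(0, nfr, 3, dimnames = list(NULL, c("AP", "ML", "PD")))
  forces <- matrix(0, nfr, length(mus), dimnames = list(NULL, mus))
  activations <- forces
  tau_series <- matrix(0, nfr, length(cdofs), dimnames = list(NULL, cdofs))
  recruit_residual <- numeric(nfr)
  for (k in seq_len(nfr)) {
    q <- qs[k, ]
    poses <- forward_kinematics(model, q)
    R <- moment_arm_matrix(model, q, dofs = cdofs, muscles = mus)
    tau <- nl$frames[[k]]$tau[cdofs]
    sol <- solve_recruitment(tau, R, strengths, config$recruitment)
    jcf <- joint_contact_force(model, poses, sol$f, fb[[k]], config$hip_joint)
    hcf_femur[k, ] <- jcf$hcf_femur
    forces[k, ] <- sol$f
    activations[k, ] <- sol$a
    tau_series[k, ] <- tau
    recruit_residual[k] <- sol$residual
    frames[[k]] <- list(lines = jcf$lines, hcf_world = jcf$hcf_world,
                        free_body = fb[[k]], f = sol$f, R = R)
  }
  contrib <- decompose_hcf(model, frames)
  flags <- flag_suspect_muscles(contrib, tau_series, events,
                                config$flag_thresholds)
  validation <- NULL
  if (!is.null(trial$measured_hcf)) {
    validation <- rmse_report(hcf_femur, trial$measured_hcf, events)
  }
  bw <- body_weight(model)
  list(model = model, qs = qs, qd = dd$qd, qdd = dd$qdd, events = events,
       net_loads = nl, free_body = fb, tau = tau_series,
       forces = forces, activations = activations,
       hcf_femur = hcf_femur, total_bw = sqrt(rowSums(hcf_femur^2)),
       frames = frames, contrib = contrib, flags = flags,
       validation = validation, calibration = calib,
       recruit_residual = recruit_residual,
       closure_residual_bw = contrib$residual / bw,
       ik_objective = ik$objective, time = trial$time)
}

#' Run the full gait analysis pipeline
#'
#' Filters the trial, optionally calibrates marker/segment parameters,
#' solves inverse kinematics, inverse dynamics, muscle recruitment, the hip
#' contact force and its per-muscle decomposition, flags suspect muscle
#' geometry, validates against a measured HCF when one is present (otherwise
#' the validation stage is skipped with a notice), and — when `out_dir` is
#' given — writes the stage outputs as CSV/JSON with a manifest of content
#' hashes so that reruns with the same configuration are bit-reproducible.
#'
#' @param model A `skeletal_model`, or a path to a model YAML.
#' @param trial A `gait_trial` (see [generate_gait_trial()], [read_trial()]).
#' @param config A [pipeline_config()], or a path to a YAML file with its
#'   fields.
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @return The pipeline result list (see `pipeline_core`), plus `manifest`
#'   when outputs were written.
#' @export
run_pipeline <- function(model, trial, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(model)) model <- build_model(model)
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg)
  }
  res <- pipeline_core(model, trial, config)
  if (is.null(trial$measured_hcf)) {
    message("no measured HCF provided; validation stage skipped")
  }
  if (!is.null(out_dir)) {
    res$manifest <- write_pipeline_outputs(res, trial, config, out_dir)
  }
  res
}

write_pipeline_outputs <- function(res, trial, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bw <- body_weight(res$model)
  pct <- seq(0, 100, length.out = nrow(res$hcf_femur))

  hcf <- data.frame(time_s = res$time, pct_gait_cycle = pct,
                    AP_BW = res$hcf_femur[, 1], ML_BW = res$hcf_femur[, 2],
                    PD_BW = res$hcf_femur[, 3], total_BW = res$total_bw)
  utils::write.csv(hcf, file.path(out_dir, "hcf.csv"), row.names = FALSE)

  kin <- data.frame(time_s = res$time, res$qs, check.names = FALSE)
  utils::write.csv(kin, file.path(out_dir, "kinematics.csv"), row.names = FALSE)

  utils::write.csv(data.frame(time_s = res$time, res$forces,
                              check.names = FALSE),
                   file.path(out_dir, "muscle_forces.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = res$time, res$activations,
                              check.names = FALSE),
                   file.path(out_dir, "activations.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = res$time, res$tau, check.names = FALSE),
                   file.path(out_dir, "net_moments.csv"), row.names = FALSE)
  utils::write.csv(contribution_table(res$contrib, bw),
                   file.path(out_dir, "contributions.csv"), row.names = FALSE)

  flags <- lapply(res$flags, function(fl) {
    fl$moment_share <- as.list(fl$moment_share)
    fl
  })
  jsonlite::write_json(flags, file.path(out_dir, "flags.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$validation)) {
    v <- res$validation
    jsonlite::write_json(list(rmse_total = v$rmse_total,
                              rmse_component = as.list(v$rmse_component),
                              rmse_stance = v$rmse_stance,
                              rmse_swing = v$rmse_swing,
                              peaks = v$peaks),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(v$error_series, file.path(out_dir, "hcf_errors.csv"),
                     row.names = FALSE)
  }

  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  manifest <- list(
    package = "hipforce",
    version = as.character(utils::packageVersion("hipforce")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(write_temp_json(config))),
    n_frames = nrow(res$qs),
    max_closure_residual_bw = max(res$closure_residual_bw),
    max_recruitment_residual = max(res$recruit_residual),
    outputs = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  x <- rapply(unclass(x), function(v) v, how = "replace")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  f
}
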