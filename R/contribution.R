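#' Per-muscle decomposition of the hip contact force
#'
#' From solved pipeline frames, assembles each crossing element's
#' contribution `F_i = f_i u_i` to the hip contact force, the summed muscle
#' force `MF_hip = sum_i F_i`, the per-dof moment contributions
#' `f_i * r_{d,i}`, the per-frame closure residual of the limb free-body
#' balance, and aggregates element contributions per actuator group.
#'
#' @param model A `skeletal_model`.
#' @param frames List of solved frames, each with `lines` (from
#'   [joint_contact_force()]), `hcf_world`, `free_body`, `f` (named muscle
#'   forces), and `R` (moment-arm matrix, constrained dofs x muscles).
#' @return Object of class `muscle_contribution`: list with `elements`
#'   (per-frame 3 x n matrices of world `F_i`), `mf_hip` (frames x 3),
#'   `residual` (per-frame closure residual norm, N), `moments` (per-frame
#'   dofs x muscles moment contributions, N m), `groups` (element-to-group
#'   map), `group_force` / `group_moment` aggregations.
#' @export
decompose_hcf <- function(model, frames) {
  nfr <- length(frames)
  if (nfr == 0L) stop("no solved frames to decompose", call. = FALSE)
  el_names <- names(frames[[1]]$lines)
  groups <- vapply(el_names, function(mn) model$muscles[[mn]]$group, "")

  elements <- vector("list", nfr)
  moments <- vector("list", nfr)
  mf_hip <- matrix(0, nfr, 3)
  residual <- numeric(nfr)
  for (k in seq_len(nfr)) {
    fr <- frames[[k]]
    if (!identical(names(fr$lines), el_names)) {
      stop("frame ", k, ": muscle set inconsistent across frames", call. = FALSE)
    }
    Fi <- vapply(fr$lines, function(l) l$f * l$u, numeric(3))
    elements[[k]] <- Fi
    mf_hip[k, ] <- rowSums(Fi)
    residual[k] <- vnorm(fr$hcf_world + fr$free_body$F_inertial +
                           fr$free_body$F_gravity + fr$free_body$GRF_sum +
                           mf_hip[k, ])
    moments[[k]] <- fr$R * rep(fr$f[colnames(fr$R)], each = nrow(fr$R))
  }

  # force contributions exist only for hip-crossing elements; moment
  # contributions cover every recruited element (e.g. mono-articular knee
  # muscles), grouped by actuator
  all_mus <- colnames(frames[[1]]$R)
  groups_all <- vapply(all_mus, function(mn) model$muscles[[mn]]$group, "")
  grp_names <- unique(groups_all)
  group_force <- lapply(grp_names, function(g) {
    sel <- groups == g
    if (!any(sel)) return(matrix(0, nfr, 3))
    t(vapply(seq_len(nfr), function(k)
      rowSums(elements[[k]][, sel, drop = FALSE]), numeric(3)))
  })
  names(group_force) <- grp_names
  dofs <- rownames(frames[[1]]$R)
  group_moment <- lapply(grp_names, function(g) {
    mus <- all_mus[groups_all == g]
    t(vapply(seq_len(nfr), function(k)
      rowSums(moments[[k]][, colnames(moments[[k]]) %in% mus, drop = FALSE]),
      numeric(length(dofs))))
  })
  names(group_moment) <- grp_names

  hcf_norm <- vapply(frames, function(fr) vnorm(fr$hcf_world), 0)
  structure(list(elements = elements, mf_hip = mf_hip, residual = residual,
                 moments = moments, groups = groups, dofs = dofs,
                 group_force = group_force, group_moment = group_moment,
                 hcf_norm = hcf_norm, n_frames = nfr),
            class = "muscle_contribution")
}

#' Flag muscles with anatomically suspect geometry
#'
#' Two heuristics mark actuator groups whose force bookkeeping is
#' disproportionate, the signature of faulty path geometry:
#' criterion (a) — a high contact-force contribution with relatively low
#' joint-moment contribution (peak `|F_group|` at least `a_hcf_share` of the
#' peak total HCF while the group's peak moment share stays below
#' `a_moment_share` on every constrained dof);
#' criterion (b) — a joint-moment contribution exceeding the overall net
#' joint moment (same sign, larger magnitude) over a contiguous episode of
#' at least `b_min_duration` of the gait cycle.
#'
#' Both thresholds are configurable; loosening a threshold never removes a
#' flag.
#'
#' @param contrib A [decompose_hcf()] result.
#' @param tau_series Frames x dofs matrix of net generalized joint moments
#'   on the constrained dofs (N m).
#' @param events Gait events from [detect_gait_events()] (for phase
#'   attribution of episodes).
#' @param thresholds List: `a_hcf_share` (default 0.15), `a_moment_share`
#'   (default 0.05), `b_min_duration` (fraction of cycle, default 0.05).
#' @return Object of class `flag_report`: per-group list with `criterion_a`
#'   (logical + shares), `criterion_b` (episodes: dof, start/end % cycle,
#'   phase), `flagged`.
#' @export
flag_suspect_muscles <- function(contrib, tau_series, events = NULL,
                                 thresholds = list()) {
  a_hcf <- thresholds$a_hcf_share %||% 0.15
  a_mom <- thresholds$a_moment_share %||% 0.05
  b_dur <- thresholds$b_min_duration %||% 0.05
  nfr <- contrib$n_frames
  pct <- seq(0, 100, length.out = nfr)
  peak_tot <- max(contrib$hcf_norm)

  report <- list()
  for (g in names(contrib$group_force)) {
    gf <- contrib$group_force[[g]]
    gm <- contrib$group_moment[[g]]
    hcf_share <- max(sqrt(rowSums(gf^2))) / peak_tot
    mom_share <- vapply(seq_along(contrib$dofs), function(d) {
      den <- max(abs(tau_series[, d]))
      if (den < 1e-12) 0 else max(abs(gm[, d])) / den
    }, 0)
    names(mom_share) <- contrib$dofs
    crit_a <- hcf_share >= a_hcf && all(mom_share <= a_mom)

    episodes <- list()
    for (d in seq_along(contrib$dofs)) {
      exceed <- abs(gm[, d]) > abs(tau_series[, d]) &
        sign(gm[, d]) == sign(tau_series[, d]) &
        abs(tau_series[, d]) > 1e-9
      runs <- rle(exceed)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      for (i in seq_along(runs$lengths)) {
        if (!runs$values[i]) next
        span <- (pct[ends[i]] - pct[starts[i]]) / 100
        if (span + 1 / nfr < b_dur) next
        phase <- if (is.null(events)) NA_character_ else {
          mid <- (pct[starts[i]] + pct[ends[i]]) / 2
          if (mid < events$stance_pct[2]) "stance" else "swing"
        }
        episodes[[length(episodes) + 1L]] <- list(
          dof = contrib$dofs[d], start_pct = pct[starts[i]],
          end_pct = pct[ends[i]], phase = phase)
      }
    }
    report[[g]] <- list(
      criterion_a = crit_a, hcf_share = hcf_share, moment_share = mom_share,
      criterion_b = episodes,
      flagged = crit_a || length(episodes) > 0)
  }
  structure(report, class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  cat("<flag_report>\n")
  for (g in names(x)) {
    r <- x[[g]]
    cat(sprintf("  %-18s %s", g, if (r$flagged) "FLAGGED" else "ok"))
    if (r$criterion_a) cat("  [a: high HCF share, low moment share]")
    for (ep in r$criterion_b) {
      cat(sprintf("  [b: %s %.0f-%.0f%% %s]", ep$dof, ep$start_pct,
                  ep$end_pct, ep$phase %||% ""))
    }
    cat("\n")
  }
  invisible(x)
}

#' Contribution time series in long format
#'
#' @param contrib A [decompose_hcf()] result.
#' @param bw Body weight (N) for normalization.
#' @return Data frame: `pct_gc`, `group`, `AP_BW` placeholder world x/y/z in
#'   BW (`fx_BW`, `fy_BW`, `fz_BW`) and per-dof moment columns.
#' @export
contribution_table <- function(contrib, bw) {
  nfr <- contrib$n_frames
  pct <- seq(0, 100, length.out = nfr)
  rows <- list()
  for (g in names(contrib$group_force)) {
    gf <- contrib$group_force[[g]] / bw
    gm <- contrib$group_moment[[g]]
    df <- data.frame(pct_gc = pct, group = g, fx_BW = gf[, 1],
                     fy_BW = gf[, 2], fz_BW = gf[, 3])
    colnames_gm <- paste0("moment_", contrib$dofs, "_Nm")
    for (d in seq_along(contrib$dofs)) df[[colnames_gm[d]]] <- gm[, d]
    rows[[g]] <- df
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
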