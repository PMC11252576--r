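# Simulation drivers: single runs, the (p,q) sweep mirroring the published
# equal-order and mixed-order experiments, and the self-convergence study.
# These are the programmatic surface behind the exec/fracad command line.

#' Order presets for the sweep
#'
#' \code{"equal"}: (v, v) for v in 0.80, 0.85, 0.90, 0.95, 1.00 — the
#' equal-order experiments.  \code{"mixed"}: pairs with p != q (plus the
#' integer-order corner), the mixed-order experiments.  The published study
#' does not print its exact order values; these presets are this package's
#' choices, overridable via \code{orders} in \code{\link{ff_sweep}}.
#'
#' @param preset \code{"equal"} or \code{"mixed"}.
#' @return A two-column matrix with columns \code{p} and \code{q}.
#' @export
order_preset <- function(preset = c("equal", "mixed")) {
  preset <- match.arg(preset)
  if (preset == "equal") {
    v <- c(0.80, 0.85, 0.90, 0.95, 1.00)
    cbind(p = v, q = v)
  } else {
    cbind(p = c(0.80, 0.90, 0.95, 0.90, 1.00),
          q = c(0.90, 0.80, 0.85, 1.00, 0.95))
  }
}

#' Run a single simulation
#'
#' Solves the AD model with the fractal-fractional scheme under a full run
#' configuration (defaults: published rates and initial populations, 20-year
#' horizon, 0.05-year step) and optionally writes the trajectory CSV plus a
#' JSON metadata sidecar (\code{<out>.meta.json}) that records every setting
#' needed to reproduce the run bit-identically.
#'
#' @param p,q fractional order and fractal dimension in (0, 1].
#' @param step grid step in years.
#' @param horizon final time in years; \code{horizon = 0} gives the single
#'   initial-state row.
#' @param init named initial state (canonical order R, Q, Abeta, Ip, Ia, S, D).
#' @param params an \code{\link{ad_parameters}} vector.
#' @param config optional path to a flat key=value config file (or a list as
#'   returned by \code{\link{read_run_config}}); applied before the direct
#'   arguments' defaults are used, see \code{\link{read_run_config}}.
#' @param out optional CSV output path.
#' @param warn_negative see \code{\link{solve_ff}}.
#' @return The \code{ff_trajectory}, invisibly when \code{out} is given.
#' @export
ff_run <- function(p = 1, q = 1, step = 0.05, horizon = 20,
                   init = ad_initial_state(), params = ad_parameters(),
                   config = NULL, out = NULL, warn_negative = TRUE) {
  cfg <- .build_config(p, q, step, horizon, init, params, config)
  traj <- solve_ff(function(t, y) ad_rhs(y, cfg$params), cfg$init,
                   step = cfg$step, p = cfg$p, q = cfg$q,
                   horizon = cfg$horizon, warn_negative = warn_negative)
  if (!is.null(out)) {
    write_trajectory(traj, out)
    .write_sidecar(cfg, paste0(out, ".meta.json"))
    return(invisible(traj))
  }
  traj
}

#' Sweep over (p, q) order pairs
#'
#' Runs one simulation per order pair and returns the trajectories plus a
#' combined long-format table with added \code{p} and \code{q} columns.
#' With \code{out_dir} set, each trajectory is written as
#' \code{traj_p<p>_q<q>.csv} (plus sidecars) and the combined table as
#' \code{sweep_combined.csv}.  Duplicate pairs are deduplicated with a
#' warning.
#'
#' @param orders two-column matrix (p, q) of order pairs; defaults to a
#'   preset from \code{\link{order_preset}}.
#' @param preset used when \code{orders} is NULL.
#' @inheritParams ff_run
#' @param out_dir optional output directory (created if missing).
#' @return List with \code{trajectories} (named list of
#'   \code{ff_trajectory}) and \code{combined} (long data.frame).
#' @export
ff_sweep <- function(orders = NULL, preset = c("equal", "mixed"),
                     step = 0.05, horizon = 20,
                     init = ad_initial_state(), params = ad_parameters(),
                     config = NULL, out_dir = NULL, warn_negative = FALSE) {
  if (is.null(orders)) orders <- order_preset(match.arg(preset))
  orders <- as.matrix(orders)
  if (nrow(orders) == 0) stop("empty order list")
  key <- paste(orders[, 1], orders[, 2], sep = "_")
  if (anyDuplicated(key)) {
    warning("duplicate (p, q) pairs removed from sweep")
    orders <- orders[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  trajs <- list()
  pieces <- list()
  for (i in seq_len(nrow(orders))) {
    p <- unname(orders[i, 1]); q <- unname(orders[i, 2])
    nm <- sprintf("p%g_q%g", p, q)
    out <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("traj_p%g_q%g.csv", p, q)) else NULL
    tr <- ff_run(p = p, q = q, step = step, horizon = horizon, init = init,
                 params = params, config = config, out = out,
                 warn_negative = warn_negative)
    trajs[[nm]] <- tr
    pieces[[nm]] <- data.frame(p = p, q = q, as.data.frame(tr),
                               check.names = FALSE)
  }
  combined <- do.call(rbind, c(pieces, make.row.names = FALSE))
  if (!is.null(out_dir))
    utils::write.csv(combined, file.path(out_dir, "sweep_combined.csv"),
                     row.names = FALSE)
  list(trajectories = trajs, combined = combined)
}

#' Self-convergence study
#'
#' Solves the AD model at one (p, q) over a ladder of step sizes and reports
#' the maximum endpoint discrepancy of each coarse run against a fine-grid
#' reference, together with the empirical convergence order between
#' successive rungs.
#'
#' @param p,q orders.
#' @param steps decreasing vector of step sizes to test.
#' @param l_ref reference step (must divide every entry of \code{steps}).
#' @param horizon years.
#' @inheritParams ff_run
#' @return data.frame with columns \code{step}, \code{endpoint_error},
#'   \code{order} (NA on the first rung).
#' @export
convergence_study <- function(p = 0.9, q = 0.9,
                              steps = c(0.08, 0.04, 0.02, 0.01),
                              l_ref = 0.0025, horizon = 2,
                              init = ad_initial_state(),
                              params = ad_parameters()) {
  rhs <- function(t, y) ad_rhs(y, params)
  if (any(abs(steps / l_ref - round(steps / l_ref)) > 1e-9))
    stop("l_ref must divide every step")
  ref <- solve_ff(rhs, init, step = l_ref, p = p, q = q, horizon = horizon,
                  warn_negative = FALSE)
  err <- vapply(steps, function(l) {
    tr <- solve_ff(rhs, init, step = l, p = p, q = q, horizon = horizon,
                   warn_negative = FALSE)
    # compare at the coarse run's own final time (horizon need not be a
    # multiple of l), located exactly on the reference grid
    t_end <- tr$time[length(tr$time)]
    max(abs(tr$states[nrow(tr$states), ] -
            ref$states[round(t_end / l_ref) + 1, ]))
  }, numeric(1))
  ord <- c(NA, log(err[-length(err)] / err[-1]) /
                log(steps[-length(steps)] / steps[-1]))
  data.frame(step = steps, endpoint_error = err, order = ord)
}
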