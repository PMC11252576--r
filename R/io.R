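# Plain-text I/O: full-precision trajectory CSV (round-trips through
# read_trajectory exactly), the flat key=value config format, and the JSON
# run-metadata sidecar.

#' Write a trajectory as CSV
#'
#' Header \code{time,R,Q,Abeta,Ip,Ia,S,D} (or the trajectory's own column
#' names), one row per node, \code{\%.17g} formatting so that
#' \code{\link{read_trajectory}} reproduces every double bit-exactly.
#' Comma separator, \code{.} decimal, LF line endings.
#'
#' @param traj an \code{ff_trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  m <- cbind(time = traj$time, traj$states)
  header <- paste(colnames(m), collapse = ",")
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  con <- file(path, open = "wb")    # binary mode forces LF on every platform
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path a file written by \code{\link{write_trajectory}}.
#' @param p,q,step optional run settings to attach (read back from the
#'   metadata sidecar by \code{\link{ff_run}} consumers; NA when unknown).
#' @return An \code{ff_trajectory}.
#' @export
read_trajectory <- function(path, p = NA_real_, q = NA_real_,
                            step = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (colnames(df)[1] != "time") stop("not a trajectory CSV: ", path)
  states <- as.matrix(df[, -1, drop = FALSE])
  if (is.na(step) && nrow(df) > 1) step <- df$time[2] - df$time[1]
  .new_trajectory(df$time, states, p, q, step, "read")
}

#' Read a flat key=value configuration file
#'
#' One \code{key = value} assignment per line; blank lines and \code{#}
#' comments ignored.  Recognized keys: \code{p}, \code{q}, \code{step},
#' \code{horizon}, the seven initial populations as \code{init.R},
#' \code{init.Q}, \code{init.Abeta}, \code{init.Ip}, \code{init.Ia},
#' \code{init.S}, \code{init.D}, and the rates \code{lambda1 .. lambda16},
#' \code{lambdaR}.  Unknown keys are an error, not a warning.
#'
#' @param path config file path.
#' @return A named list of numeric values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- c("p", "q", "step", "horizon",
             paste0("init.", .compartments), .lambda_names)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (!(key %in% known)) stop("unknown config key: '", key, "'")
    if (is.na(val)) stop("non-numeric value for key '", key, "'")
    out[[key]] <- val
  }
  out
}

# assemble a full RunConfig from defaults + config-file + direct overrides
.build_config <- function(p = 1, q = 1, step = 0.05, horizon = 20,
                          init = ad_initial_state(),
                          params = ad_parameters(), config = NULL) {
  if (!is.null(config)) {
    cf <- if (is.character(config)) read_run_config(config) else config
    for (key in names(cf)) {
      if (key %in% c("p", "q", "step", "horizon")) {
        assign(key, cf[[key]])
      } else if (startsWith(key, "init.")) {
        init[[sub("^init\\.", "", key)]] <- cf[[key]]
      } else {
        params[[key]] <- cf[[key]]
      }
    }
  }
  .check_order(p, q)
  if (step <= 0 || horizon < 0) stop("need step > 0 and horizon >= 0")
  list(p = p, q = q, step = step, horizon = horizon,
       init = init, params = params)
}

.write_sidecar <- function(cfg, path) {
  meta <- list(p = cfg$p, q = cfg$q, step = cfg$step, horizon = cfg$horizon,
               init = as.list(cfg$init),
               params = as.list(unclass(cfg$params)))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
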