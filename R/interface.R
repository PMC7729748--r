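# File formats, configuration and the command-line entry point.
# Units in files are SI (s, rad/s, m/s^2, m); angle outputs are degrees.
# Orientations are serialized as unit quaternions (w, x, y, z).

#' Read a long-format IMU measurement table
#'
#' CSV with header `t,imu_id,gx,gy,gz,ax,ay,az` (s, rad/s, m/s^2), IMU ids
#' 1-7 in the lumbar / right thigh / right shank / right foot / left thigh /
#' left shank / left foot numbering. All seven IMUs must be present with
#' monotone, uniform timestamps.
#'
#' @param path CSV path.
#' @return list of class `"imu_streams"` (7 streams with `t`, `gyro`,
#'   `accel`).
#' @export
read_imu_table <- function(path) {
  dt <- data.table::fread(path)
  need <- c("t", "imu_id", "gx", "gy", "gz", "ax", "ay", "az")
  if (!all(need %in% names(dt)))
    stop("missing columns: ", paste(setdiff(need, names(dt)), collapse = ", "))
  ids <- sort(unique(dt$imu_id))
  if (!identical(as.integer(ids), 1:7))
    stop("missing IMU id(s): ", paste(setdiff(1:7, ids), collapse = ", "),
         "; present: ", paste(ids, collapse = ", "))
  streams <- vector("list", 7)
  for (s in 1:7) {
    rows <- which(dt$imu_id == s)
    d <- dt[rows]
    o <- order(d$t)
    d <- d[o]
    steps <- diff(d$t)
    if (any(steps <= 0))
      stop("non-monotone time for IMU ", s, " at input line ",
           rows[o][which(steps <= 0)[1] + 1] + 1L)
    if (max(abs(steps - stats::median(steps))) > 1e-6)
      stop("non-uniform sample times for IMU ", s)
    streams[[s]] <- list(t = d$t,
                         gyro = as.matrix(d[, c("gx", "gy", "gz")]),
                         accel = as.matrix(d[, c("ax", "ay", "az")]))
  }
  message("read ", nrow(dt), " rows: ", length(streams[[1]]$t),
          " samples/IMU over ",
          signif(diff(range(streams[[1]]$t)), 4), " s")
  structure(streams, class = "imu_streams")
}

# format doubles so that re-parsing recovers them bit-exactly
.fwrite_exact <- function(dt, path) {
  for (nm in names(dt)) {
    if (is.double(dt[[nm]])) dt[[nm]] <- sprintf("%.17g", dt[[nm]])
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write IMU streams as a long-format table
#'
#' Doubles are serialized with 17 significant digits, so reading the file
#' back recovers them bit-exactly.
#'
#' @param streams an `"imu_streams"` list.
#' @param path output CSV path.
#' @export
write_imu_table <- function(streams, path) {
  long <- data.table::rbindlist(lapply(1:7, function(s) {
    st <- streams[[s]]
    data.table::data.table(t = st$t, imu_id = s,
                           gx = st$gyro[, 1], gy = st$gyro[, 2],
                           gz = st$gyro[, 3],
                           ax = st$accel[, 1], ay = st$accel[, 2],
                           az = st$accel[, 3])
  }))
  .fwrite_exact(long, path)
}

# rotation <-> unit quaternion (w, x, y, z), w >= 0 canonical
.rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    k <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    i <- k; j <- i %% 3 + 1; l <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[l, l] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[l, j] - R[j, l]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[l + 1] <- (R[l, i] + R[i, l]) / s
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

.quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Write a solution to a directory
#'
#' Writes `states.csv` (keyframe states: time, IMU id, quaternion wxyz,
#' position, velocity, angular velocity, bias), `skeleton.json` (knee axes
#' and joint-center offsets), `angles.csv` (per-keyframe knee angles by
#' side) and `solver_log.txt`.
#'
#' @param solution an [optimize_graph()] result.
#' @param angles a [derive_knee_angles()] result (or `NULL` to derive here).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_solution <- function(solution, angles = NULL, dir) {
  if (is.null(angles)) angles <- derive_knee_angles(solution)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- solution$M
  rows <- vector("list", 7 * M)
  for (k in seq_len(M)) {
    for (s in 1:7) {
      idx <- (k - 1L) * 7L + s
      q <- .rot_to_quat(solution$values$R[, , idx])
      rows[[idx]] <- data.table::data.table(
        t = solution$t[k], imu_id = s,
        qw = q[1], qx = q[2], qy = q[3], qz = q[4],
        px = solution$values$p[1, idx], py = solution$values$p[2, idx],
        pz = solution$values$p[3, idx],
        vx = solution$values$v[1, idx], vy = solution$values$v[2, idx],
        vz = solution$values$v[3, idx],
        wx = solution$values$w[1, idx], wy = solution$values$w[2, idx],
        wz = solution$values$w[3, idx],
        bgx = solution$values$b[1, idx], bgy = solution$values$b[2, idx],
        bgz = solution$values$b[3, idx],
        bax = solution$values$b[4, idx], bay = solution$values$b[5, idx],
        baz = solution$values$b[6, idx])
    }
  }
  .fwrite_exact(data.table::rbindlist(rows), file.path(dir, "states.csv"))

  term <- if (is.null(solution$termination)) "none" else solution$termination
  errv <- suppressWarnings(as.numeric(
    if (is.null(solution$error)) NA_real_ else solution$error))
  if (!length(errv)) errv <- NA_real_
  skel <- list(
    axes = stats::setNames(lapply(1:4, function(a) solution$values$axes[, a]),
                           c("r2", "r3", "r5", "r6")),
    offsets = stats::setNames(lapply(1:12, function(o) solution$values$offs[, o]),
                              .offset_names()),
    error = errv, termination = term,
    decimation = solution$decimation,
    disambiguated = isTRUE(solution$disambiguated))
  jsonlite::write_json(skel, file.path(dir, "skeleton.json"),
                       auto_unbox = TRUE, digits = NA)

  ang_tab <- data.table::rbindlist(lapply(c("right", "left"), function(sd) {
    a <- angles[[sd]]
    data.table::data.table(t = angles$t, side = sd, flexion = a$flexion,
                           rotation = a$rotation, adduction = a$adduction)
  }))
  .fwrite_exact(ang_tab, file.path(dir, "angles.csv"))

  lines <- sprintf("termination %s total_error %s", term,
                   format(errv, digits = 17))
  it <- solution$iterations
  if (!is.null(it) && nrow(it) > 0)
    lines <- c(lines,
               sprintf("iter %d error %.17g lambda %.3e step %.6e %s",
                       it$iter, it$error, it$lambda, it$step_norm,
                       ifelse(it$accepted, "accepted", "rejected")))
  writeLines(lines, file.path(dir, "solver_log.txt"))
  invisible(dir)
}

#' Read a solution directory written by [write_solution()]
#' @param dir solution directory.
#' @return an `"imu_solution"`-shaped list (states, skeleton variables,
#'   keyframe times).
#' @export
read_solution <- function(dir) {
  st <- data.table::fread(file.path(dir, "states.csv"))
  t_kf <- sort(unique(st$t))
  M <- length(t_kf)
  n <- 7L * M
  R <- array(0, c(3, 3, n))
  p <- v <- w <- matrix(0, 3, n)
  b <- matrix(0, 6, n)
  for (r in seq_len(nrow(st))) {
    k <- match(st$t[r], t_kf)
    idx <- (k - 1L) * 7L + st$imu_id[r]
    R[, , idx] <- .quat_to_rot(c(st$qw[r], st$qx[r], st$qy[r], st$qz[r]))
    p[, idx] <- c(st$px[r], st$py[r], st$pz[r])
    v[, idx] <- c(st$vx[r], st$vy[r], st$vz[r])
    w[, idx] <- c(st$wx[r], st$wy[r], st$wz[r])
    b[, idx] <- c(st$bgx[r], st$bgy[r], st$bgz[r],
                  st$bax[r], st$bay[r], st$baz[r])
  }
  skel <- jsonlite::read_json(file.path(dir, "skeleton.json"),
                              simplifyVector = TRUE)
  axes <- do.call(cbind, skel$axes)
  offs <- do.call(cbind, skel$offsets)
  structure(list(
    values = list(R = R, p = p, v = v, w = w, b = b, axes = axes,
                  offs = offs, M = M),
    M = M, t = t_kf, decimation = skel$decimation,
    error = skel$error, termination = skel$termination,
    disambiguated = isTRUE(skel$disambiguated)
  ), class = "imu_solution")
}

#' Read a flat key-value (YAML) configuration into a [noise_spec()]
#'
#' Recognized keys are the [noise_spec()] arguments; unknown keys error.
#'
#' @param path YAML file path.
#' @return a [noise_spec()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(noise_spec))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(noise_spec, y)
}

.cli_usage <- function() {
  paste(
    "usage: imumocap <simulate|estimate|angles|evaluate> [flags]",
    "  simulate --out-dir D [--seed N] [--duration S] [--rate HZ]",
    "           [--noise-free] [--soft-tissue-mm MM] [--config F]",
    "  estimate --input imu.csv --out-dir D [--decimation N] [--config F]",
    "           [--max-iterations N]",
    "  angles   --solution-dir D",
    "  evaluate --solution-dir D --truth-dir D [--out F]",
    sep = "\n")
}

.parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (key %in% c("noise-free")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(argv)) stop("flag ", a, " needs a value")
      flags[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (synthetic dataset + ground-truth sidecars),
#' `estimate` (run the smoother on a measurement table), `angles`
#' (re-derive disambiguated knee angles from a solution directory) and
#' `evaluate` (compare a solution against simulated truth). Invoked by the
#' `inst/scripts/imumocap` Rscript; returns the exit code instead of
#' quitting, so it is testable in-process.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 success, 1 runtime failure, 2 usage error).
#' @export
run_cli <- function(argv) {
  code <- tryCatch({
    if (length(argv) < 1) { message(.cli_usage()); return(2L) }
    cmd <- argv[1]
    if (!cmd %in% c("simulate", "estimate", "angles", "evaluate")) {
      message("unknown subcommand: ", cmd, "\n", .cli_usage())
      return(2L)
    }
    flags <- tryCatch(.parse_flags(argv[-1]),
                      error = function(e) e)
    if (inherits(flags, "error")) {
      message(conditionMessage(flags), "\n", .cli_usage())
      return(2L)
    }
    fnum <- function(key, default) {
      if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
    }
    switch(cmd,
      simulate = {
        out <- flags[["out-dir"]]
        if (is.null(out)) stop("simulate requires --out-dir")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        noise <- if (!is.null(flags$config)) read_config(flags$config)
                 else noise_spec()
        rate <- fnum("rate", 200)
        noise$dt <- 1 / rate
        seed <- as.integer(fnum("seed", 1))
        message("simulate: seed ", seed, ", duration ",
                fnum("duration", 60), " s, rate ", rate, " Hz")
        sim <- simulate_dataset(
          duration = fnum("duration", 60), seed = seed, noise = noise,
          noisy = !isTRUE(flags[["noise-free"]]),
          soft_tissue_mm = fnum("soft-tissue-mm", 0),
          soft_tissue_deg = if (fnum("soft-tissue-mm", 0) > 0) 1 else 0,
          rate = rate)
        write_imu_table(sim$streams, file.path(out, "imu.csv"))
        .write_truth_sidecar(sim$truth, out)
        message("wrote ", file.path(out, "imu.csv"))
        0L
      },
      estimate = {
        if (is.null(flags$input) || is.null(flags[["out-dir"]]))
          stop("estimate requires --input and --out-dir")
        noise <- if (!is.null(flags$config)) read_config(flags$config)
                 else noise_spec()
        streams <- read_imu_table(flags$input)
        cfg <- solver_config(
          max_iterations = as.integer(fnum("max-iterations", 10000)))
        sol <- estimate_lower_body(streams, noise = noise, config = cfg,
                                   decimation = as.integer(fnum("decimation", 20)))
        write_solution(sol, NULL, flags[["out-dir"]])
        message("solution written to ", flags[["out-dir"]],
                " (termination: ", sol$termination, ")")
        0L
      },
      angles = {
        if (is.null(flags[["solution-dir"]]))
          stop("angles requires --solution-dir")
        sol <- read_solution(flags[["solution-dir"]])
        ang <- derive_knee_angles(sol)
        write_solution(ang$solution, ang, flags[["solution-dir"]])
        0L
      },
      evaluate = {
        if (is.null(flags[["solution-dir"]]) || is.null(flags[["truth-dir"]]))
          stop("evaluate requires --solution-dir and --truth-dir")
        sol <- read_solution(flags[["solution-dir"]])
        metrics <- .evaluate_from_sidecar(sol, flags[["truth-dir"]])
        outf <- if (is.null(flags$out))
          file.path(flags[["solution-dir"]], "metrics.json") else flags$out
        jsonlite::write_json(metrics, outf, auto_unbox = TRUE, digits = NA)
        message("metrics written to ", outf)
        0L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  code
}

# Truth sidecars: statics as JSON, full-rate IMU pose states and true knee
# angles as CSV (enough to evaluate any keyframe subsampling later).
.write_truth_sidecar <- function(truth, dir) {
  sk <- list(
    axes = stats::setNames(lapply(1:4, function(a) truth$axes_true[, a]),
                           c("r2", "r3", "r5", "r6")),
    offsets = stats::setNames(lapply(1:12, function(o) truth$offs_true[, o]),
                              .offset_names()),
    femur = as.list(truth$skeleton$femur),
    tibia = as.list(truth$skeleton$tibia),
    hip_width = truth$skeleton$hip_width,
    rate = truth$rate, duration = truth$duration)
  jsonlite::write_json(sk, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  rows <- data.table::rbindlist(lapply(1:7, function(s) {
    imu <- truth$imus[[s]]
    n <- truth$n
    qs <- t(vapply(seq_len(n), function(k) .rot_to_quat(imu$R[, , k]),
                   numeric(4)))
    data.table::data.table(t = truth$t, imu_id = s, qw = qs[, 1],
                           qx = qs[, 2], qy = qs[, 3], qz = qs[, 4],
                           px = imu$p[1, ], py = imu$p[2, ], pz = imu$p[3, ])
  }))
  data.table::fwrite(rows, file.path(dir, "truth_states.csv"))
  ang <- data.table::data.table(
    t = truth$t,
    flexion_right = truth$knee_angles_true$right$flexion,
    flexion_left = truth$knee_angles_true$left$flexion)
  data.table::fwrite(ang, file.path(dir, "truth_angles.csv"))
  invisible(dir)
}

.evaluate_from_sidecar <- function(solution, truth_dir) {
  st <- data.table::fread(file.path(truth_dir, "truth_states.csv"))
  ang <- data.table::fread(file.path(truth_dir, "truth_angles.csv"))
  kt <- solution$t
  sel <- match(round(kt, 9), round(ang$t, 9))
  if (anyNA(sel)) stop("solution keyframe times not found in truth sidecar")
  sol_ang <- derive_knee_angles(solution)
  res <- list(
    knee_flexion_rmse_right =
      angle_error_stats(sol_ang$right$flexion, ang$flexion_right[sel])$rmse,
    knee_flexion_rmse_left =
      angle_error_stats(sol_ang$left$flexion, ang$flexion_left[sel])$rmse)
  pitch <- roll <- dist <- NULL
  p_ref <- vector("list", 7)
  for (s in 1:7) {
    ss <- st[st$imu_id == s][sel]
    Rarr <- array(0, c(3, 3, length(sel)))
    for (k in seq_along(sel))
      Rarr[, , k] <- .quat_to_rot(c(ss$qw[k], ss$qx[k], ss$qy[k], ss$qz[k]))
    e_ref <- .euler_zyx(Rarr)
    e_est <- .euler_zyx(.sol_R(solution, s))
    pitch <- c(pitch, sqrt(mean((e_est["pitch", ] - e_ref["pitch", ])^2)))
    roll <- c(roll, sqrt(mean((e_est["roll", ] - e_ref["roll", ])^2)))
    p_ref[[s]] <- t(as.matrix(ss[, c("px", "py", "pz")]))
  }
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(5, 6), c(6, 7))
  dist <- apply(pairs, 1, function(pr)
    distance_rmse(.sol_mat(solution, "p", pr[1]),
                  .sol_mat(solution, "p", pr[2]),
                  p_ref[[pr[1]]], p_ref[[pr[2]]]))
  res$pitch_rmse_mean <- mean(pitch)
  res$roll_rmse_mean <- mean(roll)
  res$distance_rmse_cm_mean <- mean(dist)
  res
}
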