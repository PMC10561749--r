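# Readers/writers for the three per-trial input streams and result tables.
# File dialects: UTF-8 CSV with "." decimal and one header row; a JSON
# alternative for skeleton streams. Readers convert everything to canonical
# body axes and SI units; files that would silently change units are rejected.

#' Axis mapping between a source device frame and the canonical body frame
#'
#' Each canonical axis is assigned a signed source axis, e.g. `y = "-y"`
#' means canonical up equals the negated source y axis. Any signed
#' permutation is an isometry, so inter-joint distances are preserved.
#'
#' @param x,y,z Signed source-axis labels (`"x"`, `"-x"`, ...) feeding the
#'   canonical X (subject's right), Y (up) and Z (anterior) axes.
#' @return An object of class `axes_config`.
#' @export
#' @examples
#' axes_camera()    # depth-camera frame: X right-of-camera, Y down, Z away
#' axes_identity()  # data already in canonical axes
axes_config <- function(x, y, z) {
  parse1 <- function(s) {
    s <- gsub("^\\+", "", s)
    sign <- if (startsWith(s, "-")) -1 else 1
    ax <- sub("^-", "", s)
    if (!ax %in% CANONICAL_AXES) {
      stop(sprintf("unknown axis label '%s'", s), call. = FALSE)
    }
    c(index = match(ax, CANONICAL_AXES), sign = sign)
  }
  m <- rbind(x = parse1(x), y = parse1(y), z = parse1(z))
  if (anyDuplicated(m[, "index"])) {
    stop("axis mapping must be a permutation of x, y, z", call. = FALSE)
  }
  structure(list(index = m[, "index"], sign = m[, "sign"]),
            class = "axes_config")
}

#' @rdname axes_config
#' @export
axes_identity <- function() axes_config("x", "y", "z")

#' @rdname axes_config
#' @details `axes_camera()` is the default for a depth camera facing the
#'   subject: the camera's x (viewer's right) is the subject's left, its y
#'   points down, and its z (depth, away from the lens) is posterior; all
#'   three are negated.
#' @export
axes_camera <- function() axes_config("-x", "-y", "-z")

apply_axes <- function(m, axes) {
  stopifnot(inherits(axes, "axes_config"))
  out <- m[, axes$index, drop = FALSE] *
    rep(axes$sign, each = nrow(m))
  colnames(out) <- CANONICAL_AXES
  out
}

#' Read a skeleton stream
#'
#' Accepts a long-format CSV (`time, joint, x, y, z`) or a JSON file with
#' `rate_hz`, `timestamps` and a `joints` map. Coordinates are converted to
#' the canonical frame via `axes`. Tracking dropouts (missing frames for a
#' joint) are linearly interpolated up to `max_gap` consecutive frames;
#' longer gaps raise a data error.
#'
#' @param path File path (`.csv` or `.json`).
#' @param axes An [axes_config()]; default [axes_camera()].
#' @param required Joints that must be present; missing ones raise a format
#'   error naming the joint.
#' @param max_gap Maximum dropout length (frames) to interpolate.
#' @param rate_hz Nominal frame rate, used when the file does not carry one.
#' @return A [skeleton_sequence].
#' @export
read_skeleton <- function(path, axes = axes_camera(),
                          required = REQUIRED_JOINTS, max_gap = 3,
                          rate_hz = 30) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    ts <- as.numeric(raw$timestamps)
    if (!is.null(raw$rate_hz)) rate_hz <- raw$rate_hz
    joints <- lapply(raw$joints, function(m) matrix(as.numeric(as.matrix(m)),
                                                    ncol = 3))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("time", "joint", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("skeleton CSV must have columns time, joint, x, y, z",
           call. = FALSE)
    }
    ts <- sort(unique(df$time))
    joints <- lapply(split(df, df$joint), function(d) {
      idx <- match(ts, d$time)
      cbind(d$x[idx], d$y[idx], d$z[idx])
    })
  }
  if (any(diff(ts) <= 0)) {
    stop("skeleton timestamps are not strictly increasing", call. = FALSE)
  }
  miss <- setdiff(required, names(joints))
  if (length(miss)) {
    stop(sprintf("required joint %s missing", miss[1]), call. = FALSE)
  }
  n_interp <- 0L
  joints <- lapply(joints, function(m) {
    bad <- !stats::complete.cases(m)
    if (any(bad)) {
      runs <- rle(bad)
      if (any(runs$values & runs$lengths > max_gap)) {
        stop(sprintf(
          "tracking gap longer than %d frames; split the recording", max_gap),
          call. = FALSE)
      }
      n_interp <<- n_interp + sum(bad)
      for (j in 1:3) {
        m[, j] <- approx(ts[!bad], m[!bad, j], xout = ts, rule = 2)$y
      }
    }
    m
  })
  if (n_interp > 0) {
    message(sprintf("read_skeleton: interpolated %d dropout frames", n_interp))
  }
  joints <- lapply(joints, apply_axes, axes = axes)
  skeleton_sequence(ts, joints, rate_hz = rate_hz)
}

#' Write a skeleton stream
#'
#' Writes canonical-frame coordinates (long CSV or JSON by extension), so a
#' round trip with `axes = axes_identity()` is lossless.
#'
#' @param skel A [skeleton_sequence].
#' @param path Output path (`.csv` or `.json`).
#' @export
write_skeleton <- function(skel, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(rate_hz = skel$rate_hz, timestamps = skel$timestamps,
           joints = lapply(skel$joints, unname)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    rows <- do.call(rbind, lapply(names(skel$joints), function(j) {
      m <- skel$joints[[j]]
      data.frame(time = skel$timestamps, joint = j,
                 x = m[, 1], y = m[, 2], z = m[, 3])
    }))
    rows <- rows[order(rows$time, rows$joint), ]
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

# accepted unit suffixes for IMU channel headers
ACCEL_UNITS <- c(m_s2 = 1, g = 9.81)
GYRO_UNITS <- c(rad_s = 1, deg_s = pi / 180)

#' Read an IMU recording
#'
#' CSV with a `time` column and six channels whose headers declare units by
#' suffix: `ax.m_s2`/`ax.g` etc. for acceleration, `gx.rad_s`/`gx.deg_s` for
#' angular velocity. Values are converted to m/s^2 and rad/s.
#'
#' @param path CSV file path.
#' @param site Sensor site, one of [IMU_SITES].
#' @param rate_hz Nominal sample rate (default 128).
#' @return An [imu_recording].
#' @export
read_imu <- function(path, site, rate_hz = 128) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"time" %in% names(df)) stop("IMU CSV needs a time column", call. = FALSE)
  chans <- setdiff(names(df), "time")
  if (length(chans) != 6) {
    stop(sprintf("IMU CSV must have 6 channels, found %d", length(chans)),
         call. = FALSE)
  }
  get_chan <- function(prefix, units) {
    hit <- grep(paste0("^", prefix, "\\."), chans, value = TRUE)
    if (length(hit) != 1) {
      stop(sprintf("channel %s missing or duplicated", prefix), call. = FALSE)
    }
    unit <- sub(paste0("^", prefix, "\\."), "", hit)
    if (!unit %in% names(units)) {
      stop(sprintf("unknown unit '%s' for channel %s", unit, prefix),
           call. = FALSE)
    }
    df[[hit]] * units[[unit]]
  }
  accel <- cbind(get_chan("ax", ACCEL_UNITS), get_chan("ay", ACCEL_UNITS),
                 get_chan("az", ACCEL_UNITS))
  gyro <- cbind(get_chan("gx", GYRO_UNITS), get_chan("gy", GYRO_UNITS),
                get_chan("gz", GYRO_UNITS))
  imu_recording(site, df$time, accel, gyro, rate_hz = rate_hz)
}

#' Write an IMU recording
#'
#' Channels are written in SI units with unit-suffixed headers
#' (`ax.m_s2`, ..., `gz.rad_s`).
#'
#' @param imu An [imu_recording].
#' @param path Output CSV path.
#' @export
write_imu <- function(imu, path) {
  df <- data.frame(time = imu$timestamps)
  for (j in 1:3) df[[paste0("a", CANONICAL_AXES[j], ".m_s2")]] <- imu$accel[, j]
  for (j in 1:3) df[[paste0("g", CANONICAL_AXES[j], ".rad_s")]] <- imu$gyro[, j]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a treadmill belt-speed log
#'
#' CSV columns `time` (s) and `speed` (m/s). Negative speeds are a data
#' error.
#'
#' @param path CSV file path.
#' @param rate_hz Nominal log rate (default 64).
#' @return A [treadmill_log].
#' @export
read_treadmill <- function(path, rate_hz = 64) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "speed") %in% names(df))) {
    stop("treadmill CSV needs columns time, speed", call. = FALSE)
  }
  if (any(df$speed < 0)) stop("negative belt speed in log", call. = FALSE)
  treadmill_log(df$time, df$speed, rate_hz = rate_hz)
}

#' @rdname read_treadmill
#' @param belt A [treadmill_log] to write.
#' @export
write_treadmill <- function(belt, path) {
  write.csv(data.frame(time = belt$timestamps, speed = belt$speed),
            path, row.names = FALSE)
  invisible(path)
}

#' Write result tables to a directory
#'
#' Serializes a named list of data frames (stride tables, summary rows,
#' agreement reports, plot data) as `<name>.csv` files.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Export a gait-event list as CSV
#'
#' @param events A [gait_events] table.
#' @param path Output CSV path.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events)[, c("time", "side", "kind", "source")],
            path, row.names = FALSE)
  invisible(path)
}
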