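#' Read frame-indexed 3-D tracked points
#'
#' Reads a delimited text export of 3-D tracking software into a tidy
#' trajectory. Two layouts are supported: `"frame"` (columns
#' `frame, x, y, z`; comma- or tab-delimited; header optional) and
#' `"xyzpts"` (a DLTdv-style export of one `x, y, z` triple per row, where
#' the row number is the frame index). Rows in which any coordinate is
#' missing or non-numeric are treated as untracked frames: they are dropped
#' and counted, never interpolated.
#'
#' @param path Path to the delimited text file.
#' @param frame_rate Recording frame rate in frames per second (> 0).
#' @param species Species or group label attached to the trajectory.
#' @param format `"frame"` (default) or `"xyzpts"`.
#' @param track_id Identifier for the track; defaults to the file name.
#' @return A `trj_trajectory`: a tibble with columns `frame`, `x`, `y`, `z`
#'   (meters), rows sorted by frame, with attributes `species`, `frame_rate`,
#'   `track_id` and `n_dropped` (count of untracked rows removed).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("frame,x,y,z", "1,0,0,0", "2,0.1,0,0", "3,0.2,0.05,0"), tf)
#' read_tracked_points(tf, frame_rate = 30, species = "demo")
#' @export
read_tracked_points <- function(path, frame_rate, species,
                                format = c("frame", "xyzpts"),
                                track_id = basename(path)) {
  format <- match.arg(format)
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1L)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (frame_rate <= 0) abort("frame_rate must be > 0")

  raw <- readr::read_delim(
    path,
    delim = detect_delim(path),
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE,
    progress = FALSE
  )
  if (nrow(raw) == 0L) abort("no data: file is empty")

  # header detection: first row entirely non-numeric tokens
  first_num <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  if (all(is.na(first_num))) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) abort("no data: no numeric rows")

  if (format == "frame") {
    if (ncol(raw) < 4L) abort("malformed track: expected columns frame, x, y, z")
    num <- suppressWarnings(vapply(raw[1:4], as.numeric, numeric(nrow(raw))))
    num <- matrix(num, ncol = 4L)
    frame <- num[, 1]
    xyz <- num[, 2:4, drop = FALSE]
  } else {
    if (ncol(raw) < 3L) abort("malformed track: expected x, y, z triples")
    num <- suppressWarnings(vapply(raw[1:3], as.numeric, numeric(nrow(raw))))
    num <- matrix(num, ncol = 3L)
    frame <- seq_len(nrow(num))
    xyz <- num
  }

  ok <- stats::complete.cases(cbind(frame, xyz)) & apply(is.finite(xyz), 1L, all)
  n_dropped <- sum(!ok)
  frame <- frame[ok]
  xyz <- xyz[ok, , drop = FALSE]
  if (length(frame) == 0L) abort("no data: no numeric rows")
  if (anyDuplicated(frame)) abort("malformed track: duplicate frame index")

  ord <- order(frame)
  out <- tibble(
    frame = as.integer(frame[ord]),
    x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3]
  )
  new_trajectory(out, species = species, frame_rate = frame_rate,
                 track_id = track_id, n_dropped = n_dropped)
}

detect_delim <- function(path) {
  l1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(l1) && grepl("\t", l1[1])) "\t" else ","
}

new_trajectory <- function(df, species, frame_rate, track_id, n_dropped = 0L) {
  structure(
    df,
    class = c("trj_trajectory", class(tibble())),
    species = species, frame_rate = frame_rate,
    track_id = track_id, n_dropped = n_dropped
  )
}

#' Build a trajectory from in-memory coordinates
#'
#' Convenience constructor used by the synthetic generators and by tests.
#'
#' @param frame Integer frame indices, strictly increasing.
#' @param x,y,z Coordinates in meters.
#' @inheritParams read_tracked_points
#' @return A `trj_trajectory` tibble.
#' @export
trajectory <- function(frame, x, y, z, frame_rate, species = "unknown",
                       track_id = "in-memory") {
  stopifnot(length(frame) == length(x), length(x) == length(y),
            length(y) == length(z))
  if (is.unsorted(frame, strictly = TRUE)) {
    abort("malformed track: frame indices must be strictly increasing")
  }
  if (!all(is.finite(c(x, y, z)))) abort("positions must be finite")
  if (frame_rate <= 0) abort("frame_rate must be > 0")
  new_trajectory(tibble(frame = as.integer(frame), x = x, y = y, z = z),
                 species = species, frame_rate = frame_rate,
                 track_id = track_id)
}

#' Split a trajectory into continuously tracked segments ("trials")
#'
#' A segment is a maximal run of consecutive frame indices. Runs shorter
#' than `min_len` frames are discarded; each surviving segment is one
#' trial of continuous tracking.
#'
#' @param traj A `trj_trajectory`.
#' @param min_len Minimum segment length in frames (default 20; runs with
#'   fewer frames are excluded).
#' @return A tibble with columns `segment` (integer id, in temporal order),
#'   `frame`, `x`, `y`, `z`; attributes of `traj` are carried along. May
#'   have zero rows if every run is short.
#' @export
segment_tracks <- function(traj, min_len = 20L) {
  stopifnot(min_len >= 2L)
  if (nrow(traj) == 0L) return(empty_segments(traj))
  run_id <- cumsum(c(1L, diff(traj$frame) != 1L))
  keep_runs <- which(tabulate(run_id) >= min_len)
  if (length(keep_runs) == 0L) return(empty_segments(traj))
  out <- traj[run_id %in% keep_runs, , drop = FALSE]
  out <- tibble::add_column(
    as_tibble(out),
    segment = match(run_id[run_id %in% keep_runs], keep_runs),
    .before = 1L
  )
  structure(out,
            class = c("trj_segments", class(tibble())),
            species = attr(traj, "species"),
            frame_rate = attr(traj, "frame_rate"),
            track_id = attr(traj, "track_id"))
}

empty_segments <- function(traj) {
  structure(tibble(segment = integer(), frame = integer(),
                   x = double(), y = double(), z = double()),
            class = c("trj_segments", class(tibble())),
            species = attr(traj, "species"),
            frame_rate = attr(traj, "frame_rate"),
            track_id = attr(traj, "track_id"))
}

#' Per-frame displacement vectors from tracked segments
#'
#' Differences consecutive positions within each segment; displacements are
#' never taken across a segment boundary, so a trajectory with S segments of
#' lengths \eqn{L_s} yields \eqn{\sum_s (L_s - 1)} vectors.
#'
#' @param segments A `trj_segments` tibble (or a list of them, which are
#'   concatenated; useful for pooling several individuals of one species).
#' @return A tibble with columns `segment`, `dx`, `dy`, `dz`
#'   (meters per frame) and attributes `species`, `frame_rate`,
#'   `source_counts` (frames contributed per segment).
#' @export
displacements <- function(segments) {
  if (is.list(segments) && !inherits(segments, "data.frame")) {
    parts <- purrr::map(segments, displacements)
    out <- bind_rows(purrr::imap(parts, function(p, i) {
      mutate(as_tibble(p), segment = paste0(i, ".", .data$segment))
    }))
    return(structure(out, class = c("trj_displacements", class(tibble())),
                     species = attr(parts[[1]], "species"),
                     frame_rate = attr(parts[[1]], "frame_rate"),
                     source_counts = unlist(purrr::map(parts, attr, "source_counts"))))
  }
  if (nrow(segments) == 0L) {
    return(structure(tibble(segment = integer(), dx = double(),
                            dy = double(), dz = double()),
                     class = c("trj_displacements", class(tibble())),
                     species = attr(segments, "species"),
                     frame_rate = attr(segments, "frame_rate"),
                     source_counts = integer()))
  }
  pieces <- split(as_tibble(segments), segments$segment)
  short <- vapply(pieces, nrow, 1L) < 2L
  if (any(short)) {
    warn(sprintf("%d segment(s) of length 1 skipped", sum(short)))
    pieces <- pieces[!short]
  }
  out <- bind_rows(purrr::map(pieces, function(p) {
    n <- nrow(p)
    tibble(segment = p$segment[-1],
           dx = diff(p$x), dy = diff(p$y), dz = diff(p$z))
  }))
  structure(out, class = c("trj_displacements", class(tibble())),
            species = attr(segments, "species"),
            frame_rate = attr(segments, "frame_rate"),
            source_counts = vapply(pieces, function(p) nrow(p) - 1L, 1L))
}

#' Trim displacement outliers, keeping the most similar fraction
#'
#' Ranks displacement vectors by Mahalanobis distance from their sample mean
#' and keeps the `ceiling(retain * N)` most central rows (input order
#' preserved among kept rows). Similarity in Mahalanobis terms is
#' scale-invariant and treats speed and direction jointly. If the sample
#' covariance is singular the distance falls back to a per-axis standardized
#' Euclidean distance, with a warning (axes with zero variance contribute
#' only through their mean offset).
#'
#' @param disp A displacement tibble with columns `dx`, `dy`, `dz` (as from
#'   [displacements()]).
#' @param retain Fraction of rows to keep, in (0, 1]; default 0.97.
#' @return The same tibble with the most extreme rows removed; attribute
#'   `n_removed` records how many.
#' @export
trim_outliers <- function(disp, retain = 0.97) {
  stopifnot(retain > 0, retain <= 1)
  n <- nrow(disp)
  if (retain == 1) {
    return(structure(disp, n_removed = 0L))
  }
  if (n < 2L) abort("need at least 2 displacement vectors to trim")
  m <- as.matrix(disp[, c("dx", "dy", "dz")])
  ctr <- colMeans(m)
  cv <- cov(m)
  d2 <- tryCatch(
    mahalanobis(m, ctr, cv),
    error = function(e) {
      warn("singular covariance; using standardized Euclidean distance")
      s <- apply(m, 2L, sd)
      s[s == 0] <- 1
      rowSums(sweep(sweep(m, 2L, ctr), 2L, s, "/")^2)
    }
  )
  keep_n <- ceiling(retain * n)
  keep <- sort(order(d2)[seq_len(keep_n)])  # stable: input order preserved
  out <- disp[keep, , drop = FALSE]
  structure(out, class = class(disp),
            species = attr(disp, "species"),
            frame_rate = attr(disp, "frame_rate"),
            source_counts = attr(disp, "source_counts"),
            n_removed = n - keep_n)
}

#' Normalize displacements into the unit cube
#'
#' Divides displacement vectors by a scale so every component lies in
#' \eqn{[-1, 1]}; the cube bounds represent the largest distance the animal
#' moves along any axis in one frame. `scale = "auto"` uses the maximum
#' absolute component of the input. When several datasets are to be compared
#' on a common support, pass the pooled maximum explicitly (see
#' [shared_scale()]); differential entropy shifts by \eqn{-3\ln s} under
#' rescaling by `s`, so comparability requires one declared scale.
#' `per_axis = TRUE` normalizes each axis by its own maximum, making the
#' result invariant to independent axis rescalings (a "shape not size"
#' convention under which geometrically similar paths have equal entropy).
#'
#' @param disp Displacement tibble with columns `dx`, `dy`, `dz`.
#' @param scale `"auto"`, or a positive number at least as large as the
#'   maximum absolute component (a length-3 vector when `per_axis = TRUE`).
#' @param per_axis Normalize each axis by its own scale (default `FALSE`).
#' @return A `displacement_set`: tibble with columns `dx`, `dy`, `dz` in
#'   \eqn{[-1,1]} and attributes `scale` (meters per frame), `species`,
#'   `source_counts`, `frame_rate`.
#' @export
normalize_to_cube <- function(disp, scale = "auto", per_axis = FALSE) {
  m <- as.matrix(disp[, c("dx", "dy", "dz")])
  if (nrow(m) < 1L) abort("need at least one displacement vector")
  axmax <- apply(abs(m), 2L, max)
  if (identical(scale, "auto")) {
    s <- if (per_axis) axmax else rep(max(axmax), 3L)
    if (any(s == 0)) abort("degenerate scale: all-zero displacements")
  } else {
    stopifnot(is.numeric(scale), all(scale > 0))
    s <- if (per_axis) rep_len(scale, 3L) else rep(scale[1], 3L)
    if (any(axmax > s * (1 + 1e-12))) {
      abort("scale smaller than the maximum absolute displacement component")
    }
  }
  out <- tibble(dx = m[, 1] / s[1], dy = m[, 2] / s[2], dz = m[, 3] / s[3])
  structure(out,
            class = c("displacement_set", class(tibble())),
            scale = if (per_axis) s else s[1],
            species = attr(disp, "species"),
            source_counts = attr(disp, "source_counts"),
            frame_rate = attr(disp, "frame_rate"))
}

#' Pooled normalization scale for a set of displacement tables
#'
#' Computes the maximum absolute displacement component across all datasets
#' entering one comparison, so that each can be normalized onto the same
#' cube support.
#'
#' @param ... Displacement tibbles (columns `dx`, `dy`, `dz`).
#' @return A single positive number (meters per frame).
#' @export
shared_scale <- function(...) {
  sets <- list(...)
  mx <- purrr::map_dbl(sets, function(d) {
    max(abs(as.matrix(d[, c("dx", "dy", "dz")])))
  })
  s <- max(mx)
  if (s == 0) abort("degenerate scale: all-zero displacements")
  s
}

#' Construct a displacement set directly from a matrix
#'
#' Low-level constructor for data already in cube coordinates (used by the
#' samplers and tests).
#'
#' @param m An N x 3 numeric matrix with entries in \eqn{[-1,1]}.
#' @param scale Normalization constant in meters per frame.
#' @param species Label.
#' @return A `displacement_set` tibble.
#' @export
displacement_set <- function(m, scale = 1, species = "unknown") {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 3L, nrow(m) >= 1L)
  if (max(abs(m)) > 1 + 1e-9) abort("components must lie in [-1, 1]")
  structure(tibble(dx = m[, 1], dy = m[, 2], dz = m[, 3]),
            class = c("displacement_set", class(tibble())),
            scale = scale, species = species)
}
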