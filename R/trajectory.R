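#' Construct a labeled-atom trajectory
#'
#' Frames of labeled coordinates with an optional cubic periodic box. Labels
#' come from the fixed role vocabulary `OC` (carbonyl oxygen), `N` (amide
#' nitrogen), `HN` (amide hydrogen), `OW` (water oxygen), `HW` (water
#' hydrogen); hydrogen and deuterium are treated identically.
#'
#' @param labels character vector of atom labels, constant across frames;
#'   at most one `OC` per frame.
#' @param frames list of frames, each a list with `coords` (n x 3 numeric
#'   matrix, Angstrom) and `time` (ps).
#' @param box_length cubic box edge, Angstrom, or `NULL` for a non-periodic
#'   trajectory.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(labels, frames, box_length = NULL) {
  stopifnot(is.character(labels), is.list(frames), length(frames) >= 1L)
  n <- length(labels)
  if (sum(labels == "OC") > 1L)
    stop("a trajectory frame must contain at most one OC atom")
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f$coords) || nrow(f$coords) != n || ncol(f$coords) != 3L)
      stop("frame ", i, " coordinates are not a ", n, " x 3 matrix")
    if (is.null(f$time)) frames[[i]]$time <- NA_real_
  }
  if (!is.null(box_length) && box_length <= 0)
    stop("box_length must be positive")
  structure(list(labels = labels, frames = frames,
                 box_length = box_length),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms (%s), box = %s A\n",
              length(x$frames), length(x$labels),
              paste(sprintf("%s:%d", names(table(x$labels)),
                            table(x$labels)), collapse = " "),
              if (is.null(x$box_length)) "none" else
                format(x$box_length)))
  invisible(x)
}

## internal: minimum-image displacement vectors from one point to many
min_image_disp <- function(from, to, box) {
  d <- sweep(to, 2L, from)
  if (!is.null(box)) d <- d - box * round(d / box)
  d
}

## internal: minimum-image distances from one point to a coordinate matrix
min_image_dist <- function(from, to, box) {
  d <- min_image_disp(from, to, box)
  sqrt(rowSums(d * d))
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: an atom count line, a comment line carrying
#' `frame=<i> time_ps=<t> box_A=<L>`, then `label x y z` rows.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$labels)
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(as.character(n), con)
    comment <- sprintf("frame=%d time_ps=%.*g", i, 12L, f$time)
    if (!is.null(traj$box_length))
      comment <- paste0(comment, sprintf(" box_A=%.*g", 12L,
                                         traj$box_length))
    writeLines(comment, con)
    writeLines(sprintf("%s %.12g %.12g %.12g", traj$labels,
                       f$coords[, 1L], f$coords[, 2L], f$coords[, 3L]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path file written by [write_xyz()] (or any XYZ whose comment line
#'   optionally carries `time_ps=` and `box_A=` tokens).
#' @return A [trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  labels <- NULL
  box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed atom-count line at line ", i)
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i)
    comment <- lines[i + 1L]
    tm <- NA_real_
    m <- regmatches(comment, regexec("time_ps=([-0-9.eE+]+)", comment))[[1L]]
    if (length(m) == 2L) tm <- as.numeric(m[2L])
    b <- regmatches(comment, regexec("box_A=([-0-9.eE+]+)", comment))[[1L]]
    if (length(b) == 2L) box <- as.numeric(b[2L])
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[[:space:]]+")
    lab <- vapply(rows, `[`, "", 1L)
    xyz <- matrix(as.numeric(vapply(rows, function(r) r[2:4],
                                    character(3L))),
                  ncol = 3L, byrow = TRUE)
    if (anyNA(xyz)) stop("malformed coordinate row in frame at line ", i)
    if (is.null(labels)) labels <- lab
    else if (!identical(labels, lab))
      stop("atom labels change between frames (frame at line ", i, ")")
    frames[[length(frames) + 1L]] <- list(coords = xyz, time = tm)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  trajectory(labels, frames, box_length = box)
}
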