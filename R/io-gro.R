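# GROMACS .gro coordinate files, single- or multi-frame. Fixed-width format:
#   title (may carry "t= <ps>"), atom count, atom records, box line.
# Atom record: %5d%-5s%5s%5d%8.3f%8.3f%8.3f (+ optional velocities).
# Coordinates and box lengths are in nm.

#' Read a GROMACS .gro file
#'
#' Reads one or more concatenated frames from a `.gro` file. All frames must
#' share the same atom table; only coordinates, box and time differ.
#'
#' @param path Path to a `.gro` file.
#' @return A list with `atoms` (tibble: `atom_index`, `resid`, `resname`,
#'   `atom_name`), `coords` (array `n_atoms x 3 x n_frames`, nm), `box`
#'   (matrix `n_frames x 3`, nm, rectangular-box edge lengths) and `times`
#'   (numeric, ps, `NA` when the title carries no time stamp).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop_ls("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop_ls("not a .gro file (too short): %s", path)

  frames <- list()
  times <- numeric()
  boxes <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i], whitespace = "[ \t\r]"))) {
    title <- lines[i]
    n_atoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n_atoms)) stop_ls("malformed atom count at line %d of %s", i + 1L, path)
    atom_lines <- lines[(i + 2L):(i + 1L + n_atoms)]
    box_line <- lines[i + 2L + n_atoms]

    t_ps <- NA_real_
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m) == 1L) t_ps <- as.numeric(sub("t=\\s*", "", m))

    resid <- as.integer(substr(atom_lines, 1L, 5L))
    resname <- trimws(substr(atom_lines, 6L, 10L))
    atom_name <- trimws(substr(atom_lines, 11L, 15L))
    x <- as.numeric(substr(atom_lines, 21L, 28L))
    y <- as.numeric(substr(atom_lines, 29L, 36L))
    z <- as.numeric(substr(atom_lines, 37L, 44L))
    box <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])[1:3]

    frames[[length(frames) + 1L]] <- list(
      atoms = tibble::tibble(
        atom_index = seq_len(n_atoms), resid = resid,
        resname = resname, atom_name = atom_name
      ),
      xyz = cbind(x, y, z)
    )
    times <- c(times, t_ps)
    boxes[[length(boxes) + 1L]] <- box
    i <- i + 3L + n_atoms
  }
  if (length(frames) == 0L) stop_ls("no frames in %s", path)

  n_atoms <- nrow(frames[[1]]$atoms)
  same <- vapply(frames, function(f) nrow(f$atoms) == n_atoms, logical(1))
  if (!all(same)) stop_ls("frames of %s differ in atom count", path)

  coords <- array(NA_real_, dim = c(n_atoms, 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]$xyz
  list(
    atoms = frames[[1]]$atoms,
    coords = coords,
    box = do.call(rbind, boxes),
    times = times
  )
}

#' Write a GROMACS .gro file
#'
#' Writes one frame per slice of `coords`; multi-frame output is the
#' concatenation GROMACS produces for trajectories saved as `.gro`.
#'
#' @param atoms Tibble with `resid`, `resname`, `atom_name` (one row per atom).
#' @param coords Array `n_atoms x 3 x n_frames` (nm) or a `n_atoms x 3` matrix.
#' @param box Numeric length-3 (nm) or `n_frames x 3` matrix.
#' @param path Output path.
#' @param times Optional frame times in ps, written into the title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(atoms, coords, box, path, times = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  n_frames <- dim(coords)[3]
  n_atoms <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames)) {
    t_ps <- if (is.null(times)) (k - 1) * 1.0 else times[k]
    writeLines(sprintf("frame t= %.4f", t_ps), con)
    writeLines(sprintf("%5d", n_atoms), con)
    writeLines(sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      atoms$resid %% 100000L, substr(atoms$resname, 1, 5),
      substr(atoms$atom_name, 1, 5), seq_len(n_atoms) %% 100000L,
      coords[, 1, k], coords[, 2, k], coords[, 3, k]
    ), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[k, 1], box[k, 2], box[k, 3]), con)
  }
  invisible(path)
}
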