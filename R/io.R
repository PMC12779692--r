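#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ dialect: each frame is an atom-count line, a comment line,
#' then one `element x y z` line per atom. All frames must share atom count
#' and order.
#'
#' @param path XYZ file.
#' @param reference_frame_index passed to [trajectory()].
#' @return a `trajectory`.
#' @export
read_xyz <- function(path, reference_frame_index = 1L) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL; i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1L + nat > length(lines))
      stop("malformed XYZ: truncated frame starting at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop("malformed XYZ: bad atom line ", i + 1L + bad[1])
    lab <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("malformed XYZ: non-numeric coordinate near line ", i + 2L)
    if (is.null(labels)) labels <- lab
    else if (length(lab) != length(labels))
      stop("frames disagree on atom count")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  trajectory(frames, atom_labels = labels,
             reference_frame_index = reference_frame_index)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are written with 6 significant figures for reproducible
#' cross-platform text output.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param comment per-frame comment prefix.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, comment = "frame") {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]; nat <- dim(traj$coords)[2]
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nf)) {
    writeLines(as.character(nat), con)
    writeLines(sprintf("%s %d", comment, i), con)
    m <- frame_coords(traj, i)
    writeLines(sprintf("%s %.6g %.6g %.6g",
                       traj$atom_labels, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a long-format trajectory CSV
#'
#' Columns `frame`, `atom`, `x`, `y`, `z`; frames and atoms taken in sorted
#' order of first appearance.
#'
#' @param path CSV file.
#' @param reference_frame_index passed to [trajectory()].
#' @return a `trajectory`.
#' @export
read_trajectory_csv <- function(path, reference_frame_index = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "atom", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory CSV missing columns: ", paste(miss, collapse = ", "))
  frames_id <- sort(unique(df$frame))
  atoms_id <- unique(df$atom[df$frame == frames_id[1]])
  frames <- lapply(frames_id, function(f) {
    sub <- df[df$frame == f, ]
    sub <- sub[match(atoms_id, sub$atom), ]
    if (any(is.na(sub$x))) stop("frame ", f, " missing atoms")
    as.matrix(sub[, c("x", "y", "z")])
  })
  trajectory(frames, atom_labels = as.character(atoms_id),
             reference_frame_index = reference_frame_index)
}

#' Read a per-frame energy-component table
#'
#' Columns `e_vdw`, `e_ele`, `g_gb`, `g_sa`, `minus_t_ds` (kcal/mol).
#'
#' @param path CSV file.
#' @return data.frame with those columns.
#' @export
read_energy_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("e_vdw", "e_ele", "g_gb", "g_sa", "minus_t_ds")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("energy table missing columns: ", paste(miss, collapse = ", "))
  df
}

write_csv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
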