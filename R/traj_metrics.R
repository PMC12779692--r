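#' Trajectory container and MD post-processing metrics
#'
#' A `trajectory` holds ordered frames of per-atom Cartesian coordinates
#' (Angstrom). Post-processing metrics implemented on it:
#' \deqn{RMSD = \sqrt{\tfrac{1}{N}\sum_{i=1}^N (r_{i2} - r_{i1})^2}}
#' between a reference frame and a compared frame (optionally after
#' least-squares rigid superposition), and the per-atom fluctuation
#' \deqn{RMSF_i = \sqrt{\tfrac{1}{N}\sum_{t=1}^N (r_i(t) - \langle r_i\rangle)^2}.}
#'
#' @name traj_metrics
NULL

#' Construct a trajectory
#'
#' @param coords numeric array `frames x atoms x 3` (Angstrom), or a list of
#'   `atoms x 3` matrices.
#' @param atom_labels optional character vector (length = atom count).
#' @param frame_times optional numeric vector of frame times (ns).
#' @param reference_frame_index frame used as RMSD reference (default 1, the
#'   initial position).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, atom_labels = NULL, frame_times = NULL,
                       reference_frame_index = 1L) {
  if (is.list(coords)) {
    nat <- unique(vapply(coords, nrow, integer(1)))
    if (length(nat) != 1) stop("all frames must share the atom count")
    arr <- array(NA_real_, dim = c(length(coords), nat, 3))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] >= 1)
  n_atoms <- dim(coords)[2]
  if (is.null(atom_labels)) atom_labels <- paste0("A", seq_len(n_atoms))
  if (length(atom_labels) != n_atoms)
    stop("atom_labels length must match the atom count")
  if (is.null(frame_times)) frame_times <- seq_len(dim(coords)[1]) - 1
  stopifnot(reference_frame_index >= 1, reference_frame_index <= dim(coords)[1])
  structure(list(coords = coords, atom_labels = atom_labels,
                 frame_times = frame_times,
                 reference_frame_index = as.integer(reference_frame_index)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms (reference frame %d)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$reference_frame_index))
  invisible(x)
}

frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rotation + translation of `mobile` onto `target` via SVD of
#' the cross-covariance of the centred coordinates, with the usual
#' determinant correction so the rotation is proper (no reflection).
#'
#' @param mobile,target `atoms x 3` matrices with matching rows.
#' @return the superposed copy of `mobile`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("atom-count mismatch between frames")
  cm <- colMeans(mobile); ct <- colMeans(target)
  a <- sweep(mobile, 2, cm); b <- sweep(target, 2, ct)
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(a %*% t(rot), 2, ct, `+`)
}

#' Root-mean-square deviation between two frames
#'
#' With `align = FALSE` (the default) the deviation is taken on the raw
#' coordinates, matching the plain two-frame formula; with `align = TRUE`
#' the compared frame is first rigidly superposed onto the reference
#' (Kabsch least squares), the convention used in MD practice.
#'
#' @param traj a `trajectory`.
#' @param frame_index frame compared against the reference.
#' @param reference_index reference frame (default the trajectory's
#'   `reference_frame_index`).
#' @param align logical; superpose before measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(traj, frame_index,
                 reference_index = traj$reference_frame_index,
                 align = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  if (frame_index < 1 || frame_index > nf ||
      reference_index < 1 || reference_index > nf)
    stop("frame index out of range")
  r1 <- frame_coords(traj, reference_index)
  r2 <- frame_coords(traj, frame_index)
  if (align) r2 <- kabsch_superpose(r2, r1)
  sqrt(mean(rowSums((r2 - r1)^2)))
}

#' Per-frame RMSD series
#'
#' @inheritParams rmsd
#' @return data.frame with `frame`, `time`, `rmsd`.
#' @export
rmsd_series <- function(traj, reference_index = traj$reference_frame_index,
                        align = FALSE) {
  nf <- dim(traj$coords)[1]
  data.frame(
    frame = seq_len(nf),
    time = traj$frame_times,
    rmsd = vapply(seq_len(nf), function(i)
      rmsd(traj, i, reference_index, align), numeric(1))
  )
}

#' Per-atom root-mean-square fluctuation
#'
#' Fluctuation of each atom about its trajectory-average position, with
#' uniform frame weighting (population variance, 1/N).
#'
#' @param traj a `trajectory` with at least 2 frames.
#' @return data.frame with `atom_label` and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  if (nf < 2) stop("RMSF needs at least 2 frames")
  mean_pos <- apply(traj$coords, c(2, 3), mean)
  dev2 <- sweep(traj$coords, c(2, 3), mean_pos)^2
  msf <- apply(dev2, 2, sum) / nf  # sums squared deviation over frames & xyz
  data.frame(atom_label = traj$atom_labels, rmsf = sqrt(msf),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond occupancy from a donor-acceptor distance series
#'
#' Occupancy is the percentage of frames in which the donor-acceptor
#' distance is within the cutoff (default 3.5 Angstrom).
#'
#' @param distances positive numeric vector of per-frame distances (Angstrom).
#' @param cutoff Angstrom (default 3.5).
#' @return occupancy percentage in [0, 100].
#' @export
hbond_occupancy <- function(distances, cutoff = 3.5) {
  stopifnot(is.numeric(distances))
  if (!length(distances)) stop("empty distance series")
  if (any(distances <= 0)) stop("distances must be positive")
  100 * sum(distances <= cutoff) / length(distances)
}

#' Hydrogen-bond occupancy report over several pairs
#'
#' Pairs with occupancy below `min_occupancy` (default 2 percent) are
#' dropped from the report as not relevant for complex stabilisation.
#'
#' @param series named list of per-frame distance vectors, one entry per
#'   donor-acceptor pair.
#' @param cutoff Angstrom (default 3.5).
#' @param min_occupancy reporting floor in percent (default 2).
#' @return data.frame with `pair` and `occupancy_pct`, filtered and sorted
#'   decreasing.
#' @export
hbond_occupancy_report <- function(series, cutoff = 3.5, min_occupancy = 2) {
  stopifnot(is.list(series), length(series) >= 1)
  occ <- vapply(series, hbond_occupancy, numeric(1), cutoff = cutoff)
  out <- data.frame(pair = names(occ), occupancy_pct = unname(occ),
                    stringsAsFactors = FALSE)
  out <- out[out$occupancy_pct >= min_occupancy, , drop = FALSE]
  out[order(-out$occupancy_pct), , drop = FALSE]
}

#' MM/GBSA binding-energy total
#'
#' \deqn{\Delta G_{bind} = E_{vdW} + E_{ele} + G_{GB} + G_{SA} - T\Delta S}
#' where the entropic column stores \eqn{-T\Delta S} directly (so the
#' per-frame total is the plain sum of the five columns). On per-frame
#' series the mean and standard deviation of the total are reported with
#' per-term means; on single-value (table-style) input the exact sum is
#' returned and the SD is `NA`.
#'
#' @param e_vdw,e_ele,g_gb,g_sa numeric vectors (kcal/mol), equal length.
#' @param minus_t_ds numeric vector of \eqn{-T\Delta S} (kcal/mol), either
#'   the common length or a single scalar recycled across frames.
#' @return list with `mean` and `sd` of the total and `term_means` (named).
#' @export
mmgbsa_total <- function(e_vdw, e_ele, g_gb, g_sa, minus_t_ds) {
  n <- length(e_vdw)
  if (length(e_ele) != n || length(g_gb) != n || length(g_sa) != n)
    stop("energy component series must have equal length")
  if (!length(minus_t_ds) %in% c(1L, n))
    stop("minus_t_ds must be a scalar or match the series length")
  minus_t_ds <- rep_len(minus_t_ds, n)
  total <- e_vdw + e_ele + g_gb + g_sa + minus_t_ds
  list(
    mean = mean(total),
    sd = if (n >= 2) stats::sd(total) else NA_real_,
    term_means = c(e_vdw = mean(e_vdw), e_ele = mean(e_ele),
                   g_gb = mean(g_gb), g_sa = mean(g_sa),
                   minus_t_ds = mean(minus_t_ds))
  )
}
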