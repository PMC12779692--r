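#' Synthetic inputs with known ground truth
#'
#' The quantum-chemistry, docking and MD engines that would normally supply
#' orbital energies, charge populations, trajectories and energy
#' decompositions are out of scope; these generators emulate their outputs
#' under a fixed seed with recorded ground truth, so every downstream metric
#' can be validated by parameter recovery. Generated text files round
#' numerics to 6 significant figures for bit-identical cross-platform
#' reruns, and each writer emits a sidecar JSON of the ground-truth
#' parameters.
#'
#' @name synthetic_data
NULL

sidecar_path <- function(path) paste0(path, ".truth.json")

write_truth <- function(truth, path) {
  jsonlite::write_json(truth, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Generate an orbital-energy compound table
#'
#' Random compounds draw `e_homo` uniformly from `homo_range` and a strictly
#' positive gap from `gap_range`, guaranteeing `e_homo < e_lumo`. With
#' `include_reference = TRUE` the six TSCZ reference rows
#' ([tscz_orbital_fixture()]) are prepended verbatim.
#'
#' @param n_compounds number of random compounds (0 allowed).
#' @param seed integer seed; fixes the output bit-for-bit.
#' @param homo_range,gap_range eV.
#' @param include_reference prepend the TSCZ fixture rows.
#' @param path optional CSV output path (plus `.truth.json` sidecar).
#' @return data.frame `compound_id`, `e_homo_ev`, `e_lumo_ev`.
#' @export
gen_orbital_table <- function(n_compounds = 10, seed = 1,
                              homo_range = c(-7, -5), gap_range = c(1.5, 4.5),
                              include_reference = TRUE, path = NULL) {
  set.seed(seed)
  rand <- if (n_compounds > 0) {
    e_homo <- signif(stats::runif(n_compounds, homo_range[1], homo_range[2]), 6)
    gap <- signif(stats::runif(n_compounds, gap_range[1], gap_range[2]), 6)
    data.frame(compound_id = sprintf("SYN%03d", seq_len(n_compounds)),
               e_homo_ev = e_homo, e_lumo_ev = e_homo + gap,
               stringsAsFactors = FALSE)
  } else {
    data.frame(compound_id = character(), e_homo_ev = numeric(),
               e_lumo_ev = numeric(), stringsAsFactors = FALSE)
  }
  out <- if (include_reference) rbind(tscz_orbital_fixture(), rand) else rand
  if (!is.null(path)) {
    write_csv6(out, path)
    write_truth(list(seed = seed, n_compounds = n_compounds,
                     homo_range = homo_range, gap_range = gap_range,
                     include_reference = include_reference), path)
  }
  out
}

#' Generate three-state charge populations with exact Fukui sums
#'
#' Per compound, the N-state charges are drawn freely, and the one-electron
#' differences are built from Dirichlet-distributed increments (normalised
#' gamma draws), so that by construction
#' \eqn{\sum_A (q_N - q_{N+1}) = \sum_A (q_{N-1} - q_N) = 1} and hence the
#' condensed Fukui functions sum to exactly 1. Planted dual-descriptor signs
#' (`f_plus - f_minus`) are recorded as ground truth so the site classifier
#' can be validated against them.
#'
#' @param n_compounds,n_atoms counts.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration parameter (larger = more
#'   even increments).
#' @param path optional CSV output path (plus sidecar).
#' @return data.frame `compound_id`, `atom_label`, `q_n`, `q_n_plus1`,
#'   `q_n_minus1`, with attribute `truth`: a data.frame of planted per-atom
#'   dual signs.
#' @export
gen_charge_populations <- function(n_compounds = 3, n_atoms = 12, seed = 1,
                                   concentration = 1, path = NULL) {
  stopifnot(n_compounds >= 1, n_atoms >= 1)
  set.seed(seed)
  rdirichlet1 <- function(k, a) { g <- stats::rgamma(k, a); g / sum(g) }
  rows <- list(); truths <- list()
  for (ci in seq_len(n_compounds)) {
    id <- sprintf("CMP%03d", ci)
    labels <- paste0("A", seq_len(n_atoms))
    # kept at full precision so the construction's unit sums hold to ~1e-16;
    # only the text output is rounded (write_csv6)
    q_n <- stats::runif(n_atoms, -0.5, 0.5)
    f_plus <- rdirichlet1(n_atoms, concentration)
    f_minus <- rdirichlet1(n_atoms, concentration)
    rows[[ci]] <- data.frame(
      compound_id = id, atom_label = labels,
      q_n = q_n,
      q_n_plus1 = q_n - f_plus,
      q_n_minus1 = q_n + f_minus,
      stringsAsFactors = FALSE)
    truths[[ci]] <- data.frame(
      compound_id = id, atom_label = labels,
      dual_sign = sign(f_plus - f_minus),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  attr(out, "truth") <- truth
  if (!is.null(path)) {
    write_csv6(out, path)
    write_truth(list(seed = seed, n_compounds = n_compounds,
                     n_atoms = n_atoms, concentration = concentration,
                     dual_sign = truth), path)
  }
  out
}

#' Generate a harmonic-fluctuation trajectory
#'
#' Each atom oscillates about a random reference position along a fixed
#' random unit direction: \eqn{r_i(t) = r_i^0 + A_i u_i \sin(\omega_i t +
#' \phi_i)}, with per-atom angular frequencies spread over
#' `omega_range` (rad/frame) so frames sample the phase densely. The RMSF
#' of a long sampled sinusoid converges to \eqn{A_i/\sqrt 2}, giving a
#' closed-form recovery target. An optional rigid drift (translation plus
#' rotation per frame) can be superimposed to exercise alignment.
#'
#' @param n_atoms,n_frames counts (`n_frames >= 2`).
#' @param amplitudes per-atom amplitude vector (Angstrom), recycled.
#' @param seed integer seed.
#' @param omega_range rad/frame.
#' @param drift logical: superimpose a global rigid translation + rotation.
#' @param path optional multi-frame XYZ output path (plus sidecar).
#' @return a `trajectory` with attribute `truth` (list with `amplitudes`,
#'   `expected_rmsf`, `drift`).
#' @export
gen_trajectory <- function(n_atoms = 20, n_frames = 1000,
                           amplitudes = 0.5, seed = 1,
                           omega_range = c(0.5, 2.5), drift = FALSE,
                           path = NULL) {
  stopifnot(n_atoms >= 1, n_frames >= 2)
  set.seed(seed)
  amplitudes <- rep_len(amplitudes, n_atoms)
  ref <- matrix(stats::runif(n_atoms * 3, -10, 10), n_atoms, 3)
  dirs <- matrix(stats::rnorm(n_atoms * 3), n_atoms, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  omega <- stats::runif(n_atoms, omega_range[1], omega_range[2])
  phi <- stats::runif(n_atoms, 0, 2 * pi)

  drift_shift <- if (drift) matrix(stats::runif(3, -0.05, 0.05), 1) else NULL
  drift_axis <- if (drift) { a <- stats::rnorm(3); a / sqrt(sum(a^2)) } else NULL
  drift_angle <- if (drift) 0.002 else 0

  rot_about <- function(axis, theta) {
    # Rodrigues rotation matrix
    k <- axis; ct <- cos(theta); st <- sin(theta)
    kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) * ct + st * kx + (1 - ct) * tcrossprod(k)
  }

  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  for (t in seq_len(n_frames)) {
    disp <- amplitudes * sin(omega * (t - 1) + phi)
    fr <- ref + dirs * disp
    if (drift) {
      r <- rot_about(drift_axis, drift_angle * (t - 1))
      fr <- fr %*% t(r) + matrix(drift_shift * (t - 1), n_atoms, 3, byrow = TRUE)
    }
    coords[t, , ] <- signif(fr, 6)
  }
  traj <- trajectory(coords)
  truth <- list(seed = seed, amplitudes = amplitudes,
                expected_rmsf = amplitudes / sqrt(2), drift = drift)
  attr(traj, "truth") <- truth
  if (!is.null(path)) {
    write_xyz(traj, path)
    write_truth(truth, path)
  }
  traj
}

#' Generate a per-frame MM/GBSA energy-component series
#'
#' Independent Gaussian samples per component with the configured means and
#' standard deviations.
#'
#' @param n_frames count (>= 2).
#' @param means,sds named numeric vectors over `e_vdw`, `e_ele`, `g_gb`,
#'   `g_sa`, `minus_t_ds` (kcal/mol); scalars are recycled.
#' @param seed integer seed.
#' @param path optional CSV output path (plus sidecar).
#' @return data.frame of the five per-frame component columns with attribute
#'   `truth` (the configured means/sds and the implied mean total).
#' @export
gen_energy_series <- function(n_frames = 1000,
                              means = c(e_vdw = -40, e_ele = -6, g_gb = 28,
                                        g_sa = -3.5, minus_t_ds = 5),
                              sds = 1, seed = 1, path = NULL) {
  stopifnot(n_frames >= 2)
  comps <- c("e_vdw", "e_ele", "g_gb", "g_sa", "minus_t_ds")
  means <- if (is.null(names(means))) stats::setNames(rep_len(means, 5), comps)
           else means[comps]
  sds <- if (is.null(names(sds))) stats::setNames(rep_len(sds, 5), comps)
         else sds[comps]
  if (any(is.na(means)) || any(is.na(sds)))
    stop("means and sds must cover all five components")
  set.seed(seed)
  out <- as.data.frame(lapply(comps, function(k)
    signif(stats::rnorm(n_frames, means[[k]], sds[[k]]), 6)))
  names(out) <- comps
  truth <- list(seed = seed, n_frames = n_frames,
                means = as.list(means), sds = as.list(sds),
                expected_total_mean = sum(unlist(means)))
  attr(out, "truth") <- truth
  if (!is.null(path)) {
    write_csv6(out, path)
    write_truth(truth, path)
  }
  out
}
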