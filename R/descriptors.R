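#' Global conceptual-DFT reactivity descriptors
#'
#' Computes the eight standard global reactivity descriptors from frontier
#' molecular orbital (FMO) energies under the finite-difference / Koopmans
#' approximations: energy gap \eqn{\Delta E = E_{LUMO} - E_{HOMO}}, ionization
#' potential \eqn{I = -E_{HOMO}}, electron affinity \eqn{EA = -E_{LUMO}},
#' electronegativity \eqn{\chi = (I + EA)/2}, global hardness
#' \eqn{\eta = (I - EA)/2}, global softness \eqn{S = 1/\eta}, electrophilicity
#' index \eqn{\omega = \chi^2 / 2\eta} and nucleophilicity index
#' \eqn{\epsilon = 1/\omega}.
#'
#' All inputs and orbital-derived descriptors are carried in eV (softness and
#' nucleophilicity are reciprocals, numerically 1/eV); no unit conversion is
#' performed. Raw values are kept at full precision; round only for display.
#'
#' @param e_homo numeric vector of HOMO energies (eV).
#' @param e_lumo numeric vector of LUMO energies (eV), pairwise above
#'   `e_homo`.
#' @param compound_id optional vector of identifiers carried into the result.
#' @return A data.frame with one row per compound and columns `compound_id`
#'   (if given), `e_homo`, `e_lumo`, `gap`, `ionization_potential`,
#'   `electron_affinity`, `electronegativity`, `hardness`, `softness`,
#'   `electrophilicity`, `nucleophilicity`.
#'   When \eqn{\chi = 0} the electrophilicity is 0 and the nucleophilicity is
#'   undefined: it is returned as `NA` with a warning of class
#'   `silicotox_undefined_nucleophilicity`, never as a silent `Inf`.
#' @examples
#' compute_global_descriptors(e_homo = -5.844, e_lumo = -2.128)
#' @export
compute_global_descriptors <- function(e_homo, e_lumo, compound_id = NULL) {
  stopifnot(is.numeric(e_homo), is.numeric(e_lumo),
            length(e_homo) == length(e_lumo))
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo)))
    stop("orbital energies must be finite")
  gap <- e_lumo - e_homo
  if (any(gap <= 0))
    stop("invalid orbital energies: e_homo must lie below e_lumo (gap > 0)")

  ip <- -e_homo
  ea <- -e_lumo
  chi <- (ip + ea) / 2
  eta <- (ip - ea) / 2
  s <- 1 / eta
  omega <- chi^2 / (2 * eta)
  eps <- ifelse(omega > 0, 1 / omega, NA_real_)
  if (any(omega == 0)) {
    warning(structure(
      class = c("silicotox_undefined_nucleophilicity", "warning", "condition"),
      list(message = "electronegativity is zero: nucleophilicity undefined (returned as NA)",
           call = sys.call(-1))))
  }

  out <- data.frame(
    e_homo = e_homo, e_lumo = e_lumo,
    gap = gap,
    ionization_potential = ip,
    electron_affinity = ea,
    electronegativity = chi,
    hardness = eta,
    softness = s,
    electrophilicity = omega,
    nucleophilicity = eps
  )
  if (!is.null(compound_id)) out <- cbind(compound_id = compound_id, out)
  out
}

#' Condensed Fukui functions from three-state charge populations
#'
#' From per-atom charges of the N, N+1 and N-1 electron states (Hirshfeld or
#' any other population scheme), computes the condensed Fukui function for
#' nucleophilic attack \eqn{f^+_A = q^A_N - q^A_{N+1}}, for electrophilic
#' attack \eqn{f^-_A = q^A_{N-1} - q^A_N}, and the dual descriptor
#' \eqn{\Delta f = f^+ - f^-}.
#'
#' For a well-formed population set the charge differences sum to the one
#' electron added/removed, i.e. \eqn{\sum_A f^+_A = \sum_A f^-_A = 1}. Real
#' population analyses deviate slightly, so a violation beyond
#' `charge_sum_tol` raises a warning (class `silicotox_charge_sum`), not an
#' error.
#'
#' @param atom_labels character vector of site identifiers (e.g. "S", "N2").
#' @param q_n,q_n_plus1,q_n_minus1 numeric vectors of per-atom charges for the
#'   N, N+1 and N-1 electron states, aligned with `atom_labels`.
#' @param charge_sum_tol tolerance on \eqn{|\sum f^\pm - 1|} before warning
#'   (default 0.05).
#' @return A data.frame (`fukui_profile`) with columns `atom_label`, `f_plus`,
#'   `f_minus`, `dual`; columns `multiphilic` and `site_class` are added by
#'   [attach_multiphilic()] and [classify_sites()].
#' @seealso [attach_multiphilic()], [classify_sites()]
#' @export
compute_fukui <- function(atom_labels, q_n, q_n_plus1, q_n_minus1,
                          charge_sum_tol = 0.05) {
  n <- length(atom_labels)
  if (length(q_n) != n || length(q_n_plus1) != n || length(q_n_minus1) != n)
    stop("charge vectors and atom labels must have identical length")
  stopifnot(is.numeric(q_n), is.numeric(q_n_plus1), is.numeric(q_n_minus1))

  f_plus <- q_n - q_n_plus1
  f_minus <- q_n_minus1 - q_n
  sums <- c(f_plus = sum(f_plus), f_minus = sum(f_minus))
  off <- sums[abs(sums - 1) > charge_sum_tol]
  if (length(off)) {
    warning(structure(
      class = c("silicotox_charge_sum", "warning", "condition"),
      list(message = paste0(
        "charge differences do not sum to ~1 for a one-electron change: ",
        paste(sprintf("sum(%s) = %.4f", names(off), off), collapse = ", ")),
        call = sys.call(-1))))
  }

  out <- data.frame(
    atom_label = as.character(atom_labels),
    f_plus = f_plus,
    f_minus = f_minus,
    dual = f_plus - f_minus,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fukui_profile", class(out))
  out
}

#' Attach the multiphilic descriptor to a Fukui profile
#'
#' The multiphilic descriptor \eqn{\Delta\omega = \omega \cdot \Delta f}
#' scales the dual descriptor by the molecule's global electrophilicity
#' index, so that electrophilic and nucleophilic atomic centres can be
#' discriminated simultaneously on an energy-weighted scale.
#'
#' @param profile a `fukui_profile` from [compute_fukui()].
#' @param electrophilicity global electrophilicity index \eqn{\omega} (eV),
#'   strictly positive; a single row of [compute_global_descriptors()] output
#'   may be passed instead.
#' @return The profile with a `multiphilic` column added.
#' @export
attach_multiphilic <- function(profile, electrophilicity) {
  if (is.data.frame(electrophilicity)) {
    stopifnot(nrow(electrophilicity) == 1L,
              "electrophilicity" %in% names(electrophilicity))
    electrophilicity <- electrophilicity$electrophilicity
  }
  stopifnot(is.numeric(electrophilicity), length(electrophilicity) == 1L)
  if (!is.finite(electrophilicity) || electrophilicity <= 0)
    stop("electrophilicity must be strictly positive to form the multiphilic descriptor")
  if (is.null(profile$dual))
    stop("profile must carry the dual descriptor; run compute_fukui() first")
  profile$multiphilic <- electrophilicity * profile$dual
  profile
}

#' Classify reactive sites from the dual and multiphilic descriptors
#'
#' Joint sign rule: a site is electrophilic when both \eqn{\Delta f} and
#' \eqn{\Delta\omega} are positive, nucleophilic when both are negative.
#' A symmetric dead zone of width `tol` around zero absorbs numerical noise:
#' sites with \eqn{|\Delta f| \le tol} or \eqn{|\Delta\omega| \le tol} are
#' reported as neutral.
#'
#' @param profile a `fukui_profile` carrying `dual` and `multiphilic`.
#' @param tol half-width of the neutral dead zone (default 1e-6).
#' @return The profile with a `site_class` factor column with levels
#'   `electrophilic`, `nucleophilic`, `neutral`.
#' @export
classify_sites <- function(profile, tol = 1e-6) {
  if (is.null(profile$dual) || is.null(profile$multiphilic))
    stop("profile must carry dual and multiphilic descriptors")
  stopifnot(is.numeric(tol), tol >= 0)
  cls <- rep("neutral", nrow(profile))
  cls[profile$dual > tol & profile$multiphilic > tol] <- "electrophilic"
  cls[profile$dual < -tol & profile$multiphilic < -tol] <- "nucleophilic"
  profile$site_class <- factor(cls,
    levels = c("electrophilic", "nucleophilic", "neutral"))
  profile
}

#' Read an orbital-energy table
#'
#' Expects columns `compound_id`, `e_homo_ev`, `e_lumo_ev`.
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_orbital_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "e_homo_ev", "e_lumo_ev")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("orbital table missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Read a three-state charge-population table
#'
#' Expects columns `compound_id`, `atom_label`, `q_n`, `q_n_plus1`,
#' `q_n_minus1`; one row per atom.
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_charge_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "atom_label", "q_n", "q_n_plus1", "q_n_minus1")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("charge table missing columns: ", paste(miss, collapse = ", "))
  df
}
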