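#' Run the full in silico assessment chain
#'
#' Orchestrates the stages -- global reactivity descriptors, Fukui site
#' classification, aquatic toxicity estimation with flags, CNS MPO scoring,
#' conformer similarity and trajectory/energy post-processing -- into one
#' per-compound assessment report. Stages whose inputs are absent from the
#' configuration are reported as skipped, not errors, so partial runs are
#' first-class. Reruns on identical configuration and seed produce
#' byte-identical outputs (no timestamps are written; all numeric output is
#' rounded to 6 significant figures).
#'
#' @param config a named list or path to a YAML file. Recognised keys:
#'   `seed`; input paths `orbital_csv`, `charge_csv`, `physchem_csv`,
#'   `conformer_csv`, `trajectory_xyz`, `energy_csv`; config paths
#'   `qsar_coefficients`, `mpo_specs`; `align_rmsd` (logical, default TRUE);
#'   `site_tol`. Alternatively `synthetic: true` with generator settings
#'   `n_compounds`, `n_atoms`, `n_frames` generates the inputs in `out_dir`.
#' @param out_dir output directory (created if missing); reports are written
#'   as `report.json`, one CSV per stage, and `summary.md`.
#' @param seed overrides `config$seed`.
#' @return the report (named list), invisibly; written to `out_dir`.
#' @export
run_assessment <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  if (!is.list(config)) stop("malformed config: expected a key-value mapping")
  known <- c("seed", "orbital_csv", "charge_csv", "physchem_csv",
             "conformer_csv", "trajectory_xyz", "energy_csv",
             "qsar_coefficients", "mpo_specs", "align_rmsd", "site_tol",
             "synthetic", "n_compounds", "n_atoms", "n_frames")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("malformed config: unknown key(s) ", paste(bad, collapse = ", "))
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(config$synthetic)) {
    config$orbital_csv <- file.path(out_dir, "synthetic_orbitals.csv")
    config$charge_csv <- file.path(out_dir, "synthetic_charges.csv")
    config$trajectory_xyz <- file.path(out_dir, "synthetic_trajectory.xyz")
    config$energy_csv <- file.path(out_dir, "synthetic_energies.csv")
    gen_orbital_table(config$n_compounds %||% 4, seed = seed,
                      path = config$orbital_csv)
    gen_charge_populations(config$n_compounds %||% 4,
                           config$n_atoms %||% 12, seed = seed,
                           path = config$charge_csv)
    gen_trajectory(config$n_atoms %||% 12, config$n_frames %||% 500,
                   seed = seed, path = config$trajectory_xyz)
    gen_energy_series(config$n_frames %||% 500, seed = seed,
                      path = config$energy_csv)
  }

  report <- list(
    metadata = list(package_version = as.character(utils::packageVersion("silicotox")),
                    config_hash = config_hash, seed = seed),
    thresholds = list(
      acute_class_bounds_mg_l = c(1, 10, 100),
      chronic_class_bounds_mg_l = c(0.1, 1, 10),
      hbond_cutoff_angstrom = 3.5,
      hbond_min_occupancy_pct = 2,
      lipophilic_log_kow = 3,
      fish_daphnia_domain_log_kow = 5.0,
      bioaccumulation_bcf_l_kg = 5000,
      site_class_tol = config$site_tol %||% 1e-6
    ),
    stages = list()
  )
  skipped <- function(what) list(status = "skipped", reason = paste("missing input:", what))

  # -- global descriptors ----------------------------------------------------
  if (!is.null(config$orbital_csv)) {
    orb <- read_orbital_table(config$orbital_csv)
    desc <- compute_global_descriptors(orb$e_homo_ev, orb$e_lumo_ev,
                                       compound_id = orb$compound_id)
    write_csv6(desc, file.path(out_dir, "global_descriptors.csv"))
    report$stages$descriptors <- list(
      status = "ok", n_compounds = nrow(desc),
      softness = stats::setNames(signif(desc$softness, 6), desc$compound_id))
  } else {
    desc <- NULL
    report$stages$descriptors <- skipped("orbital_csv")
  }

  # -- Fukui site classification --------------------------------------------
  if (!is.null(config$charge_csv) && !is.null(desc)) {
    chg <- read_charge_table(config$charge_csv)
    profs <- lapply(split(chg, chg$compound_id), function(sub) {
      p <- compute_fukui(sub$atom_label, sub$q_n, sub$q_n_plus1, sub$q_n_minus1)
      drow <- desc[match(sub$compound_id[1], desc$compound_id), ]
      if (!is.na(drow$electrophilicity) && drow$electrophilicity > 0)
        p <- classify_sites(attach_multiphilic(p, drow$electrophilicity),
                            tol = config$site_tol %||% 1e-6)
      cbind(compound_id = sub$compound_id[1], p)
    })
    sites <- do.call(rbind, c(profs, make.row.names = FALSE))
    write_csv6(sites, file.path(out_dir, "fukui_sites.csv"))
    report$stages$fukui <- list(
      status = "ok", n_atoms = nrow(sites),
      site_class_counts = as.list(table(sites$site_class)))
  } else {
    report$stages$fukui <- skipped("charge_csv (and orbital_csv)")
  }

  # -- ecotoxicity -----------------------------------------------------------
  if (!is.null(config$physchem_csv)) {
    phys <- utils::read.csv(config$physchem_csv, stringsAsFactors = FALSE)
    for (cn in intersect(c("log_kow", "solubility", "molecular_weight"), names(phys)))
      phys[[cn]] <- as.numeric(phys[[cn]])
    if (nrow(phys) == 0)
      warning("empty compound table: ecotox report will be empty")
    coeffs <- read_qsar_coefficients(config$qsar_coefficients %||%
      system.file("extdata", "qsar_coefficients.yaml", package = "silicotox"))
    tox <- do.call(rbind, lapply(seq_len(nrow(phys)), function(i) {
      row <- phys[i, ]
      est <- do.call(rbind, lapply(coeffs, function(cf)
        predict_lc50(row$log_kow, row$molecular_weight, cf,
                     solubility = row$solubility %||% NA_real_)))
      cbind(compound_id = row$compound_id, est, row.names = NULL)
    }))
    if (is.null(tox))
      tox <- data.frame(compound_id = character(), endpoint_id = character(),
                        lc50_mmol_l = numeric(), concentration_mg_l = numeric(),
                        tox_class = character(), exceeds_solubility = logical(),
                        outside_kow_domain = logical())
    flags <- lipophilicity_flags(phys$log_kow)
    flags <- cbind(compound_id = phys$compound_id, flags,
                   hc5_umol_l = hc5(phys$log_kow))
    write_csv6(tox, file.path(out_dir, "toxicity_estimates.csv"))
    write_csv6(flags, file.path(out_dir, "ecotox_flags.csv"))
    report$stages$ecotox <- list(
      status = "ok", n_compounds = nrow(phys),
      n_endpoints = length(coeffs),
      class_counts = as.list(table(tox$tox_class)))
  } else {
    report$stages$ecotox <- skipped("physchem_csv")
  }

  # -- CNS MPO ---------------------------------------------------------------
  mpo_cols <- c("log_kow", "log_d", "tpsa", "pka", "molecular_weight", "hbd_count")
  if (!is.null(config$physchem_csv) &&
      all(mpo_cols %in% names(utils::read.csv(config$physchem_csv, nrows = 1)))) {
    phys <- utils::read.csv(config$physchem_csv, stringsAsFactors = FALSE)
    specs <- if (!is.null(config$mpo_specs)) read_mpo_specs(config$mpo_specs)
             else default_mpo_specs()
    mpo <- score_cns_mpo_table(phys, specs)
    write_csv6(mpo, file.path(out_dir, "cns_mpo.csv"))
    report$stages$cns_mpo <- list(
      status = "ok",
      totals = stats::setNames(round(mpo$mpo_total, 3), mpo$compound_id))
  } else {
    report$stages$cns_mpo <- skipped("physchem_csv with the six MPO columns")
  }

  # -- conformer similarity --------------------------------------------------
  if (!is.null(config$conformer_csv)) {
    sets <- read_conformer_csv(config$conformer_csv)
    dmat <- conformer_distance_matrix(sets)
    utils::write.csv(signif(dmat, 6), file.path(out_dir, "similarity_matrix.csv"))
    report$stages$similarity <- list(status = "ok", n_molecules = length(sets))
  } else {
    report$stages$similarity <- skipped("conformer_csv")
  }

  # -- trajectory metrics ----------------------------------------------------
  if (!is.null(config$trajectory_xyz)) {
    traj <- read_xyz(config$trajectory_xyz)
    align <- config$align_rmsd %||% TRUE
    rs <- rmsd_series(traj, align = align)
    rf <- rmsf(traj)
    write_csv6(rs, file.path(out_dir, "rmsd.csv"))
    write_csv6(rf, file.path(out_dir, "rmsf.csv"))
    report$stages$trajectory <- list(
      status = "ok", n_frames = dim(traj$coords)[1],
      n_atoms = dim(traj$coords)[2], align = align,
      rmsd_final = signif(rs$rmsd[nrow(rs)], 6),
      rmsf_mean = signif(mean(rf$rmsf), 6))
  } else {
    report$stages$trajectory <- skipped("trajectory_xyz")
  }

  # -- MM/GBSA totals --------------------------------------------------------
  if (!is.null(config$energy_csv)) {
    en <- read_energy_series(config$energy_csv)
    tot <- mmgbsa_total(en$e_vdw, en$e_ele, en$g_gb, en$g_sa, en$minus_t_ds)
    report$stages$mmgbsa <- list(
      status = "ok", n_frames = nrow(en),
      dg_bind_mean = signif(tot$mean, 6),
      dg_bind_sd = signif(tot$sd, 6),
      term_means = as.list(signif(tot$term_means, 6)))
  } else {
    report$stages$mmgbsa <- skipped("energy_csv")
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_summary_md(report, file.path(out_dir, "summary.md"))
  invisible(report)
}

#' Read a conformer descriptor-vector CSV
#'
#' Columns: `molecule_id`, `conformer` (stability rank, 1 = most stable),
#' then one numeric column per descriptor component.
#'
#' @param path CSV file.
#' @return list of [conformer_vectors()] objects.
#' @export
read_conformer_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "conformer")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("conformer CSV missing columns: ", paste(miss, collapse = ", "))
  comp <- setdiff(names(df), need)
  if (!length(comp)) stop("conformer CSV has no descriptor columns")
  lapply(split(df, df$molecule_id), function(sub) {
    sub <- sub[order(sub$conformer), ]
    conformer_vectors(sub$molecule_id[1], as.matrix(sub[, comp, drop = FALSE]))
  })
}

write_summary_md <- function(report, path) {
  ln <- c(
    "# Assessment summary",
    "",
    sprintf("- package: silicotox %s", report$metadata$package_version),
    sprintf("- seed: %s | config hash: %s",
            report$metadata$seed, report$metadata$config_hash),
    "",
    "## Stages")
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    ln <- c(ln, sprintf("- **%s**: %s%s", nm, st$status,
                        if (st$status == "skipped") paste0(" (", st$reason, ")") else ""))
  }
  ln <- c(ln, "", "## Applied thresholds",
          vapply(names(report$thresholds), function(k)
            sprintf("- %s: %s", k,
                    paste(report$thresholds[[k]], collapse = ", ")),
            character(1)))
  writeLines(ln, path)
  invisible(path)
}
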