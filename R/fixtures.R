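# Fixture tables transcribing values printed in the source study of six
# (thio)semicarbazone insecticide candidates (TSCZ1-6). Only literally
# printed values are transcribed; quantities the study reports solely in its
# supplement are not invented here. Attribute sets that had to be
# constructed (CNS MPO physchem) are clearly labelled synthetic.

#' Frontier orbital energies of the TSCZ1-6 reference set
#'
#' HOMO/LUMO energies (eV, B3LYP/6-311++G(d,p) in implicit water) for the six
#' reference (thio)semicarbazones: TSCZ1-3 are furan-bearing
#' thiosemicarbazones, TSCZ4-6 thiophene-bearing semicarbazones, each
#' para-substituted with F, Cl or Br.
#'
#' @return data.frame with columns `compound_id`, `e_homo_ev`, `e_lumo_ev`.
#' @export
tscz_orbital_fixture <- function() {
  data.frame(
    compound_id = paste0("TSCZ", 1:6),
    e_homo_ev = c(-5.860, -5.866, -5.867, -5.844, -5.850, -5.851),
    e_lumo_ev = c(-2.224, -2.232, -2.233, -2.128, -2.136, -2.137),
    stringsAsFactors = FALSE
  )
}

#' MM/GBSA energy-component tables for the cholinesterase complexes
#'
#' Per-complex mean energy components (kcal/mol) of the MM/GBSA
#' decomposition for the acetylcholinesterase (AChE) complexes with
#' galantamine (GNT), TSCZ4 and TSCZ1, and the butyrylcholinesterase (BChE)
#' complexes with the 8U2 inhibitor, TSCZ4 and TSCZ6. The `minus_t_ds`
#' column stores \eqn{-T\Delta S} directly (positive as reported). The
#' printed binding totals are carried in `dg_bind_printed` with their
#' standard deviations for comparison against [mmgbsa_total()].
#'
#' @return data.frame with one row per complex.
#' @export
mmgbsa_table_fixture <- function() {
  data.frame(
    complex = c("GNT-AChE", "TSCZ4-AChE", "TSCZ1-AChE",
                "8U2-BChE", "TSCZ4-BChE", "TSCZ6-BChE"),
    e_vdw = c(-41.56, -43.94, -44.79, -35.56, -31.56, -32.93),
    e_ele = c(-5.65, -5.33, -5.97, -8.43, -6.43, -7.19),
    g_gb = c(28.60, 29.15, 29.82, 19.93, 16.66, 18.04),
    g_sa = c(-3.11, -4.01, -3.53, -7.45, -4.45, -5.67),
    minus_t_ds = c(4.83, 6.32, 5.83, 5.24, 6.24, 4.89),
    dg_bind_printed = c(-16.89, -17.81, -18.64, -26.27, -19.54, -22.86),
    dg_bind_sd_printed = c(2.16, 2.59, 2.32, 3.89, 2.73, 3.02),
    stringsAsFactors = FALSE
  )
}

#' Reported aquatic toxicity concentrations for the reference set
#'
#' Selected acute LC50/EC50 and chronic (ChV) concentrations (mg/L) reported
#' for the TSCZ set across fish, Daphnia magna and green algae endpoints,
#' used to exercise the toxicity classifier against its reported classes.
#'
#' @return data.frame with columns `compound_id`, `endpoint`, `chronic`,
#'   `concentration`, `reported_class`.
#' @export
tscz_toxicity_fixture <- function() {
  data.frame(
    compound_id = c("TSCZ4", "TSCZ5", "TSCZ4",
                    "TSCZ1", "TSCZ6", "TSCZ2", "TSCZ3",
                    "TSCZ3", "TSCZ2", "TSCZ6"),
    endpoint = c("fish_96h", "fish_96h", "daphnia_48h",
                 "fish_96h", "fish_96h", "algae_96h", "algae_96h",
                 "daphnia_chv", "daphnia_chv", "fish_chv"),
    chronic = c(FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE),
    concentration = c(2.511, 1.059, 1.747,
                      0.263, 0.903, 0.713, 0.553,
                      0.047, 0.063, 0.098),
    reported_class = c("toxic", "toxic", "toxic",
                       "very_toxic", "very_toxic", "very_toxic", "very_toxic",
                       "very_toxic", "very_toxic", "very_toxic"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic CNS MPO attribute table for the reference set
#'
#' The source study reports a CNS MPO score band of 4.05-4.71 for the six
#' reference compounds but not the underlying attribute values. This fixture
#' is a SYNTHETIC stand-in constructed once from typical halogenated
#' (thio)semicarbazone physicochemistry: log Kow inside the reported
#' 4.2-5.385 range, thiosemicarbazone/semicarbazone-typical TPSA, MW, logD,
#' pKa and two H-bond donors. Only set-level (band) properties are
#' meaningful; no per-compound score claim is made.
#'
#' @return data.frame with columns `compound_id`, `log_kow`, `log_d`,
#'   `tpsa`, `pka`, `molecular_weight`, `hbd_count`.
#' @export
tscz_mpo_fixture_synthetic <- function() {
  data.frame(
    compound_id = paste0("TSCZ", 1:6),
    log_kow = c(4.20, 4.75, 5.385, 4.30, 4.80, 5.30),
    log_d = c(2.6, 2.6, 2.8, 2.7, 2.5, 2.7),
    tpsa = c(75, 75, 75, 70, 70, 70),
    pka = c(7.6, 7.5, 7.4, 7.8, 7.7, 7.6),
    molecular_weight = c(289.3, 305.8, 350.2, 305.4, 321.8, 366.3),
    hbd_count = c(2L, 2L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}
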