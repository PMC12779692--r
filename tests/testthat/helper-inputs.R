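# Builds a complete on-disk input set for pipeline tests: the reference
# orbital table, a seeded synthetic charge table, the synthetic physchem/MPO
# attribute table, a small conformer table, trajectory and energy series.
write_pipeline_inputs <- function(dir, seed = 1) {
  orbital_csv <- file.path(dir, "orbitals.csv")
  write.csv(tscz_orbital_fixture(), orbital_csv, row.names = FALSE, quote = FALSE)

  charge_csv <- file.path(dir, "charges.csv")
  gen_charge_populations(2, 10, seed = seed, path = charge_csv)

  phys <- tscz_mpo_fixture_synthetic()
  phys$solubility <- c(1.2, 0.8, 0.3, 1.5, 0.9, 0.4)  # mg/L, low-solubility lipophiles
  physchem_csv <- file.path(dir, "physchem.csv")
  write.csv(phys, physchem_csv, row.names = FALSE, quote = FALSE)

  set.seed(seed)
  conf <- do.call(rbind, lapply(c("M1", "M2", "M3"), function(id)
    data.frame(molecule_id = id, conformer = 1:4,
               matrix(signif(rnorm(4 * 6), 6), 4, 6,
                      dimnames = list(NULL, paste0("v", 1:6))))))
  conformer_csv <- file.path(dir, "conformers.csv")
  write.csv(conf, conformer_csv, row.names = FALSE, quote = FALSE)

  trajectory_xyz <- file.path(dir, "traj.xyz")
  gen_trajectory(8, 40, amplitudes = 0.4, seed = seed, path = trajectory_xyz)

  energy_csv <- file.path(dir, "energy.csv")
  gen_energy_series(60, seed = seed, path = energy_csv)

  list(orbital_csv = orbital_csv, charge_csv = charge_csv,
       physchem_csv = physchem_csv, conformer_csv = conformer_csv,
       trajectory_xyz = trajectory_xyz, energy_csv = energy_csv,
       seed = seed)
}
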