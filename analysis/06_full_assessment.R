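#!/usr/bin/env Rscript
# One-shot orchestrated run: generates every synthetic input and the
# reference tables into results/06_inputs, executes all stages, and writes
# the per-compound assessment report (JSON + CSVs + Markdown summary).
# Rerunning this script reproduces the outputs byte-for-byte.

library(silicotox)

in_dir <- "results/06_inputs"
out_dir <- "results/06_assessment"
dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)

write.csv(tscz_orbital_fixture(), file.path(in_dir, "orbitals.csv"),
          row.names = FALSE, quote = FALSE)
gen_charge_populations(2, 10, seed = 1, path = file.path(in_dir, "charges.csv"))
phys <- tscz_mpo_fixture_synthetic()
phys$solubility <- c(1.2, 0.8, 0.3, 1.5, 0.9, 0.4)
write.csv(phys, file.path(in_dir, "physchem.csv"), row.names = FALSE, quote = FALSE)
gen_trajectory(8, 200, amplitudes = 0.4, seed = 1,
               path = file.path(in_dir, "traj.xyz"))
gen_energy_series(500, seed = 1, path = file.path(in_dir, "energy.csv"))

cfg <- list(
  seed = 1,
  orbital_csv = file.path(in_dir, "orbitals.csv"),
  charge_csv = file.path(in_dir, "charges.csv"),
  physchem_csv = file.path(in_dir, "physchem.csv"),
  trajectory_xyz = file.path(in_dir, "traj.xyz"),
  energy_csv = file.path(in_dir, "energy.csv")
)
rep <- run_assessment(cfg, out_dir)

cat("Stages:\n")
for (nm in names(rep$stages))
  cat(sprintf("  %-12s %s\n", nm, rep$stages[[nm]]$status))
cat("\nSoftness by compound:\n")
print(round(unlist(rep$stages$descriptors$softness), 3))
cat("\nReport written to", out_dir, "\n")
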