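#!/usr/bin/env Rscript
# Manhattan conformer-similarity matrix on a seeded synthetic descriptor set.
#
# Each molecule is an ordered stack of 18-component conformer descriptor
# vectors; the molecule-level distance is the best rank-aligned conformer
# match (minimum Manhattan distance).

library(silicotox)
dir.create("results", showWarnings = FALSE)

set.seed(42)
base <- matrix(rnorm(18 * 6), 6, 18)
sets <- lapply(paste0("TSCZ", 1:6), function(id) {
  # siblings share a backbone vector with small conformer perturbations
  conformer_vectors(id, base[as.integer(substring(id, 5)), ][rep(1, 5)] |>
    matrix(5, 18, byrow = TRUE) + matrix(rnorm(5 * 18, sd = 0.1), 5, 18))
})
m <- conformer_distance_matrix(sets)
write.csv(signif(m, 5), "results/04_similarity_matrix.csv")
cat("Symmetric:", isTRUE(all.equal(m, t(m))), "| zero diagonal:",
    all(diag(m) == 0), "\n")
closest <- which(m == min(m[m > 0]), arr.ind = TRUE)[1, ]
cat("Closest pair:", rownames(m)[closest[1]], "-", colnames(m)[closest[2]],
    sprintf("(d = %.3f)\n", min(m[m > 0])))
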