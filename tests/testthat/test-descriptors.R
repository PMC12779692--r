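test_that("global descriptors follow the closed-form definitions on round numbers", {
  d <- compute_global_descriptors(e_homo = -2, e_lumo = 0)
  expect_equal(d$gap, 2)
  expect_equal(d$ionization_potential, 2)
  expect_equal(d$electron_affinity, 0)
  expect_equal(d$electronegativity, 1)
  expect_equal(d$hardness, 1)
  expect_equal(d$softness, 1)
  expect_equal(d$electrophilicity, 0.5)
  expect_equal(d$nucleophilicity, 2)
})

test_that("reference orbital energies reproduce the reported group softness values", {
  fix <- tscz_orbital_fixture()
  d <- compute_global_descriptors(fix$e_homo_ev, fix$e_lumo_ev,
                                  compound_id = fix$compound_id)
  # agreement to the printed precision (one unit in the third decimal); the
  # reported values are truncations of the full-precision reciprocals
  expect_true(all(abs(d$softness[1:3] - 0.550) < 1e-3))
  expect_true(all(abs(d$softness[4:6] - 0.538) < 1e-3))
})

test_that("hardness ranking of the reference set matches the reported order", {
  fix <- tscz_orbital_fixture()
  d <- compute_global_descriptors(fix$e_homo_ev, fix$e_lumo_ev,
                                  compound_id = fix$compound_id)
  eta <- round(d$hardness, 3)
  names(eta) <- d$compound_id
  # TSCZ3 = TSCZ2 < TSCZ1 < TSCZ6 = TSCZ5 < TSCZ4 (ties at 3 d.p.)
  expect_equal(eta[["TSCZ3"]], eta[["TSCZ2"]])
  expect_lt(eta[["TSCZ2"]], eta[["TSCZ1"]])
  expect_lt(eta[["TSCZ1"]], eta[["TSCZ6"]])
  expect_equal(eta[["TSCZ6"]], eta[["TSCZ5"]])
  expect_lt(eta[["TSCZ5"]], eta[["TSCZ4"]])
})

test_that("reciprocal and gap identities hold to machine precision on random orbitals", {
  set.seed(11)
  e_homo <- runif(50, -9, -3)
  e_lumo <- e_homo + runif(50, 0.5, 5)
  d <- compute_global_descriptors(e_homo, e_lumo)
  expect_equal(d$softness * d$hardness, rep(1, 50), tolerance = 1e-12)
  expect_equal(d$electrophilicity * d$nucleophilicity, rep(1, 50),
               tolerance = 1e-12)
  expect_equal(d$gap, 2 * d$hardness, tolerance = 1e-12)
  expect_equal(d$ionization_potential, -e_homo)
  expect_equal(d$electron_affinity, -e_lumo)
})

test_that("degenerate orbital inputs are rejected or signalled", {
  expect_error(compute_global_descriptors(-2, -2), "gap")
  expect_error(compute_global_descriptors(-1, -3), "gap")
  # symmetric orbitals give zero electronegativity: nucleophilicity undefined
  expect_warning(d <- compute_global_descriptors(-1, 1),
                 class = "silicotox_undefined_nucleophilicity")
  expect_true(is.na(d$nucleophilicity))
  expect_equal(d$electrophilicity, 0)
})

test_that("condensed Fukui functions match direct per-atom differences", {
  p <- compute_fukui("X", q_n = 0.1, q_n_plus1 = 0.1, q_n_minus1 = 0.1,
                     charge_sum_tol = Inf)
  expect_equal(p$f_plus, 0)
  expect_equal(p$f_minus, 0)
  expect_equal(p$dual, 0)

  p2 <- compute_fukui("Y", q_n = 0.0, q_n_plus1 = -0.4, q_n_minus1 = 0.3,
                      charge_sum_tol = Inf)
  expect_equal(p2$f_plus, 0.4)
  expect_equal(p2$f_minus, 0.3)
  expect_equal(p2$dual, 0.1)

  # brute-force element-wise oracle on a random 3-atom system
  set.seed(7)
  qn <- rnorm(3); qp <- rnorm(3); qm <- rnorm(3)
  p3 <- suppressWarnings(compute_fukui(c("a", "b", "c"), qn, qp, qm))
  for (i in 1:3) {
    expect_equal(p3$f_plus[i], qn[i] - qp[i])
    expect_equal(p3$f_minus[i], qm[i] - qn[i])
    expect_equal(p3$dual[i], p3$f_plus[i] - p3$f_minus[i])
  }
})

test_that("misaligned charge vectors and abnormal sums are flagged", {
  expect_error(compute_fukui(c("a", "b"), 1, c(1, 2), c(1, 2)), "length")
  expect_warning(compute_fukui("a", 0.5, 0.1, 0.6),
                 class = "silicotox_charge_sum")
})

test_that("multiphilic descriptor scales the dual by the electrophilicity", {
  p <- suppressWarnings(compute_fukui(c("a", "b"), c(0.2, 0), c(0.1, -0.1),
                                      c(0.25, 0.05)))
  p1 <- attach_multiphilic(p, 0.5)
  expect_equal(p1$multiphilic, 0.5 * p1$dual)
  expect_equal(attach_multiphilic(data.frame(dual = 0), 2)$multiphilic, 0)
  expect_equal(attach_multiphilic(data.frame(dual = 0.1), 0.5)$multiphilic, 0.05)

  set.seed(3)
  dual <- rnorm(20); omega <- runif(1, 0.1, 3)
  prof <- data.frame(dual = dual)
  expect_equal(attach_multiphilic(prof, omega)$multiphilic, omega * dual)

  expect_error(attach_multiphilic(prof, 0), "positive")
  expect_error(attach_multiphilic(prof, -1), "positive")
})

test_that("site classification agrees with the 9-case sign truth table", {
  v <- c(-0.1, 0, 0.1)
  grid <- expand.grid(dual = v, multiphilic = v)
  out <- classify_sites(grid, tol = 1e-6)
  expected <- with(grid, ifelse(dual > 0 & multiphilic > 0, "electrophilic",
                         ifelse(dual < 0 & multiphilic < 0, "nucleophilic",
                                "neutral")))
  expect_equal(as.character(out$site_class), expected)
})

test_that("site classification honours the dead zone and sign coherence", {
  p <- data.frame(dual = c(0.1, -0.1, 0, 5e-7),
                  multiphilic = c(0.05, -0.05, 0, 2.5e-7))
  out <- classify_sites(p, tol = 1e-6)
  expect_equal(as.character(out$site_class),
               c("electrophilic", "nucleophilic", "neutral", "neutral"))
  # sign(multiphilic) = sign(dual) whenever omega > 0, so joint rule reduces
  # to the dual sign for any attach_multiphilic() output
  set.seed(5)
  prof <- data.frame(dual = rnorm(50))
  prof <- classify_sites(attach_multiphilic(prof, 1.7), tol = 0)
  expect_equal(as.character(prof$site_class),
               ifelse(prof$dual > 0, "electrophilic",
                      ifelse(prof$dual < 0, "nucleophilic", "neutral")))
})
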