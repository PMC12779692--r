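make_traj <- function(frames) trajectory(frames)

rand_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("RMSD is zero on identical frames and exact on pure translation", {
  set.seed(41)
  f1 <- matrix(runif(30, -5, 5), 10, 3)
  tr <- make_traj(list(f1, f1, sweep(f1, 2, c(3, 4, 0), `+`)))
  expect_equal(rmsd(tr, 2), 0)
  expect_equal(rmsd(tr, 3, align = FALSE), 5.0)
  expect_lt(rmsd(tr, 3, align = TRUE), 1e-9)
  expect_error(rmsd(tr, 9), "range")
})

test_that("aligned RMSD is invariant under rigid motion and never exceeds unaligned", {
  set.seed(43)
  for (i in 1:10) {
    f1 <- matrix(rnorm(36), 12, 3)
    f2 <- f1 + matrix(rnorm(36, sd = 0.3), 12, 3)
    r <- rand_rotation(); shift <- runif(3, -4, 4)
    f2_moved <- sweep(f2 %*% t(r), 2, shift, `+`)
    tr <- make_traj(list(f1, f2, f2_moved))
    expect_equal(rmsd(tr, 3, align = TRUE), rmsd(tr, 2, align = TRUE),
                 tolerance = 1e-9)
    expect_gte(rmsd(tr, 2, align = FALSE), rmsd(tr, 2, align = TRUE) - 1e-12)
  }
})

test_that("RMSD and superposition agree with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(47)
  f1 <- matrix(rnorm(30), 10, 3)
  f2 <- f1 + matrix(rnorm(30, sd = 0.5), 10, 3)
  tr <- make_traj(list(f1, f2))
  a <- as.vector(t(f1)); b <- as.vector(t(f2))
  # the reference implementation reports RMSD rounded to 3 decimals
  expect_lt(abs(rmsd(tr, 2, align = FALSE) -
                as.numeric(bio3d::rmsd(a, b, fit = FALSE))), 5.1e-4)
  expect_lt(abs(rmsd(tr, 2, align = TRUE) -
                as.numeric(bio3d::rmsd(a, b, fit = TRUE))), 5.1e-4)
})

test_that("RMSF is zero for static atoms and exact for two-point alternation", {
  f <- matrix(runif(15), 5, 3)
  static <- make_traj(list(f, f, f, f))
  expect_equal(rmsf(static)$rmsf, rep(0, 5))

  a <- 0.7
  up <- f; up[2, 1] <- f[2, 1] + a
  dn <- f; dn[2, 1] <- f[2, 1] - a
  alt <- make_traj(list(up, dn, up, dn))
  out <- rmsf(alt)
  expect_equal(out$rmsf[2], a)
  expect_equal(out$rmsf[-2], rep(0, 4))
  expect_error(rmsf(make_traj(list(f))), "2 frames")
})

test_that("hydrogen-bond occupancy counts frames within the cutoff", {
  expect_equal(hbond_occupancy(c(rep(3.0, 100), rep(4.0, 100))), 50)
  expect_equal(hbond_occupancy(rep(2.5, 30)), 100)
  set.seed(53)
  d <- runif(500, 2, 5)
  n_in <- 0
  for (x in d) if (x <= 3.5) n_in <- n_in + 1
  expect_equal(hbond_occupancy(d), 100 * n_in / 500)
  expect_error(hbond_occupancy(numeric(0)), "empty")
})

test_that("the occupancy report drops pairs under the reporting floor", {
  series <- list(
    strong = rep(3.0, 100),
    weak = c(rep(3.0, 1), rep(4.0, 99)),   # 1% < 2% floor
    half = c(rep(3.4, 50), rep(3.6, 50))
  )
  rep_ <- hbond_occupancy_report(series)
  expect_equal(rep_$pair, c("strong", "half"))
  expect_equal(rep_$occupancy_pct, c(100, 50))
})

test_that("MM/GBSA totals reproduce all reported table decompositions to 0.01 kcal/mol", {
  tab <- mmgbsa_table_fixture()
  for (i in seq_len(nrow(tab))) {
    got <- mmgbsa_total(tab$e_vdw[i], tab$e_ele[i], tab$g_gb[i],
                        tab$g_sa[i], tab$minus_t_ds[i])
    expect_equal(got$mean, tab$dg_bind_printed[i], tolerance = 0.01)
    expect_true(is.na(got$sd))  # table input: exact sum, no spread
  }
  expect_equal(mmgbsa_total(0, 0, 0, 0, 0)$mean, 0)
})

test_that("per-term means decompose the mean total on per-frame series", {
  set.seed(59)
  n <- 200
  en <- list(e_vdw = rnorm(n, -40), e_ele = rnorm(n, -6),
             g_gb = rnorm(n, 28), g_sa = rnorm(n, -3.5))
  got <- mmgbsa_total(en$e_vdw, en$e_ele, en$g_gb, en$g_sa, minus_t_ds = 5)
  expect_equal(sum(got$term_means), got$mean, tolerance = 1e-9)
  expect_equal(got$term_means[["minus_t_ds"]], 5)  # scalar recycled
  expect_false(is.na(got$sd))
  expect_error(mmgbsa_total(1:3, 1:2, 1:3, 1:3, 0), "length")
})

test_that("multi-frame XYZ files round-trip through write and read", {
  set.seed(61)
  tr <- make_traj(list(matrix(signif(runif(12), 6), 4, 3),
                       matrix(signif(runif(12), 6), 4, 3)))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, path)
  back <- read_xyz(path)
  expect_equal(dim(back$coords), dim(tr$coords))
  expect_equal(back$coords, tr$coords, tolerance = 1e-5)
  expect_error(read_xyz(withr::local_tempfile(lines = "nonsense")), "malformed")
})

test_that("long-format trajectory CSVs load with atoms kept in frame order", {
  df <- expand.grid(atom = c("CA1", "CA2"), frame = 1:3)
  df$x <- as.numeric(seq_len(nrow(df))); df$y <- 0; df$z <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, c("frame", "atom", "x", "y", "z")], path, row.names = FALSE)
  tr <- read_trajectory_csv(path)
  expect_equal(dim(tr$coords), c(3, 2, 3))
  expect_equal(tr$atom_labels, c("CA1", "CA2"))
  expect_equal(tr$coords[2, 1, 1], 3)
})
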