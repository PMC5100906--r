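test_that("RMSD series vanish for constant or rigidly rotated trajectories", {
  h <- build_ideal_helix(10)
  ref <- as.vector(t(structure_xyz(h)))
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- as.vector(t(sweep(structure_xyz(h) %*% t(R), 2, c(1, 0, -2), `+`)))
  tr <- md_traj(h$atoms, rbind(ref, ref, rot))
  rs <- rmsd_series(tr, h, sel_calpha())
  expect_equal(rs, rep(0, 3), tolerance = 1e-9)

  jt <- jittered_trajectory(h, sigma = 0.05, n_frames = 5, seed = 3)
  got <- rmsd_series(jt, h, sel_backbone(), sel_calpha())
  want <- vapply(seq_len(5), function(f)
    oracle_rmsd_after_fit(traj_frame(jt, f), h, sel_backbone(), sel_calpha()),
    numeric(1))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("RMSF is zero for static input and sqrt(3) sigma for isotropic jitter", {
  h <- build_ideal_helix(15)
  static <- jittered_trajectory(h, sigma = 0, n_frames = 6, seed = 1)
  expect_equal(unname(rmsf(static)), rep(0, 15), tolerance = 1e-12)

  # enough atoms that the 6 rigid-body degrees of freedom removed by the
  # fit are a small fraction of the 3N coordinates
  sigma <- 0.04
  big <- build_ideal_helix(40)
  jt <- jittered_trajectory(big, sigma = sigma, n_frames = 2000, seed = 5)
  r <- rmsf(jt)
  expect_equal(mean(r), sqrt(3) * sigma, tolerance = 0.05)

  # small fixture against a direct computation through the bio3d fit
  small <- jittered_trajectory(build_ideal_helix(6), sigma = 0.03,
                               n_frames = 5, seed = 9)
  got <- rmsf(small, sel_calpha())
  idx <- select_atoms(md_structure(small$atoms), sel_calpha())
  inds3 <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xyz_sel <- small$xyz[, inds3]
  for (pass in 1:2) {
    ref <- if (pass == 1) xyz_sel[1, ] else colMeans(fitted)
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = ref, mobile = xyz_sel))
  }
  mu <- colMeans(fitted)
  dev2 <- sweep(fitted, 2, mu)^2
  want <- sqrt(colMeans(t(rowsum(t(dev2), rep(seq_along(idx), each = 3)))))
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
})

test_that("histogram PMF: flat for uniform samples, exact zero at the mode, Gaussian curvature", {
  set.seed(11)
  u <- runif(2e5, -1, 1)
  f <- pmf_from_samples(u, breaks = seq(-1, 1, by = 0.2))
  expect_lt(max(f$F, na.rm = TRUE), 0.1)
  expect_equal(min(f$F, na.rm = TRUE), 0)

  sigma <- 0.5
  g <- rnorm(2e5, sd = sigma)
  edges <- seq(-2, 2, by = 0.1)
  fg <- pmf_from_samples(g, breaks = edges)
  counts <- hist(g[g >= -2 & g <= 2], breaks = edges, plot = FALSE)$counts
  expect_identical(fg$F[which.max(counts)], 0)   # modal bin is the zero
  ok <- !fg$mask & abs(fg$centers) < 1.2
  fit <- lm(fg$F[ok] ~ I(fg$centers[ok]^2 / 2))
  expect_equal(unname(coef(fit)[2]), kB * 300 / sigma^2, tolerance = 0.1)
})

test_that("cross-correlation recovers exact limits and is time-reversal invariant", {
  # two atoms translated identically, one mirrored: ccc +1 / -1 without fitting
  n_fr <- 400
  set.seed(13)
  d <- rnorm(n_fr, sd = 0.1)
  base <- build_ideal_helix(3)
  idx_ca <- which(base$atoms$name == "CA")
  xyz <- matrix(as.vector(t(structure_xyz(base))), n_fr,
                3 * nrow(base$atoms), byrow = TRUE)
  for (k in idx_ca) {
    sgn <- if (k == idx_ca[3]) -1 else 1
    xyz[, 3 * (k - 1) + 1] <- xyz[, 3 * (k - 1) + 1] + sgn * d
  }
  tr <- md_traj(base$atoms, xyz)
  cc <- cross_correlation(tr, window_fraction = 1, n_blocks = 1, fit = FALSE)
  expect_equal(diag(cc$C), rep(1, 3))
  expect_equal(cc$C[1, 2], 1, tolerance = 1e-9)
  expect_equal(cc$C[1, 3], -1, tolerance = 1e-9)

  rev_tr <- md_traj(base$atoms, xyz[n_fr:1, , drop = FALSE])
  cc_rev <- cross_correlation(rev_tr, window_fraction = 1, n_blocks = 1, fit = FALSE)
  expect_equal(cc_rev$C, cc$C, tolerance = 1e-12)
})

test_that("cross-correlation recovers a prescribed covariance", {
  n_res <- 12
  S <- outer(1:n_res, 1:n_res, function(i, j) exp(-abs(i - j) / 3))
  S[1:4, 9:12] <- S[1:4, 9:12] - 0.3
  S[9:12, 1:4] <- S[9:12, 1:4] - 0.3
  S <- S + diag(n_res) * 0.1
  S <- 4e-4 * S   # ~0.02 nm displacement scale
  tr <- correlated_gaussian_trajectory(S, n_frames = 4000, seed = 21)
  # generator frames share one reference frame, so the estimator is compared
  # without the rigid-body fit (which would strip collective components of
  # the prescribed field)
  cc <- cross_correlation(tr, window_fraction = 1, n_blocks = 4, fit = FALSE)
  truth <- stats::cov2cor(S)
  off <- upper.tri(truth)
  expect_lt(sqrt(mean((cc$C[off] - truth[off])^2)), 0.08)
})

test_that("correlation networks honour the class bins and the |i-j| > 10 exclusion", {
  resno <- c(1, 12, 51, 16)
  C <- diag(4)
  C[1, 3] <- C[3, 1] <- 0.5    # |i-j| = 50: moderate
  C[1, 2] <- C[2, 1] <- 0.9    # |i-j| = 11: strong
  C[2, 4] <- C[4, 2] <- 0.9    # |i-j| = 4: excluded
  C[3, 4] <- C[4, 3] <- 0.1    # below all bins
  C[1, 4] <- C[4, 1] <- -0.3   # |i-j| = 15: anti
  mat <- structure(list(resno = resno, C = C, n_blocks = 1, n_trajs = 1),
                   class = "ccc_matrix")
  net <- correlation_network(mat)
  key <- paste(net$resno_i, net$resno_j, net$class)
  expect_setequal(key, c("1 51 moderate", "1 12 strong", "1 16 anti"))
})

test_that("GROMOS clustering: trivial partitions and the brute-force oracle", {
  h <- build_ideal_helix(8)
  same <- jittered_trajectory(h, sigma = 0, n_frames = 5, seed = 1)
  cs <- gromos_cluster(same)
  expect_length(cs$clusters, 1)
  expect_setequal(cs$clusters[[1]], 1:5)
  expect_true(cs$representatives[1] %in% cs$clusters[[1]])

  # frames pairwise farther than the cutoff: all singletons
  far <- md_traj(h$atoms, t(vapply(0:3, function(i)
    as.vector(t(structure_xyz(h) + i * 0.5)), numeric(3 * nrow(h$atoms)))))
  # identical shapes translated are RMSD 0 after fitting; stretch instead
  far$xyz <- t(vapply(0:3, function(i)
    as.vector(t(structure_xyz(h) * (1 + 0.4 * i))), numeric(3 * nrow(h$atoms))))
  cf <- gromos_cluster(far, cutoff = 0.1)
  expect_length(cf$clusters, 4)

  # two conformer groups
  pair <- build_two_state_pair(seed = 7)
  frames <- c(lapply(1:6, function(i) {
    set.seed(100 + i)
    set_structure_xyz(pair$state_a, structure_xyz(pair$state_a) +
                        matrix(rnorm(3 * nrow(pair$state_a$atoms), sd = 0.02), ncol = 3))
  }), lapply(1:5, function(i) {
    set.seed(200 + i)
    set_structure_xyz(pair$state_b, structure_xyz(pair$state_b) +
                        matrix(rnorm(3 * nrow(pair$state_b$atoms), sd = 0.02), ncol = 3))
  }))
  tr <- traj_from_structures(frames)
  cs2 <- gromos_cluster(tr, cutoff = 0.2)
  expect_length(cs2$clusters, 2)
  expect_setequal(cs2$clusters[[1]], 1:6)
  expect_setequal(cs2$clusters[[2]], 7:11)
  # full agreement with the independent oracle
  D <- oracle_rmsd_matrix(tr)
  expect_equal(lapply(oracle_gromos(D, 0.2), sort),
               lapply(cs2$clusters, sort), tolerance = 0)
  # representative minimises the summed distance within its cluster
  for (ci in seq_along(cs2$clusters)) {
    mem <- cs2$clusters[[ci]]
    sums <- vapply(mem, function(i) sum(D[i, mem]), numeric(1))
    expect_equal(cs2$representatives[ci], mem[which.min(sums)])
  }
})

test_that("GROMOS clustering is invariant to frame order up to relabelling", {
  pair <- build_two_state_pair(seed = 4)
  frames <- c(lapply(1:4, function(i) pair$state_a), lapply(1:3, function(i) pair$state_b))
  perm <- c(3, 6, 1, 7, 2, 5, 4)
  tr1 <- traj_from_structures(frames)
  tr2 <- traj_from_structures(frames[perm])
  c1 <- gromos_cluster(tr1)
  c2 <- gromos_cluster(tr2)
  part1 <- lapply(c1$clusters, function(m) sort(m))
  part2 <- lapply(c2$clusters, function(m) sort(match(perm[m], seq_along(perm))))
  expect_setequal(vapply(part1, paste, character(1), collapse = ","),
                  vapply(part2, paste, character(1), collapse = ","))
})

test_that("dihedral PCA separates a two-state flipper and keeps the variance identity", {
  h <- build_ideal_helix(10)
  static <- jittered_trajectory(h, sigma = 0, n_frames = 8, seed = 1)
  d0 <- dpca(static, 1:10)
  expect_lt(max(d0$sdev), 1e-9)
  expect_equal(diff(range(d0$projections[, 1])), 0, tolerance = 1e-9)

  # alternate between the helix and a conformer with the tail swung out
  pair <- build_two_state_pair(chain_length = 12, core_fraction = 0.5,
                               target_rmsd = 0.8, jitter = 0.005, seed = 6)
  frames <- lapply(1:40, function(i) {
    s <- if (i %% 2 == 0) pair$state_a else pair$state_b
    set.seed(300 + i)
    set_structure_xyz(s, structure_xyz(s) +
                        matrix(rnorm(3 * nrow(s$atoms), sd = 0.003), ncol = 3))
  })
  tr <- traj_from_structures(frames)
  dp <- dpca(tr, 1:12)
  lab <- rep(c(1, 2), 20)
  m1 <- mean(dp$projections[lab == 1, 1])
  m2 <- mean(dp$projections[lab == 2, 1])
  spread <- sd(dp$projections[lab == 1, 1]) + sd(dp$projections[lab == 2, 1])
  expect_gt(abs(m1 - m2), 3 * spread)   # PC1 separates the two states
  expect_false(is.null(dp$pmf))
  # PCA identity: component variances sum to the sin/cos coordinate variance
  rad <- dp$angles * pi / 180
  X <- cbind(cos(rad), sin(rad))
  expect_equal(sum(dp$sdev^2), sum(apply(X, 2, var)), tolerance = 1e-9)
})

test_that("histogram PMF and WHAM agree on unbiased single-window data", {
  dw <- double_well_potential(2.5, 1)
  s <- boltzmann_sampler(dw, n = 15000, seed = 31, lower = -2, upper = 2)
  edges <- seq(-2, 2, by = 0.1)
  expect_equal(wham(list(umbrella_window(0, 0, s)), bin_edges = edges,
                    n_bootstrap = 0)$F,
               pmf_from_samples(s, edges)$F, tolerance = 1e-9)
})
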