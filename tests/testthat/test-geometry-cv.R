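test_that("Kabsch superposition is exact on rigid copies and matches the quaternion oracle", {
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  B <- sweep(A %*% t(R), 2, c(0.3, -1, 2), `+`)
  expect_equal(kabsch_superpose(B, A)$rmsd, 0, tolerance = 1e-12)

  for (s in 1:5) {
    set.seed(100 + s)
    P <- matrix(rnorm(30), 10, 3)
    Q <- sweep(P %*% t(R), 2, rnorm(3), `+`) + matrix(rnorm(30, sd = 0.05), 10, 3)
    fit <- kabsch_superpose(Q, P)
    expect_equal(fit$rmsd, oracle_quaternion_rmsd(Q, P), tolerance = 1e-10)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    moved <- apply_superpose(Q, fit)
    expect_equal(sqrt(mean(rowSums((moved - P)^2))), fit$rmsd, tolerance = 1e-12)
  }
  expect_error(kabsch_superpose(A[1:4, ], A[1:5, ]), "matched")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 0.1), "degenerate")
})

test_that("fit-then-evaluate RMSD honours its contract and the bio3d oracle", {
  pair <- build_two_state_pair(seed = 3)
  fit_sel <- sel_backbone(pair$core_resno)
  calc_sel <- sel_calpha(pair$tail_resno)
  expect_equal(rmsd_after_fit(pair$state_a, pair$state_a, fit_sel, calc_sel), 0,
               tolerance = 1e-12)
  # calc = fit reduces to the plain superposition RMSD
  ca_core <- sel_calpha(pair$core_resno)
  expect_equal(
    rmsd_after_fit(pair$state_a, pair$state_b, ca_core, ca_core),
    kabsch_superpose(select_coords(pair$state_a, ca_core),
                     select_coords(pair$state_b, ca_core))$rmsd,
    tolerance = 1e-12)
  got <- rmsd_after_fit(pair$state_a, pair$state_b, fit_sel, calc_sel)
  want <- oracle_rmsd_after_fit(pair$state_a, pair$state_b, fit_sel, calc_sel)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("delta-RMSD signs, antisymmetry and midpoint agree with the oracle", {
  pair <- build_two_state_pair(seed = 5)
  spec <- delta_rmsd_spec(pair$state_a, pair$state_b,
                          fit_sel = sel_backbone(pair$core_resno),
                          calc_sel = sel_calpha(pair$tail_resno))
  d <- rmsd_after_fit(pair$state_a, pair$state_b,
                      spec$fit_sel, spec$calc_sel)
  expect_gt(d, 0)
  expect_equal(delta_rmsd(pair$state_a, spec), -d, tolerance = 1e-9)
  expect_equal(delta_rmsd(pair$state_b, spec), d, tolerance = 1e-9)
  # swapping the references flips the sign, preserving magnitude
  swapped <- delta_rmsd_spec(pair$state_b, pair$state_a,
                             fit_sel = spec$fit_sel, calc_sel = spec$calc_sel)
  mid <- interpolate_path(pair$state_a, pair$state_b, 3,
                          fit_sel = spec$fit_sel)[[2]]
  expect_equal(delta_rmsd(mid, spec), -delta_rmsd(mid, swapped), tolerance = 1e-9)
  expect_equal(delta_rmsd(mid, spec), oracle_delta_rmsd(mid, spec),
               tolerance = 1e-6)
})

test_that("helix crossing angle is 0 on itself, 90 on orthogonal vectors, rotation invariant", {
  h <- build_ideal_helix(20)
  ax1 <- helix_axis_spec(1:4, 12:15)
  expect_equal(helix_cross_angle(h, ax1, ax1), 0, tolerance = 1e-9)

  # two straight CA chains along x and along y
  mk <- function(resno, dir) data.frame(
    serial = seq_along(resno), name = "CA", resname = "ALA", chain = "A",
    resno = resno,
    x = if (dir == "x") 0.38 * seq_along(resno) else 0,
    y = if (dir == "y") 0.38 * seq_along(resno) else 0,
    z = 0, element = "C", stringsAsFactors = FALSE)
  cross <- md_structure(rbind(mk(1:8, "x"), mk(101:108, "y")))
  expect_equal(helix_cross_angle(cross, helix_axis_spec(1:2, 7:8),
                                 helix_axis_spec(101:102, 107:108)),
               90, tolerance = 1e-9)

  ax2 <- helix_axis_spec(16:20, 5:8)   # reversed direction, different span
  ang <- helix_cross_angle(h, ax1, ax2)
  set.seed(21)
  th <- runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2])), 3, 3, byrow = TRUE)
  moved <- set_structure_xyz(h, sweep(structure_xyz(h) %*% (Rz %*% Rx), 2, c(1, -2, 0.5), `+`))
  expect_equal(helix_cross_angle(moved, ax1, ax2), ang, tolerance = 1e-8)
  expect_error(helix_axis_spec(1:4, 4:8), "overlap")
})

test_that("switching function and contact number: limit, tail, continuity, monotonicity", {
  expect_equal(switching_fn(0.85, 0.85), 2 / 3, tolerance = 1e-9)
  expect_lt(switching_fn(5, 0.85), 1e-3)
  # continuity across the removable singularity
  eps <- c(1e-9, 1e-7, 1e-5)
  vals <- switching_fn(0.85 + c(-eps, 0, eps), 0.85)
  expect_true(all(abs(vals - 2 / 3) < 1e-4))
  # single pair at r0
  expect_equal(contact_number(matrix(0, 1, 3), matrix(c(0.85, 0, 0), 1, 3)), 2 / 3,
               tolerance = 1e-9)
  # strictly decreasing in each pairwise distance
  rs <- seq(0.2, 2.5, by = 0.05)
  fs <- switching_fn(rs, 0.85)
  expect_true(all(diff(fs) < 0))
  # finite-difference check of the derivative
  r <- c(0.3, 0.8, 0.86, 1.4)
  fd <- (switching_fn(r + 1e-7, 0.85) - switching_fn(r - 1e-7, 0.85)) / 2e-7
  expect_equal(switching_fn_deriv(r, 0.85), fd, tolerance = 1e-5)
})

test_that("alpha-helix RMSD CV matches the per-window oracle and its bounds", {
  h <- build_ideal_helix(12)
  s <- alpha_helix_rmsd_cv(h, 1:12)
  expect_equal(s, 7, tolerance = 0.05 * 7)
  # per-window oracle: quaternion RMSD to the template + switching function
  template <- select_coords(build_ideal_helix(6), sel_backbone(1:6))
  oracle <- sum(vapply(1:7, function(i) {
    w <- select_coords(h, sel_backbone(i:(i + 5)))
    switching_fn(oracle_quaternion_rmsd(w, template), 0.08)
  }, numeric(1)))
  expect_equal(s, oracle, tolerance = 1e-8)
  # a jittered helix still scores each window through the same oracle
  set.seed(8)
  j <- set_structure_xyz(h, structure_xyz(h) +
                           matrix(rnorm(3 * nrow(h$atoms), sd = 0.02), ncol = 3))
  oj <- sum(vapply(1:7, function(i) {
    w <- select_coords(j, sel_backbone(i:(i + 5)))
    switching_fn(oracle_quaternion_rmsd(w, template), 0.08)
  }, numeric(1)))
  expect_equal(alpha_helix_rmsd_cv(j, 1:12), oj, tolerance = 1e-8)
  # a straightened chain is far from the template in every window
  zig <- h$atoms
  zig$x <- 0.12 * seq_len(nrow(zig))
  zig$y <- rep(c(0, 0.05, 0, -0.05), length.out = nrow(zig))
  zig$z <- rep(c(0, 0.02), length.out = nrow(zig))
  expect_lt(alpha_helix_rmsd_cv(md_structure(zig), 1:12), 0.2)
  expect_error(alpha_helix_rmsd_cv(h, 1:5), "at least 6")
})

test_that("function-group distances and the close-contact rule", {
  mk_atom <- function(serial, name, resname, resno, x, y, z)
    data.frame(serial = serial, name = name, resname = resname, chain = "A",
               resno = resno, x = x, y = y, z = z,
               element = substr(name, 1, 1), stringsAsFactors = FALSE)
  # Arg side-chain N centroid at origin, Glu O centroid at (0.3, 0, 0)
  arg <- rbind(mk_atom(1, "NE", "ARG", 1, 0, 0.1, 0),
               mk_atom(2, "NH1", "ARG", 1, 0.0866, -0.05, 0),
               mk_atom(3, "NH2", "ARG", 1, -0.0866, -0.05, 0))
  glu <- rbind(mk_atom(4, "OE1", "GLU", 2, 0.3, 0.05, 0),
               mk_atom(5, "OE2", "GLU", 2, 0.3, -0.05, 0))
  s <- md_structure(rbind(arg, glu))
  expect_equal(sidechain_group_distance(s, 1, 2), 0.3, tolerance = 1e-9)

  # coincident centroids
  lys <- mk_atom(1, "NZ", "LYS", 1, 0.1, 0.2, -0.3)
  asp <- rbind(mk_atom(2, "OD1", "ASP", 2, 0.1, 0.25, -0.3),
               mk_atom(3, "OD2", "ASP", 2, 0.1, 0.15, -0.3))
  s2 <- md_structure(rbind(lys, asp))
  expect_equal(sidechain_group_distance(s2, 1, 2), 0, tolerance = 1e-12)

  # Lys NZ vs Asp O centroid, hand-computed
  asp2 <- rbind(mk_atom(2, "OD1", "ASP", 2, 0.4, 0.3, -0.1),
                mk_atom(3, "OD2", "ASP", 2, 0.6, 0.5, 0.1))
  s3 <- md_structure(rbind(lys, asp2))
  expect_equal(sidechain_group_distance(s3, 1, 2),
               sqrt(sum((c(0.5, 0.4, 0) - c(0.1, 0.2, -0.3))^2)),
               tolerance = 1e-12)

  expect_true(is_close_contact(0.49))
  expect_false(is_close_contact(0.51))
  expect_true(is_close_contact(0.3))
})

test_that("pi-cation criterion applies both the distance and the printed angle window", {
  # benzene-like hexagonal ring in the xy plane, centroid at origin
  ang <- seq(0, 300, by = 60) * pi / 180
  names6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ring <- data.frame(serial = 1:6, name = names6, resname = "PHE", chain = "A",
                     resno = 1, x = 0.14 * cos(ang), y = 0.14 * sin(ang), z = 0,
                     element = "C", stringsAsFactors = FALSE)
  cation_at <- function(x, y, z) {
    at <- data.frame(serial = 7, name = "NZ", resname = "LYS", chain = "A",
                     resno = 2, x = x, y = y, z = z, element = "N",
                     stringsAsFactors = FALSE)
    md_structure(rbind(ring, at))
  }
  # in-plane at 0.5 nm: angle to normal = 90, inside both bounds
  expect_true(is_pi_cation(cation_at(0.5, 0, 0), 1, 2))
  # too far
  expect_false(is_pi_cation(cation_at(0.7, 0, 0), 1, 2))
  # stacked above the ring: angle to normal ~ 0, outside [60, 120]
  expect_false(is_pi_cation(cation_at(0, 0, 0.5), 1, 2))
  # 0.5 nm away at 30 degrees from the normal: rejected as printed
  expect_false(is_pi_cation(cation_at(0.25, 0, 0.25 * sqrt(3)), 1, 2))
})
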