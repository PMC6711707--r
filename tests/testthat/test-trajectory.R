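flat_plane <- function() fixed_membrane_plane()

test_that("membrane plane fitting recovers constructed planes", {
  fr <- build_toy_trajectory()[build_toy_trajectory()$frame == 1, ]
  pl <- membrane_plane(fr, atom = "P")
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$offset, 0, tolerance = 1e-9)

  # anchors rotated 10 degrees about x: normal 10 degrees from z
  th <- 10 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  fr_rot <- rigid_transform(fr, R)
  pl_rot <- membrane_plane(fr_rot, atom = "P")
  ang <- acos(sum(pl_rot$normal * c(0, 0, 1))) * 180 / pi
  expect_equal(ang, 10, tolerance = 1e-6)

  # fewer than 3 anchors, or collinear anchors, fail
  expect_error(membrane_plane(fr[fr$atom == "P", ][1:2, ], atom = "P"),
               "at least 3")
  col <- data.frame(frame = 1, atom = "P", resno = 1:4, resname = "MEM",
                    chain = "M", x = 1:4, y = 2 * (1:4), z = 0)
  expect_error(membrane_plane(col, atom = "P"), "collinear")
})

test_that("helix tilt covers the trivial and constructed cases", {
  mk_helix <- function(dir) {
    pos <- t(vapply(0:9, function(i) i * 1.5 * dir, numeric(3)))
    data.frame(frame = 1, atom = "CA", resno = 222:231, resname = "ALA",
               chain = "A", x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  expect_equal(helix_tilt_angle(mk_helix(c(0, 0, 1)), flat_plane(), "222-231"),
               90, tolerance = 1e-9)
  expect_equal(helix_tilt_angle(mk_helix(c(1, 0, 0)), flat_plane(), "222-231"),
               0, tolerance = 1e-9)
  expect_error(helix_tilt_angle(mk_helix(c(0, 0, 1))[1:3, ], flat_plane(),
                                "222-224"), "at least 4")
})

test_that("inclination covers the vertical, flat and error cases", {
  mk <- function(link_dz, link_dx) {
    tm <- data.frame(frame = 1, atom = "CA", resno = 222:224, resname = "ALA",
                     chain = "A", x = c(-1, 0, 1), y = 0, z = 0)
    lk <- data.frame(frame = 1, atom = "CA", resno = 130:132, resname = "GLY",
                     chain = "A", x = link_dx + c(-1, 0, 1), y = 0, z = link_dz)
    rbind(tm, lk)
  }
  expect_equal(ectodomain_inclination(mk(25, 0), flat_plane()), 90,
               tolerance = 1e-9)
  expect_equal(ectodomain_inclination(mk(0, 30), flat_plane()), 0,
               tolerance = 1e-9)
  # pointing into the bilayer gives a negative signed angle
  expect_lt(ectodomain_inclination(mk(-10, 30), flat_plane()), 0)
  expect_error(ectodomain_inclination(mk(25, 0)[1:3, ], flat_plane()),
               "missing residue group")
})

test_that("distances and spans are direct projections", {
  dom <- data.frame(frame = 1, atom = "CA", resno = 101:103, resname = "GLY",
                    chain = "A", x = c(0, 1, -1), y = 0, z = 30)
  expect_equal(domain_membrane_distance(dom, flat_plane(), resno = "101-103"),
               30, tolerance = 1e-12)
  # rigid in-plane translation leaves the distance unchanged
  shifted <- rigid_transform(dom, t = c(12, -7, 0))
  expect_equal(domain_membrane_distance(shifted, flat_plane(), resno = "101-103"),
               30, tolerance = 1e-12)
  expect_error(domain_membrane_distance(dom, flat_plane(), resno = 999),
               "empty")

  bb <- function(resno, zc) {
    data.frame(frame = 1, atom = c("N", "CA", "C", "O"), resno = resno,
               resname = "SER", chain = "A",
               x = c(1, -1, 0, 0), y = c(0, 0, 1, -1), z = zc)
  }
  fr <- rbind(bb(218, 5), bb(221, 16))
  expect_equal(segment_normal_length(fr, flat_plane()), 11, tolerance = 1e-12)
  flat <- rbind(bb(218, 5), bb(221, 5))
  expect_equal(segment_normal_length(flat, flat_plane()), 0, tolerance = 1e-12)
  expect_error(segment_normal_length(fr[-1, ], flat_plane()), "backbone atoms")
})

test_that("dihedrals follow the IUPAC sign convention", {
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
               -90, tolerance = 1e-9)
  # planar trans arrangement
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               180, tolerance = 1e-9)
  # chirality: mirroring z negates the angle
  set.seed(2)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    d <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    pm <- p; pm[, 3] <- -pm[, 3]
    dm <- dihedral_angle(pm[1, ], pm[2, ], pm[3, ], pm[4, ])
    expect_equal(dm, -d, tolerance = 1e-9)
    expect_true(d > -180 && d <= 180)
  }

  fr <- data.frame(frame = 1,
                   atom = c("C", "N", "CA", "C", "N"),
                   resno = c(216, 217, 217, 217, 218), resname = "PRO",
                   chain = "A",
                   x = c(1, 0, 0, 0, 1), y = c(0, 0, 1, 1, 1),
                   z = c(0, 0, 0, 1, 1))
  pp <- backbone_dihedrals(fr, 217)
  expect_named(pp, c("phi", "psi"))
  expect_equal(unname(pp["phi"]), -90, tolerance = 1e-9)
  expect_error(backbone_dihedrals(fr, 218), "missing")
})

test_that("atom-pair distance takes the nearest candidate and calls H-bonds", {
  fr <- data.frame(frame = 1, atom = c("OG1", "O", "O"),
                   resno = c(232, 228, 228), resname = c("THR", "VAL", "VAL"),
                   chain = "A",
                   x = c(0, 3, 10), y = c(0, 4, 0), z = 0)
  res <- atom_pair_distance(fr, "A:232:OG1", "A:228:O")
  expect_equal(res$distance, 5)       # 3-4-5, nearest of the two O atoms
  expect_false(res$hbond)
  fr2 <- fr; fr2$x[2] <- 3.4; fr2$y[2] <- 0
  expect_true(atom_pair_distance(fr2, "A:232:OG1", "A:228:O")$hbond)
  same <- fr; same$x[2] <- 0; same$y[2] <- 0
  expect_equal(atom_pair_distance(same, "A:232:OG1", "A:228:O")$distance, 0)
  expect_error(atom_pair_distance(fr, "A:999:XX", "A:228:O"), "exactly one")
})

test_that("probability distributions are normalised aligned histograms", {
  const <- probability_distribution(rep(4.2, 50), bin_width = 0.5)
  expect_equal(sum(const$prob), 1, tolerance = 1e-9)
  expect_identical(sum(const$prob > 0), 1L)

  set.seed(9)
  u <- runif(20000, 0, 10)
  h <- probability_distribution(u, bin_width = 1)
  expect_equal(sum(h$prob), 1, tolerance = 1e-9)
  se <- sqrt(0.1 * 0.9 / length(u))
  expect_true(all(abs(h$prob - 0.1) < 3 * se))
  # edges aligned to multiples of the bin width; bin-count bound
  expect_true(all(abs(h$edges / 1 - round(h$edges / 1)) < 1e-9))
  v <- rnorm(500)
  hb <- probability_distribution(v, bin_width = 0.25)
  expect_lte(length(hb$prob), ceiling(diff(range(v)) / 0.25) + 1)
  expect_equal(sum(hb$prob), 1, tolerance = 1e-9)
  expect_error(probability_distribution(numeric(0), 1), "empty")
})

test_that("toy trajectory is recovered exactly without jitter", {
  spec <- list(tilt = 40, incl = 40, d_c1 = 30, span = 11)
  traj <- build_toy_trajectory(spec$tilt, spec$incl, spec$d_c1, spec$span)
  fr <- traj[traj$frame == 1, ]
  pl <- membrane_plane(fr, atom = "P")
  expect_equal(helix_tilt_angle(fr, pl, "222-248"), spec$tilt,
               tolerance = 1e-6)
  expect_equal(ectodomain_inclination(fr, pl), spec$incl, tolerance = 1e-6)
  expect_equal(domain_membrane_distance(fr, pl, resno = "101-103"),
               spec$d_c1, tolerance = 1e-6)
  expect_equal(segment_normal_length(fr, pl), spec$span, tolerance = 1e-6)
  # vertical helix special case
  up <- build_toy_trajectory(tilt_deg = 90)
  expect_equal(helix_tilt_angle(up[up$frame == 1, ], flat_plane(), "222-248"),
               90, tolerance = 1e-9)
  # built-in hydrogen-bond pair sits at 3.0 A
  hb <- atom_pair_distance(fr, "A:232:OG1", "A:228:O")
  expect_equal(hb$distance, 3.0, tolerance = 1e-9)
  expect_true(hb$hbond)
})

test_that("jittered toy frames fluctuate around the construction values", {
  traj <- build_toy_trajectory(40, 40, 30, 11, n_frames = 200,
                               jitter_sd = 0.5, seed = 12)
  vals <- list(
    tilt = per_frame(traj, function(fr) {
      helix_tilt_angle(fr, membrane_plane(fr, atom = "P"), "222-248")
    }),
    incl = per_frame(traj, function(fr) {
      ectodomain_inclination(fr, membrane_plane(fr, atom = "P"))
    }),
    span = per_frame(traj, function(fr) {
      segment_normal_length(fr, membrane_plane(fr, atom = "P"))
    }))
  truth <- c(tilt = 40, incl = 40, span = 11)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    expect_gt(sd(v), 0)
    expect_lt(abs(mean(v) - truth[[nm]]), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("descriptors are invariant under rigid transforms", {
  traj <- build_toy_trajectory(40, 40, 30, 11)
  fr <- traj[traj$frame == 1, ]
  link_ref <- function(f) {
    colMeans(as.matrix(select_atoms(f, resno = "130-132",
                                    atom = "CA")[, c("x", "y", "z")]))
  }
  desc <- function(f) {
    pl <- membrane_plane(f, atom = "P", orient_ref = link_ref(f))
    c(tilt = helix_tilt_angle(f, pl, "222-248"),
      incl = ectodomain_inclination(f, pl),
      dist = domain_membrane_distance(f, pl, resno = "101-103"),
      span = segment_normal_length(f, pl),
      phipsi = backbone_dihedrals(f, 217),
      pair = atom_pair_distance(f, "A:232:OG1", "A:228:O")$distance)
  }
  base <- desc(fr)
  set.seed(99)
  for (i in 1:100) {
    R <- random_rotation()
    t <- rnorm(3, 0, 50)
    expect_equal(desc(rigid_transform(fr, R, t)), base, tolerance = 1e-6)
  }
  # angle ranges
  expect_true(base["tilt"] >= 0 && base["tilt"] <= 90)
  expect_true(base["incl"] >= -90 && base["incl"] <= 90)
})
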