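test_that("radius_of_gyration matches hand-computed values", {
  topo1 <- single_atom_topology(1)
  expect_equal(radius_of_gyration(toy_frame(rbind(c(0, 0))), topo1), 0)

  topo2 <- single_atom_topology(2)
  fr2 <- toy_frame(rbind(c(0, 0), c(2, 0)))       # each atom 1 A from centroid
  expect_equal(radius_of_gyration(fr2, topo2), 1)

  topo4 <- single_atom_topology(4)
  sq <- toy_frame(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_equal(radius_of_gyration(sq, topo4), sqrt(2))

  # mass weighting shifts the centroid toward the heavy atom
  topo_w <- molecular_topology(atom_res = 1:2, masses = c(3, 1))
  rg_w <- radius_of_gyration(fr2, topo_w, mass_weighted = TRUE)
  expect_equal(rg_w, sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4))
  expect_error(radius_of_gyration(fr2, topo2, selection = integer(0)),
               "input error")
})

test_that("superposed RMSD removes rigid motion and matches the quaternion oracle", {
  set.seed(51)
  x <- matrix(runif(15, 0, 10), 5, 3)
  expect_equal(superposed_rmsd(x, x), 0)
  for (k in 1:10) {
    R <- random_rotation()
    y <- sweep(x %*% t(R), 2, rnorm(3, 0, 20), "+")
    expect_lt(superposed_rmsd(x, y), 1e-6)
  }
  # spec toy: third point stretched along y
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  b <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  expect_equal(superposed_rmsd(a, b), horn_rmsd(a, b), tolerance = 1e-6)
  # 50 random 5-point instances against the independent oracle
  for (k in 1:50) {
    x <- matrix(runif(15, 0, 10), 5, 3)
    y <- x + matrix(rnorm(15, 0, 1), 5, 3)
    expect_lt(abs(superposed_rmsd(x, y) - horn_rmsd(x, y)), 1e-4)
  }
})

test_that("degenerate point sets are flagged but still superposed optimally", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0))     # 2 points: no unique rotation
  y <- rbind(c(5, 0, 0), c(6, 0, 0))
  expect_warning(r <- superposed_rmsd(x, y), "degenerate")
  expect_equal(r, 0)                     # congruent segments align exactly
  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))  # collinear
  expect_warning(r2 <- superposed_rmsd(coll, coll + 1), "degenerate")
  expect_equal(r2, 0)                    # pure translation removed
  # collinear against full-rank: value still matches the quaternion oracle
  set.seed(50)
  full <- matrix(runif(9, 0, 5), 3, 3)
  suppressWarnings(expect_equal(superposed_rmsd(coll, full),
                                horn_rmsd(coll, full), tolerance = 1e-6))
})

test_that("rmsd_to_reference uses the backbone by default and validates shapes", {
  set.seed(52)
  topo <- molecular_topology(atom_res = rep(1:4, each = 2),
                             atom_names = rep(c("CA", "CB"), 4))
  ref <- matrix(runif(24, 0, 10), 8, 3)
  R <- random_rotation()
  moved <- sweep(ref %*% t(R), 2, c(3, -2, 7), "+")
  expect_lt(rmsd_to_reference(moved, ref, topo), 1e-6)
  # perturbing only side-chain (CB) atoms leaves backbone RMSD at ~0
  pert <- ref
  cb <- select_atoms(topo, atom_names = "CB")
  pert[cb, ] <- pert[cb, ] + 5
  expect_lt(rmsd_to_reference(pert, ref, topo), 1e-6)
  expect_gt(rmsd_to_reference(pert, ref, topo,
                              selection = seq_len(8)), 0.5)
})

test_that("helix_rmsd restricts fitting and deviation to the helix residues", {
  set.seed(53)
  n <- 12
  topo <- single_atom_topology(n)
  helix <- rinmap:::helix_coords(n, 2.3, 1.5)
  # same helix region (residues 2-8), divergent tails
  other <- helix
  other[c(1, 9:12), ] <- other[c(1, 9:12), ] + matrix(rnorm(15, 0, 4), 5, 3)
  expect_lt(helix_rmsd(other, helix, topo, residue_range = 2:8), 1e-6)
  # consistency: equals rmsd_to_reference on the restricted selection
  # (a straightened chain is collinear, hence the degeneracy warnings)
  straight <- rinmap:::extended_coords(n, 3.8)
  sel <- select_atoms(topo, residues = 2:8, author = TRUE)
  suppressWarnings({
    expect_equal(helix_rmsd(straight, helix, topo, residue_range = 2:8),
                 rmsd_to_reference(straight, helix, topo, selection = sel))
    # straightened helix deviates from the ideal helix by the oracle value
    expect_equal(helix_rmsd(straight, helix, topo, residue_range = 2:8),
                 horn_rmsd(straight[2:8, ], helix[2:8, ]), tolerance = 1e-6)
  })
  expect_error(helix_rmsd(straight, helix, topo, residue_range = 10:14),
               "input error")
})

test_that("vertical_shift is the signed difference of CA distances", {
  topo <- single_atom_topology(20)
  fr <- rinmap:::extended_coords(20, 3.8)
  # straight chain: d(1,11) = 38, d(11,20) = 34.2
  expect_equal(vertical_shift(fr, topo), 38 - 34.2)
  # three-point hand case on a 20-residue chain
  fr2 <- fr
  fr2[1, ] <- c(0, 0, 0); fr2[11, ] <- c(10, 0, 0); fr2[20, ] <- c(14, 0, 0)
  expect_equal(vertical_shift(fr2, topo), 6)
  # symmetric conformation gives 0
  fr3 <- fr
  fr3[1, ] <- c(-5, 0, 0); fr3[11, ] <- c(0, 0, 0); fr3[20, ] <- c(5, 0, 0)
  expect_equal(vertical_shift(fr3, topo), 0)
  # rigid-motion invariance
  set.seed(54)
  R <- random_rotation()
  expect_equal(vertical_shift(sweep(fr2 %*% t(R), 2, c(1, 2, 3), "+"), topo), 6)
  topo_noca <- molecular_topology(atom_res = 1:20,
                                  atom_names = rep("CB", 20))
  expect_error(vertical_shift(fr, topo_noca), "input error")
})

test_that("domain_contact_score counts red contacts positively, blue negatively", {
  # 10 nodes; probe = {1,2}; red = {5,6}; blue = {8,9}
  probe <- 1:2; red <- 5:6; blue <- 8:9
  g1 <- residue_graph(10, rbind(c(1, 5), c(1, 6), c(2, 5), c(2, 8)))
  topo <- single_atom_topology(10)
  expect_equal(domain_contact_score(g1, topo, probe, red, blue), 2)  # 3 - 1
  g2 <- residue_graph(10, rbind(c(1, 8), c(2, 9)))
  expect_equal(domain_contact_score(g2, topo, probe, red, blue), -2)
  g3 <- residue_graph(10, rbind(c(3, 4), c(5, 6)))  # no probe contacts
  expect_equal(domain_contact_score(g3, topo, probe, red, blue), 0)
  expect_error(domain_contact_score(g1, topo, probe, red, c(6, 9)),
               "input error")
})

test_that("contact score from coordinates equals the score from the built graph", {
  set.seed(55)
  topo <- single_atom_topology(12)
  for (k in 1:5) {
    fr <- matrix(runif(36, 0, 12), ncol = 3)
    g <- build_rin(fr, topo)
    s_graph <- domain_contact_score(g, topo, 1:3, 6:8, 10:12)
    s_frame <- domain_contact_score(fr, topo, 1:3, 6:8, 10:12)
    expect_identical(s_frame, s_graph)
  }
})

test_that("map_density conserves counts and bins points where expected", {
  one <- matrix(c(0.3, 0.7), 1, 2)
  d1 <- map_density(one, bins = 4)
  expect_equal(sum(d1$counts), 1)
  expect_equal(sum(d1$counts == 1), 1)

  quad <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  d4 <- map_density(quad, bins = 2)
  expect_equal(unname(d4$counts), matrix(1, 2, 2))

  set.seed(56)
  pts <- matrix(rnorm(400), 200, 2)
  dd <- map_density(pts, bins = 7)
  expect_equal(sum(dd$counts), 200)
  dn <- map_density(pts, bins = 7, normalize = TRUE)
  expect_equal(sum(dn$counts), 1)
  expect_length(dd$frame_density, 200)
  expect_error(map_density(rbind(c(NA, 1))), "input error")
})

test_that("cv_series assembles per-frame CV columns", {
  toy <- toy_two_state_trajectory(
    toy_trajectory_spec(n_frames = 20, p_switch = 0.3, seed = 2))
  df <- suppressWarnings(
    cv_series(toy$trajectory, toy$topology, cvs = c("rg", "rmsd")))
  expect_equal(nrow(df), 20)
  expect_named(df, c("rg", "rmsd"))
  expect_true(all(is.finite(df$rg)) && all(df$rg > 0))
  expect_equal(df$rmsd[1], 0)  # reference defaults to frame 1
  # compact frames are more compact than extended frames
  expect_lt(mean(df$rg[toy$labels == "compact"]),
            mean(df$rg[toy$labels == "extended"]))
  expect_error(cv_series(toy$trajectory, toy$topology, cvs = "nope"),
               "input error")
})
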