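# Topology: critical-point search and classification, basin assignment and
# charge integration, and their structural invariants.

test_that("two-lump critical points bifurcate at a = 1/sqrt(2 beta)", {
  # beta = 1: critical separation parameter a* = 1/sqrt(2) ~ 0.7071
  wide <- find_cps(two_lump_model(0.9))
  expect_equal(nrow(wide), 3)
  expect_equal(sort(wide$signature), c(-3, -3, -1))
  bcp <- wide[wide$cp_type == "bond", ]
  expect_equal(bcp$x, 0, tolerance = 1e-8)
  expect_equal(bcp$rho, two_lump_rho(0, 0.9), tolerance = 1e-8)

  narrow <- find_cps(two_lump_model(0.5))
  expect_equal(nrow(narrow), 1)
  expect_equal(narrow$signature, -3)
  expect_equal(narrow$x, 0, tolerance = 1e-8)
  expect_equal(narrow$rho, two_lump_rho(0, 0.5), tolerance = 1e-8)
})

test_that("a wide Gaussian triangle carries a ring critical point", {
  ang <- 2 * pi * (0:2) / 3
  m <- toy_gaussian_system(cbind(2 * cos(ang), 2 * sin(ang), 0),
                           rep(0.5, 3), rep(1, 3))
  cps <- find_cps(m)
  counts <- table(cps$cp_type)
  expect_equal(unname(counts["bond"]), 3)
  expect_equal(unname(counts["ring"]), 1)
  expect_equal(sum(cps$cp_type %in% c("nuclear_max", "nna")), 3)
  ring <- cps[cps$cp_type == "ring", ]
  expect_equal(c(ring$x, ring$y), c(0, 0), tolerance = 1e-6)
  expect_equal(ring$signature, 1)
  expect_equal(poincare_hopf(cps), 1)
})

test_that("H2 has a covalent bond critical point at the midpoint", {
  fx <- qm_fixture("h2_sto3g")
  cps <- qm_cps("h2_sto3g")
  expect_equal(nrow(cps), 3)
  bcp <- cps[cps$cp_type == "bond", ]
  expect_equal(bcp$z, fx$atoms$z[2] / 2, tolerance = 1e-8)
  expect_equal(bcp$signature, -1)
  expect_equal(bcp$rank, 3)
  expect_lt(bcp$laplacian, 0)           # covalent: charge concentration
  expect_equal(sort(bcp$eig1), bcp$eig1) # eigenvalues sorted ascending
})

test_that("nuclear maxima and the Li2 non-nuclear attractor are classified", {
  cps_lih <- qm_cps("lih_sto3g")
  nuc <- cps_lih[cps_lih$cp_type == "nuclear_max", ]
  expect_equal(nrow(nuc), 2)
  expect_true(all(nuc$signature == -3))
  expect_true(all(nuc$dist1 <= 0.2))

  cps_li2 <- qm_cps("li2_sto3g")
  nna <- cps_li2[cps_li2$cp_type == "nna", ]
  expect_equal(nrow(nna), 1)
  expect_equal(nna$signature, -3)
  expect_gt(nna$dist1, 0.2)             # a maximum away from any nucleus
  fx <- qm_fixture("li2_sto3g")
  expect_equal(nna$z, fx$atoms$z[2] / 2, tolerance = 1e-6)

  # classify_cp refuses non-critical points
  expect_error(classify_cp(c(0.3, 0.2, 0.1), qm_model("lih_sto3g")),
               "not critical")
})

test_that("every reported CP satisfies the gradient tolerance when re-evaluated", {
  for (id in c("h2_sto3g", "lih_sto3g", "li2_sto3g", "hcn_sto3g")) {
    cps <- qm_cps(id)
    m <- qm_model(id)
    for (i in seq_len(nrow(cps))) {
      g <- eval_point(m, c(cps$x[i], cps$y[i], cps$z[i]))$gradient
      expect_lt(sqrt(sum(g^2)), 1e-10)
    }
  }
})

test_that("the Poincare-Hopf relation holds on fixtures and toys", {
  for (id in fixture_catalog()$id) {
    expect_equal(poincare_hopf(qm_cps(id)), 1, info = id)
  }
  expect_equal(poincare_hopf(find_cps(two_lump_model(0.9))), 1)
  expect_equal(poincare_hopf(find_cps(two_lump_model(0.5))), 1)
})

test_that("basins: counts, symmetry, and charge conservation", {
  # one Gaussian, one basin
  mt <- toy_gaussian_system(matrix(0, 1, 3), 1, 1)
  gt <- default_grid(mt$wavefunction$atoms, 0.2, 5)
  map <- suppressMessages(assign_basins(mt, gt))
  expect_equal(nrow(map$attractors), 1)
  lab <- as.integer(map$labels)
  expect_true(all(lab[!is.na(lab)] == 1))

  # H2: two basins, mirror-equal populations and voxel counts
  ch2 <- qm_charges("h2_sto3g", 0.1)
  expect_equal(nrow(ch2), 2)
  expect_equal(ch2$population[1], ch2$population[2], tolerance = 1e-6)
  fx <- qm_fixture("h2_sto3g")
  m <- qm_model("h2_sto3g")
  map2 <- suppressMessages(assign_basins(m, default_grid(fx$atoms, 0.1, 7),
                                         cps = qm_cps("h2_sto3g")))
  nvox <- table(as.integer(map2$labels))
  expect_lt(abs(nvox[1] - nvox[2]) / sum(nvox), 0.001)

  # Li2: two nuclear basins plus the midbond NNA basin
  ch3 <- qm_charges("li2_sto3g", 0.1)
  expect_equal(nrow(ch3), 3)
  expect_equal(sort(unique(ch3$element)), c("Li", "NNA"))
  expect_equal(ch3$charge[ch3$element == "Li"][1],
               ch3$charge[ch3$element == "Li"][2], tolerance = 2e-3)

  # conservation: sum q = sum Z - grid integral of rho, within 0.03 e
  for (id in c("h2_sto3g", "lih_sto3g", "li2_sto3g", "hcn_sto3g")) {
    ch <- qm_charges(id, 0.1)
    zsum <- sum(qm_fixture(id)$atoms$Z)
    expect_lt(abs(sum(ch$charge) - (zsum - attr(ch, "grid_integral"))), 0.03)
    expect_true(all(ch$population >= 0))
  }
})

test_that("charges are stable under grid refinement on compact systems", {
  for (id in c("h2_sto3g", "lih_sto3g")) {
    coarse <- qm_charges(id, 0.1)
    fine <- qm_charges(id, 0.05)
    expect_lt(max(abs(coarse$charge - fine$charge)), 0.01)
  }
})

test_that("the ascent method is deterministic and symmetric on H2", {
  fx <- qm_fixture("h2_sto3g")
  m <- qm_model("h2_sto3g")
  g <- default_grid(fx$atoms, 0.15, 6)
  m1 <- suppressMessages(assign_basins(m, g, cps = qm_cps("h2_sto3g"),
                                       method = "ascent"))
  m2 <- suppressMessages(assign_basins(m, g, cps = qm_cps("h2_sto3g"),
                                       method = "ascent"))
  expect_identical(m1$labels, m2$labels)
  nvox <- table(as.integer(m1$labels))
  expect_lt(abs(nvox[1] - nvox[2]) / sum(nvox), 0.001)
  ch <- basin_charges(m1, m)
  expect_equal(ch$charge[1], ch$charge[2], tolerance = 1e-6)
})
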