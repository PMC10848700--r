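# Analytic density evaluation: closed-form Gaussian oracles, finite-
# difference agreement for the derivatives, grid sampling, integration, and
# model differences.

test_that("a single normalized s Gaussian matches its closed form", {
  m <- toy_gaussian_system(matrix(0, 1, 3), exponents = 1, weights = 1)
  pe <- eval_point(m, c(0, 0, 0))
  expect_equal(pe$rho, (2 / pi)^1.5, tolerance = 1e-10)
  expect_equal(pe$laplacian, -12 * (2 / pi)^1.5, tolerance = 1e-10)
  expect_equal(pe$laplacian, sum(diag(pe$hessian)))  # defining identity

  # rho(r) = N^2 exp(-2 alpha r^2) off the origin as well
  set.seed(20)
  for (i in 1:5) {
    p <- rnorm(3, sd = 0.8)
    want <- (2 / pi)^1.5 * exp(-2 * sum(p^2))
    expect_equal(eval_point(m, p)$rho, want, tolerance = 1e-10)
  }
})

test_that("analytic derivatives match finite differences on every fixture", {
  for (id in fixture_catalog()$id) {
    m <- qm_model(id)
    pos <- as.matrix(qm_fixture(id)$atoms[, c("x", "y", "z")])
    set.seed(123)
    npt <- 100
    anchor <- pos[sample(nrow(pos), npt, replace = TRUE), , drop = FALSE]
    pts <- anchor + matrix(runif(3 * npt, -2, 2), ncol = 3)
    ev <- densiwit:::density_batch(m, pts, order = 2)
    # errors are measured relative to the scale of the derivative object
    # (individual components pass through zero)
    worst_g <- worst_h <- worst_l <- 0
    for (i in seq_len(npt)) {
      fd <- fd_point(m, pts[i, ])
      gs <- max(abs(fd$gradient), 1e-8)
      hs <- max(abs(fd$hessian), 1e-8)
      worst_g <- max(worst_g, max(abs(ev$grad[i, ] - fd$gradient)) / gs)
      worst_h <- max(worst_h, max(abs(matrix(ev$hess[i, ], 3) -
                                        fd$hessian)) / hs)
      worst_l <- max(worst_l, abs(ev$lap[i] - fd$laplacian) / hs)
    }
    expect_lt(worst_g, 1e-6)
    expect_lt(worst_h, 1e-6)
    expect_lt(worst_l, 1e-6)
  }
})

test_that("grid densities respect point-group symmetry and peak at nuclei", {
  # symmetric two-lump system on a mirror-symmetric grid
  m <- two_lump_model(0.9)
  g <- grid_spec(c(-2, -1, -1), diag(rep(0.25, 3)), c(17, 9, 9))
  f <- eval_grid(m, g)
  flipped <- f$values[17:1, , ]           # x -> -x about the grid center
  expect_lt(max(abs(f$values - flipped)), 1e-10)

  # H2: the density maximum lies near the nuclei, not at the box edge
  fx <- qm_fixture("h2_sto3g")
  fh <- eval_grid(qm_model("h2_sto3g"), default_grid(fx$atoms, 0.2, 5))
  peak <- which(fh$values == max(fh$values), arr.ind = TRUE)[1, ]
  peak_xyz <- fh$grid$origin + (peak - 1) * 0.2
  expect_lt(min(sqrt(colSums((t(as.matrix(fx$atoms[, c("x", "y", "z")])) -
                                peak_xyz)^2))), 0.3)
  expect_gt(max(fh$values), max(fh$values[1, , ]) * 10)
})

test_that("the density is linear in the 1-RDM", {
  fx <- qm_fixture("lih_sto3g")
  d1 <- embed_active(fx$rdm)
  d2 <- embed_active(apply_noise(fx$rdm, noise_spec("depolarizing", 0.3)))
  mix <- d1
  mix$matrix <- 0.3 * d1$matrix + 0.7 * d2$matrix
  m1 <- density_model(fx$wavefunction, d1)
  m2 <- density_model(fx$wavefunction, d2)
  mm <- density_model(fx$wavefunction, mix)
  set.seed(9)
  pts <- matrix(rnorm(30, sd = 1.5), ncol = 3)
  r1 <- densiwit:::density_batch(m1, pts, 0)$rho
  r2 <- densiwit:::density_batch(m2, pts, 0)$rho
  rm_ <- densiwit:::density_batch(mm, pts, 0)$rho
  expect_equal(rm_, 0.3 * r1 + 0.7 * r2, tolerance = 1e-13)
})

test_that("densities integrate to the electron count", {
  # constant field of one over a unit-volume grid
  g <- grid_spec(c(0, 0, 0), diag(rep(0.1, 3)), c(10, 10, 10))
  expect_equal(integrate_density(scalar_field(g, array(1, c(10, 10, 10)),
                                              "density")), 1.0)

  # normalized toy orbital integrates to one electron
  mt <- toy_gaussian_system(matrix(0, 1, 3), 1, 1)
  gt <- default_grid(mt$wavefunction$atoms, 0.1, 8)
  expect_equal(integrate_density(eval_grid(mt, gt)), 1.0, tolerance = 1e-4)

  # every bundled fixture recovers its electron count within 0.5% on the
  # default grid
  for (id in c("h2_sto3g", "lih_sto3g", "li2_sto3g", "hcn_sto3g")) {
    fx <- qm_fixture(id)
    m <- qm_model(id)
    n_el <- sum(fx$wavefunction$mos$occupations)
    got <- integrate_density(eval_grid(m, default_grid(fx$atoms, 0.1,
                                                       fx$margin)))
    expect_lt(abs(got - n_el) / n_el, 0.005)
  }
})

test_that("density differences integrate to trace differences", {
  fx <- qm_fixture("h2_sto3g")
  g <- default_grid(fx$atoms, 0.2, 6)
  m0 <- qm_model("h2_sto3g")

  zero <- density_difference(m0, m0, g)
  expect_equal(max(abs(zero$values)), 0)
  expect_equal(zero$quantity, "difference")

  noisy <- density_model(fx$wavefunction,
                         apply_noise(fx$rdm, noise_spec("depolarizing", 0.2)))
  dif <- density_difference(noisy, m0, g)
  want <- sum(diag(noisy$rdm$matrix)) - sum(diag(m0$rdm$matrix))
  expect_equal(sum(dif$values) * 0.2^3, want, tolerance = 0.005)

  mitd <- density_model(fx$wavefunction,
                        mitigate(apply_noise(fx$rdm,
                                             noise_spec("depolarizing", 0.2))))
  dif2 <- density_difference(mitd, m0, g)
  expect_lt(abs(sum(dif2$values) * 0.2^3), 0.005)
})

test_that("grids beyond the memory budget are refused", {
  fx <- qm_fixture("h2_sto3g")
  g <- default_grid(fx$atoms, 0.1, 7)
  expect_error(eval_grid(qm_model("h2_sto3g"), g, max_voxels = 1000),
               "memory budget")
})

test_that("laplacian grids agree with pointwise evaluation", {
  m <- qm_model("h2_sto3g")
  g <- default_grid(m$wavefunction$atoms, 0.5, 3)
  fl <- eval_grid(m, g, quantity = "laplacian")
  i <- c(3L, 4L, 5L)
  p <- g$origin + (i - 1) * 0.5
  expect_equal(fl$values[i[1], i[2], i[3]], eval_point(m, p)$laplacian,
               tolerance = 1e-12)
})

test_that("active-space perturbations cannot touch the HCN molecular axis", {
  # the (4,4) active space holds only pi/pi* orbitals, whose nodal planes
  # contain the axis: any change to the active block leaves axial rho fixed
  fx <- qm_fixture("hcn_sto3g")
  m0 <- qm_model("hcn_sto3g")
  zax <- seq(-2.5, 3.0, length.out = 40)
  pts <- cbind(0, 0, zax)
  base <- densiwit:::density_batch(m0, pts, 0)$rho
  set.seed(77)
  for (i in 1:5) {
    pert <- fx$rdm
    pert$matrix <- pert$matrix + matrix(rnorm(16, sd = 0.2), 4)
    mp <- density_model(fx$wavefunction, pert)
    got <- densiwit:::density_batch(mp, pts, 0)$rho
    expect_lt(max(abs(got - base)), 1e-12)
  }
})
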