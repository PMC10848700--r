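# Analytic evaluation of the electron density rho(r) = sum_pq D_pq
# phi_p(r) phi_q(r), its gradient, Hessian and Laplacian, from Gaussian-basis
# molecular orbitals and a full-space 1-RDM.  The model diagonalizes D once
# (natural orbitals), so per-point work scales with the number of occupied
# natural orbitals; all derivatives are analytic (finite differences appear
# only in test oracles).

#' Density model: wavefunction plus full-space 1-RDM
#'
#' The 1-RDM is symmetrized exactly at construction (its defining symmetry),
#' then diagonalized into natural orbitals; natural occupations below 1e-14
#' in magnitude are dropped.
#'
#' @param wavefunction a `wavefunction` (see [read_molden()])
#' @param rdm a full-space [one_rdm()] over the wavefunction's MOs, or an
#'   active-space one (it is then embedded via [embed_active()])
#' @return a `density_model` object
#' @export
density_model <- function(wavefunction, rdm) {
  stopifnot(inherits(rdm, "one_rdm"))
  validate_wavefunction(wavefunction)
  if (rdm$space == "active") rdm <- embed_active(rdm)
  nmo <- nrow(wavefunction$mos$coefficients)
  if (nrow(rdm$matrix) != nmo) {
    stop("1-RDM dimension (", nrow(rdm$matrix),
         ") does not match the MO count (", nmo, ")")
  }
  d <- (rdm$matrix + t(rdm$matrix)) / 2
  eig <- eigen(d, symmetric = TRUE)
  keep <- abs(eig$values) > 1e-14
  cno <- t(eig$vectors[, keep, drop = FALSE]) %*%
    wavefunction$mos$coefficients
  structure(list(wavefunction = wavefunction, rdm = rdm,
                 basis = basis_tables(wavefunction),
                 no_occ = eig$values[keep],
                 no_coef = unname(cno)),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> %s; %d natural orbitals, electron count %.6f\n",
              x$wavefunction$label, length(x$no_occ), sum(diag(x$rdm$matrix))))
  invisible(x)
}

# rho (and derivatives) at arbitrary points; order 0 = value, 1 = +gradient,
# 2 = +Hessian/Laplacian
density_batch <- function(model, points, order = 0) {
  points <- matrix(as.numeric(points), ncol = 3)
  res <- cpp_eval_density(points, model$basis, model$no_coef,
                          model$no_occ, as.integer(order))
  if (order > 1) {
    res$lap <- res$hess[, 1] + res$hess[, 5] + res$hess[, 9]
  }
  res
}

#' Evaluate the density and its derivatives at one point
#'
#' @param model a [density_model()]
#' @param position 3-vector, bohr
#' @return a `point_evaluation` list: `position`, `rho` (e bohr^-3),
#'   `gradient` (e bohr^-4), `hessian` (symmetric 3x3, e bohr^-5), and
#'   `laplacian` (trace of the Hessian, e bohr^-5)
#' @export
eval_point <- function(model, position) {
  stopifnot(length(position) == 3, all(is.finite(position)))
  r <- density_batch(model, matrix(position, 1), order = 2)
  structure(list(position = as.numeric(position),
                 rho = r$rho[1],
                 gradient = as.numeric(r$grad[1, ]),
                 hessian = matrix(r$hess[1, ], 3, 3),
                 laplacian = r$lap[1]),
            class = "point_evaluation")
}

#' Default evaluation grid for a molecule
#'
#' Uniform axis-aligned grid with the stated spacing, extending `margin`
#' bohr beyond the farthest nucleus in each direction.  Spatially extended
#' systems (e.g. a dimer with a diffuse midbond attractor) should use the
#' larger margin of 8 bohr.
#'
#' @param atoms an [atom_sites()] data frame
#' @param spacing grid spacing, bohr (default 0.1)
#' @param margin margin beyond the farthest nucleus, bohr (default 7)
#' @return a [grid_spec()]
#' @export
default_grid <- function(atoms, spacing = 0.1, margin = 7.0) {
  stopifnot(spacing > 0, margin > 0)
  pos <- atom_positions(atoms)
  lo <- apply(pos, 2, min) - margin
  hi <- apply(pos, 2, max) + margin
  # grid anchored at the bounding-box center with an even voxel count per
  # dimension: symmetric molecules then get exactly mirror-symmetric
  # sampling (and no voxel sits on a mirror plane), so symmetry-equivalent
  # basins receive identical populations
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  shape <- shape + shape %% 2L
  ctr <- (lo + hi) / 2
  origin <- ctr - (shape - 1) / 2 * spacing
  grid_spec(origin, diag(rep(spacing, 3)), shape)
}

#' Sample the density (or its Laplacian) on a grid
#'
#' @param model a [density_model()]
#' @param grid a [grid_spec()]
#' @param quantity `"density"` or `"laplacian"`
#' @param max_voxels memory budget: grids with more voxels raise an error
#' @return a [scalar_field()]
#' @export
eval_grid <- function(model, grid, quantity = c("density", "laplacian"),
                      max_voxels = 5e7) {
  quantity <- match.arg(quantity)
  nv <- prod(grid$shape)
  if (nv > max_voxels) {
    stop("grid has ", nv, " voxels, exceeding the memory budget of ",
         max_voxels, " (raise max_voxels if intended)")
  }
  if (quantity == "density") {
    v <- cpp_eval_density_grid(grid$origin, grid$axes, grid$shape,
                               model$basis, model$no_coef, model$no_occ)
  } else {
    pts <- grid_points(grid)
    v <- numeric(nv)
    chunk <- 262144L
    for (from in seq(1L, nv, by = chunk)) {
      to <- min(from + chunk - 1L, nv)
      v[from:to] <- density_batch(model, pts[from:to, , drop = FALSE],
                                  order = 2)$lap
    }
  }
  scalar_field(grid, array(v, dim = grid$shape), quantity)
}

#' Integrate a density field (Riemann sum times voxel volume)
#'
#' @param field a [scalar_field()] with `quantity = "density"`
#' @return the integral, electrons
#' @export
integrate_density <- function(field) {
  if (field$quantity != "density") {
    stop("integrate_density expects a density field")
  }
  sum(field$values) * voxel_volume(field$grid)
}

#' Pointwise difference of two model densities on a shared grid
#'
#' @param a,b [density_model()] objects on the same geometry
#' @param grid a [grid_spec()]
#' @return a [scalar_field()] with `quantity = "difference"`; its integral
#'   equals `Tr(D_a) - Tr(D_b)` to within the grid tolerance
#' @export
density_difference <- function(a, b, grid) {
  fa <- eval_grid(a, grid)
  fb <- eval_grid(b, grid)
  scalar_field(grid, fa$values - fb$values, "difference")
}
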