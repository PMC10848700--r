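# Shared helpers: memoized fixture models and feature sets (the heavy
# topology runs are reused across test files), finite-difference oracles for
# the analytic derivatives, and closed-form toy systems.

.qm_cache <- new.env(parent = emptyenv())

qm_memo <- function(key, expr) {
  if (!exists(key, envir = .qm_cache)) {
    assign(key, force(expr), envir = .qm_cache)
  }
  get(key, envir = .qm_cache)
}

qm_fixture <- function(id) qm_memo(paste0("fx_", id), load_fixture(id))

qm_model <- function(id) {
  qm_memo(paste0("model_", id), {
    fx <- qm_fixture(id)
    density_model(fx$wavefunction, fx$rdm)
  })
}

qm_cps <- function(id) qm_memo(paste0("cps_", id), find_cps(qm_model(id)))

qm_charges <- function(id, spacing) {
  qm_memo(sprintf("charges_%s_%g", id, spacing), {
    fx <- qm_fixture(id)
    m <- qm_model(id)
    map <- suppressMessages(assign_basins(
      m, default_grid(fx$atoms, spacing, fx$margin), cps = qm_cps(id)))
    basin_charges(map, m)
  })
}

qm_features <- function(id, spacing) {
  qm_memo(sprintf("features_%s_%g", id, spacing), {
    fx <- qm_fixture(id)
    suppressMessages(extract_features(qm_model(id), spacing = spacing,
                                      margin = fx$margin))
  })
}

# central finite differences of rho (order-0 evaluations only), the
# independent oracle for the analytic gradient/Hessian/Laplacian;
# Richardson-extrapolated (h and h/2) so the oracle keeps 1e-6 relative
# accuracy even near nuclei where fourth derivatives are huge
fd_point <- function(model, p, h = 4e-4) {
  f <- function(q) densiwit:::density_batch(model, matrix(q, 1), 0)$rho[1]
  fd_once <- function(h) {
    g <- numeric(3)
    hess <- matrix(0, 3, 3)
    for (d in 1:3) {
      ep <- numeric(3); ep[d] <- h
      g[d] <- (f(p + ep) - f(p - ep)) / (2 * h)
      hess[d, d] <- (f(p + ep) - 2 * f(p) + f(p - ep)) / h^2
    }
    for (d1 in 1:2) {
      for (d2 in (d1 + 1):3) {
        e1 <- numeric(3); e1[d1] <- h
        e2 <- numeric(3); e2[d2] <- h
        hess[d1, d2] <- hess[d2, d1] <-
          (f(p + e1 + e2) - f(p + e1 - e2) - f(p - e1 + e2) +
             f(p - e1 - e2)) / (4 * h^2)
      }
    }
    list(gradient = g, hessian = hess)
  }
  a <- fd_once(h)
  b <- fd_once(h / 2)
  g <- (4 * b$gradient - a$gradient) / 3
  hess <- (4 * b$hessian - a$hessian) / 3
  list(gradient = g, hessian = hess, laplacian = sum(diag(hess)))
}

# two equal s-Gaussian lumps exp(-beta |r -/+ a x|^2); beta = 2 alpha
two_lump_model <- function(a, beta = 1) {
  toy_gaussian_system(rbind(c(-a, 0, 0), c(a, 0, 0)),
                      exponents = rep(beta / 2, 2), weights = c(1, 1))
}

# closed-form two-lump density on the x axis
two_lump_rho <- function(x, a, beta = 1) {
  n2 <- (beta / pi)^1.5
  n2 * (exp(-beta * (x - a)^2) + exp(-beta * (x + a)^2))
}

rel_err <- function(got, want, floor = 1e-10) {
  abs(got - want) / pmax(abs(want), floor)
}
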