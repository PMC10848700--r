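# Expansion of Gaussian shells into the flattened per-AO monomial/primitive
# tables consumed by the compiled density evaluator.  Each AO is a polynomial
# P(x,y,z) (one or more monomials) times a shared radial contraction
# sum_p c_p N_p exp(-a_p r^2); derivatives are taken analytically in C++.

# Cartesian component orders within a shell (Molden dialect)
cart_components <- function(l) {
  switch(as.character(l),
    "0" = matrix(c(0L, 0L, 0L), 1, 3),
    "1" = rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)),
    "2" = rbind(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
                c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L)),
    "3" = rbind(c(3L, 0L, 0L), c(0L, 3L, 0L), c(0L, 0L, 3L),
                c(1L, 2L, 0L), c(2L, 1L, 0L), c(2L, 0L, 1L),
                c(1L, 0L, 2L), c(0L, 1L, 2L), c(0L, 2L, 1L),
                c(1L, 1L, 1L)),
    stop("unsupported angular momentum l = ", l))
}

# Real solid harmonics as monomial tables (rows: i, j, k, coefficient),
# Molden m order 0, +1, -1, +2, -2 (, +3, -3).  Scaled so each spherical
# function shares the axial component's normalization.
sph_monomials <- function(l) {
  if (l == 2) {
    list(
      rbind(c(0, 0, 2, 1), c(2, 0, 0, -0.5), c(0, 2, 0, -0.5)),
      rbind(c(1, 0, 1, sqrt(3))),
      rbind(c(0, 1, 1, sqrt(3))),
      rbind(c(2, 0, 0, sqrt(3) / 2), c(0, 2, 0, -sqrt(3) / 2)),
      rbind(c(1, 1, 0, sqrt(3))))
  } else if (l == 3) {
    list(
      rbind(c(0, 0, 3, 1), c(2, 0, 1, -1.5), c(0, 2, 1, -1.5)),
      rbind(c(1, 0, 2, sqrt(6)), c(3, 0, 0, -sqrt(6) / 4),
            c(1, 2, 0, -sqrt(6) / 4)),
      rbind(c(0, 1, 2, sqrt(6)), c(0, 3, 0, -sqrt(6) / 4),
            c(2, 1, 0, -sqrt(6) / 4)),
      rbind(c(2, 0, 1, sqrt(15) / 2), c(0, 2, 1, -sqrt(15) / 2)),
      rbind(c(1, 1, 1, sqrt(15))),
      rbind(c(3, 0, 0, sqrt(10) / 4), c(1, 2, 0, -3 * sqrt(10) / 4)),
      rbind(c(2, 1, 0, 3 * sqrt(10) / 4), c(0, 3, 0, -sqrt(10) / 4)))
  } else {
    stop("spherical functions only defined for l >= 2")
  }
}

# Flattened AO description for the compiled evaluator
basis_tables <- function(wf) {
  pows <- list()
  mcoef <- list()
  pexp <- list()
  pcoef <- list()
  center <- list()
  nmono <- integer(0)
  nprim <- integer(0)
  pos <- atom_positions(wf$atoms)
  for (sh in wf$shells) {
    l <- sh$l
    ctr <- pos[sh$center_index, ]
    primc <- sh$coefficients * prim_norm_axial(sh$exponents, l)
    if (sh$spherical && l >= 2) {
      for (tab in sph_monomials(l)) {
        pows[[length(pows) + 1]] <- matrix(as.integer(tab[, 1:3]), ncol = 3)
        mcoef[[length(mcoef) + 1]] <- tab[, 4]
        pexp[[length(pexp) + 1]] <- sh$exponents
        pcoef[[length(pcoef) + 1]] <- primc
        center[[length(center) + 1]] <- ctr
        nmono <- c(nmono, nrow(tab))
        nprim <- c(nprim, length(sh$exponents))
      }
    } else {
      comps <- cart_components(l)
      for (ci in seq_len(nrow(comps))) {
        ijk <- comps[ci, ]
        ratio <- sqrt(double_factorial(2 * l - 1) /
                        (double_factorial(2 * ijk[1] - 1) *
                         double_factorial(2 * ijk[2] - 1) *
                         double_factorial(2 * ijk[3] - 1)))
        pows[[length(pows) + 1]] <- matrix(ijk, 1, 3)
        mcoef[[length(mcoef) + 1]] <- ratio
        pexp[[length(pexp) + 1]] <- sh$exponents
        pcoef[[length(pcoef) + 1]] <- primc
        center[[length(center) + 1]] <- ctr
        nmono <- c(nmono, 1L)
        nprim <- c(nprim, length(sh$exponents))
      }
    }
  }
  list(nmono = nmono, nprim = nprim,
       pows = do.call(rbind, pows),
       mcoef = as.numeric(unlist(mcoef)),
       pexp = as.numeric(unlist(pexp)),
       pcoef = as.numeric(unlist(pcoef)),
       center = do.call(rbind, center))
}
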