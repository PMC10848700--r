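# 1-RDM handling: symmetrization, trace rescaling, the combined mitigation,
# frozen-core embedding, error decomposition, and the synthetic noise
# channels.

active_rdm <- function(m, nel = 2L, frozen = integer(0),
                       nmo = nrow(m) + length(frozen)) {
  one_rdm(m, space = "active", frozen_indices = frozen,
          active_indices = setdiff(seq_len(nmo), frozen)[seq_len(nrow(m))],
          n_active_electrons = nel, n_mo_total = nmo)
}

test_that("symmetrize averages off-diagonal pairs and preserves the trace", {
  r <- active_rdm(rbind(c(1.0, 0.2), c(0.4, 1.0)))
  s <- symmetrize(r)
  expect_equal(s$matrix, rbind(c(1.0, 0.3), c(0.3, 1.0)),
               tolerance = 1e-15)

  expect_identical(symmetrize(s)$matrix, s$matrix)  # idempotent

  anti <- active_rdm(rbind(c(0.5, -0.1), c(0.1, 0.5)))
  expect_identical(symmetrize(anti)$matrix, rbind(c(0.5, 0), c(0, 0.5)))

  set.seed(7)
  m <- matrix(rnorm(16), 4)
  expect_identical(sum(diag(symmetrize(active_rdm(m, 4))$matrix)),
                   sum(diag(m)))
})

test_that("rescale_trace restores the electron count by uniform scaling", {
  set.seed(11)
  m <- matrix(rnorm(9, sd = 0.1), 3)
  m <- (m + t(m)) / 2
  diag(m) <- c(0.9, 0.68, 0.3)          # trace 1.88
  r <- rescale_trace(active_rdm(m, 2L))
  expect_identical(r$matrix, m * (2 / 1.88))
  expect_equal(sum(diag(r$matrix)), 2, tolerance = 1e-14)
  # uniform scaling preserves eigenvectors exactly
  expect_equal(eigen(r$matrix)$vectors, eigen(m)$vectors, tolerance = 1e-12)

  ok <- active_rdm(diag(c(1.2, 0.8, 0)), 2L)
  expect_identical(rescale_trace(ok)$matrix, ok$matrix)

  expect_error(rescale_trace(active_rdm(matrix(0, 2, 2))), "not positive")
  expect_error(rescale_trace(active_rdm(diag(c(-1, 0.5)))), "not positive")
})

test_that("mitigate composes symmetrization and rescaling and is idempotent", {
  m <- rbind(c(0.8, 0.3, 0.0), c(0.1, 0.9, -0.2), c(0.0, 0.05, 0.25))
  r <- mitigate(active_rdm(m, 2L))
  expect_equal(r$matrix, t(r$matrix))
  expect_equal(sum(diag(r$matrix)), 2, tolerance = 1e-14)
  expect_match(r$provenance, "^mitigated")

  # fixed point on an already clean matrix
  clean <- active_rdm(diag(c(1.5, 0.5)), 2L)
  expect_equal(mitigate(clean)$matrix, clean$matrix, tolerance = 1e-15)

  # idempotence
  r2 <- mitigate(r)
  expect_equal(r2$matrix, r$matrix, tolerance = 1e-14)
})

test_that("embed_active places frozen cores and the active block", {
  for (cfg in list(list(id = "h2_sto3g", total = 2),
                   list(id = "lih_sto3g", total = 4),
                   list(id = "li2_sto3g", total = 6),
                   list(id = "hcn_sto3g", total = 14),
                   list(id = "hcn_631g", total = 14))) {
    rdm <- qm_fixture(cfg$id)$rdm
    if (rdm$space == "active") {
      full <- embed_active(rdm)
      expect_equal(sum(diag(full$matrix)), cfg$total, tolerance = 1e-9)
      expect_equal(diag(full$matrix)[full$frozen_indices],
                   rep(2, length(full$frozen_indices)))
      expect_equal(full$matrix[full$active_indices, full$active_indices],
                   rdm$matrix)
      # everything outside frozen diagonal and active block is zero
      probe <- full$matrix
      probe[full$active_indices, full$active_indices] <- 0
      diag(probe)[full$frozen_indices] <- 0
      expect_equal(max(abs(probe)), 0)
    }
  }
  bad <- one_rdm(diag(2) , space = "active", frozen_indices = 1L,
                 active_indices = c(2L, 3L), n_active_electrons = 2L,
                 n_mo_total = 3L)
  expect_error(embed_active(bad, n_mo_total = 2L), "exceed")
})

test_that("error_stats decomposes errors into symmetric and antisymmetric parts", {
  ref <- active_rdm(rbind(c(1.0, 0.3), c(0.3, 1.0)))
  same <- error_stats(ref, ref)
  expect_equal(max(abs(same$error_matrix)), 0)
  expect_equal(same$asymmetry_norm, 0)

  noisy <- active_rdm(rbind(c(1.0, 0.2), c(0.4, 1.0)))
  es <- error_stats(noisy, ref)
  expect_equal(es$asymmetric_part, rbind(c(0, -0.1), c(0.1, 0)))
  expect_equal(es$symmetric_part, matrix(0, 2, 2))

  set.seed(3)
  pert <- active_rdm(ref$matrix + matrix(rnorm(4, sd = 0.05), 2))
  es <- error_stats(pert, ref, shots = 400)
  expect_equal(es$symmetric_part + es$asymmetric_part, es$error_matrix,
               tolerance = 1e-15)
  expect_equal(es$asymmetric_part, -t(es$asymmetric_part))
  expect_equal(es$electron_count_sd, sqrt(2) / sqrt(400))
})

test_that("noise channels have the right limits and drift direction", {
  fx <- qm_fixture("li2_sto3g")
  d0 <- fx$rdm

  # lambda = 0 depolarizing is the identity map, bit for bit
  expect_identical(apply_noise(d0, noise_spec("depolarizing", 0))$matrix,
                   d0$matrix)
  # lambda = 1 gives the identity matrix; the embedded count overshoots
  lim <- apply_noise(d0, noise_spec("depolarizing", 1))
  expect_equal(lim$matrix, diag(4))
  expect_gt(sum(diag(embed_active(lim)$matrix)), 6)
  # partial depolarizing also overcounts (the simulator's direction)
  dep <- apply_noise(d0, noise_spec("depolarizing", 0.14))
  expect_gt(sum(diag(embed_active(dep)$matrix)), 6)
  # damping undercounts (the hardware direction)
  dmp <- apply_noise(d0, noise_spec("damping", 0.06))
  expect_lt(sum(diag(embed_active(dmp)$matrix)), 6)

  # seeded reproducibility of the shot channel
  s1 <- apply_noise(d0, noise_spec("shot", shots = 1e4, seed = 5))
  s2 <- apply_noise(d0, noise_spec("shot", shots = 1e4, seed = 5))
  s3 <- apply_noise(d0, noise_spec("shot", shots = 1e4, seed = 6))
  expect_identical(s1$matrix, s2$matrix)
  expect_false(identical(s1$matrix, s3$matrix))
  # the shot channel must not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(apply_noise(d0, noise_spec("shot", seed = 2)))
  expect_identical(rnorm(1), before)
})

test_that("shot-noise asymmetry shrinks as one over the square root of M", {
  d0 <- qm_fixture("lih_sto3g")$rdm
  shots <- c(1e2, 1e4, 1e6)
  mean_asym <- vapply(shots, function(M) {
    mean(vapply(1:100, function(s) {
      noisy <- apply_noise(d0, noise_spec("shot", shots = M, seed = s))
      error_stats(noisy, d0)$asymmetry_norm
    }, 1))
  }, 1)
  expect_true(all(mean_asym > 0))
  slope <- diff(log(mean_asym)) / diff(log(shots))
  expect_equal(slope, c(-0.5, -0.5), tolerance = 0.02)
})

test_that("mitigation undoes the depolarizing count drift for any lambda < 1", {
  d0 <- qm_fixture("li2_sto3g")$rdm
  for (lam in c(0.05, 0.3, 0.6, 0.9)) {
    noisy <- apply_noise(d0, noise_spec("depolarizing", lam))
    fixed <- embed_active(mitigate(noisy))
    expect_equal(sum(diag(fixed$matrix)), 6, tolerance = 1e-12)
  }
})
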