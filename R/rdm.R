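# One-particle reduced density matrices (1-RDMs): representation, embedding
# of an active-space block into the full MO space, synthetic noise channels,
# and the two-step error mitigation (off-diagonal symmetrization followed by
# trace rescaling to the exact electron number).
#
# Convention: spin-summed spatial 1-RDM over restricted MOs, so physical
# occupations lie in [0, 2] and the trace equals the number of electrons
# covered by the matrix.

#' One-particle reduced density matrix
#'
#' @param matrix real square matrix D over spatial MOs (spin-summed)
#' @param space `"active"` if the matrix covers only the active orbitals,
#'   `"full"` if it covers the whole MO space
#' @param frozen_indices 1-based MO indices kept doubly occupied (frozen core
#'   plus any doubly occupied inactive valence orbitals)
#' @param active_indices 1-based MO indices of the active space
#' @param n_active_electrons number of electrons in the active space
#' @param n_mo_total total number of MOs in the full space
#' @param provenance free-form provenance string
#' @return a `one_rdm` object
#' @export
one_rdm <- function(matrix, space = c("active", "full"),
                    frozen_indices = integer(0),
                    active_indices = seq_len(nrow(matrix)),
                    n_active_electrons,
                    n_mo_total = max(c(active_indices, frozen_indices, 0L)),
                    provenance = "") {
  space <- match.arg(space)
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || is.complex(matrix)) {
    stop("1-RDM entries must be real")
  }
  if (nrow(matrix) != ncol(matrix)) stop("1-RDM must be square")
  stopifnot(all(is.finite(matrix)))
  frozen_indices <- as.integer(frozen_indices)
  active_indices <- as.integer(active_indices)
  if (length(intersect(frozen_indices, active_indices))) {
    stop("frozen and active index sets overlap")
  }
  if (space == "full" && nrow(matrix) != n_mo_total) {
    stop("full-space 1-RDM dimension (", nrow(matrix),
         ") does not match mo_space_size (", n_mo_total, ")")
  }
  if (space == "active" && nrow(matrix) != length(active_indices)) {
    stop("active-space 1-RDM dimension does not match active_indices")
  }
  tr <- sum(diag(matrix))
  if (tr > 2 * nrow(matrix) + 1e-9) {
    warning(sprintf("1-RDM trace %.4f exceeds 2 x n_orbitals = %d; matrix is wildly unphysical", tr, 2L * nrow(matrix)))
  }
  structure(list(matrix = unname(matrix), space = space,
                 frozen_indices = frozen_indices,
                 active_indices = active_indices,
                 n_active_electrons = as.integer(n_active_electrons),
                 n_total_electrons = as.integer(n_active_electrons +
                                                  2L * length(frozen_indices)),
                 n_mo_total = as.integer(n_mo_total),
                 provenance = as.character(provenance)),
            class = "one_rdm")
}

#' @export
print.one_rdm <- function(x, ...) {
  cat(sprintf("<one_rdm> %dx%d (%s space), trace %.6f, %d active e-, %d frozen orbitals\n  %s\n",
              nrow(x$matrix), ncol(x$matrix), x$space, sum(diag(x$matrix)),
              x$n_active_electrons, length(x$frozen_indices), x$provenance))
  invisible(x)
}

rdm_update <- function(rdm, matrix = rdm$matrix, note = NULL) {
  rdm$matrix <- unname(as.matrix(matrix))
  if (!is.null(note)) rdm$provenance <- paste0(note, ": ", rdm$provenance)
  rdm
}

#' Symmetrize a 1-RDM
#'
#' Enforces the transpose symmetry implied by hermiticity of the 1-RDM with
#' real orbitals by averaging each pair of off-diagonal elements:
#' out_pq = out_qp = (in_pq + in_qp) / 2.  The diagonal (and therefore the
#' trace) is unchanged.
#'
#' @param rdm a [one_rdm()]
#' @return the symmetrized [one_rdm()]
#' @export
symmetrize <- function(rdm) {
  stopifnot(inherits(rdm, "one_rdm"))
  rdm_update(rdm, (rdm$matrix + t(rdm$matrix)) / 2, note = "symmetrized")
}

#' Rescale a 1-RDM so its trace equals the electron number
#'
#' Multiplies the entire matrix (diagonal and off-diagonal elements are
#' subject to the same rescaling) by n_el / Tr(D), where n_el is the number
#' of electrons the matrix should account for: the active electron count for
#' an active-space matrix, the total electron count for a full-space one.
#'
#' @param rdm a [one_rdm()]
#' @return the rescaled [one_rdm()]; its trace equals the target electron
#'   count to machine precision
#' @export
rescale_trace <- function(rdm) {
  stopifnot(inherits(rdm, "one_rdm"))
  target <- if (rdm$space == "active") rdm$n_active_electrons else
    rdm$n_total_electrons
  tr <- sum(diag(rdm$matrix))
  if (tr <= 0) {
    stop("1-RDM trace is not positive (", format(tr),
         "); trace rescaling is impossible")
  }
  rdm_update(rdm, rdm$matrix * (target / tr), note = "rescaled")
}

#' Mitigate measurement noise on a 1-RDM
#'
#' The two-step mitigation: [symmetrize()] (restores hermiticity broken by
#' finite sampling) followed by [rescale_trace()] (restores particle number).
#' The operation is idempotent.
#'
#' @param rdm a [one_rdm()]
#' @return the mitigated [one_rdm()], flagged in its provenance
#' @export
mitigate <- function(rdm) {
  out <- rescale_trace(symmetrize(rdm))
  out$provenance <- paste0("mitigated: ",
                           sub("^(rescaled: |symmetrized: )+", "",
                               out$provenance))
  out
}

#' Embed an active-space 1-RDM into the full MO space
#'
#' Frozen-core (and doubly occupied inactive valence) orbitals receive 2.0 on
#' the diagonal; the active block is inserted at the active indices; all
#' remaining entries are zero.
#'
#' @param rdm a [one_rdm()] with `space = "active"`
#' @param n_mo_total total MO count of the embedding space (defaults to the
#'   bundle's `mo_space_size`)
#' @return a full-space [one_rdm()] with trace
#'   `2 * length(frozen_indices) + Tr(D_active)`
#' @export
embed_active <- function(rdm, n_mo_total = rdm$n_mo_total) {
  stopifnot(inherits(rdm, "one_rdm"))
  if (rdm$space != "active") stop("embed_active expects an active-space 1-RDM")
  idx <- c(rdm$frozen_indices, rdm$active_indices)
  if (any(idx < 1 | idx > n_mo_total)) {
    stop("frozen/active indices exceed the MO space size")
  }
  if (anyDuplicated(idx)) stop("frozen and active indices collide")
  full <- matrix(0, n_mo_total, n_mo_total)
  diag(full)[rdm$frozen_indices] <- 2
  full[rdm$active_indices, rdm$active_indices] <- rdm$matrix
  one_rdm(full, space = "full", frozen_indices = rdm$frozen_indices,
          active_indices = rdm$active_indices,
          n_active_electrons = rdm$n_active_electrons,
          n_mo_total = n_mo_total,
          provenance = paste0("embedded: ", rdm$provenance))
}

#' Noise channel specification
#'
#' Three synthetic channels acting on an active-space 1-RDM emulate the
#' error modes seen on quantum hardware and simulators:
#' \describe{
#'   \item{depolarizing}{`D' = (1 - lambda) D + lambda I`: every spatial
#'     orbital drifts toward occupation 1 (the spin-summed image of the
#'     maximally mixed state); overcounts electrons whenever the active
#'     trace is below half filling.}
#'   \item{damping}{`D' = (1 - lambda) D`: uniform decay toward the empty
#'     state; undercounts electrons.}
#'   \item{shot}{adds independent zero-mean Gaussian noise with standard
#'     deviation `1/sqrt(shots)` to every entry independently, so (p,q) and
#'     (q,p) deviate independently -- the sole source of diagonally
#'     asymmetric errors.}
#' }
#'
#' @param kind `"depolarizing"`, `"damping"` or `"shot"`
#' @param strength channel strength lambda in `[0, 1]` (ignored for shot)
#' @param shots number of measurement samples M >= 1 (shot channel)
#' @param seed RNG seed (all stochastic operations are seeded; default 0)
#' @return a `noise_spec` object
#' @export
noise_spec <- function(kind = c("depolarizing", "damping", "shot"),
                       strength = 0, shots = 1e6, seed = 0) {
  kind <- match.arg(kind)
  stopifnot(strength >= 0, strength <= 1, shots >= 1)
  structure(list(kind = kind, strength = strength,
                 shots = as.numeric(shots), seed = as.integer(seed)),
            class = "noise_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Apply a synthetic noise channel to an active-space 1-RDM
#'
#' @param rdm a [one_rdm()] with `space = "active"`
#' @param spec a [noise_spec()]
#' @return the perturbed [one_rdm()] (reproducible given the spec's seed)
#' @export
apply_noise <- function(rdm, spec) {
  stopifnot(inherits(rdm, "one_rdm"), inherits(spec, "noise_spec"))
  if (rdm$space != "active") stop("apply_noise expects an active-space 1-RDM")
  n <- nrow(rdm$matrix)
  m <- switch(spec$kind,
    depolarizing = (1 - spec$strength) * rdm$matrix +
      spec$strength * diag(n),
    damping = (1 - spec$strength) * rdm$matrix,
    shot = rdm$matrix + with_seed(spec$seed,
      matrix(rnorm(n * n, sd = 1 / sqrt(spec$shots)), n, n)))
  rdm_update(rdm, m, note = sprintf("noise[%s]", spec$kind))
}

#' Elementwise error decomposition of a noisy 1-RDM
#'
#' The error matrix eps = D - D_ref splits into a diagonally symmetric part
#' (eps + t(eps))/2 and an antisymmetric part (eps - t(eps))/2; under ideal
#' measurement assumptions the antisymmetric part arises solely from finite
#' sampling.
#'
#' @param noisy,reference [one_rdm()] objects of identical shape and space
#' @param shots optional sample count; when given, the standard deviation of
#'   the trace-derived electron count is reported as
#'   `sqrt(n_orbitals) / sqrt(shots)` (independent Gaussian errors of width
#'   `1/sqrt(shots)` on each of the n diagonal entries)
#' @return an `error_report` list: `error_matrix`, `symmetric_part`,
#'   `asymmetric_part`, `asymmetry_norm` (Frobenius), `electron_count`
#'   (from the frozen-core-embedded trace) and `electron_count_sd`
#' @export
error_stats <- function(noisy, reference, shots = NULL) {
  stopifnot(inherits(noisy, "one_rdm"), inherits(reference, "one_rdm"))
  if (!identical(dim(noisy$matrix), dim(reference$matrix)) ||
      noisy$space != reference$space) {
    stop("noisy and reference 1-RDMs must share shape and space")
  }
  eps <- noisy$matrix - reference$matrix
  s <- (eps + t(eps)) / 2
  a <- (eps - t(eps)) / 2
  count <- sum(diag(noisy$matrix)) +
    if (noisy$space == "active") 2 * length(noisy$frozen_indices) else 0
  structure(list(
    error_matrix = eps, symmetric_part = s, asymmetric_part = a,
    asymmetry_norm = sqrt(sum(a^2)),
    electron_count = count,
    electron_count_sd = if (is.null(shots)) NA_real_ else
      sqrt(nrow(eps)) / sqrt(shots)),
    class = "error_report")
}
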