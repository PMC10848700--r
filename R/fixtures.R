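# Bundled benchmark systems (committed, checksum-pinned fixture files
# generated by inst/scripts/make_fixtures.py), fully synthetic toy Gaussian
# systems with closed-form densities, and the experiment driver that reruns
# the noise-free / noisy / mitigated comparisons.

#' Analytic toy Gaussian system
#'
#' Builds a density model whose density is exactly
#' `rho(r) = sum_i w_i N_i^2 exp(-2 a_i |r - c_i|^2)` with
#' `N_i = (2 a_i / pi)^(3/4)`: one normalized s orbital per center and a
#' diagonal 1-RDM of the weights.  Used as a closed-form oracle for the
#' density evaluator and the critical-point machinery.
#'
#' @param centers matrix (n x 3) of centers, bohr
#' @param exponents positive Gaussian exponents, one per center
#' @param weights positive weights (occupations), one per center
#' @return a [density_model()]
#' @export
toy_gaussian_system <- function(centers, exponents, weights) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  stopifnot(length(exponents) == n, length(weights) == n,
            all(exponents > 0), all(weights > 0))
  atoms <- atom_sites(rep("H", n), centers)
  shells <- lapply(seq_len(n), function(i) {
    list(center_index = i, l = 0L, spherical = FALSE,
         exponents = exponents[i], coefficients = 1.0)
  })
  wf <- structure(list(
    atoms = atoms, shells = shells,
    mos = list(coefficients = diag(n), occupations = pmin(weights, 2),
               energies = NULL, ao_order = "one s AO per center"),
    label = sprintf("toy gaussian system (%d centers)", n)),
    class = "wavefunction")
  rdm <- one_rdm(diag(weights, n), space = "full",
                 frozen_indices = integer(0), active_indices = seq_len(n),
                 n_active_electrons = round(sum(weights)), n_mo_total = n,
                 provenance = "toy gaussian system")
  density_model(wf, rdm)
}

#' Catalog of bundled fixture systems
#'
#' Each bundle carries a geometry (XYZ), an RHF wavefunction (Molden) and a
#' noise-free active-space 1-RDM from exact diagonalization in the active
#' space (JSON), generated once by `inst/scripts/make_fixtures.py` and
#' checksum-pinned.  `hcn_sto3g` and `hcn_631g` share one geometry; the
#' spatially extended Li2 is flagged diffuse (grid margin 8 bohr).
#'
#' @return data frame with columns `id`, `molecule`, `basis`,
#'   `active_space`, `margin`, `witness`
#' @export
fixture_catalog <- function() {
  data.frame(
    id = c("h2_sto3g", "lih_sto3g", "li2_sto3g", "hcn_sto3g", "hcn_631g",
           "h2_witness_augccpvtz"),
    molecule = c("H2", "LiH", "Li2", "HCN", "HCN", "H2"),
    basis = c("STO-3G", "STO-3G", "STO-3G", "STO-3G", "6-31G",
              "aug-cc-pVTZ"),
    active_space = c("(2,2)", "(2,3)", "(2,4)", "(4,4)", "(4,4)", "full"),
    margin = c(7, 7, 8, 7, 7, 7),
    witness = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "densiwit")
  if (!nzchar(p)) stop("bundled fixture file not found: ", file)
  p
}

fixture_manifest <- function() {
  jsonlite::fromJSON(fixture_path("MANIFEST.json"))
}

check_fixture_file <- function(file) {
  p <- fixture_path(file)
  want <- fixture_manifest()[[file]]
  got <- unname(tools::md5sum(p))
  if (!identical(got, want)) {
    stop("fixture checksum mismatch for ", file,
         " (corrupted installation?): ", got, " != ", want)
  }
  p
}

#' Load a bundled fixture
#'
#' Verifies the pinned checksum of every file before parsing.
#'
#' @param id a fixture id from [fixture_catalog()]
#' @return list with `id`, `atoms`, `wavefunction`, `rdm` (the noise-free
#'   active-space [one_rdm()]), `margin`, and `refpoints` (independent
#'   generator-computed density samples for cross-checks)
#' @export
load_fixture <- function(id) {
  cat_ <- fixture_catalog()
  if (!id %in% cat_$id) {
    stop("unknown fixture '", id, "'; available: ",
         paste(cat_$id, collapse = ", "))
  }
  wf <- read_molden(check_fixture_file(paste0(id, ".molden")))
  wf$label <- id
  rdm <- read_rdm_bundle(check_fixture_file(paste0(id, "_rdm.json")))
  atoms <- read_xyz(check_fixture_file(paste0(id, ".xyz")))
  ref <- jsonlite::fromJSON(check_fixture_file(paste0(id, "_refpoints.json")))
  list(id = id, atoms = atoms, wavefunction = wf, rdm = rdm,
       margin = cat_$margin[cat_$id == id], refpoints = ref)
}

#' Run a noise / mitigation experiment on a bundled fixture
#'
#' Computes topological feature sets for the three conditions of the study
#' design -- noise-free, noisy ([apply_noise()]) and mitigated
#' ([mitigate()]) -- on the frozen-core-embedded full-space 1-RDMs, plus the
#' electron-count table and (optionally) density difference fields.  Fully
#' reproducible from (bundle, noise, seed).
#'
#' @param id fixture id (see [fixture_catalog()])
#' @param noise a [noise_spec()]
#' @param spacing grid spacing for basin integration, bohr
#' @param seed RNG seed for the CP search
#' @param witness optional witness fixture id; when given, its feature set
#'   and a mitigated-minus-witness difference field are included
#' @param fields logical: compute difference fields (noisy - noise-free and
#'   mitigated - noise-free)
#' @return an `experiment_result` list: `features` (per condition),
#'   `electron_counts`, `comparisons` (noisy and mitigated vs noise-free,
#'   plus vs witness when given), `difference_fields`
#' @export
run_noise_experiment <- function(id, noise, spacing = 0.1, seed = 0,
                                 witness = NULL, fields = FALSE) {
  fx <- load_fixture(id)
  conds <- list(
    noise_free = fx$rdm,
    noisy = apply_noise(fx$rdm, noise))
  conds$mitigated <- mitigate(conds$noisy)
  models <- lapply(conds, function(r) density_model(fx$wavefunction, r))
  features <- lapply(models, extract_features, spacing = spacing,
                     margin = fx$margin, seed = seed)
  counts <- vapply(models, function(m) sum(diag(m$rdm$matrix)), 1)
  comparisons <- list(
    noisy_vs_noise_free = compare_features(features$noisy,
                                           features$noise_free),
    mitigated_vs_noise_free = compare_features(features$mitigated,
                                               features$noise_free))
  wit_features <- NULL
  if (!is.null(witness)) {
    wfx <- load_fixture(witness)
    wmodel <- density_model(wfx$wavefunction, wfx$rdm)
    wit_features <- extract_features(wmodel, spacing = spacing,
                                     margin = wfx$margin, seed = seed)
    comparisons$mitigated_vs_witness <-
      compare_features(features$mitigated, wit_features)
  }
  diff_fields <- NULL
  if (fields) {
    grid <- default_grid(fx$atoms, spacing, fx$margin)
    diff_fields <- list(
      noisy_minus_noise_free = density_difference(models$noisy,
                                                  models$noise_free, grid),
      mitigated_minus_noise_free = density_difference(models$mitigated,
                                                      models$noise_free, grid))
  }
  structure(list(id = id, noise = noise, spacing = spacing, seed = seed,
                 features = features, witness_features = wit_features,
                 electron_counts = counts, comparisons = comparisons,
                 difference_fields = diff_fields),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s (%s noise)\n", x$id, x$noise$kind))
  cat("electron counts:\n")
  print(round(x$electron_counts, 4))
  invisible(x)
}
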