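# Readers and writers for the standard chemistry formats the pipeline
# touches: XYZ (Angstrom), Molden (geometry + Gaussian shells + MOs),
# Gaussian cube (volumetric scalar fields), and the package's own JSON
# 1-RDM bundle.  Everything is converted to atomic units on the way in.

#' Atom site table constructor
#'
#' @param element character vector of element symbols
#' @param position numeric matrix (n x 3) of nuclear positions in bohr
#' @return a data frame of class `atom_sites` with columns `element`, `Z`,
#'   `x`, `y`, `z` (positions in bohr)
#' @export
atom_sites <- function(element, position) {
  position <- matrix(as.numeric(position), ncol = 3)
  stopifnot(length(element) == nrow(position), all(is.finite(position)))
  out <- data.frame(element = as.character(element),
                    Z = element_to_z(element),
                    x = position[, 1], y = position[, 2], z = position[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("atom_sites", "data.frame")
  out
}

atom_positions <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Read an XYZ geometry
#'
#' Parses XYZ-format content (first line: atom count; second line: comment;
#' then `element x y z` in Angstrom) and returns the atoms with positions
#' converted to bohr (1 Angstrom = 1.8897261246 bohr).
#'
#' @param text XYZ content as a single string, a character vector of lines,
#'   or a file path
#' @return an [atom_sites()] data frame (positions in bohr)
#' @export
read_xyz <- function(text) {
  lines <- as_lines(text)
  if (length(lines) < 1) stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ atom-count line: ", lines[1])
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) stop("XYZ file lists fewer atoms than its count line")
  fields <- strsplit(trimws(body[seq_len(n)]), "[[:space:]]+")
  sym <- vapply(fields, `[`, "", 1)
  pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (anyNA(pos)) stop("malformed XYZ coordinate line")
  atom_sites(sym, pos * BOHR_PER_ANGSTROM)
}

#' Write an XYZ geometry (positions converted from bohr to Angstrom)
#' @param atoms an [atom_sites()] data frame (bohr)
#' @param comment comment line
#' @return character vector of XYZ lines
#' @export
write_xyz <- function(atoms, comment = "") {
  pos <- atom_positions(atoms) / BOHR_PER_ANGSTROM
  c(sprintf("%d", nrow(atoms)), comment,
    sprintf("%s %.10f %.10f %.10f", atoms$element, pos[, 1], pos[, 2], pos[, 3]))
}

# number of basis functions generated by a shell
shell_nfun <- function(l, spherical) {
  if (spherical && l >= 2) 2L * l + 1L else ((l + 1L) * (l + 2L)) %/% 2L
}

#' Read a Molden wavefunction file
#'
#' Supports the `[Atoms]` (AU or Angs), `[GTO]` and `[MO]` sections with
#' restricted (single spin set) orbitals and angular momenta up to f.  The
#' `[5D]`/`[7F]` (or combined `[5D7F]`) flags switch d and f shells to the
#' spherical convention.  The pinned AO ordering is: shells in file order;
#' within a shell, Cartesian p as x, y, z; Cartesian d as xx, yy, zz, xy,
#' xz, yz; Cartesian f as xxx, yyy, zzz, xyy, xxy, xxz, xzz, yzz, yyz, xyz;
#' spherical shells in m order 0, +1, -1, +2, -2 (, +3, -3).  Contractions
#' are renormalized to unit self-overlap of the axial component, so files
#' carrying either raw basis-set coefficients or pre-normalized contractions
#' are read identically.
#'
#' @param text Molden content as a string, character vector of lines, or path
#' @return a `wavefunction` object: list with `atoms` ([atom_sites()]),
#'   `shells` (list of shell descriptors), `mos` (list with `coefficients`
#'   n_mo x n_ao, `occupations`, `energies`, `ao_order`), and `label`
#' @export
read_molden <- function(text) {
  lines <- as_lines(text)
  tags <- grepl("^\\s*\\[", lines)
  tagname <- tolower(gsub("[^A-Za-z0-9]", "", sub("\\].*$", "", lines[tags])))
  tagidx <- which(tags)
  section <- function(name) {
    hit <- which(tagname == name)
    if (!length(hit)) return(NULL)
    from <- tagidx[hit[1]]
    to <- if (hit[1] < length(tagidx)) tagidx[hit[1] + 1] - 1 else length(lines)
    list(header = lines[from], body = lines[seq(from + 1, to)])
  }
  sph_d <- any(tagname %in% c("5d", "5d7f", "5d10f"))
  sph_f <- any(tagname %in% c("7f", "5d7f"))

  sec <- section("atoms")
  if (is.null(sec)) stop("Molden file is missing the [Atoms] section")
  in_au <- grepl("au", tolower(sec$header))
  rows <- sec$body[nzchar(trimws(sec$body))]
  f <- strsplit(trimws(rows), "[[:space:]]+")
  sym <- vapply(f, `[`, "", 1)
  pos <- t(vapply(f, function(x) as.numeric(x[4:6]), numeric(3)))
  if (!in_au) pos <- pos * BOHR_PER_ANGSTROM
  atoms <- atom_sites(sym, pos)

  sec <- section("gto")
  if (is.null(sec)) stop("Molden file is missing the [GTO] section")
  shells <- parse_gto(sec$body, nrow(atoms), sph_d, sph_f)

  sec <- section("mo")
  if (is.null(sec)) stop("Molden file is missing the [MO] section")
  nao <- sum(vapply(shells, function(s) shell_nfun(s$l, s$spherical), 1L))
  mos <- parse_mo(sec$body, nao)

  wf <- list(atoms = atoms, shells = shells, mos = mos,
             label = "molden import")
  class(wf) <- "wavefunction"
  validate_wavefunction(wf)
  wf
}

parse_gto <- function(body, natom, sph_d, sph_f) {
  body <- body[nzchar(trimws(body))]
  shells <- list()
  i <- 1
  lmap <- c(s = 0L, p = 1L, d = 2L, f = 3L)
  while (i <= length(body)) {
    hdr <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    iatom <- as.integer(hdr[1])
    if (is.na(iatom) || iatom < 1 || iatom > natom) {
      stop("malformed [GTO] atom header: ", body[i])
    }
    i <- i + 1
    while (i <= length(body)) {
      f <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
      if (length(f) >= 2 && is.na(suppressWarnings(as.numeric(f[1])))) {
        ltag <- tolower(f[1])
        if (ltag == "sp") stop("SP shells are not supported; split them")
        if (!ltag %in% names(lmap)) {
          stop("unsupported angular momentum '", f[1],
               "' (only s, p, d, f are supported)")
        }
        l <- lmap[[ltag]]
        nprim <- as.integer(f[2])
        prim <- t(vapply(strsplit(trimws(body[i + seq_len(nprim)]),
                                  "[[:space:]]+"),
                         function(x) as.numeric(gsub("[dD]", "e", x[1:2])),
                         numeric(2)))
        if (anyNA(prim) || any(prim[, 1] <= 0)) {
          stop("malformed primitive line in [GTO] shell")
        }
        shells[[length(shells) + 1]] <- list(
          center_index = iatom, l = l,
          spherical = if (l == 2) sph_d else if (l == 3) sph_f else FALSE,
          exponents = prim[, 1],
          coefficients = normalize_contraction(prim[, 1], prim[, 2], l))
        i <- i + nprim + 1
      } else if (!nzchar(trimws(body[i]))) {
        i <- i + 1
        break
      } else {
        # next atom header (two integers)
        break
      }
    }
    # skip to next non-blank
    while (i <= length(body) && !nzchar(trimws(body[i]))) i <- i + 1
    if (i <= length(body)) {
      f <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
      if (!(length(f) >= 1 && !is.na(suppressWarnings(as.integer(f[1]))))) break
    }
  }
  shells
}

# Norm of the axial (x^l) component of a primitive Gaussian
prim_norm_axial <- function(alpha, l) {
  (2 * alpha / pi)^0.75 * sqrt((4 * alpha)^l / double_factorial(2 * l - 1))
}

# scale contraction coefficients (given per normalized primitive) so the
# contracted axial component has unit self-overlap
normalize_contraction <- function(exps, coefs, l) {
  nrm <- prim_norm_axial(exps, l)
  p <- outer(exps, exps, "+")
  s <- sum(outer(coefs * nrm, coefs * nrm) *
             double_factorial(2 * l - 1) / (2 * p)^l * (pi / p)^1.5)
  if (s <= 0) stop("non-normalizable contraction in [GTO]")
  coefs / sqrt(s)
}

parse_mo <- function(body, nao) {
  occ <- numeric(0)
  ene <- numeric(0)
  coefs <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      if (length(cur) != nao) {
        stop("MO coefficient count (", length(cur),
             ") does not match the AO count (", nao, ")")
      }
      coefs[[length(coefs) + 1]] <<- cur
    }
    cur <<- NULL
  }
  for (ln in body) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (grepl("^Sym\\s*=", t, ignore.case = TRUE)) {
      flush()
    } else if (grepl("^Ene\\s*=", t, ignore.case = TRUE)) {
      ene <- c(ene, as.numeric(sub(".*=", "", t)))
    } else if (grepl("^Spin\\s*=", t, ignore.case = TRUE)) {
      if (!grepl("alpha", t, ignore.case = TRUE)) {
        stop("only restricted (Spin= Alpha) Molden files are supported")
      }
    } else if (grepl("^Occup\\s*=", t, ignore.case = TRUE)) {
      occ <- c(occ, as.numeric(sub(".*=", "", t)))
      if (is.null(cur)) cur <- numeric(0)
    } else {
      f <- strsplit(t, "[[:space:]]+")[[1]]
      idx <- as.integer(f[1])
      val <- as.numeric(gsub("[dD]", "e", f[2]))
      if (is.na(idx) || is.na(val)) stop("malformed MO coefficient line: ", ln)
      if (is.null(cur)) cur <- numeric(0)
      cur[idx] <- val
    }
  }
  flush()
  cm <- do.call(rbind, lapply(coefs, function(v) {
    v[is.na(v)] <- 0
    length(v) <- nao
    v[is.na(v)] <- 0
    v
  }))
  if (length(occ) != nrow(cm)) {
    stop("number of Occup= entries does not match the number of MOs")
  }
  if (any(occ < -1e-9 | occ > 2 + 1e-9)) {
    stop("MO occupations must lie in [0, 2]")
  }
  list(coefficients = cm, occupations = occ,
       energies = if (length(ene) == nrow(cm)) ene else NULL,
       ao_order = "shells in file order; p: x,y,z; cart d: xx,yy,zz,xy,xz,yz; cart f: xxx,yyy,zzz,xyy,xxy,xxz,xzz,yzz,yyz,xyz; spherical: m = 0,+1,-1,+2,-2(,+3,-3)")
}

validate_wavefunction <- function(wf) {
  nao <- sum(vapply(wf$shells, function(s) shell_nfun(s$l, s$spherical), 1L))
  stopifnot(nrow(wf$mos$coefficients) <= nao,
            ncol(wf$mos$coefficients) == nao,
            all(is.finite(wf$mos$coefficients)))
  ci <- vapply(wf$shells, `[[`, 1L, "center_index")
  if (any(ci < 1 | ci > nrow(wf$atoms))) {
    stop("shell center_index out of range")
  }
  invisible(wf)
}

#' @export
print.wavefunction <- function(x, ...) {
  cat(sprintf("<wavefunction> %d atoms, %d shells, %d MOs / %d AOs (%s)\n",
              nrow(x$atoms), length(x$shells), nrow(x$mos$coefficients),
              ncol(x$mos$coefficients), x$label))
  invisible(x)
}

#' Regular grid specification
#'
#' @param origin 3-vector, bohr
#' @param axes 3 x 3 matrix whose rows are the step vectors, bohr
#' @param shape integer 3-vector of voxel counts (each >= 2)
#' @return a `grid_spec` object
#' @export
grid_spec <- function(origin, axes, shape) {
  axes <- matrix(as.numeric(axes), 3, 3)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, all(is.finite(origin)),
            all(is.finite(axes)), length(shape) == 3, all(shape >= 2))
  if (abs(det(axes)) < 1e-14) stop("grid axes must be linearly independent")
  structure(list(origin = as.numeric(origin), axes = axes, shape = shape),
            class = "grid_spec")
}

#' Scalar field on a regular grid
#'
#' @param grid a [grid_spec()]
#' @param values numeric array with dim equal to `grid$shape`
#' @param quantity one of `"density"`, `"laplacian"`, `"difference"`
#' @return a `scalar_field` object
#' @export
scalar_field <- function(grid, values, quantity = c("density", "laplacian",
                                                    "difference")) {
  quantity <- match.arg(quantity)
  values <- as.array(values)
  stopifnot(identical(dim(values), as.integer(grid$shape)),
            all(is.finite(values)))
  structure(list(grid = grid, values = values, quantity = quantity),
            class = "scalar_field")
}

voxel_volume <- function(grid) abs(det(grid$axes))

# Cartesian coordinates of every voxel center (n x 3), x index fastest,
# matching the storage order of scalar_field values.
grid_points <- function(grid) {
  s <- grid$shape
  ii <- seq_len(s[1]) - 1
  jj <- seq_len(s[2]) - 1
  kk <- seq_len(s[3]) - 1
  g <- expand.grid(i = ii, j = jj, k = kk)
  sweep(as.matrix(g) %*% grid$axes, 2, grid$origin, "+")
}

#' Serialize a scalar field as Gaussian cube content
#'
#' Standard cube layout: two comment lines, `natom origin`, three axis lines
#' (voxel counts and step vectors, bohr), one line per atom, then values in
#' Z-fastest order, six per line.
#'
#' @param field a [scalar_field()]
#' @param atoms an [atom_sites()] data frame (may have zero rows)
#' @return character vector of cube lines
#' @export
write_cube <- function(field, atoms = NULL) {
  g <- field$grid
  natom <- if (is.null(atoms)) 0L else nrow(atoms)
  hdr <- c(sprintf("densiwit %s field", field$quantity),
           "generated by densiwit::write_cube",
           sprintf("%5d %15.8f %15.8f %15.8f", natom,
                   g$origin[1], g$origin[2], g$origin[3]),
           sprintf("%5d %15.8f %15.8f %15.8f", g$shape[1],
                   g$axes[1, 1], g$axes[1, 2], g$axes[1, 3]),
           sprintf("%5d %15.8f %15.8f %15.8f", g$shape[2],
                   g$axes[2, 1], g$axes[2, 2], g$axes[2, 3]),
           sprintf("%5d %15.8f %15.8f %15.8f", g$shape[3],
                   g$axes[3, 1], g$axes[3, 2], g$axes[3, 3]))
  if (natom > 0) {
    hdr <- c(hdr, sprintf("%5d %15.8f %15.8f %15.8f %15.8f", atoms$Z,
                          as.numeric(atoms$Z), atoms$x, atoms$y, atoms$z))
  }
  # values: loop x, then y, z fastest
  v <- aperm(field$values, c(3, 2, 1))  # now z fastest in linear order
  flat <- as.numeric(v)
  rows <- split(flat, ceiling(seq_along(flat) / 6))
  body <- vapply(rows, function(r) paste(sprintf("%13.6E", r), collapse = " "),
                 "")
  c(hdr, unname(body))
}

#' Read Gaussian cube content
#'
#' @param text cube content (string, lines, or path)
#' @return list with `field` (a [scalar_field()]) and `atoms`
#' @export
read_cube <- function(text) {
  lines <- as_lines(text)
  num <- function(ln) as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
  l3 <- num(lines[3])
  natom <- as.integer(l3[1])
  origin <- l3[2:4]
  ax <- t(vapply(lines[4:6], num, numeric(4)))
  shape <- as.integer(ax[, 1])
  axes <- ax[, 2:4]
  atoms <- NULL
  if (natom > 0) {
    at <- t(vapply(lines[7:(6 + natom)], num, numeric(5)))
    atoms <- atom_sites(z_to_element(as.integer(at[, 1])), at[, 3:5])
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + natom):length(lines)]),
                                     "[[:space:]]+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape)) {
    stop("cube value count does not match the declared shape")
  }
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  list(field = scalar_field(grid_spec(origin, axes, shape), arr, "density"),
       atoms = atoms)
}

#' Read a 1-RDM bundle (JSON)
#'
#' The bundle schema has fields `matrix` (real square matrix over the active
#' or full MO space), `mo_space_size` (total MO count), `frozen_indices` and
#' `active_indices` (0-based MO indices, converted to 1-based on read),
#' `n_active_electrons`, and `provenance`.
#'
#' @param text JSON content (string, lines, or path)
#' @return a [one_rdm()] object (`space = "active"` when the matrix covers
#'   only the active indices, `"full"` when it covers the whole MO space)
#' @export
read_rdm_bundle <- function(text) {
  txt <- paste(as_lines(text), collapse = "\n")
  obj <- jsonlite::fromJSON(txt, simplifyMatrix = TRUE)
  need <- c("matrix", "mo_space_size", "frozen_indices", "active_indices",
            "n_active_electrons", "provenance")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("RDM bundle is missing fields: ",
                         paste(miss, collapse = ", "))
  m <- obj$matrix
  if (is.list(m) || !is.numeric(unlist(m))) {
    stop("RDM matrix entries must be real numbers")
  }
  m <- matrix(as.numeric(unlist(m)), nrow = length(obj$matrix[[1]]) %||%
                nrow(obj$matrix))
  if (is.matrix(obj$matrix)) m <- obj$matrix
  if (nrow(m) != ncol(m)) stop("RDM matrix must be square")
  frozen <- as.integer(obj$frozen_indices) + 1L
  active <- as.integer(obj$active_indices) + 1L
  nmo <- as.integer(obj$mo_space_size)
  # a matrix covering exactly the active indices is an active-space RDM,
  # even when the active space spans all MOs (no frozen orbitals)
  space <- if (nrow(m) == length(active)) "active" else "full"
  one_rdm(m, space = space, frozen_indices = frozen, active_indices = active,
          n_active_electrons = as.integer(obj$n_active_electrons),
          n_mo_total = nmo, provenance = as.character(obj$provenance))
}

#' Write a 1-RDM bundle (JSON, 0-based indices)
#' @param rdm a [one_rdm()]
#' @param path optional output file; when NULL the JSON string is returned
#' @return JSON string (invisibly when writing to a file)
#' @export
write_rdm_bundle <- function(rdm, path = NULL) {
  obj <- list(matrix = unclass(rdm$matrix),
              mo_space_size = rdm$n_mo_total,
              frozen_indices = as.integer(rdm$frozen_indices - 1L),
              active_indices = as.integer(rdm$active_indices - 1L),
              n_active_electrons = rdm$n_active_electrons,
              provenance = rdm$provenance)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# Accept file paths, single strings with newlines, or character vectors.
as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}
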