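# Solvent accessibility, surface/interior classification and 3-state
# secondary structure for antigen residues.

# Deterministic quasi-uniform unit sphere points (golden-spiral lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Molecule-intrinsic orthonormal frame (principal axes with odd-moment sign
# convention) in which the sphere lattice is expressed, so the SASA estimate
# is invariant under rigid-body rotation/translation of the input for generic
# (asymmetric) structures; exactly symmetric point sets retain the usual
# lattice-orientation ambiguity.
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  X <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors
  fix_sign <- function(v) {
    s <- sum((X %*% v)^3)
    if (abs(s) > 1e-8) v * sign(s) else v
  }
  v1 <- fix_sign(ev[, 1]); v2 <- fix_sign(ev[, 2])
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over each atom using a fixed deterministic
#' golden-spiral point lattice: a surface point is accessible when it lies
#' outside every neighbouring atom's probe-expanded sphere, and the atom's
#' SASA is the accessible fraction of its expanded-sphere area.
#'
#' @param xyz Numeric matrix of atom coordinates (rows atoms, columns x/y/z).
#' @param radii Van der Waals radii in Angstrom, one per atom.
#' @param probe_radius Probe (solvent) radius in Angstrom; water is 1.4.
#' @param n_sphere_points Number of lattice points per atom; more points give
#'   a finer area estimate.
#' @return Numeric vector of per-atom SASA in Angstrom^2.
#' @export
atom_sasa <- function(xyz, radii, probe_radius = 1.4, n_sphere_points = 960) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, length(radii) == nrow(xyz), probe_radius > 0,
            n_sphere_points >= 12)
  n <- nrow(xyz)
  R <- radii + probe_radius
  sph <- fibonacci_sphere(n_sphere_points) %*% t(canonical_frame(xyz))
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    if (length(nb) == 0) {
      areas[i] <- 4 * pi * R[i]^2
      next
    }
    pts <- sweep(sph * R[i], 2, xyz[i, ], "+")
    Xn <- xyz[nb, , drop = FALSE]
    pd2 <- outer(rowSums(pts^2), rowSums(Xn^2), "+") - 2 * tcrossprod(pts, Xn)
    buried <- pd2 < matrix(R[nb]^2, nrow(pts), length(nb), byrow = TRUE)
    acc <- rowSums(buried) == 0
    areas[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  areas
}

#' Per-residue solvent-accessible surface area
#'
#' Sums [atom_sasa()] over each residue's heavy atoms. Only chains with the
#' requested role participate, both as area carriers and as occluders, so the
#' antigen's accessibility is computed on the antigen alone (the antibody,
#' when present, never buries the epitope it binds).
#'
#' @param structure An `epitope_structure`.
#' @inheritParams atom_sasa
#' @param role Chain role(s) to include; default `"antigen"`.
#' @return Named numeric vector of residue SASA (Angstrom^2), keyed by
#'   residue uid, in residue file order.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960,
                         role = "antigen") {
  at <- structure$atoms[structure$atoms$role %in% role, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms with role ", paste(role, collapse = "/"))
  a <- atom_sasa(as.matrix(at[, c("x", "y", "z")]), vdw_radius(at$element),
                 probe_radius, n_sphere_points)
  uids <- residue_uids(structure, role)
  out <- rowsum(a, group = factor(at$res_uid, levels = uids))[, 1]
  names(out) <- uids
  out
}

#' Relative accessible surface area
#'
#' Divides each residue's SASA by the fully exposed reference area of its
#' amino-acid type (Gly-X-Gly maxima by default, see [max_asa_gxg]).
#'
#' @param sasa Named numeric vector from [compute_sasa()].
#' @param aa One-letter residue types aligned with `sasa`.
#' @param reference_areas Named reference table (Angstrom^2 per type).
#' @return Named numeric vector of RASA values (0 is fully buried; values a
#'   little above 1 can occur for extended conformations).
#' @export
compute_rasa <- function(sasa, aa, reference_areas = max_asa_gxg) {
  stopifnot(length(sasa) == length(aa))
  ref <- reference_areas[aa]
  if (any(is.na(ref) | ref <= 0))
    stop("no positive reference area for residue type(s): ",
         paste(unique(aa[is.na(ref) | ref <= 0]), collapse = ", "))
  out <- unname(sasa) / unname(ref)
  names(out) <- names(sasa)
  out
}

#' Surface/interior classification
#'
#' A residue is a surface residue when its relative accessible surface area
#' is strictly greater than the threshold (5 percent by default); residues at
#' or below the threshold are interior and are never patch centres.
#'
#' @param rasa Named numeric vector of RASA values.
#' @param threshold Strict RASA cutoff.
#' @return Named logical vector.
#' @export
classify_surface <- function(rasa, threshold = 0.05) {
  rasa > threshold
}

DSSP_SS3 <- function(ss8) {
  ifelse(ss8 %in% c("H", "G", "I"), "helix",
         ifelse(ss8 %in% c("E", "B"), "sheet", "coil"))
}

#' Read a DSSP classic-format file
#'
#' Parses the fixed-column residue table of a DSSP text output and collapses
#' the 8-state code to 3 states: H/G/I to helix, E/B to sheet, everything
#' else (including blank) to coil. Chain-break rows are skipped.
#'
#' @param dssp Path to a DSSP file or a character vector of its lines.
#' @return Data frame with chain, resno, insert, aa, ss8 and ss3.
#' @export
read_dssp <- function(dssp) {
  lines <- if (length(dssp) == 1 && !grepl("\n", dssp) && file.exists(dssp)) {
    readLines(dssp)
  } else {
    unlist(strsplit(dssp, "\n", fixed = TRUE))
  }
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file: residue table header not found")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  data.frame(
    chain = trimws(substr(body, 12, 12)),
    resno = as.integer(trimws(substr(body, 6, 10))),
    insert = trimws(substr(body, 11, 11)),
    aa = substr(body, 14, 14),
    ss8 = substr(body, 17, 17),
    ss3 = DSSP_SS3(substr(body, 17, 17)),
    stringsAsFactors = FALSE
  )
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / b2n, sum(n1 * n2)) * 180 / pi
}

# phi/psi-window fallback secondary-structure heuristic: backbone dihedrals
# binned into broad helix/sheet basins, then runs shorter than the minimal
# element length reset to coil. A documented approximation used only when no
# DSSP file is supplied.
fallback_ss3 <- function(structure, role = "antigen") {
  res <- structure$residues[structure$residues$role %in% role, , drop = FALSE]
  out <- rep("coil", nrow(res)); names(out) <- res$res_uid
  bb <- function(uid, name) {
    a <- structure$atoms
    i <- which(a$res_uid == uid & a$elety == name)
    if (length(i) == 0) return(NULL)
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  for (ch in unique(res$chain)) {
    uids <- res$res_uid[res$chain == ch]
    if (length(uids) < 3) next
    raw <- rep("coil", length(uids))
    for (k in 2:(length(uids) - 1)) {
      Cm <- bb(uids[k - 1], "C"); N <- bb(uids[k], "N")
      CA <- bb(uids[k], "CA"); C <- bb(uids[k], "C"); Np <- bb(uids[k + 1], "N")
      if (is.null(Cm) || is.null(N) || is.null(CA) || is.null(C) || is.null(Np)) next
      phi <- dihedral(Cm, N, CA, C); psi <- dihedral(N, CA, C, Np)
      if (phi > -120 && phi < -20 && psi > -100 && psi < 30) raw[k] <- "helix"
      else if (phi > -180 && phi < -40 && (psi > 60 || psi < -150)) raw[k] <- "sheet"
    }
    r <- rle(raw)
    r$values[r$values == "helix" & r$lengths < 3] <- "coil"
    r$values[r$values == "sheet" & r$lengths < 2] <- "coil"
    out[uids] <- inverse.rle(r)
  }
  out
}

#' Assign 3-state secondary structure to antigen residues
#'
#' Uses a DSSP file when one is supplied (collapsing its 8-state codes), and
#' otherwise falls back to a built-in backbone-dihedral heuristic, announcing
#' the fallback with a message. With a DSSP file, every antigen residue must
#' be matched by chain, author number and insertion code.
#'
#' @param structure An `epitope_structure`.
#' @param dssp Optional DSSP file path, text, or a data frame from
#'   [read_dssp()].
#' @param role Chain role(s) to annotate.
#' @return Named character vector over residue uids with values `"helix"`,
#'   `"sheet"` or `"coil"`.
#' @export
assign_secondary_structure <- function(structure, dssp = NULL, role = "antigen") {
  res <- structure$residues[structure$residues$role %in% role, , drop = FALSE]
  if (is.null(dssp)) {
    message("no DSSP file supplied; using the built-in dihedral-window ",
            "secondary-structure heuristic")
    return(fallback_ss3(structure, role))
  }
  d <- if (is.data.frame(dssp)) dssp else read_dssp(dssp)
  key_d <- res_uid(d$chain, d$resno, d$insert)
  idx <- match(res$res_uid, key_d)
  if (anyNA(idx))
    stop("DSSP/structure residue mismatch; unmatched residues: ",
         paste(utils::head(res$res_uid[is.na(idx)], 10), collapse = ", "))
  out <- d$ss3[idx]
  names(out) <- res$res_uid
  out
}

#' Full surface annotation for antigen residues
#'
#' Convenience wrapper computing SASA, RASA, the surface flag and secondary
#' structure in one pass.
#'
#' @inheritParams compute_sasa
#' @param reference_areas Fully-exposed reference areas for RASA.
#' @param dssp Optional DSSP input forwarded to
#'   [assign_secondary_structure()].
#' @param surface_threshold Strict RASA cutoff for surface residues.
#' @return Data frame (one row per antigen residue, file order): res_uid, aa,
#'   sasa, rasa, is_surface, ss3.
#' @export
annotate_surface <- function(structure, probe_radius = 1.4,
                             n_sphere_points = 960,
                             reference_areas = max_asa_gxg, dssp = NULL,
                             surface_threshold = 0.05, role = "antigen") {
  res <- structure$residues[structure$residues$role %in% role, , drop = FALSE]
  sasa <- compute_sasa(structure, probe_radius, n_sphere_points, role)
  rasa <- compute_rasa(sasa, res$aa, reference_areas)
  ss3 <- assign_secondary_structure(structure, dssp, role)
  data.frame(
    res_uid = res$res_uid, aa = res$aa, sasa = unname(sasa),
    rasa = unname(rasa), is_surface = unname(classify_surface(rasa, surface_threshold)),
    ss3 = unname(ss3[res$res_uid]), stringsAsFactors = FALSE
  )
}
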