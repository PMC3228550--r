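# Deterministic synthetic antigen-antibody fixtures: a pseudo-globular
# antigen chain, an antibody chain whose placement defines the epitope under
# the 4 Angstrom rule, matching DSSP-format and PSSM files, and an optional
# local density thinning that gives epitope patches larger adjacent-residue
# distances.

#' Specification for the synthetic complex generator
#'
#' @param n_residues Number of antigen residues.
#' @param radius Confinement radius of the antigen globule (Angstrom).
#' @param contact_size Number of designated antibody-contact (epitope)
#'   residues.
#' @param shift Epitope distance shift (Angstrom): how much farther, on
#'   average, residues neighbouring the epitope site are placed. Implemented
#'   as a radial expansion of the coordinate field around the epitope-site
#'   centroid (every residue's distance to the site centroid grows by
#'   `shift`), which inflates adjacent distances strongly near the site and
#'   negligibly far from it, and never decreases any pairwise distance.
#' @param n_extra_ab Additional antibody residues placed behind the paratope
#'   (never within the contact cutoff).
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return Object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_residues = 60, radius = 12.5, contact_size = 6,
                           shift = 0, n_extra_ab = 6, seed = 1) {
  stopifnot(n_residues >= 25, radius > 5, contact_size >= 1,
            contact_size < n_residues / 3, shift >= 0, n_extra_ab >= 0)
  out <- list(n_residues = as.integer(n_residues), radius = radius,
              contact_size = as.integer(contact_size), shift = shift,
              n_extra_ab = as.integer(n_extra_ab), seed = as.integer(seed))
  class(out) <- "generator_spec"
  out
}

rand_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# 4-atom backbone template plus a pseudo-CB, local frame (Angstrom)
RES_TEMPLATE <- rbind(
  N  = c(-1.20, 0.80, 0.00),
  CA = c(0.00, 0.00, 0.00),
  C  = c(1.25, 0.75, 0.00),
  O  = c(1.95, 1.40, 0.75),
  CB = c(0.00, -1.45, 0.55)
)
RES_ELEMENTS <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

# Self-avoiding confined random walk of residue centres.
walk_chain <- function(n, radius, step = 3.8, min_sep = 3.5) {
  for (restart in 1:25) {
    centres <- matrix(NA_real_, n, 3)
    centres[1, ] <- stats::rnorm(3) * radius / 4
    ok <- TRUE
    for (k in 2:n) {
      placed <- FALSE
      for (try in 1:300) {
        dir <- stats::rnorm(3) - 0.35 * centres[k - 1, ] / radius
        dir <- dir / sqrt(sum(dir^2))
        cand <- centres[k - 1, ] + step * dir
        if (sqrt(sum(cand^2)) > radius) next
        if (k > 2) {
          d2 <- rowSums(sweep(centres[1:(k - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < min_sep^2) next
        }
        centres[k, ] <- cand; placed <- TRUE; break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(centres)
  }
  stop("could not place a self-avoiding chain of ", n, " residues in radius ",
       radius, "; try a larger radius")
}

build_residue_atoms <- function(centre, rot) {
  sweep(RES_TEMPLATE %*% t(rot), 2, centre, "+")
}

min_atom_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

format_pdb_atom <- function(serial, name, resname, chain, resno, xyz, element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

# deterministic secondary-structure truth pattern: helix/coil/sheet/coil runs
ss_truth_pattern <- function(n) {
  pat <- rep(c(rep("H", 8), rep(" ", 4), rep("E", 6), rep(" ", 4)),
             length.out = n)
  pat
}

write_dssp_lines <- function(chain, resno, aa, ss8) {
  c("==== Secondary Structure Definition; synthetic fixture ====",
    "REFERENCE  synthetic",
    sprintf("%5d%3d", length(resno), 1),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA",
    paste0(formatC(seq_along(resno), width = 5),
           formatC(resno, width = 5), " ", chain, " ", aa, "  ", ss8))
}

#' Generate a synthetic antigen-antibody complex
#'
#' Builds a self-avoiding pseudo-globular antigen chain (chain A, five heavy
#' atoms per residue), designates a surface-proximal cluster of
#' `contact_size` residues as the epitope, optionally thins the local
#' residue density around that site (see [generator_spec()]), and places an
#' antibody chain (chain B) so that exactly the designated residues fall
#' within 4 Angstrom of it. The result is verified against the package's own
#' labelling oracle on the coordinates as written (PDB precision); placement
#' is retried with a different site if verification fails.
#'
#' @param spec A [generator_spec()].
#' @return List with `pdb` (PDB-format lines), `dssp` (DSSP-format lines for
#'   the antigen chain), `labels` (truth data frame: res_uid, label),
#'   `manifest` (spec, per-residue truth and design geometry), `sequences`
#'   (named per-chain one-letter strings) and `ss3` (truth secondary
#'   structure by residue uid).
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  aa_ag <- sample(AA1, n, replace = TRUE)
  rot_ag <- lapply(seq_len(n), function(i) rand_rotation())

  for (attempt in 1:12) {
    centres <- walk_chain(n, spec$radius)
    g <- colMeans(centres)
    rho_g <- sqrt(rowSums(sweep(centres, 2, g)^2))
    shell <- which(rho_g >= stats::median(rho_g))
    site0 <- sample(shell, 1)
    nb <- order(rowSums(sweep(centres, 2, centres[site0, ])^2))
    contact <- sort(nb[seq_len(spec$contact_size)])

    # epitope-site density thinning: radial expansion around the site centroid
    s <- colMeans(centres[contact, , drop = FALSE])
    if (spec$shift > 0) {
      v <- sweep(centres, 2, s)
      rho <- sqrt(rowSums(v^2))
      fac <- ifelse(rho > 1e-6, (rho + spec$shift) / rho, 1)
      centres <- sweep(v * fac, 2, s, "+")
      g <- colMeans(centres)
    }

    atoms_ag <- lapply(seq_len(n), function(i)
      round(build_residue_atoms(centres[i, ], rot_ag[[i]]), 3))

    # antibody partner residue per contact residue, pushed along the outward
    # normal until the minimal heavy-atom distance falls in (3.3, 3.7)
    ab_atoms <- list(); ab_ok <- TRUE
    others <- setdiff(seq_len(n), contact)
    for (ci in contact) {
      v0 <- centres[ci, ] - g; v0 <- v0 / sqrt(sum(v0^2))
      placed <- FALSE
      for (jit in 1:25) {
        dirv <- v0 + if (jit == 1) 0 else 0.25 * stats::rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        rot <- rand_rotation()
        lo <- 2; hi <- 14
        f <- function(t) min_atom_dist(
          round(build_residue_atoms(centres[ci, ] + t * dirv, rot), 3),
          atoms_ag[[ci]])
        if (f(hi) < 3.7) next
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          if (f(mid) < 3.5) lo <- mid else hi <- mid
        }
        cand <- round(build_residue_atoms(centres[ci, ] + hi * dirv, rot), 3)
        dmin <- min_atom_dist(cand, atoms_ag[[ci]])
        if (dmin >= 3.7 || dmin <= 3.2) next
        far_ok <- all(vapply(others, function(j)
          min_atom_dist(cand, atoms_ag[[j]]) >= 4.25, logical(1)))
        if (!far_ok) next
        ab_atoms[[length(ab_atoms) + 1]] <- cand
        placed <- TRUE; break
      }
      if (!placed) { ab_ok <- FALSE; break }
    }
    if (!ab_ok) next

    # bulk antibody residues stacked behind the paratope
    if (spec$n_extra_ab > 0) {
      pc <- colMeans(do.call(rbind, ab_atoms))
      outd <- pc - g; outd <- outd / sqrt(sum(outd^2))
      extra_ok <- TRUE
      for (j in seq_len(spec$n_extra_ab)) {
        for (try in 1:50) {
          cand_c <- pc + outd * (4 + 2.2 * j) + stats::rnorm(3) * 1.2
          cand <- round(build_residue_atoms(cand_c, rand_rotation()), 3)
          if (all(vapply(seq_len(n), function(k)
            min_atom_dist(cand, atoms_ag[[k]]) >= 4.5, logical(1)))) {
            ab_atoms[[length(ab_atoms) + 1]] <- cand
            break
          }
          if (try == 50) extra_ok <- FALSE
        }
        if (!extra_ok) break
      }
      if (!extra_ok) next
    }

    # assemble PDB text and verify against the labelling oracle on the
    # rounded coordinates actually written to the file
    n_ab <- length(ab_atoms)
    aa_ab <- sample(AA1, n_ab, replace = TRUE)
    lines <- character(0); serial <- 0
    for (i in seq_len(n)) {
      for (k in seq_len(nrow(RES_TEMPLATE))) {
        serial <- serial + 1
        lines <- c(lines, format_pdb_atom(
          serial, rownames(RES_TEMPLATE)[k], AA3[[aa_ag[i]]], "A", i,
          atoms_ag[[i]][k, ], RES_ELEMENTS[[k]]))
      }
    }
    lines <- c(lines, "TER")
    for (i in seq_len(n_ab)) {
      for (k in seq_len(nrow(RES_TEMPLATE))) {
        serial <- serial + 1
        lines <- c(lines, format_pdb_atom(
          serial, rownames(RES_TEMPLATE)[k], AA3[[aa_ab[i]]], "B", i,
          ab_atoms[[i]][k, ], RES_ELEMENTS[[k]]))
      }
    }
    lines <- c(lines, "TER", "END")

    st <- parse_structure(lines, chain_roles = c(A = "antigen", B = "antibody"),
                          id = sprintf("synth%d", spec$seed))
    lab <- label_epitopes(st, cutoff = 4.0)
    truth <- as.integer(seq_len(n) %in% contact)
    if (!identical(lab$label, truth)) next

    ss8 <- ss_truth_pattern(n)
    ss3 <- DSSP_SS3(ss8); names(ss3) <- res_uid("A", seq_len(n), "")
    manifest <- list(
      spec = unclass(spec), structure_id = st$id,
      contact_residues = res_uid("A", contact, ""),
      site_centroid = as.numeric(s), attempt = attempt,
      residues = data.frame(res_uid = res_uid("A", seq_len(n), ""),
                            aa = aa_ag, label = truth,
                            x = vapply(seq_len(n), function(i) atoms_ag[[i]]["CA", 1], numeric(1)),
                            y = vapply(seq_len(n), function(i) atoms_ag[[i]]["CA", 2], numeric(1)),
                            z = vapply(seq_len(n), function(i) atoms_ag[[i]]["CA", 3], numeric(1)),
                            stringsAsFactors = FALSE))
    return(list(pdb = lines,
                dssp = write_dssp_lines("A", seq_len(n), aa_ag, ss8),
                labels = data.frame(res_uid = res_uid("A", seq_len(n), ""),
                                    label = truth, stringsAsFactors = FALSE),
                manifest = manifest,
                sequences = list(A = paste(aa_ag, collapse = ""),
                                 B = paste(aa_ab, collapse = "")),
                ss3 = ss3, spec = spec))
  }
  stop("antibody placement failed repeatedly for seed ", spec$seed,
       "; try a larger radius or smaller contact_size")
}

#' Generate a PSI-BLAST ASCII PSSM fixture
#'
#' Conserved positions receive a self-substitution score at or above the
#' BLOSUM62 diagonal (conservation score 0 downstream); all other positions
#' score 2-6 below the diagonal (positive conservation score). Off-type
#' columns are filled with plausible background scores.
#'
#' @param sequence One-letter amino-acid string.
#' @param conserved_positions Integer positions treated as conserved.
#' @param seed Integer seed.
#' @return Character vector of PSSM lines parseable by [read_pssm()].
#' @export
generate_pssm <- function(sequence, conserved_positions = integer(0), seed = 1) {
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(all(aa %in% AA1))
  set.seed(seed)
  m <- length(aa)
  scores <- matrix(sample(-4:2, m * 20, replace = TRUE), m, 20,
                   dimnames = list(NULL, AA1))
  for (i in seq_len(m)) {
    b <- blosum62_diagonal[[aa[i]]]
    scores[i, aa[i]] <- if (i %in% conserved_positions)
      b + sample(0:2, 1) else b - sample(2:6, 1)
  }
  c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", AA1), collapse = "")),
    vapply(seq_len(m), function(i)
      paste0(sprintf("%5d %s ", i, aa[i]),
             paste(sprintf("%3d", scores[i, ]), collapse = "")),
      character(1)),
    "")
}

#' Simulate a labelled dataset ready for training
#'
#' Generates `n_structures` synthetic complexes (per-structure seeds spawned
#' from `seed`), plants an evolutionary-conservation signal in the PSSMs
#' (epitope positions are mostly non-conserved, the rest mostly conserved,
#' with `conservation_noise` label-flip probability), and runs the full
#' feature pipeline on each.
#'
#' @param n_structures Number of complexes.
#' @param spec Template [generator_spec()]; its seed is replaced per
#'   structure.
#' @param seed Master seed.
#' @param conservation_noise Probability that a position's conservation
#'   state contradicts its class.
#' @param n Patch size.
#' @param mode Patch mode.
#' @param permute_labels Shuffle each structure's instance labels after the
#'   features are built (null-model runs; destroys all feature-label
#'   association).
#' @return List of labelled `epitope_features` objects.
#' @export
simulate_epitope_dataset <- function(n_structures = 8,
                                     spec = generator_spec(shift = 0.5),
                                     seed = 1, conservation_noise = 0.15,
                                     n = 20, mode = "thick",
                                     permute_labels = FALSE) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_structures + 1)
  out <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    sp <- spec; sp$seed <- seeds[i]
    fx <- generate_complex(sp)
    st <- parse_structure(fx$pdb, chain_roles = c(A = "antigen", B = "antibody"),
                          id = sprintf("synth%02d", i))
    labels <- fx$labels
    set.seed(seeds[i] %% 2^20 + i)
    flip <- stats::runif(nrow(labels)) < conservation_noise
    conserved <- which((labels$label == 0) != flip)
    pssm <- read_pssm(generate_pssm(fx$sequences$A, conserved,
                                    seed = seeds[i] %% 2^16 + 7))
    ann <- annotate_surface(st, dssp = fx$dssp)
    out[[i]] <- structure_features(st, pssms = list(A = pssm),
                                   annotations = ann, n = n, mode = mode,
                                   labels = labels)
    # null-model runs: shuffle the response after the features are built, so
    # any residual signal reflects chance alone
    if (permute_labels) out[[i]]$y <- sample(out[[i]]$y)
  }
  out
}
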