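# Per-residue descriptors and assembly of the 7-per-residue patch feature
# vector: RASA, conservation, adjacent-residue-distance weight, amino-acid
# composition and one-hot secondary structure.

#' Adjacent residue distance (ARD) weights
#'
#' Each adjacent residue in a patch is weighted by the reciprocal of its
#' minimal heavy-atom distance to the central residue, normalised over the
#' patch: \eqn{S(x_i) = p_i / \sum_j p_j} with \eqn{p_i = 1/d_i}. Nearer
#' neighbours therefore contribute more, and the weights sum to one. The
#' central residue itself carries no ARD weight (its slot in the assembled
#' feature vector is a zero sentinel, since 1/d is singular at d = 0).
#'
#' @param patch A `residue_patch`.
#' @return Named numeric vector of S values over the adjacent residues, in
#'   patch (ascending-distance) order.
#' @examples
#' # two neighbours at 1 and 3 Angstrom -> weights 0.75 and 0.25
#' @export
ard_weights <- function(patch) {
  d <- patch$adjacent$d
  if (any(d <= 0)) stop("non-positive adjacent distance in patch at ",
                        patch$central, " (duplicate coordinates?)")
  p <- 1 / d
  s <- p / sum(p)
  names(s) <- patch$adjacent$res_uid
  s
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the classic `-out_ascii_pssm` text format. Both the 20-column and
#' the 40-column (scores plus weighted percentages) variants are accepted;
#' the first 20 score columns are used, in the standard PSI-BLAST residue
#' order A R N D C Q E G H I L K M F P S T W Y V.
#'
#' @param pssm File path or character vector of lines.
#' @return Object of class `"pssm_profile"`: list with `sequence` (one-letter
#'   string) and `scores` (positions x 20 integer matrix, columns named by
#'   residue type).
#' @export
read_pssm <- function(pssm) {
  lines <- if (length(pssm) == 1 && !grepl("\n", pssm) && file.exists(pssm)) {
    readLines(pssm)
  } else {
    unlist(strsplit(pssm, "\n", fixed = TRUE))
  }
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  hdr <- which(vapply(toks, function(t)
    length(t) >= 20 && all(t[1:20] == AA1), logical(1)))
  if (length(hdr) == 0)
    stop("not a PSI-BLAST ASCII PSSM: residue-order header line not found")
  rows <- list(); seq_aa <- character(0)
  for (i in (hdr[1] + 1):length(toks)) {
    t <- toks[[i]]
    if (length(t) < 22 || is.na(suppressWarnings(as.integer(t[1])))) {
      if (length(seq_aa) > 0) break else next
    }
    if (!t[2] %in% AA1) next
    seq_aa <- c(seq_aa, t[2])
    rows[[length(rows) + 1]] <- as.numeric(t[3:22])
  }
  if (length(rows) == 0) stop("PSSM contains no score rows")
  scores <- do.call(rbind, rows)
  colnames(scores) <- AA1
  out <- list(sequence = paste(seq_aa, collapse = ""), scores = scores)
  class(out) <- "pssm_profile"
  out
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("pssm_profile:", nchar(x$sequence), "positions x 20 scores\n")
  invisible(x)
}

#' Evolutionary conservation score from a PSSM
#'
#' For position i holding residue type r, the score is
#' \eqn{|M_{ir} - B_{rr}|} when \eqn{M_{ir} - B_{rr} < 0} and 0 otherwise,
#' where \eqn{M_{ir}} is the PSSM score of the position's own residue type
#' and \eqn{B_{rr}} the BLOSUM62 diagonal. A position scoring below its
#' self-substitution baseline is less conserved and gets a positive score.
#'
#' @param pssm A `pssm_profile` aligned with the chain sequence.
#' @param sequence Optional one-letter chain sequence to validate against;
#'   a length mismatch is a hard error.
#' @param blosum_diag Baseline diagonal table, see [blosum62_diagonal].
#' @return Numeric vector of non-negative per-position scores.
#' @export
conservation_scores <- function(pssm, sequence = NULL,
                                blosum_diag = blosum62_diagonal) {
  aa <- strsplit(pssm$sequence, "")[[1]]
  if (!is.null(sequence)) {
    sq <- if (length(sequence) > 1) sequence else strsplit(sequence, "")[[1]]
    if (length(sq) != length(aa))
      stop("sequence/PSSM length mismatch: chain has ", length(sq),
           " residues, PSSM has ", length(aa), " positions")
    if (any(sq != aa))
      stop("sequence/PSSM residue mismatch at position(s): ",
           paste(utils::head(which(sq != aa), 10), collapse = ", "))
  }
  M <- pssm$scores[cbind(seq_along(aa), match(aa, AA1))]
  B <- unname(blosum_diag[aa])
  pmax(B - M, 0)
}

#' Amino-acid composition feature of a patch
#'
#' Every residue in the patch is assigned the fraction of patch residues
#' (central included) sharing its amino-acid type.
#'
#' @param patch A `residue_patch`.
#' @param aa Named one-letter residue types keyed by residue uid (covering
#'   the whole patch).
#' @return Named numeric vector over the patch residues, central first.
#' @export
composition_feature <- function(patch, aa) {
  uids <- c(patch$central, patch$adjacent$res_uid)
  t_aa <- aa[uids]
  if (anyNA(t_aa)) stop("missing residue type for: ",
                        paste(uids[is.na(t_aa)], collapse = ", "))
  counts <- table(t_aa)
  out <- as.numeric(counts[t_aa]) / patch$n
  names(out) <- uids
  out
}

#' Contact number of a residue
#'
#' Number of other residues whose alpha carbon lies within a distance
#' threshold (10 Angstrom by default) of this residue's alpha carbon. Used
#' only in the optional comparison configuration; a residue without a CA
#' atom gets contact number 0 with a warning.
#'
#' @param structure An `epitope_structure`.
#' @param residue Residue uid.
#' @param threshold Distance threshold in Angstrom.
#' @param role Chain role(s) whose CA atoms are counted.
#' @return Integer count.
#' @export
contact_number <- function(structure, residue, threshold = 10.0,
                           role = "antigen") {
  at <- structure$atoms
  ca <- at[at$elety == "CA" & at$role %in% role, , drop = FALSE]
  i <- which(ca$res_uid == residue)
  if (length(i) == 0) {
    warning("residue ", residue, " has no CA atom; contact number set to 0")
    return(0L)
  }
  d2 <- (ca$x - ca$x[i[1]])^2 + (ca$y - ca$y[i[1]])^2 + (ca$z - ca$z[i[1]])^2
  sum(d2[-i[1]] <= threshold^2 & ca$res_uid[-i[1]] != residue)
}

# Fixed per-residue slot order of the assembled vector.
FEATURE_SLOTS <- c("rasa", "cons", "ard", "comp", "ss_helix", "ss_sheet", "ss_coil")

#' Assemble the patch feature vector
#'
#' Concatenates, for each patch residue (central first, then neighbours by
#' ascending distance), the 7 per-residue descriptors in the fixed order
#' rasa, conservation, ARD weight, composition, and the one-hot secondary
#' structure triple (helix, sheet, coil), giving a 7 x n vector. With
#' `contact_numbers` supplied an eighth slot per residue is appended
#' (comparison configuration), giving 8 x n.
#'
#' @param patch A `residue_patch`.
#' @param annotations Surface annotation data frame (provides rasa and ss3).
#' @param conservation Named per-residue conservation scores (by uid).
#' @param contact_numbers Optional named per-residue contact numbers.
#' @return Named numeric vector of length 7 * n (or 8 * n); names encode
#'   slot semantics as `r<rank>_<slot>` with rank 0 for the centre.
#' @export
assemble_patch_vector <- function(patch, annotations, conservation,
                                  contact_numbers = NULL) {
  uids <- c(patch$central, patch$adjacent$res_uid)
  ai <- match(uids, annotations$res_uid)
  if (anyNA(ai)) stop("patch residue(s) missing from annotations: ",
                      paste(uids[is.na(ai)], collapse = ", "))
  cons <- conservation[uids]
  if (anyNA(cons)) stop("missing conservation score for residue(s): ",
                        paste(uids[is.na(cons)], collapse = ", "))
  aa <- structure(annotations$aa, names = annotations$res_uid)
  comp <- composition_feature(patch, aa)
  ard <- c(0, unname(ard_weights(patch)))  # central sentinel 0
  ss <- annotations$ss3[ai]
  per <- cbind(rasa = annotations$rasa[ai], cons = unname(cons), ard = ard,
               comp = unname(comp), ss_helix = as.numeric(ss == "helix"),
               ss_sheet = as.numeric(ss == "sheet"),
               ss_coil = as.numeric(ss == "coil"))
  if (!is.null(contact_numbers)) {
    cn <- contact_numbers[uids]
    if (anyNA(cn)) stop("missing contact number for residue(s): ",
                        paste(uids[is.na(cn)], collapse = ", "))
    per <- cbind(per, cn = unname(cn))
  }
  v <- as.numeric(t(per))
  names(v) <- paste0("r", rep(seq_along(uids) - 1, each = ncol(per)), "_",
                     rep(colnames(per), length(uids)))
  v
}

#' Compute the full feature matrix of a structure
#'
#' Runs the whole per-structure feature pipeline: surface annotation, patch
#' enumeration, per-chain conservation from the supplied PSSM profiles, and
#' patch-vector assembly, producing one feature row per surface antigen
#' residue. When the structure carries an antibody chain (or `labels` is
#' given) epitope labels are attached.
#'
#' @param structure An `epitope_structure`.
#' @param pssms Named list of `pssm_profile` objects (or file paths), keyed
#'   by antigen chain id. Each profile must match its chain sequence.
#' @param annotations Optional precomputed [annotate_surface()] result.
#' @param n Patch size.
#' @param mode Patch mode, `"thick"` or `"surface"`.
#' @param with_contact_number Append the per-residue contact-number slot.
#' @param labels Optional label data frame ([label_epitopes()] /
#'   [read_labels()]); by default labels are derived from the antibody chain
#'   when one is present.
#' @param dssp Optional DSSP input for secondary structure.
#' @param contact_threshold Threshold for the optional contact-number slot.
#' @return Object of class `"epitope_features"`: list with `x` (matrix,
#'   rows = surface residues), `ids`, `y` (0/1 labels or NULL), `patches`,
#'   `annotations` and `structure_id`.
#' @export
structure_features <- function(structure, pssms, annotations = NULL, n = 20,
                               mode = c("thick", "surface"),
                               with_contact_number = FALSE, labels = NULL,
                               dssp = NULL, contact_threshold = 10.0) {
  mode <- match.arg(mode)
  if (is.null(annotations))
    annotations <- annotate_surface(structure, dssp = dssp)
  res <- structure$residues[structure$residues$role == "antigen", , drop = FALSE]

  cons <- rep(NA_real_, nrow(res)); names(cons) <- res$res_uid
  for (ch in unique(res$chain)) {
    if (is.null(pssms[[ch]]))
      stop("no PSSM supplied for antigen chain '", ch, "'")
    prof <- pssms[[ch]]
    if (!inherits(prof, "pssm_profile")) prof <- read_pssm(prof)
    in_ch <- res$chain == ch
    cons[in_ch] <- conservation_scores(prof, sequence = res$aa[in_ch])
  }

  patches <- enumerate_patches(structure, annotations, n, mode)
  cn <- NULL
  if (with_contact_number) {
    cn <- vapply(res$res_uid, function(u)
      as.numeric(contact_number(structure, u, contact_threshold)), numeric(1))
  }
  x <- t(vapply(patches, function(p)
    assemble_patch_vector(p, annotations, cons, cn),
    numeric((7 + as.integer(with_contact_number)) * n)))
  ids <- names(patches)
  rownames(x) <- ids

  y <- NULL
  if (!is.null(labels) || any(structure$residues$role == "antibody")) {
    lab <- if (is.null(labels)) label_epitopes(structure) else labels
    li <- match(ids, lab$res_uid)
    if (anyNA(li)) stop("labels missing for surface residue(s): ",
                        paste(ids[is.na(li)], collapse = ", "))
    y <- lab$label[li]
  }
  out <- list(x = x, ids = ids, y = y, patches = patches,
              annotations = annotations, structure_id = structure$id)
  class(out) <- "epitope_features"
  out
}

#' @export
print.epitope_features <- function(x, ...) {
  cat("epitope_features '", x$structure_id, "': ", nrow(x$x),
      " surface residues x ", ncol(x$x), " features",
      if (!is.null(x$y)) sprintf(" (%d epitope)", sum(x$y)), "\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' One row per patch centre; the header names encode slot semantics
#' (`r<rank>_<slot>`). A label column is included when labels are known.
#'
#' @param features An `epitope_features` object.
#' @param path Output file path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(res_uid = features$ids, features$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(features$y)) df$label <- features$y
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
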