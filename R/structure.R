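# Reading PDB structures into the residue/atom model used throughout the
# package, plus the minimal heavy-atom residue distance primitive.

res_uid <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == "", "", as.character(insert))
  paste0(chain, ":", resno, ins)
}

is_hydrogen_name <- function(elety) {
  # legacy PDB files leave the element column blank; fall back to the atom
  # name with leading digits stripped ("1HB2" etc.)
  first <- substr(sub("^[0-9]+", "", trimws(elety)), 1, 1)
  first %in% c("H", "D")
}

#' Parse a PDB structure into the antigen/antibody residue model
#'
#' Reads ATOM records (and MSE HETATM records, remapped to methionine) from a
#' PDB file or text, removes hydrogens and waters/ligands, resolves alternate
#' locations by keeping the highest-occupancy conformer of each atom, and
#' attaches a role (antigen, antibody or ignored) to every chain. Residues
#' whose type is not one of the 20 standard amino acids are skipped with a
#' warning; residues left with no heavy atom are dropped. For multi-model
#' entries only the first model is used.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines.
#' @param chain_roles Named character vector mapping chain identifiers to
#'   `"antigen"`, `"antibody"` or `"ignored"`. Chains not named are ignored.
#' @param id Structure label; defaults to the file name or `"structure"`.
#' @return An object of class `"epitope_structure"`: a list with `atoms`
#'   (one row per heavy atom: residue uid, chain, author residue number,
#'   insertion code, one-letter type, atom name, element, coordinates,
#'   occupancy), `residues` (one row per residue, in file order, with its
#'   chain role) and `chain_roles`.
#' @examples
#' fx <- generate_complex(generator_spec(n_residues = 30, seed = 1))
#' s <- parse_structure(fx$pdb, chain_roles = c(A = "antigen", B = "antibody"))
#' s
#' @export
parse_structure <- function(pdb, chain_roles, id = NULL) {
  stopifnot(is.character(pdb), length(pdb) >= 1)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  }
  if (is.null(id)) id <- "structure"
  roles <- validate_chain_roles(chain_roles)

  p <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found in '", id, "'")
  at$resid[at$resid == "MSE"] <- "MET"

  # hydrogen filter: element symbol when present, atom-name heuristic otherwise
  ele <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  hyd <- ifelse(ele != "", ele %in% c("H", "D"), is_hydrogen_name(at$elety))
  at <- at[!hyd, , drop = FALSE]
  ele <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  ele[ele == ""] <- toupper(substr(sub("^[0-9]+", "", trimws(at$elety[ele == ""])), 1, 1))

  at$chain[is.na(at$chain)] <- " "
  uid <- res_uid(at$chain, at$resno, at$insert)

  unknown <- !(at$resid %in% names(AA3_TO_1))
  if (any(unknown)) {
    skipped <- unique(paste0(at$resid[unknown], " ", uid[unknown]))
    warning("skipping ", length(skipped), " non-standard residue(s): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
    at <- at[!unknown, , drop = FALSE]
    ele <- ele[!unknown]
    uid <- uid[!unknown]
  }
  if (nrow(at) == 0) stop("no standard amino-acid residues in '", id, "'")

  # alternate locations: per atom (residue + atom name) keep max occupancy,
  # ties broken by altloc identifier order
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  key <- paste(uid, at$elety)
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]; ele <- ele[ord]; uid <- uid[ord]
  first <- !duplicated(paste(uid, at$elety))
  # only collapse rows that actually carry altloc markers; identical atom
  # names without altlocs (unusual but legal) are kept as-is
  has_alt <- stats::ave(ifelse(is.na(at$alt), 0, 1), paste(uid, at$elety),
                        FUN = max) > 0
  keep2 <- first | !has_alt
  at <- at[keep2, , drop = FALSE]; ele <- ele[keep2]; uid <- uid[keep2]
  # restore original file order
  ord2 <- order(at$eleno)
  at <- at[ord2, , drop = FALSE]; ele <- ele[ord2]; uid <- uid[ord2]

  role <- unname(roles[at$chain])
  role[is.na(role)] <- "ignored"
  keep3 <- role != "ignored"
  at <- at[keep3, , drop = FALSE]; ele <- ele[keep3]; uid <- uid[keep3]
  role <- role[keep3]
  if (!any(role == "antigen"))
    stop("structure '", id, "' has no residues in any antigen chain; ",
         "check the chain_roles assignment")

  atoms <- data.frame(
    res_uid = uid, chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    aa = unname(AA3_TO_1[at$resid]), elety = trimws(at$elety),
    element = ele, x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), role = role,
    stringsAsFactors = FALSE
  )
  firstres <- !duplicated(atoms$res_uid)
  residues <- atoms[firstres, c("res_uid", "chain", "resno", "insert", "aa", "role")]
  rownames(residues) <- NULL
  out <- list(id = id, atoms = atoms, residues = residues, chain_roles = roles)
  class(out) <- "epitope_structure"
  out
}

validate_chain_roles <- function(chain_roles) {
  if (is.null(names(chain_roles)) || any(names(chain_roles) == ""))
    stop("chain_roles must be a named vector (names are chain identifiers)")
  ok <- chain_roles %in% c("antigen", "antibody", "ignored")
  if (!all(ok))
    stop("invalid chain role(s): ", paste(unique(chain_roles[!ok]), collapse = ", "))
  if (!any(chain_roles == "antigen")) stop("at least one chain must be the antigen")
  chain_roles
}

#' @export
print.epitope_structure <- function(x, ...) {
  tab <- table(x$residues$role)
  cat("epitope_structure '", x$id, "': ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " heavy atoms\n", sep = "")
  for (r in names(tab)) {
    ch <- unique(x$residues$chain[x$residues$role == r])
    cat("  ", r, ": ", tab[[r]], " residues (chain ",
        paste(ch, collapse = ","), ")\n", sep = "")
  }
  invisible(x)
}

residue_uids <- function(structure, role = NULL) {
  r <- structure$residues
  if (!is.null(role)) r <- r[r$role %in% role, , drop = FALSE]
  r$res_uid
}

#' Coordinates of a residue's heavy atoms
#'
#' @param structure An `epitope_structure`.
#' @param uid Residue uid (`"chain:resno[insert]"`).
#' @return Numeric matrix with one row per heavy atom and columns x, y, z.
#' @export
residue_coords <- function(structure, uid) {
  a <- structure$atoms[structure$atoms$res_uid == uid, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown residue uid: ", uid)
  as.matrix(a[, c("x", "y", "z")])
}

#' Minimal heavy-atom distance between two residues
#'
#' The residue-residue distance used everywhere in the package: the minimum
#' Euclidean distance between the centres of any pair of non-hydrogen atoms,
#' one from each residue.
#'
#' @param a,b Numeric matrices of heavy-atom coordinates (rows are atoms,
#'   columns x/y/z), e.g. from [residue_coords()].
#' @return Distance in Angstrom; symmetric in its arguments.
#' @examples
#' residue_min_distance(matrix(0, 1, 3), matrix(c(0, 0, 5), 1, 3)) # 5
#' @export
residue_min_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) >= 1, nrow(b) >= 1)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

# Pairwise min heavy-atom distance matrix between two residue sets.
# Computed from one atom-level distance matrix then reduced group-wise;
# structures handled here are small enough that the dense matrix is cheap.
residue_distance_matrix <- function(structure, uids_a, uids_b = uids_a) {
  at <- structure$atoms
  ia <- match(at$res_uid, uids_a)
  ib <- match(at$res_uid, uids_b)
  A <- as.matrix(at[!is.na(ia), c("x", "y", "z")]); ga <- ia[!is.na(ia)]
  B <- as.matrix(at[!is.na(ib), c("x", "y", "z")]); gb <- ib[!is.na(ib)]
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty residue selection")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  # min over columns grouped by residue of B, then rows grouped by residue of A
  colmin <- vapply(split(seq_len(ncol(d2)), gb), function(j) {
    do.call(pmin, as.data.frame(d2[, j, drop = FALSE]))
  }, numeric(nrow(d2)))
  colmin <- matrix(colmin, nrow = nrow(d2))
  out <- t(vapply(split(seq_len(nrow(colmin)), ga), function(i) {
    apply(colmin[i, , drop = FALSE], 2, min)
  }, numeric(ncol(colmin))))
  out <- sqrt(matrix(out, nrow = length(uids_a), ncol = length(uids_b)))
  dimnames(out) <- list(uids_a, uids_b)
  out
}
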