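# Surface patches and thick surface patches: a central surface residue plus
# its n-1 spatially nearest antigen residues.

#' Build the residue patch around a surface residue
#'
#' The patch of size `n` consists of the central residue plus its `n - 1`
#' nearest antigen residues by minimal heavy-atom distance. In `"thick"`
#' mode every antigen residue is an eligible neighbour, interior residues
#' included; in `"surface"` mode only surface residues are eligible.
#' Neighbours are sorted by ascending distance, with ties broken by residue
#' file order so feature vectors are reproducible.
#'
#' @param structure An `epitope_structure`.
#' @param annotations Surface annotation data frame from [annotate_surface()].
#' @param central Residue uid of the patch centre (must be a surface residue).
#' @param n Patch size including the central residue.
#' @param mode `"thick"` (default) or `"surface"`.
#' @param distmat Optional precomputed antigen residue distance matrix (as
#'   produced internally by [enumerate_patches()]); avoids recomputation.
#' @return An object of class `"residue_patch"`: list with `central`,
#'   `adjacent` (data frame: res_uid, d, is_surface, ascending d), `mode`
#'   and `n`.
#' @export
build_patch <- function(structure, annotations, central, n = 20,
                        mode = c("thick", "surface"), distmat = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 2)
  ann <- annotations
  ci <- match(central, ann$res_uid)
  if (is.na(ci)) stop("central residue ", central, " is not an annotated antigen residue")
  if (!ann$is_surface[ci])
    stop("central residue ", central, " is interior; patches are centred on surface residues")
  eligible <- if (mode == "thick") seq_len(nrow(ann)) else which(ann$is_surface)
  eligible <- setdiff(eligible, ci)
  if (length(eligible) < n - 1)
    stop("structure '", structure$id, "': residue ", central, " has only ",
         length(eligible), " eligible ", mode, " neighbours; need ", n - 1)
  d <- if (is.null(distmat)) {
    drop(residue_distance_matrix(structure, central, ann$res_uid[eligible]))
  } else {
    distmat[central, ann$res_uid[eligible]]
  }
  ord <- order(d, eligible)[seq_len(n - 1)]
  sel <- eligible[ord]
  if (any(d[ord] <= 0))
    stop("zero residue-residue distance at ", central,
         " (duplicate coordinates?)")
  out <- list(
    central = central,
    adjacent = data.frame(res_uid = ann$res_uid[sel], d = unname(d[ord]),
                          is_surface = ann$is_surface[sel],
                          stringsAsFactors = FALSE),
    mode = mode, n = n
  )
  class(out) <- "residue_patch"
  out
}

#' @export
print.residue_patch <- function(x, ...) {
  cat(x$mode, "patch of", x$n, "residues centred on", x$central,
      sprintf("(neighbour distances %.2f-%.2f A)\n",
              min(x$adjacent$d), max(x$adjacent$d)))
  invisible(x)
}

#' Enumerate patches for every surface residue
#'
#' Builds one patch per surface antigen residue; the patch count always
#' equals the surface residue count. The antigen residue distance matrix is
#' computed once and shared across patches.
#'
#' @inheritParams build_patch
#' @return Named list of `residue_patch` objects keyed by central residue uid
#'   (empty, with a warning, when the structure has no surface residues).
#' @export
enumerate_patches <- function(structure, annotations, n = 20,
                              mode = c("thick", "surface")) {
  mode <- match.arg(mode)
  centres <- annotations$res_uid[annotations$is_surface]
  if (length(centres) == 0) {
    warning("structure '", structure$id, "' has no surface residues; no patches")
    return(structure(list(), names = character(0)))
  }
  dm <- residue_distance_matrix(structure, annotations$res_uid)
  out <- lapply(centres, function(u)
    build_patch(structure, annotations, u, n, mode, distmat = dm))
  names(out) <- centres
  out
}

#' Write a patch dump for inspection
#'
#' TSV with one row per (patch, neighbour): central uid, mode, neighbour
#' rank, neighbour uid, distance and surface flag.
#'
#' @param patches List of `residue_patch` objects.
#' @param path Output file path.
#' @export
write_patches <- function(patches, path) {
  rows <- do.call(rbind, lapply(patches, function(p) {
    data.frame(central = p$central, mode = p$mode,
               rank = seq_len(nrow(p$adjacent)), neighbour = p$adjacent$res_uid,
               d = p$adjacent$d, is_surface = p$adjacent$is_surface,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
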