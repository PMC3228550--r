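# Epitope/non-epitope labelling of antigen residues from an
# antigen-antibody complex under the 4 Angstrom contact rule.

#' Label antigen residues as epitope or non-epitope
#'
#' An antigen residue is an epitope residue when its minimal heavy-atom
#' distance to any antibody residue is strictly less than the cutoff
#' (4 Angstrom by default). Every antigen residue, interior ones included,
#' receives its minimal antibody distance for diagnostics; training instances
#' are later restricted to surface residues because patches are centred on
#' surface residues only.
#'
#' @param structure An `epitope_structure` containing at least one antigen
#'   and one antibody chain.
#' @param cutoff Strict distance cutoff in Angstrom.
#' @return Data frame, one row per antigen residue in file order: res_uid,
#'   label (1 epitope / 0 non-epitope) and min_ab_distance.
#' @examples
#' fx <- generate_complex(generator_spec(n_residues = 30, seed = 7))
#' s <- parse_structure(fx$pdb, chain_roles = c(A = "antigen", B = "antibody"))
#' table(label_epitopes(s)$label)
#' @export
label_epitopes <- function(structure, cutoff = 4.0) {
  ag <- residue_uids(structure, "antigen")
  ab <- residue_uids(structure, "antibody")
  if (length(ab) == 0)
    stop("structure '", structure$id, "' has no antibody chain; labels ",
         "cannot be derived -- use prediction-only mode or supply a label ",
         "annotation file (read_labels)")
  d <- residue_distance_matrix(structure, ag, ab)
  mind <- apply(d, 1, min)
  data.frame(res_uid = ag, label = as.integer(mind < cutoff),
             min_ab_distance = unname(mind), stringsAsFactors = FALSE)
}

#' Read a residue label annotation file
#'
#' Two-column whitespace-separated text: residue uid (`chain:resnum`) and a
#' 0/1 label; an optional third column carries the minimal antibody distance.
#' This is how epitope annotations are supplied for unbound structures, where
#' no antibody chain is present in the coordinates.
#'
#' @param path File path.
#' @return Data frame with res_uid, label and (possibly NA) min_ab_distance.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("res_uid", "label", "min_ab_distance")[
                             seq_len(max(utils::count.fields(path)))])
  if (!all(tab$label %in% c(0L, 1L))) stop("labels must be 0 or 1 in ", path)
  if (is.null(tab$min_ab_distance)) tab$min_ab_distance <- NA_real_
  tab
}

#' Write a residue label annotation file
#'
#' @param labels Data frame from [label_epitopes()] or [read_labels()].
#' @param path Output file path.
#' @export
write_labels <- function(labels, path) {
  df <- labels[, intersect(c("res_uid", "label", "min_ab_distance"),
                           names(labels)), drop = FALSE]
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
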