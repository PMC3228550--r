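# Shared fixtures, all built in code at test time.

# hand-rolled PDB line formatter, independent of the generator's writer
pdb_line <- function(type = "ATOM", serial, name, alt = " ", resname, chain,
                     resno, x, y, z, occ = 1, element = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resname, chain, resno, x, y, z, occ, 0, element)
}

# 3-residue antigen + 1-residue antibody toy with a hydrogen, an altloc pair,
# an MSE selenomethionine and a water
toy_pdb <- function() {
  c(pdb_line(serial = 1, name = "N", alt = "A", resname = "ALA", chain = "A",
             resno = 1, x = 0, y = 0, z = 0, occ = 0.6, element = "N"),
    pdb_line(serial = 2, name = "N", alt = "B", resname = "ALA", chain = "A",
             resno = 1, x = 0.5, y = 0, z = 0, occ = 0.4, element = "N"),
    pdb_line(serial = 3, name = "CA", resname = "ALA", chain = "A",
             resno = 1, x = 1.5, y = 0, z = 0, element = "C"),
    pdb_line(serial = 4, name = "HB1", resname = "ALA", chain = "A",
             resno = 1, x = 2, y = 1, z = 0, element = "H"),
    pdb_line(serial = 5, name = "CA", resname = "GLY", chain = "A",
             resno = 2, x = 5, y = 0, z = 0, element = "C"),
    pdb_line(type = "HETATM", serial = 6, name = "SE", resname = "MSE",
             chain = "A", resno = 3, x = 9, y = 0, z = 0, element = "SE"),
    pdb_line(serial = 7, name = "CA", resname = "MSE", chain = "A",
             resno = 3, x = 9.5, y = 0.5, z = 0, element = "C"),
    pdb_line(type = "HETATM", serial = 8, name = "O", resname = "HOH",
             chain = "A", resno = 90, x = 3, y = 3, z = 3, element = "O"),
    pdb_line(serial = 9, name = "CA", resname = "LYS", chain = "B",
             resno = 1, x = 0, y = 0, z = 3.9, element = "C"),
    "END")
}

toy_roles <- c(A = "antigen", B = "antibody")

# memoised synthetic fixtures (generation is deterministic, caching is purely
# a speed-up within a test file)
.fx_cache <- new.env(parent = emptyenv())

cached_complex <- function(seed = 3, shift = 0, ...) {
  key <- paste("cx", seed, shift, ..., sep = "_")
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- generate_complex(generator_spec(seed = seed,
                                                        shift = shift, ...))
  .fx_cache[[key]]
}

cached_parsed <- function(seed = 3, shift = 0, ...) {
  key <- paste("st", seed, shift, ..., sep = "_")
  if (is.null(.fx_cache[[key]])) {
    fx <- cached_complex(seed, shift, ...)
    .fx_cache[[key]] <- parse_structure(fx$pdb, c(A = "antigen", B = "antibody"),
                                        id = paste0("synth", seed))
  }
  .fx_cache[[key]]
}

cached_annotation <- function(seed = 3, shift = 0, ...) {
  key <- paste("ann", seed, shift, ..., sep = "_")
  if (is.null(.fx_cache[[key]])) {
    fx <- cached_complex(seed, shift, ...)
    .fx_cache[[key]] <- annotate_surface(cached_parsed(seed, shift, ...),
                                         dssp = fx$dssp)
  }
  .fx_cache[[key]]
}

# independent brute-force oracles -------------------------------------------

# all-pairs atom-loop minimum distance (no vectorised shortcuts)
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# rank-statistic AUC with half credit for ties (Mann-Whitney)
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
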