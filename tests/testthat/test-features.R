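fake_patch <- function(d, central = "A:1",
                       uids = paste0("A:", seq_along(d) + 1)) {
  structure(list(central = central,
                 adjacent = data.frame(res_uid = uids, d = d,
                                       is_surface = TRUE,
                                       stringsAsFactors = FALSE),
                 mode = "thick", n = length(d) + 1),
            class = "residue_patch")
}

test_that("ARD weights follow the inverse-distance formula", {
  # equidistant neighbours share the weight equally
  expect_equal(unname(ard_weights(fake_patch(rep(2.5, 4)))), rep(0.25, 4))
  # d = 1 and 3: p = 1, 1/3 -> S = 0.75, 0.25
  expect_equal(unname(ard_weights(fake_patch(c(1, 3)))), c(0.75, 0.25))
  # random patches: direct formula re-evaluation, unit sum, monotone decreasing
  set.seed(4)
  for (rep in 1:20) {
    d <- sort(runif(19, 2, 14))
    s <- ard_weights(fake_patch(d))
    expect_equal(unname(s), (1 / d) / sum(1 / d), tolerance = 1e-12)
    expect_equal(sum(s), 1, tolerance = 1e-9)
    expect_true(all(diff(unname(s)) <= 0))
  }
  expect_error(ard_weights(fake_patch(c(0, 1))), "non-positive")
})

test_that("conservation scores match the truncated-difference formula", {
  mk_pssm <- function(aa, M) {
    scores <- matrix(0L, length(aa), 20, dimnames = list(NULL, epipatch:::AA1))
    scores[cbind(seq_along(aa), match(aa, epipatch:::AA1))] <- M
    structure(list(sequence = paste(aa, collapse = ""), scores = scores),
              class = "pssm_profile")
  }
  # boundary: M equal to the diagonal gives 0
  expect_equal(conservation_scores(mk_pssm("A", 4L)), 0)
  # ALA with M = 1 (B = 4) -> |1 - 4| = 3
  expect_equal(conservation_scores(mk_pssm("A", 1L)), 3)
  # TRP with M = 12 (B = 11) -> 12 - 11 >= 0 -> 0
  expect_equal(conservation_scores(mk_pssm("W", 12L)), 0)
  # grid over all 20 types and M in -5..15: zero iff M >= B_rr
  for (aa in epipatch:::AA1) {
    B <- blosum62_diagonal[[aa]]
    for (M in -5:15) {
      sc <- conservation_scores(mk_pssm(aa, as.integer(M)))
      expect_identical(sc == 0, M >= B)
      expect_equal(sc, if (M < B) abs(M - B) else 0)
    }
  }
  expect_error(conservation_scores(mk_pssm(c("A", "G"), c(1L, 1L)),
                                   sequence = "AGW"), "length mismatch")
})

test_that("composition assigns each residue its type's patch fraction", {
  p <- fake_patch(rep(3, 19), central = "A:1", uids = paste0("A:", 2:20))
  aa <- structure(c("A", rep("A", 9), rep("G", 10)),
                  names = paste0("A:", 1:20))
  comp <- composition_feature(p, aa)
  expect_equal(unname(comp), rep(0.5, 20)) # 10 ALA + 10 GLY split
  aa2 <- structure(rep("W", 20), names = paste0("A:", 1:20))
  expect_equal(unname(composition_feature(p, aa2)), rep(1, 20))
  # counting oracle on random type assignments
  set.seed(9)
  for (rep in 1:10) {
    aa3 <- structure(sample(epipatch:::AA1, 20, replace = TRUE),
                     names = paste0("A:", 1:20))
    comp3 <- composition_feature(p, aa3)
    for (u in names(comp3))
      expect_equal(comp3[[u]], sum(aa3 == aa3[[u]]) / 20)
  }
})

test_that("contact number counts CA atoms within the threshold", {
  mk <- function(coords) {
    lines <- c(vapply(seq_len(nrow(coords)), function(i)
      pdb_line(serial = i, name = "CA", resname = "ALA", chain = "A",
               resno = i, x = coords[i, 1], y = coords[i, 2], z = coords[i, 3],
               element = "C"), character(1)), "END")
    parse_structure(lines, c(A = "antigen"))
  }
  s1 <- mk(matrix(c(0, 0, 0), 1))
  expect_equal(contact_number(s1, "A:1"), 0)
  s2 <- mk(rbind(c(0, 0, 0), c(9.9, 0, 0)))
  expect_equal(contact_number(s2, "A:1"), 1)
  expect_equal(contact_number(s2, "A:2"), 1)
  # all-pairs oracle on a synthetic globule
  s <- cached_parsed(seed = 3)
  ca <- s$atoms[s$atoms$elety == "CA" & s$atoms$role == "antigen", ]
  for (i in c(1, 17, 40)) {
    d <- sqrt((ca$x - ca$x[i])^2 + (ca$y - ca$y[i])^2 + (ca$z - ca$z[i])^2)
    expect_equal(contact_number(s, ca$res_uid[i]), sum(d[-i] <= 10))
  }
})

test_that("PSSM fixtures round-trip through the reader", {
  txt <- generate_pssm("ARNDCQEGHILKMFPSTWYV", conserved_positions = 1:10,
                       seed = 21)
  p <- read_pssm(txt)
  expect_equal(p$sequence, "ARNDCQEGHILKMFPSTWYV")
  expect_equal(dim(p$scores), c(20, 20))
  sc <- conservation_scores(p)
  expect_equal(sc[1:10], rep(0, 10))
  expect_true(all(sc[11:20] > 0))
})

test_that("assembled vectors have 7 slots per residue in the documented order", {
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  cons <- structure(seq_len(nrow(ann)) / 10, names = ann$res_uid)
  u <- ann$res_uid[ann$is_surface][3]
  for (n in c(12, 20)) {
    p <- build_patch(s, ann, u, n = n)
    v <- assemble_patch_vector(p, ann, cons)
    expect_length(v, 7 * n)
    # slot-by-slot check against hand-assembled expectation
    uids <- c(p$central, p$adjacent$res_uid)
    ard <- c(0, unname(ard_weights(p)))
    aa <- structure(ann$aa, names = ann$res_uid)
    comp <- composition_feature(p, aa)
    for (k in seq_along(uids)) {
      ai <- match(uids[k], ann$res_uid)
      exp_block <- c(ann$rasa[ai], cons[[uids[k]]], ard[k], comp[[uids[k]]],
                     as.numeric(ann$ss3[ai] == c("helix", "sheet", "coil")))
      expect_equal(unname(v[(7 * (k - 1) + 1):(7 * k)]), exp_block,
                   tolerance = 1e-12)
    }
    # one-hot secondary structure sums to 1 per residue
    ssm <- matrix(v, ncol = 7, byrow = TRUE)[, 5:7]
    expect_equal(rowSums(ssm), rep(1, n))
  }
})

test_that("the optional contact-number slot extends the vector to 8 per residue", {
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  cons <- structure(rep(1, nrow(ann)), names = ann$res_uid)
  cn <- structure(rep(5, nrow(ann)), names = ann$res_uid)
  p <- build_patch(s, ann, ann$res_uid[ann$is_surface][1], n = 20)
  v <- assemble_patch_vector(p, ann, cons, contact_numbers = cn)
  expect_length(v, 8 * 20)
  expect_true(all(grepl("_cn$", names(v)[seq(8, 160, by = 8)])))
})

test_that("feature assembly errors when conservation is missing", {
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  p <- build_patch(s, ann, ann$res_uid[ann$is_surface][1], n = 20)
  cons <- structure(rep(1, 5), names = ann$res_uid[1:5])
  expect_error(assemble_patch_vector(p, ann, cons), "missing conservation")
})

test_that("structure_features is deterministic and shaped one-row-per-surface-residue", {
  fx <- cached_complex(seed = 3)
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  pssm <- read_pssm(generate_pssm(fx$sequences$A, 1:30, seed = 5))
  f1 <- structure_features(s, list(A = pssm), annotations = ann)
  f2 <- structure_features(s, list(A = pssm), annotations = ann)
  expect_identical(f1$x, f2$x)
  expect_equal(nrow(f1$x), sum(ann$is_surface))
  expect_equal(ncol(f1$x), 140)
  expect_true(all(is.finite(f1$x)))
  expect_equal(length(f1$y), nrow(f1$x))
  expect_error(structure_features(s, list()), "no PSSM")
})
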