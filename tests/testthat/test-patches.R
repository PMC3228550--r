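# hand-made straight chain: 10 single-atom residues, 4 Angstrom apart
linear_chain <- function() {
  lines <- c(vapply(1:10, function(i)
    pdb_line(serial = i, name = "CA", resname = "GLY", chain = "A",
             resno = i, x = 4 * (i - 1), y = 0, z = 0, element = "C"),
    character(1)), "END")
  parse_structure(lines, c(A = "antigen"))
}

linear_annotations <- function(interior = integer(0)) {
  data.frame(res_uid = paste0("A:", 1:10), aa = "G", sasa = 100, rasa = 1,
             is_surface = !(1:10 %in% interior), ss3 = "coil",
             stringsAsFactors = FALSE)
}

test_that("a straight chain's thick patch contains the sequence flankers", {
  s <- linear_chain()
  p <- build_patch(s, linear_annotations(), "A:5", n = 5, mode = "thick")
  expect_equal(sort(p$adjacent$res_uid), sort(paste0("A:", c(3, 4, 6, 7))))
  expect_equal(sort(p$adjacent$d), c(4, 4, 8, 8))
  # ascending distance order
  expect_false(is.unsorted(p$adjacent$d))
})

test_that("surface mode excludes interior residues and substitutes the next nearest", {
  s <- linear_chain()
  p <- build_patch(s, linear_annotations(interior = 4), "A:5", n = 5,
                   mode = "surface")
  expect_false("A:4" %in% p$adjacent$res_uid)
  # next-nearest eligible residues substitute; A:2 and A:8 tie at 12 Angstrom
  # and the deterministic file-order tie-break picks A:2
  expect_equal(sort(p$adjacent$res_uid), sort(paste0("A:", c(2, 3, 6, 7))))
})

test_that("an interior centre or too-small structure is a hard error", {
  s <- linear_chain()
  expect_error(build_patch(s, linear_annotations(interior = 5), "A:5", n = 5),
               "interior")
  expect_error(build_patch(s, linear_annotations(), "A:5", n = 11),
               "eligible")
})

test_that("patches equal the exhaustive distance-sort oracle on synthetic globules", {
  for (sd in c(3, 7)) {
    s <- cached_parsed(seed = sd)
    ann <- cached_annotation(seed = sd)
    uids <- ann$res_uid
    set.seed(sd)
    centres <- sample(ann$res_uid[ann$is_surface], 8)
    for (u in centres) {
      # brute force: all residue distances to the centre, exhaustive sort
      d_all <- vapply(uids, function(v)
        residue_min_distance(residue_coords(s, u), residue_coords(s, v)),
        numeric(1))
      for (mode in c("thick", "surface")) {
        elig <- if (mode == "thick") uids else uids[ann$is_surface]
        elig <- setdiff(elig, u)
        expected <- sort(d_all[elig])[1:19]
        p <- build_patch(s, ann, u, n = 20, mode = mode)
        expect_equal(p$adjacent$d, unname(expected), tolerance = 1e-12)
      }
    }
  }
})

test_that("thick patches never reach farther than surface patches", {
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  for (u in ann$res_uid[ann$is_surface]) {
    pt <- build_patch(s, ann, u, n = 15, mode = "thick")
    ps <- build_patch(s, ann, u, n = 15, mode = "surface")
    expect_lte(max(pt$adjacent$d), max(ps$adjacent$d) + 1e-12)
  }
})

test_that("enumerate_patches yields exactly one valid patch per surface residue", {
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  ps <- enumerate_patches(s, ann, n = 20, mode = "thick")
  expect_equal(length(ps), sum(ann$is_surface))
  expect_equal(names(ps), ann$res_uid[ann$is_surface])
  for (p in ps) {
    expect_equal(nrow(p$adjacent), 19)
    expect_true(all(p$adjacent$d > 0))
    expect_false(is.unsorted(p$adjacent$d))
  }
  # pathological all-interior annotation: zero patches with a warning
  ann0 <- ann; ann0$is_surface <- FALSE
  expect_warning(p0 <- enumerate_patches(s, ann0, n = 20), "no surface")
  expect_length(p0, 0)
})

test_that("patch construction is invariant to rigid-body transforms", {
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  u <- ann$res_uid[ann$is_surface][5]
  p0 <- build_patch(s, ann, u, n = 20)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2$atoms$x <- xyz[, 1] + 25; s2$atoms$y <- xyz[, 2] - 8; s2$atoms$z <- xyz[, 3]
  p1 <- build_patch(s2, ann, u, n = 20)
  expect_equal(p1$adjacent$res_uid, p0$adjacent$res_uid)
  expect_equal(p1$adjacent$d, p0$adjacent$d, tolerance = 1e-9)
})
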