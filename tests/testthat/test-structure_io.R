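test_that("parsing filters hydrogens, waters and unknown residues, keeps MSE as MET", {
  s <- parse_structure(toy_pdb(), toy_roles, id = "toy")
  expect_s3_class(s, "epitope_structure")
  # hydrogen and water gone
  expect_false(any(s$atoms$element %in% c("H", "D")))
  expect_false(any(grepl("^H", s$atoms$elety)))
  expect_false(any(s$residues$resno == 90))
  # MSE remapped to methionine, selenium atom retained
  expect_equal(s$residues$aa[s$residues$resno == 3], "M")
  expect_true("SE" %in% s$atoms$element)
  # 3 antigen residues + 1 antibody residue
  expect_equal(sum(s$residues$role == "antigen"), 3)
  expect_equal(sum(s$residues$role == "antibody"), 1)
})

test_that("alternate locations keep only the highest-occupancy conformer", {
  s <- parse_structure(toy_pdb(), toy_roles)
  n_at_1 <- s$atoms[s$atoms$res_uid == "A:1" & s$atoms$elety == "N", ]
  expect_equal(nrow(n_at_1), 1)
  expect_equal(n_at_1$o, 0.6)
  expect_equal(n_at_1$x, 0) # the 60%-occupancy A conformer
})

test_that("unknown residue types are skipped with a warning", {
  lines <- c(toy_pdb()[1:9],
             pdb_line(serial = 20, name = "C1", resname = "LIG", chain = "A",
                      resno = 50, x = 7, y = 7, z = 7, element = "C"),
             "END")
  expect_warning(s <- parse_structure(lines, toy_roles), "non-standard")
  expect_false("A:50" %in% s$residues$res_uid)
})

test_that("a structure without antigen residues is a hard error", {
  expect_error(parse_structure(toy_pdb(), c(C = "antigen", A = "ignored", B = "ignored")),
               "no residues in any antigen chain|no antigen")
  expect_error(parse_structure(toy_pdb(), c(A = "antibody", B = "antibody")),
               "at least one chain must be the antigen")
  expect_error(parse_structure(toy_pdb(), c(A = "bogus")), "invalid chain role")
})

test_that("residue_min_distance matches examples and the brute-force oracle", {
  expect_equal(residue_min_distance(matrix(0, 1, 3), matrix(0, 1, 3)), 0)
  expect_equal(residue_min_distance(matrix(c(0, 0, 0), 1, 3),
                                    matrix(c(0, 0, 5), 1, 3)), 5.0)
  set.seed(11)
  for (rep in 1:10) {
    a <- matrix(rnorm(15, sd = 4), ncol = 3)
    b <- matrix(rnorm(12, sd = 4), ncol = 3)
    expect_equal(residue_min_distance(a, b), brute_min_dist(a, b))
    # symmetry
    expect_equal(residue_min_distance(a, b), residue_min_distance(b, a))
    # lower bound: min distance never exceeds any specific atom pair
    expect_lte(residue_min_distance(a, b), sqrt(sum((a[1, ] - b[1, ])^2)) + 1e-12)
  }
})

test_that("residue_distance_matrix agrees with pairwise residue_min_distance", {
  s <- cached_parsed(seed = 5)
  uids <- residue_uids(s, "antigen")[1:12]
  dm <- epipatch:::residue_distance_matrix(s, uids)
  for (i in c(1, 4, 9)) for (j in c(2, 7, 12)) {
    expect_equal(dm[i, j],
                 residue_min_distance(residue_coords(s, uids[i]),
                                      residue_coords(s, uids[j])))
  }
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, length(uids)))
})

test_that("parsing the generator's PDB output round-trips residues and coordinates", {
  fx <- cached_complex(seed = 5)
  s <- cached_parsed(seed = 5)
  man <- fx$manifest$residues
  ag <- s$residues[s$residues$role == "antigen", ]
  expect_equal(nrow(ag), nrow(man))
  expect_equal(ag$res_uid, man$res_uid)
  expect_equal(ag$aa, man$aa)
  ca <- s$atoms[s$atoms$elety == "CA" & s$atoms$role == "antigen", ]
  expect_equal(ca$x, man$x, tolerance = 1e-3)
  expect_equal(ca$y, man$y, tolerance = 1e-3)
  expect_equal(ca$z, man$z, tolerance = 1e-3)
})
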