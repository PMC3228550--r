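test_that("confusion metrics follow their defining formulas", {
  m <- confusion_metrics(tp = 1, tn = 8, fp = 1, fn = 0)
  expect_equal(m$SN, 1.0)
  expect_equal(m$SP, 8 / 9)
  expect_equal(m$ACC, 0.9)
  expect_equal(m$precision, 0.5)
  expect_equal(m$F, 2 / 3)
  # perfect classifier
  mp <- confusion_metrics(5, 5, 0, 0)
  expect_equal(unlist(mp), c(SN = 1, SP = 1, ACC = 1, precision = 1,
                             recall = 1, F = 1))
  # zero numerator
  expect_equal(confusion_metrics(0, 5, 2, 3)$SN, 0)
  # undefined metrics are NA, never 0
  expect_true(is.na(confusion_metrics(0, 5, 0, 0)$precision))
  expect_true(is.na(confusion_metrics(0, 0, 0, 5)$SP))
  # random count tables: recompute from the printed formulas
  set.seed(13)
  for (rep in 1:25) {
    k <- sample(0:30, 4, replace = TRUE)
    m <- confusion_metrics(k[1], k[2], k[3], k[4])
    if (k[1] + k[4] > 0) expect_equal(m$SN, k[1] / (k[1] + k[4]), tolerance = 1e-12)
    if (k[2] + k[3] > 0) expect_equal(m$SP, k[2] / (k[2] + k[3]), tolerance = 1e-12)
    if (sum(k) > 0) expect_equal(m$ACC, (k[1] + k[2]) / sum(k), tolerance = 1e-12)
    if (!is.na(m$precision) && !is.na(m$SN) && m$precision + m$SN > 0)
      expect_equal(m$F, 2 * m$precision * m$SN / (m$precision + m$SN),
                   tolerance = 1e-12)
  }
})

test_that("vote-sweep AUC equals the rank-statistic oracle", {
  # degenerate scorers
  expect_equal(roc_auc(rep(3, 10), rep(0:1, 5), n_sub = 10)$auc, 0.5)
  perf <- roc_auc(c(9, 8, 7, 2, 1, 0), c(1, 1, 1, 0, 0, 0), n_sub = 10)
  expect_equal(perf$auc, 1.0)
  # curve spans the two corners
  expect_true(any(perf$points$fpr == 0 & perf$points$tpr == 0))
  expect_true(any(perf$points$fpr == 1 & perf$points$tpr == 1))
  # random vote/label sets vs Mann-Whitney with tie credit
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(6:40, 1); ns <- sample(4:12, 1)
    votes <- sample(0:ns, n, replace = TRUE)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(votes, labels, ns)$auc, rank_auc(votes, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5), 5), "positive and one negative")
})

test_that("LOOCV partitions by structure with no leakage", {
  ds <- simulate_epitope_dataset(2, spec = generator_spec(n_residues = 40),
                                 seed = 3)
  cv <- suppressWarnings(epitope_loocv(ds, seed = 1))
  expect_equal(nrow(cv$per_structure), 2)
  expect_setequal(cv$per_structure$structure, c("synth01", "synth02"))
  # every instance appears exactly once in the predictions, under its own fold
  expect_equal(sort(paste(cv$predictions$structure, cv$predictions$res_uid)),
               sort(unlist(lapply(ds, function(d)
                 paste(d$structure_id, d$ids)))))
  # counts add up per structure
  with(cv$per_structure, expect_equal(TP + TN + FP + FN, n))
  expect_error(epitope_loocv(ds[1]), "length")
})

test_that("paired t-test matches the closed form and stats::t.test", {
  x <- c(7.1, 6.4, 8.0, 5.9, 7.7)
  y <- c(6.8, 6.6, 7.1, 5.5, 7.0)
  r <- epipatch:::paired_t_test(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # hand-computed toy: d = (1, 2, 3), t = 2/(1/sqrt(3)) = 2*sqrt(3)
  r2 <- epipatch:::paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-12)
})

test_that("identical patch sets for both classes give zero difference and p = 1", {
  s <- cached_parsed(seed = 3)
  ann <- cached_annotation(seed = 3)
  ps <- enumerate_patches(s, ann, n = 10)
  half <- length(ps) %/% 2
  # duplicate the same patches under both labels
  patches <- c(ps[1:half], setNames(ps[1:half], paste0("dup_", names(ps)[1:half])))
  labels <- structure(c(rep(1, half), rep(0, half)), names = names(patches))
  dp <- patch_distance_statistics(patches, labels)
  expect_equal(dp$by_k$epitope, dp$by_k$non_epitope, tolerance = 1e-12)
  expect_equal(dp$p_k, 1)
})

test_that("distance statistics recover the planted shift direction", {
  fx <- cached_complex(seed = 11, shift = 0.5)
  s <- parse_structure(fx$pdb, c(A = "antigen", B = "antibody"))
  ann <- annotate_surface(s, dssp = fx$dssp)
  ps <- enumerate_patches(s, ann, n = 20)
  labels <- structure(fx$labels$label, names = fx$labels$res_uid)
  aa <- structure(ann$aa, names = ann$res_uid)
  dp <- patch_distance_statistics(ps, labels, aa)
  expect_true(all(dp$by_k$epitope > dp$by_k$non_epitope))
  expect_equal(dp$n_pos + dp$n_neg, length(ps))
  # by-type table only pairs types present in both classes
  paired <- dp$by_type$n_epitope > 0 & dp$by_type$n_non > 0
  expect_true(all(!is.na(dp$by_type$epitope[paired])))
})
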