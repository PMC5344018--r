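# two-tip fixture with controllable node values: root 3, tips 1 and 2
two_tip_records <- function(v_root, v_a, v_b, t_a = 1, t_b = 1) {
  tr <- ape::read.tree(text = sprintf("(A:%g,B:%g);", t_a, t_b))
  branch_changes(tr, c(v_a, v_b, v_root))
}

test_that("darwins has its defining unit and hand-computed values", {
  rec <- two_tip_records(1.0, exp(1), 1.0)
  ia <- which(rec$child_label == "A")
  expect_equal(rec$darwins[ia], 1.0, tolerance = 1e-12)
  ib <- which(rec$child_label == "B")
  expect_equal(rec$change[ib], 0)
  expect_equal(rec$darwins[ib], 0)

  rec2 <- two_tip_records(1.2, 1.5, 1.2, t_a = 2)
  i2 <- which(rec2$child_label == "A")
  expect_equal(rec2$change[i2], 0.3, tolerance = 1e-12)
  expect_equal(rec2$darwins[i2], abs(log(1.25)) / 2, tolerance = 1e-12)
  expect_equal(rec2$darwins[i2], 0.111572, tolerance = 1e-5)
})

test_that("darwins is invariant to trait-unit rescaling, change is not", {
  tr <- simulate_yule_tree(15, 0.2, seed = 3)
  sim <- simulate_bm_bivariate(tr, seed = 4)
  rec_mm <- branch_changes(tr, sim$node_values[, "male"])
  rec_um <- branch_changes(tr, sim$node_values[, "male"] * 1000)
  expect_equal(rec_um$darwins, rec_mm$darwins, tolerance = 1e-12)
  expect_equal(rec_um$change, rec_mm$change * 1000, tolerance = 1e-9)
})

test_that("undefined darwins are flagged, never zeroed", {
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  tr <- resolve_polytomies(poly, seed = 1)
  m <- length(tr$tip.label) + tr$Nnode
  rec <- branch_changes(tr, seq_len(m) + 0.5)
  zl <- rec$duration == 0
  expect_true(any(zl))
  expect_true(all(is.na(rec$darwins[zl])))
  expect_true(all(!rec$darwins_defined[zl]))
  # negative trait values also yield undefined darwins
  rec2 <- two_tip_records(-1, 2, 1)
  expect_true(any(!rec2$darwins_defined))
})

test_that("per-branch changes telescope from root to each tip", {
  tr <- simulate_yule_tree(20, 0.2, seed = 6)
  sim <- simulate_bm_bivariate(tr, seed = 7)
  vals <- sim$node_values[, "female"]
  rec <- branch_changes(tr, vals)
  root <- length(tr$tip.label) + 1L
  parent <- stats::setNames(rec$parent, rec$child)
  chg <- stats::setNames(rec$change, rec$child)
  for (tip in seq_len(length(tr$tip.label))) {
    tot <- 0; node <- tip
    while (node != root) {
      tot <- tot + chg[[as.character(node)]]
      node <- parent[[as.character(node)]]
    }
    expect_equal(tot, vals[tip] - vals[root], tolerance = 1e-10)
  }
})

test_that("5% coding rules follow the thresholds", {
  recs <- function(mi, mf, fi, ff) {
    tr <- ape::read.tree(text = "(A:1,B:1);")
    list(m = branch_changes(tr, c(mf, mi, mi)),
         f = branch_changes(tr, c(ff, fi, fi)))
  }
  # male 1.00 -> 1.04: 4% < 5% => "="
  r <- recs(1.00, 1.04, 1.00, 1.00)
  c1 <- code_branches(r$m, r$f, ssd_range = 0.5)
  ia <- which(c1$child == 1L)
  expect_equal(c1$code_male[ia], "=")
  # male 1.00 -> 1.10: 10% => "+"
  r <- recs(1.00, 1.10, 1.00, 1.00)
  c2 <- code_branches(r$m, r$f, ssd_range = 0.5)
  expect_equal(c2$code_male[ia], "+")
  # SSD: range 0.5 mm => threshold 0.025; delta 0.02 => "=", -0.04 => "-"
  r <- recs(1.00, 1.02, 1.00, 1.00)       # dSSD = +0.02
  expect_equal(code_branches(r$m, r$f, ssd_range = 0.5)$code_ssd[ia], "=")
  r <- recs(1.00, 0.96, 1.00, 1.00)       # dSSD = -0.04
  expect_equal(code_branches(r$m, r$f, ssd_range = 0.5)$code_ssd[ia], "-")
  # all-changes mode has no "=" category for nonzero change
  r <- recs(1.00, 1.02, 1.00, 1.00)
  expect_equal(
    code_branches(r$m, r$f, ssd_range = 0.5, mode = "all_changes")$code_male[ia],
    "+")
})

test_that("coding is monotone in |change|", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  f0 <- branch_changes(tr, c(1, 1, 1))
  deltas <- seq(0, 0.3, by = 0.01)
  codes <- vapply(deltas, function(d) {
    m <- branch_changes(tr, c(1 + d, 1, 1))
    code_branches(m, f0, ssd_range = 1)$code_male[
      which(m$child_label == "A")]
  }, character(1))
  # once "+" appears it never reverts to "="
  first_plus <- match("+", codes)
  expect_true(all(codes[first_plus:length(codes)] == "+"))
})

test_that("cross-tabulation conserves branch counts", {
  d <- limnebius_like_dataset(seed = 11, n_tips = 31)
  am <- asr_bm(d$tree, stats::setNames(d$traits$male_length,
                                       d$traits$species))
  af <- asr_bm(d$tree, stats::setNames(d$traits$female_length,
                                       d$traits$species))
  rm_ <- branch_changes(d$tree, am)
  rf_ <- branch_changes(d$tree, af)
  for (mode in c("over_5pct", "all_changes")) {
    codes <- code_branches(rm_, rf_, mode = mode)
    tab <- crosstab(codes)
    expect_equal(sum(tab$count), nrow(codes))
    expect_equal(attr(tab, "total"), 2 * 31 - 2)
  }
})

test_that("the exact binomial sign test reproduces known values", {
  expect_equal(sign_binomial_test(24, 7), 0.003326893, tolerance = 1e-6)
  expect_lt(sign_binomial_test(24, 7), 0.005)
  expect_equal(sign_binomial_test(5, 5), 1.0)
  expect_error(sign_binomial_test(0, 0), "zero")
  expect_error(sign_binomial_test(-1, 3), "non-negative")
})

test_that("rate-difference regression: degenerate and replication cases", {
  tr <- simulate_yule_tree(20, 0.2, seed = 13)
  sim <- simulate_bm_bivariate(tr, seed = 14)
  recm <- branch_changes(tr, sim$node_values[, "male"])
  recf0 <- recm
  recf0$darwins <- 0
  recf0$abs_change <- 0
  recf0$darwins_defined <- TRUE
  # female metric identically 0: difference == male metric (the perfect
  # fit makes lm warn about its own summary; expected here)
  fit <- suppressWarnings(
    rate_difference_regression(recm, recf0, metric = "darwins"))
  expect_equal(fit$male$slope, 1, tolerance = 1e-10)
  expect_equal(fit$male$r2, 1, tolerance = 1e-10)
  # duplicating rows leaves OLS slopes unchanged
  recf <- branch_changes(tr, sim$node_values[, "female"])
  f1 <- rate_difference_regression(recm, recf, metric = "absolute")
  f2 <- rate_difference_regression(rbind(recm, recm), rbind(recf, recf),
                                   metric = "absolute")
  expect_equal(f2$male$slope, f1$male$slope, tolerance = 1e-10)
  expect_equal(f2$female$slope, f1$female$slope, tolerance = 1e-10)
})

test_that("male-biased rates dominate the male-driven summary cells", {
  tr <- simulate_yule_tree(40, 0.2, seed = 17)
  sim <- simulate_bm_bivariate(tr, sigma_male = 0.15, sigma_female = 0.015,
                               rho = 0.5, seed = 18)
  recm <- branch_changes(tr, sim$node_values[, "male"])
  recf <- branch_changes(tr, sim$node_values[, "female"])
  codes <- code_branches(recm, recf)
  moved <- codes[codes$code_ssd != "=", ]
  expect_gt(sum(moved$code_male != "="), sum(moved$code_female != "="))
  fit <- rate_difference_regression(recm, recf, metric = "darwins")
  expect_gt(fit$male$r2, fit$female$r2)
})
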