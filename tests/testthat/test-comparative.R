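test_that("contrasts follow the hand formula on a cherry", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  p <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(nrow(p$contrasts), 1L)
  expect_equal(abs(p$contrasts$contrast), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(p$contrasts$variance, 2)
})

test_that("identical tip values give all-zero contrasts; n-1 of them", {
  tr <- simulate_yule_tree(17, 0.2, seed = 2)
  p <- pic_contrasts(tr, stats::setNames(rep(1.3, 17), tr$tip.label))
  expect_equal(nrow(p$contrasts), 16L)
  expect_equal(p$contrasts$contrast, rep(0, 16))
})

test_that("contrasts agree with an independent implementation", {
  for (seed in 1:5) {
    tr <- random_tree(12, seed + 40)
    x <- random_named_values(tr, seed + 80)
    mine <- pic_contrasts(tr, x)$contrasts
    ref <- ape::pic(x[tr$tip.label], tr)
    expect_equal(sort(abs(mine$contrast)), sort(abs(unname(ref))),
                 tolerance = 1e-10)
  }
})

test_that("polytomies are refused with a pointer to the resolver", {
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(pic_contrasts(poly, c(A = 1, B = 2, C = 3)),
               "resolve_polytomies")
})

test_that("contrasts under BM are standardized and uncorrelated", {
  tr <- simulate_yule_tree(50, 0.2, seed = 9)
  cons <- unlist(lapply(1:40, function(i) {
    sim <- simulate_bm_bivariate(tr, sigma_male = 0.2, sigma_female = 0.2,
                                 rho = 1, seed = 700 + i)
    pic_contrasts(tr, stats::setNames(sim$tips$male_length,
                                      sim$tips$species))$contrasts$contrast
  }))
  expect_lt(abs(stats::var(cons) / 0.04 - 1), 0.15)
  # no relation between a contrast's position in the traversal and value
  expect_lt(abs(stats::cor(seq_along(cons), cons)), 0.05)
})

test_that("RMA recovers exact lines and the through-origin hand case", {
  f <- rma(c(1, 2, 3), c(2, 4, 6), ci_method = "bootstrap", seed = 1)
  expect_equal(f$slope, 2)
  expect_equal(f$r2, 1)
  expect_equal(f$p, 0)
  expect_equal(c(f$ci_low, f$ci_high), c(2, 2))

  g <- rma(c(1, 2, 1), c(1, 4, 1), through_origin = TRUE,
           ci_method = "analytic")
  # slope = sqrt(sum y^2 / sum x^2) = sqrt(18/6)
  expect_equal(g$slope, sqrt(3), tolerance = 1e-12)

  expect_error(rma(c(1, 1, 1), c(1, 2, 3)), "zero variation")
  expect_error(rma(c(1, 2), c(1, 2)), "at least 3")
})

test_that("standard RMA slopes are reciprocal under axis exchange", {
  set.seed(14)
  x <- rnorm(30); y <- 1.4 * x + rnorm(30, 0, 0.4)
  f1 <- rma(x, y, ci_method = "analytic")
  f2 <- rma(y, x, ci_method = "analytic")
  expect_equal(f1$slope, 1 / f2$slope, tolerance = 1e-12)
})

test_that("bootstrap RMA interval covers a known SD ratio", {
  # bivariate normal, SD ratio 1.44, r = 0.9: the RMA slope estimates the
  # SD ratio; check calibration over replicates
  cover <- vapply(1:30, function(i) {
    set.seed(1000 + i)
    x <- rnorm(59)
    y <- 1.44 * (0.9 * x + sqrt(1 - 0.81) * rnorm(59))
    f <- rma(x, y, ci_method = "bootstrap", n_boot = 300, seed = i)
    f$ci_low <= 1.44 && 1.44 <= f$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("contrast correlation is symmetric and exact for identical traits", {
  tr <- simulate_yule_tree(20, 0.2, seed = 21)
  sim <- simulate_bm_bivariate(tr, seed = 22)
  x <- stats::setNames(sim$tips$male_length, sim$tips$species)
  y <- stats::setNames(sim$tips$female_length, sim$tips$species)
  expect_equal(contrast_correlation(tr, x, x, ci_method = "analytic")$r2, 1)
  f_xy <- contrast_correlation(tr, x, y, ci_method = "analytic")
  f_yx <- contrast_correlation(tr, y, x, ci_method = "analytic")
  expect_equal(f_xy$r2, f_yx$r2, tolerance = 1e-12)
  bad <- x; names(bad)[1] <- "nope"
  expect_error(contrast_correlation(tr, bad, y), "nope")
})

test_that("Blomberg's K matches an independent implementation", {
  skip_if_not_installed("picante")
  for (seed in 1:4) {
    tr <- random_tree(15, seed + 200)
    x <- random_named_values(tr, seed + 300)
    k <- blomberg_k(tr, x, n_perm = 19, seed = 1)
    expect_equal(k$K, as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-10)
  }
})

test_that("K is invariant to affine trait maps and branch-length scaling", {
  tr <- simulate_yule_tree(25, 0.2, seed = 31)
  sim <- simulate_bm_bivariate(tr, seed = 32)
  x <- stats::setNames(sim$tips$male_length, sim$tips$species)
  k0 <- blomberg_k(tr, x, n_perm = 9, seed = 5)$K
  expect_equal(blomberg_k(tr, 3.2 * x - 7, n_perm = 9, seed = 5)$K, k0,
               tolerance = 1e-10)
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  expect_equal(blomberg_k(tr2, x, n_perm = 9, seed = 5)$K, k0,
               tolerance = 1e-10)
  expect_error(blomberg_k(tr, x * 0, n_perm = 9), "constant")
})

test_that("permutation p is small for strongly structured data", {
  tr <- simulate_yule_tree(40, 0.2, seed = 41)
  sim <- simulate_bm_bivariate(tr, seed = 43)
  x <- stats::setNames(sim$tips$male_length, sim$tips$species)
  k <- blomberg_k(tr, x, n_perm = 199, seed = 7)
  expect_lt(k$p, 0.05)
  expect_gt(k$p, 0)
})
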