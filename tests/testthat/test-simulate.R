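test_that("cell-type simulation hits its marginal expectations and is seed-stable", {
  sim <- simulate_celltype_specific(seed = 61)
  bg <- sim$matrix$values[sim$labels == "background", ]
  sp <- sim$matrix$values[sim$labels == "specific", ]
  # expected load: background 100*0.3 = 30, specific 10*0.9 + 90*0.1 = 18
  se_bg <- sqrt(100 * 0.3 * 0.7 / nrow(bg))
  se_sp <- sqrt((10 * 0.09 + 90 * 0.09) / nrow(sp))
  expect_lt(abs(mean(rowSums(bg)) - 30), 3 * se_bg)
  expect_lt(abs(mean(rowSums(sp)) - 18), 3 * se_sp)
  sim2 <- simulate_celltype_specific(seed = 61)
  expect_identical(sim$matrix$values, sim2$matrix$values)
  expect_identical(sim$hot_ids, sim2$hot_ids)
  expect_error(simulate_celltype_specific(p_background = 1.2, seed = 1),
               "probabilities")
})

test_that("null simulation (no signal) flags at about the threshold rate", {
  sim <- simulate_celltype_specific(n_background = 2000, n_specific = 300,
                                    p_hot = 0.3, p_cold = 0.3,
                                    p_background = 0.3, seed = 62)
  bg_rows <- sim$labels == "background"
  bmat <- wrap_matrix(sim$matrix$values[bg_rows, ])
  W <- manual_weights(bmat$schema, sim$hot_ids, 4)
  prs <- significance_pairs(sim$matrix, bmat, W, k = 30)
  det <- detect_specific_variants(prs$diagonal_angle[!bg_rows],
                                  prs$diagonal_angle[bg_rows])
  rate <- mean(det$flag)
  # roughly calibrated: out-of-sample queries run slightly hot against the
  # in-sample background angle reference (see the methods vignette), so the
  # check is a factor-of-3 band around the threshold, not a binomial CI
  expect_gt(rate, 0.05 / 3)
  expect_lt(rate, 0.05 * 3)
})

test_that("block simulation: independence across blocks, calibrated correlation within", {
  sim <- simulate_blocks(n_variants = 10000, within_block_correlation = 0.7,
                         seed = 63)
  R <- cor(sim$values)
  blk <- attr(sim, "block")
  same <- outer(blk, blk, "==") & upper.tri(R)
  diff_blk <- !outer(blk, blk, "==") & upper.tri(R)
  expect_lt(abs(mean(R[same]) - 0.7), 0.05)
  expect_lt(mean(abs(R[diff_blk])), 0.05)

  sim0 <- simulate_blocks(n_variants = 10000, within_block_correlation = 0,
                          seed = 64)
  R0 <- cor(sim0$values)
  expect_lt(mean(abs(R0[upper.tri(R0)])), 0.05)

  expect_error(simulate_blocks(within_block_correlation = 0.999, p = 0.01,
                               n_variants = 10, seed = 1), "infeasible")
})

test_that("the green and blue probe variants both carry raw count 10", {
  sim <- simulate_blocks(n_variants = 100, seed = 65)
  blk <- attr(sim, "block")
  green <- as.integer(!duplicated(blk))          # first annotation of each block
  blue <- as.integer(blk == 1)                   # all of block 1
  expect_equal(sum(green), 10L)
  expect_equal(sum(blue), 10L)
  expect_false(all(green == blue))
})

test_that("random correlation matrices are positive definite with unit diagonal", {
  for (s in 1:3) {
    Sigma <- random_correlation_matrix(80, seed = s)
    expect_equal(unname(diag(Sigma)), rep(1, 80))
    expect_gt(min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values),
              0)
  }
})

test_that("correlated-annotation simulation tracks its target margins", {
  sim <- simulate_correlated_annotations(n_annotations = 50,
                                         n_variants = 4000, seed = 66)
  freq <- colMeans(sim$values)
  expect_true(all(abs(freq - 0.3) < 3 * sqrt(0.3 * 0.7 / 4000) + 0.02))
  # mostly positive pairwise correlation by construction
  R <- cor(sim$values)
  expect_gt(mean(R[upper.tri(R)] > 0), 0.9)
})

test_that("fixture bundle ground truth matches the annotation engine, byte-reproducibly", {
  d1 <- withr::local_tempdir()
  fx <- generate_fixture_tracks(d1, seed = 67)
  tracks <- lapply(fx$tracks, load_peak_track)
  m <- suppressWarnings(
    build_annotation_matrix(fx$variants, tracks, fx$schema))
  expect_equal(unname(m$values), unname(fx$truth_overlap))

  bg <- construct_background(fx$candidates, fx$clinvar, fx$gwas_catalog,
                             fx$enhancers, fx$af)
  expect_equal(c(fx$expected_cascade[1], bg$filter_log$n_after),
               fx$expected_cascade)

  d2 <- withr::local_tempdir()
  fx2 <- generate_fixture_tracks(d2, seed = 67)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})
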