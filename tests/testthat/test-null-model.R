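test_that("filter cascade reproduces the hand-enumerated survivor counts", {
  fx <- generate_fixture_tracks(withr::local_tempdir(), seed = 8)
  bg <- construct_background(fx$candidates, clinvar = fx$clinvar,
                             gwas_catalog = fx$gwas_catalog,
                             enhancers = fx$enhancers, af = fx$af)
  expect_equal(bg$filter_log$step,
               c("clinvar", "gwas_catalog", "enhancer", "allele_frequency"))
  expect_equal(bg$filter_log$n_before, c(10L, 8L, 7L, 6L))
  expect_equal(bg$filter_log$n_after, c(8L, 7L, 6L, 4L))
  expect_equal(nrow(bg$variants), 4L)
  # any-ancestry rule: rs06 has high EUR but ASN = 0.02, so it is removed
  expect_false("rs06" %in% bg$variants$id)
  expect_false("rs05" %in% bg$variants$id)
  # benign ClinVar entries are kept
  expect_true("rs07" %in% bg$variants$id)
})

test_that("candidates with missing allele frequency are removed, not fatal", {
  cand <- variant_table(rep("1", 3), c(10L, 20L, 30L), c("a", "b", "c"))
  af <- data.frame(id = c("a", "b"), EUR = c(0.4, 0.3))
  bg <- construct_background(cand, af = af)
  expect_equal(sort(bg$variants$id), c("a", "b"))
  expect_equal(bg$n_missing_af, 1L)
})

test_that("empty candidate list yields empty set with a warning", {
  cand <- variant_table(character(0), integer(0), character(0))
  expect_warning(bg <- construct_background(cand), "empty")
  expect_equal(nrow(bg$variants), 0L)
})

test_that("add-one empirical p-value conventions", {
  bg <- sort(runif(999))
  expect_equal(empirical_pvalue(min(bg) - 1, bg), 1 / 1000)
  expect_equal(empirical_pvalue(max(bg), bg), 1)
  expect_error(empirical_pvalue(0.5, numeric(0)), "empty")
  # monotone non-decreasing in the score
  q <- seq(-0.2, 1.2, length.out = 101)
  expect_true(all(diff(empirical_pvalue(q, bg)) >= 0))
  # ties count towards the tail
  expect_equal(empirical_pvalue(2, c(1, 2, 2, 3)), 4 / 5)
})

test_that("leave-one-out p-values of background scores are uniform", {
  set.seed(31)
  X <- random_binary_matrix(2000, 40, p = 0.3)
  m <- estimate_background_model(X, k = 20)
  s <- score_matrix(X, m)$raw_score
  loo <- vapply(seq_along(s), function(i) {
    (1 + sum(s[-i] <= s[i])) / length(s)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(loo, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("score_variants: determinism, per-class handling and the all-1 minimum", {
  set.seed(32)
  d <- 30
  Xb <- random_binary_matrix(800, d, p = 0.3)
  bmat <- wrap_matrix(Xb)
  model <- estimate_background_model(bmat, "pooled", k = 15)
  Xq <- rbind(Xb[7, ], rep(1, d), rbinom(d, 1, 0.5))
  qv <- variant_table(rep("1", 4), 1:4, c("dup", "allone", "rand", "excl"),
                      variant_class = c("intergenic", "intergenic",
                                        "intergenic", "excluded"))
  qmat <- annotation_matrix(qv, rbind(Xq, 0), synthetic_schema(d))
  st <- score_variants(qmat, model, bmat)
  # a variant identical to a background variant gets that variant's score
  bg_scores <- score_matrix(bmat, model)$raw_score
  expect_equal(st$raw_score[1], bg_scores[7])
  expect_equal(st$empirical_p[1],
               (1 + sum(bg_scores <= bg_scores[7])) / (length(bg_scores) + 1))
  # the all-1 variant attains the smallest raw score in its class
  expect_true(st$raw_score[2] <= min(bg_scores))
  # excluded variants are reported unscored
  expect_true(is.na(st$raw_score[4]) && is.na(st$empirical_p[4]))
  expect_identical(st, score_variants(qmat, model, bmat))
  # a class without any model errors, naming the class
  m_int <- estimate_background_model(bmat, "pooled", k = 10)
  m_int$variant_class <- "intronic"
  expect_error(score_variants(qmat, list(intronic = m_int), bmat),
               "intergenic")
})

test_that("weighted p-values are computed against the re-scored background", {
  set.seed(33)
  sim <- simulate_celltype_specific(n_background = 1200, n_specific = 60,
                                    seed = 33)
  bg_rows <- sim$labels == "background"
  bmat <- wrap_matrix(sim$matrix$values[bg_rows, ])
  qmat <- wrap_matrix(sim$matrix$values[!bg_rows, ])
  model <- estimate_background_model(bmat, "pooled", k = 20)
  W <- manual_weights(bmat$schema, sim$hot_ids, 4)
  p_u <- score_variants(qmat, model, bmat)$empirical_p
  p_w <- score_variants(qmat, model, bmat, W = W)$empirical_p
  # specific variants: weighted p stochastically smaller than unweighted
  wt <- stats::wilcox.test(p_w, p_u, alternative = "less")
  expect_lt(wt$p.value, 1e-4)
})
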