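test_that("uptake normalization matches the %WT formula and its edge cases", {
  expect_equal(normalize_uptake(55, wt_mean = 100, ev_mean = 10), 50)
  expect_equal(normalize_uptake(100, 100, 10), 100)  # variant == WT
  expect_equal(normalize_uptake(10, 100, 10), 0)     # variant == EV
  expect_equal(normalize_uptake(5, 100, 10), -100 / 18)  # below background
  expect_error(normalize_uptake(55, 10, 10), "degenerate controls")
  expect_error(normalize_uptake(55, 5, 10), "degenerate controls")

  # affine invariance: a constant background added to all three signals
  # leaves %WT unchanged
  for (bg in c(-5, 13.7, 200)) {
    expect_equal(normalize_uptake(55 + bg, 100 + bg, 10 + bg),
                 normalize_uptake(55, 100, 10))
  }
})

test_that("replicate summarization averages technical wells first", {
  s <- summarize_replicates(c(40, 50, 60), bio_rep = 1:3)
  expect_equal(s$mean, 50)
  expect_equal(s$sem, 10 / sqrt(3))  # sd {40,50,60} = 10

  s0 <- summarize_replicates(rep(7.5, 6), bio_rep = rep(1:3, 2))
  expect_equal(s0$mean, 7.5)
  expect_equal(s0$sem, 0)

  # unbalanced technical wells: technical-then-biological averaging must
  # differ from the naive pooled mean
  vals <- c(10, 10, 10, 10, 40)   # rep 1 has 4 wells, rep 2 has 1
  reps <- c(1, 1, 1, 1, 2)
  s1 <- summarize_replicates(vals, reps)
  expect_equal(s1$mean, 25)            # (10 + 40) / 2
  expect_false(isTRUE(all.equal(s1$mean, mean(vals))))  # pooled = 16

  expect_warning(s2 <- summarize_replicates(c(1, 2), c(1, 1)), "single")
  expect_true(is.na(s2$sem))
  expect_true(s1$mean >= min(10, 40) && s1$mean <= max(10, 40))
})

test_that("the variant-vs-WT test applies the Bonferroni level", {
  tt <- test_vs_wt(c(10, 12, 11), c(95, 102, 99), n_tests = 150)
  expect_equal(tt$alpha, 0.05 / 150)
  expect_equal(signif(tt$alpha, 2), 3.3e-4)
  expect_true(tt$significant)

  same <- test_vs_wt(c(50, 60, 70), c(50, 60, 70), n_tests = 1)
  expect_gt(same$p_value, 0.99)
  expect_false(same$significant)
  expect_error(test_vs_wt(5, c(1, 2)), "at least 2 replicates")

  # p-value agrees with a Monte-Carlo permutation oracle on exchangeable
  # data (Student t is approximate for n = 6 + 6; allow MC + approximation
  # slack)
  set.seed(4)
  a <- rnorm(6, 10, 2); b <- rnorm(6, 12, 2)
  p_t <- test_vs_wt(a, b, 1)$p_value
  p_perm <- permutation_p(a, b, nperm = 2e4)
  expect_lt(abs(p_t - p_perm), 0.05)
})

test_that("LOF calls use a strict threshold and are monotone", {
  expect_true(call_lof(19.99))
  expect_false(call_lof(20))     # boundary value is NOT LOF
  expect_false(call_lof(20.01))
  expect_true(call_lof(-0.25))   # negative %WT retained and LOF
  expect_equal(call_lof(c(5, 20, 35), threshold = 20),
               c(TRUE, FALSE, FALSE))
  # monotone: lowering function never flips LOF -> functional
  f <- runif(100, -10, 120)
  expect_false(any(call_lof(f) & !call_lof(f - 5)))
})

test_that("characterize_assay recovers known truth from noiseless wells", {
  st <- smoke_study(seed = 3, noise_bio_sd = 0, noise_tech_sd = 0)
  chr <- characterize_assay(st$assay)
  m <- match(st$variants$label, chr$label)
  expect_equal(chr$function_pct[m], st$variants$true_fn, tolerance = 1e-9)
  expect_equal(chr$lof[m], st$variants$true_lof)
  expect_true(all(chr$sem[m] < 1e-9))
})

test_that("group summaries give medians, LOF fractions and Tukey post hoc", {
  set.seed(8)
  fn <- c(rnorm(20, 70, 15), rnorm(20, 40, 15), rnorm(10, 15, 10))
  gr <- rep(c("Shared", "Random", "Clinical"), c(20, 20, 10))
  gs <- group_summary(fn, gr)
  expect_setequal(gs$groups$group, c("Shared", "Random", "Clinical"))
  for (g in unique(gr)) {
    expect_equal(gs$groups$median[gs$groups$group == g],
                 median(fn[gr == g]))
    expect_equal(gs$groups$frac_lof[gs$groups$group == g],
                 mean(fn[gr == g] < 20))
  }
  expect_equal(nrow(gs$tukey), 3L)
  expect_true(all(gs$tukey$p_adj >= 0 & gs$tukey$p_adj <= 1))
  # medians invariant to row order
  o <- sample(length(fn))
  expect_equal(group_summary(fn[o], gr[o])$groups, gs$groups)
  # a singleton group is excluded from the omnibus test with a warning
  expect_warning(group_summary(c(fn, 50), c(gr, "Solo")), "Solo")
})

test_that("the group omnibus p-value is uniform under the null", {
  set.seed(21)
  ps <- replicate(300, {
    fn <- rnorm(80, 50, 20)
    gr <- rep(letters[1:4], each = 20)
    group_summary(fn, gr)$anova$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("Games-Howell matches an independent implementation to 3 decimals", {
  # frozen oracle values computed with an independent statistics library
  # on this fixed dataset
  vals <- c(72.4, 95.1, 60.3, 88.2, 101.5, 70.9, 55.4, 99.0,
            54.5, 40.2, 66.8, 30.1, 72.3, 48.8,
            19.0, 5.2, 28.4, 12.7, 33.9, 8.1, 22.6)
  grp <- rep(c("membrane", "mixed", "intracellular"), c(8, 6, 7))
  gh <- games_howell(vals, grp)
  row <- function(a, b) gh[gh$group1 == a & gh$group2 == b, ]
  im <- row("intracellular", "membrane")
  expect_equal(im$t, 8.244455, tolerance = 1e-3)
  expect_equal(im$df, 11.541912, tolerance = 1e-3)
  expect_equal(im$p_adj, 0.000010, tolerance = 1e-3)
  ix <- row("intracellular", "mixed")
  expect_equal(ix$t, 4.399507, tolerance = 1e-3)
  expect_equal(ix$df, 8.487284, tolerance = 1e-3)
  expect_equal(ix$p_adj, 0.005021, tolerance = 1e-3)
  mm <- row("membrane", "mixed")
  expect_equal(mm$t, 3.109982, tolerance = 1e-3)
  expect_equal(mm$df, 11.565739, tolerance = 1e-3)
  expect_equal(mm$p_adj, 0.023595, tolerance = 1e-3)

  # Welch ANOVA wiring on the same fixture (same oracle run)
  ls <- localization_summary(vals, grp)
  expect_equal(ls$welch_anova$F, 34.295659, tolerance = 1e-4)
  expect_equal(unname(ls$welch_anova$df[2]), 11.031639, tolerance = 1e-3)
  expect_equal(ls$welch_anova$p, 0.000018, tolerance = 1e-2)
  expect_equal(ls$classes$n[ls$classes$class == "membrane"], 8L)
  expect_equal(ls$classes$median[ls$classes$class == "intracellular"],
               median(vals[grp == "intracellular"]))
})

test_that("Welch ANOVA keeps its size under an equal-mean null", {
  set.seed(31)
  sig <- replicate(1000, {
    fn <- rnorm(45, 50, 12)
    cls <- rep(c("membrane", "mixed", "intracellular"), each = 15)
    localization_summary(fn, cls)$welch_anova$p < 0.05
  })
  expect_gte(mean(!sig), 0.94)
})
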