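test_that("paired_t matches the reference implementation on random inputs", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- x + rnorm(n, mean = runif(1, -1, 1))
    ours <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$cohens_d, mean(x - y) / sd(x - y), tolerance = 1e-12)
  }
})

test_that("paired_t handles degenerate and closed-form cases", {
  x <- rnorm(10)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_true(same$degenerate)
  # constant shift delta over noise of known sd: d = delta / sd(diff)
  set.seed(2)
  eps <- rnorm(30)
  y <- rnorm(30)
  res <- paired_t(y + 0.8 + eps, y)
  expect_equal(res$cohens_d, (0.8 + mean(eps)) / sd(eps), tolerance = 1e-12)
  expect_error(paired_t(x + 1, x), "zero variance")
  expect_error(paired_t(x, x[1:5]), "equal length")
  expect_error(paired_t(1:2, 3:4), "at least 3")
})

test_that("paired_t type-I error is calibrated at alpha = 0.05", {
  set.seed(77)
  reps <- 2500
  rejections <- sum(vapply(seq_len(reps), function(i) {
    paired_t(rnorm(30), rnorm(30))$p < 0.05
  }, logical(1)))
  ci <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("Bonferroni threshold division", {
  expect_equal(round(bonferroni_alpha(0.05, 30), 4), 0.0017)
  expect_equal(bonferroni_alpha(0.03, 1), 0.03)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "n_tests")
})

test_that("pearson_cor recovers exact linear relations", {
  x <- rnorm(20)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$r, -1, tolerance = 1e-12)
  y <- x^2 + rnorm(20)
  ref <- cor.test(x, y)
  got <- pearson_cor(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 20)), "zero variance")
})

test_that("Bland-Altman limits, proportion and category behave as defined", {
  x <- rnorm(30)
  perfect <- bland_altman(x, x)
  expect_equal(perfect$mean_diff, 0)
  expect_equal(perfect$upper_limit, 0)
  expect_equal(perfect$lower_limit, 0)
  expect_equal(perfect$proportion_within, 1)
  expect_equal(perfect$category, "good")
  # limits recompute exactly from the returned mean and SD
  set.seed(5)
  a <- rnorm(180); b <- rnorm(180)
  rep180 <- bland_altman(a, b)
  expect_equal(rep180$upper_limit, rep180$mean_diff + 1.96 * rep180$sd_diff)
  expect_equal(rep180$lower_limit, rep180$mean_diff - 1.96 * rep180$sd_diff)
  expect_equal(rep180$n, 180)
  # Gaussian differences: about 95% fall within the limits at large n
  big <- bland_altman(rnorm(20000), rnorm(20000))
  expect_equal(big$proportion_within, 0.95, tolerance = 0.01)
  expect_equal(bland_altman(a, b, fair_cutoff = 0.9)$category,
               "fairly good")
})

test_that("condition_tests runs one paired contrast per feature column", {
  set.seed(9)
  subj <- rep(sprintf("S%02d", 1:12), each = 2)
  tab <- data.frame(subject = subj,
                    condition = rep(c("target", "nontarget"), 12),
                    f1 = rnorm(24), f2 = rnorm(24))
  tab$f1[tab$condition == "target"] <- tab$f1[tab$condition == "target"] + 3
  res <- condition_tests(tab, n_tests = 2)
  expect_equal(nrow(res), 2)
  expect_true(res$significant[res$feature == "f1"])
  expect_equal(attr(res, "bonferroni_threshold"), 0.025)
  ref <- t.test(tab$f1[tab$condition == "target"],
                tab$f1[tab$condition == "nontarget"], paired = TRUE)
  expect_equal(res$t[res$feature == "f1"], unname(ref$statistic),
               tolerance = 1e-10)
})

test_that("permutation test is seed-stable, calibrated under the null and powerful", {
  set.seed(31)
  n_sub <- 10
  subj <- rep(sprintf("S%02d", 1:n_sub), each = 2)
  cond <- rep(c("target", "nontarget"), n_sub)
  null_tab <- data.frame(subject = subj, condition = cond,
                         f1 = rnorm(2 * n_sub), f2 = rnorm(2 * n_sub),
                         f3 = rnorm(2 * n_sub))
  p1 <- permutation_test(null_tab, "NB", n_permutations = 100, seed = 4)
  p2 <- permutation_test(null_tab, "NB", n_permutations = 100, seed = 4)
  expect_identical(p1, p2)
  expect_gt(p1$p, 0.05)  # shuffled labels give chance-level accuracy
  sep_tab <- null_tab
  sep_tab$f1 <- ifelse(cond == "target", 10, -10) + rnorm(2 * n_sub, sd = 0.1)
  p_sep <- permutation_test(sep_tab, "NB", n_permutations = 100, seed = 4)
  expect_lte(p_sep$p, 0.02)
  expect_error(permutation_test(null_tab, "NB", n_permutations = 10),
               ">= 100")
})
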