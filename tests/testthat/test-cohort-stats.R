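# Ordered-trend, signed-rank, multi-group and correlation statistics

test_that("Jonckheere-Terpstra statistic and exact p match brute-force enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(1:3, each = 2)
  res <- jonckheere_terpstra(x, g, method = "exact")
  expect_equal(res$statistic, 12)          # all 12 between-group pairs concordant
  expect_equal(res$statistic, oracle_jt_stat(x, g))
  null_J <- oracle_jt_null(x, c(2, 2, 2))
  expect_equal(res$p_one_sided, mean(null_J >= 12))
  expect_equal(res$p_one_sided, min(vapply(unique(null_J), function(j)
    mean(null_J >= j), numeric(1))))       # smallest attainable p

  # perfectly reversed ordering: no concordant pairs
  expect_equal(jonckheere_terpstra(rev(x), g, method = "exact")$statistic, 0)

  # all ties: half the between-group pairs
  res_t <- jonckheere_terpstra(rep(2, 6), g, method = "exact")
  expect_equal(res_t$statistic, 12 / 2)

  expect_error(jonckheere_terpstra(x, rep(1, 6)), "2 non-empty")
})

test_that("exact JT null equals full enumeration on random small cohorts", {
  set.seed(7)
  for (rep_i in 1:4) {
    sizes <- sample(2:4, 3, replace = TRUE)
    while (sum(sizes) > 10) sizes <- sample(2:4, 3, replace = TRUE)
    x <- round(rnorm(sum(sizes)), 1)       # rounding induces occasional ties
    g <- rep(seq_along(sizes), sizes)
    res <- jonckheere_terpstra(x, g, method = "exact")
    null_J <- oracle_jt_null(x, sizes)
    expect_equal(res$statistic, oracle_jt_stat(x, g))
    expect_equal(res$p_one_sided, mean(null_J >= res$statistic - 1e-9))
    expect_equal(sort(res$null_distribution), sort(null_J))
  }
})

test_that("J is antisymmetric under reversal of the group ordering", {
  set.seed(11)
  for (rep_i in 1:20) {
    sizes <- sample(3:6, 4, replace = TRUE)
    x <- rnorm(sum(sizes))                 # continuous: no ties
    g <- rep(1:4, sizes)
    J_fwd <- jonckheere_terpstra(x, factor(g, levels = 1:4))$statistic
    J_rev <- jonckheere_terpstra(x, factor(g, levels = 4:1))$statistic
    total <- (sum(sizes)^2 - sum(sizes^2)) / 2
    expect_equal(J_fwd + J_rev, total)
  }
})

test_that("permutation and normal-approximation p-values agree with exact", {
  set.seed(3)
  x <- rnorm(10)
  g <- rep(1:3, c(3, 3, 4))
  p_ex <- jonckheere_terpstra(x, g, method = "exact")$p_one_sided
  p_pm <- jonckheere_terpstra(x, g, method = "permutation",
                              n_perm = 20000, seed = 5)$p_one_sided
  expect_lt(abs(p_pm - p_ex), 0.02)
  p_na <- jonckheere_terpstra(x, g, method = "normal_approx")$p_one_sided
  expect_lt(abs(p_na - p_ex), 0.08)
  expect_error(jonckheere_terpstra(x, g, method = "permutation",
                                   n_perm = 500), "at least 1000")
})

test_that("JT permutation test holds its nominal size", {
  set.seed(19)
  g <- rep(1:4, each = 5)
  rejections <- vapply(1:1000, function(i) {
    x <- rnorm(20)
    jonckheere_terpstra(x, g, method = "permutation", n_perm = 2000,
                        seed = i)$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("signed-rank exact p matches 2^n sign enumeration (with and without ties)", {
  # all-positive differences, n = 5: one-sided p = 1/32
  res <- wilcoxon_signed_rank(c(0.3, 1.1, 2.2, 0.7, 1.9))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_one_sided, 1 / 32)

  set.seed(13)
  for (rep_i in 1:5) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n), if (rep_i %% 2) 1 else 3)  # coarse rounding -> ties
    d <- d[d != 0]
    if (length(d) < 5) next
    res <- wilcoxon_signed_rank(d)
    orc <- oracle_signrank_p(d)
    expect_equal(res$statistic, orc$v)
    expect_equal(res$p_one_sided, orc$p_one, tolerance = 1e-12)
    expect_equal(res$p_two_sided, orc$p_two, tolerance = 1e-12)
  }

  # tie-free case cross-checked against the base-R exact distribution
  d <- c(1.3, -0.4, 2.2, -3.1, 0.9, 1.7, -0.2, 2.8)
  res <- wilcoxon_signed_rank(d)
  bw <- wilcox.test(d, exact = TRUE)
  expect_equal(res$p_two_sided, bw$p.value, tolerance = 1e-12)
})

test_that("signed-rank handles zeros, symmetry, small n and large n", {
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "degenerate")

  # antisymmetric differences sit at the null centre n(n+1)/4
  expect_warning(res_sym <- wilcoxon_signed_rank(c(1, -1, 2, -2)),
                 "fewer than 5")
  expect_equal(res_sym$statistic, 4 * 5 / 4)
  expect_true(is.na(res_sym$p_one_sided))

  expect_warning(res3 <- wilcoxon_signed_rank(c(1, 2, 3)), "fewer than 5")
  expect_true(is.na(res3$p_two_sided))

  # zeros dropped and counted
  res0 <- wilcoxon_signed_rank(c(0, 0, 1.2, -0.5, 0.8, 1.5, 2.1))
  expect_equal(res0$n_zero_dropped, 2)
  expect_equal(res0$n, 5)

  # normal approximation tracks the exact tail beyond the exact limit
  set.seed(2)
  d <- rnorm(25, mean = 0.4)
  p_norm <- wilcoxon_signed_rank(d)$p_two_sided
  p_base <- wilcox.test(d, exact = TRUE)$p.value
  expect_lt(abs(log(p_norm) - log(p_base)), 0.35)
})

test_that("Kruskal-Wallis with Dunn post hoc matches hand computation", {
  # identical values in all groups: H = 0
  res0 <- kruskal_wallis_dunn(rep(1, 12), rep(1:3, each = 4))
  expect_equal(res0$h_statistic, 0)

  # disjoint group ranges, n = 4 each: hand-ranked H
  x <- c(1, 2, 3, 4, 11, 12, 13, 14, 21, 22, 23, 24)
  g <- rep(1:3, each = 4)
  res <- kruskal_wallis_dunn(x, g)
  rbar <- c(mean(1:4), mean(5:8), mean(9:12))
  H_hand <- 12 / (12 * 13) * sum(4 * (rbar - 6.5)^2)
  expect_equal(res$h_statistic, H_hand, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
  # extreme groups are the most separated after adjustment
  expect_lte(res$pairwise$p_adjusted[res$pairwise$group1 == "1" &
                                      res$pairwise$group2 == "3"],
             min(res$pairwise$p_adjusted))
  # hand-computed Dunn z for the extreme pair (no ties)
  z13 <- (rbar[1] - rbar[3]) / sqrt((12 * 13 / 12) * (1 / 4 + 1 / 4))
  i13 <- which(res$pairwise$group1 == "1" & res$pairwise$group2 == "3")
  expect_equal(abs(res$pairwise$z[i13]), abs(z13), tolerance = 1e-10)

  expect_error(kruskal_wallis_dunn(x[1:8], g[1:8]), "at least 3")
})

test_that("Pearson correlation and regression follow the closed forms", {
  res <- pearson_linreg(0:2, 0:2)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 1)

  res_neg <- pearson_linreg(1:5, -2 * (1:5))
  expect_equal(res_neg$r, -1)
  expect_equal(res_neg$slope, -2)

  # hand computation on a small asymmetric set
  x <- c(0, 1, 2, 4)
  y <- c(1, 0, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res4 <- pearson_linreg(x, y)
  expect_equal(res4$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(res4$p_value, 2 * pt(-abs(t_stat), 2), tolerance = 1e-12)

  expect_error(pearson_linreg(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_linreg(1:2, 2:3), "at least 3")
})
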