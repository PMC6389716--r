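test_that("permutation p-values agree with exhaustive enumeration (n = 3 + 3)", {
  set.seed(13)
  for (case in 1:4) {
    vc <- rnorm(3)
    vp <- rnorm(3, mean = case / 2)
    ex <- oracle_perm_exhaustive(vc, vp)
    pt <- permutation_group_test(vc, vp, n_perm = 2000, seed = case)
    for (tail in c("p_greater", "p_smaller")) {
      se <- sqrt(ex[[tail]] * (1 - ex[[tail]]) / 2000)
      expect_lt(abs(pt[[tail]] - ex[[tail]]), 3 * se + 1e-3,
                label = sprintf("case %d %s", case, tail))
    }
  }
})

test_that("identical values give the degenerate p = 1 in both tails", {
  pt <- permutation_group_test(rep(1, 3), rep(1, 3), n_perm = 200, seed = 1)
  expect_equal(pt$observed_diff, 0)
  expect_equal(pt$p_greater, 1)
  expect_equal(pt$p_smaller, 1)
  expect_true(pt$degenerate)
})

test_that("swapping group labels mirrors the difference and the tails", {
  set.seed(29)
  vc <- rnorm(8)
  vp <- rnorm(9, 0.7)
  a <- permutation_group_test(vc, vp, n_perm = 4000, seed = 5)
  b <- permutation_group_test(vp, vc, n_perm = 4000, seed = 5)
  expect_equal(a$observed_diff, -b$observed_diff)
  # mirrored tails agree up to Monte-Carlo error (group sizes differ so the
  # permutation streams are not identical)
  expect_lt(abs(a$p_greater - b$p_smaller), 0.03)
  expect_lt(abs(a$p_smaller - b$p_greater), 0.03)
})

test_that("doubling n_perm shrinks the Monte-Carlo spread of p", {
  set.seed(41)
  vc <- rnorm(10)
  vp <- rnorm(10, 0.5)
  spread <- function(n_perm) {
    ps <- sapply(1:50, function(s) {
      permutation_group_test(vc, vp, n_perm = n_perm, seed = s)$p_greater
    })
    stats::sd(ps)
  }
  s1 <- spread(400)
  s2 <- spread(1600)  # 4x permutations -> about half the SE
  expect_lt(s2, s1 * 0.75)
})

test_that("sign-flip p-values agree with the exhaustive 2^n oracle", {
  set.seed(43)
  for (case in 1:4) {
    d <- rnorm(4, mean = c(-0.5, 0, 0.5, 1)[case])
    ex <- oracle_signflip_exhaustive(d)
    pt <- paired_signflip_test(d, rep(0, 4), n_perm = 2000, seed = case)
    for (tail in c("p_greater", "p_smaller")) {
      se <- sqrt(ex[[tail]] * (1 - ex[[tail]]) / 2000)
      expect_lt(abs(pt[[tail]] - ex[[tail]]), 3 * se + 1e-3)
    }
  }
  all0 <- paired_signflip_test(rep(0.3, 5), rep(0.3, 5), n_perm = 200,
                               seed = 1)
  expect_equal(all0$p_greater, 1)
  expect_equal(all0$p_smaller, 1)
})

test_that("outlier rule is a single 3-SD pass with n-1 SD", {
  # {1,1,1,100}: mean 25.75, SD 49.5 -> 3 SD = 148.5, nothing removed
  expect_identical(remove_outliers(c(1, 1, 1, 100)), 1:4)
  # a clear extreme among standard normals is removed
  set.seed(47)
  x <- c(rnorm(50), 10)
  kept <- remove_outliers(x)
  expect_false(51 %in% kept)
  expect_true(all(1:50 %in% kept))
  # constant vector: keep all
  expect_identical(remove_outliers(rep(2, 6)), 1:6)
  expect_error(remove_outliers(c(1, 2)), ">= 3")
})

test_that("Spearman correlation handles monotone, reversed and screened data", {
  v <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  s <- c(3, 8, 12, 20, 25, 33)
  up <- spearman_with_outlier_removal(v, s)
  expect_equal(up$rho, 1, ignore_attr = TRUE)
  down <- spearman_with_outlier_removal(v, rev(s))
  expect_equal(down$rho, -1, ignore_attr = TRUE)
  expect_equal(up$n_outliers, 0)

  # an extreme variability value is screened out before correlating
  set.seed(53)
  v2 <- c(rnorm(30, 0.5, 0.05), 5)
  s2 <- c(v2[1:30] * 40 + rnorm(30, 0, 0.8), 1)
  res <- spearman_with_outlier_removal(v2, s2)
  expect_equal(res$n_outliers, 1, ignore_attr = TRUE)
  expect_equal(res$n_used, 30, ignore_attr = TRUE)
  expect_gt(res$rho, 0.8)
  expect_error(spearman_with_outlier_removal(v[1:4], s[1:4]), ">= 5")
})

test_that("sex-ratio chi-square reproduces the published demographics p", {
  tab <- matrix(c(23, 19, 21, 19), nrow = 2, byrow = TRUE)
  res <- sex_ratio_test(tab)
  expect_equal(round(res$p_value, 3), 0.837)

  expect_equal(sex_ratio_test(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  expect_lt(sex_ratio_test(matrix(c(20, 0, 0, 20), 2))$p_value, 1e-8)
  # chi-square tail oracle for the perfectly split table
  chi <- sum((c(20, 0, 0, 20) - 10)^2 / 10)
  expect_equal(sex_ratio_test(matrix(c(20, 0, 0, 20), 2))$p_value,
               stats::pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(sex_ratio_test(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("t-test entry points agree with each other and with base R", {
  set.seed(59)
  x <- rnorm(20, 1)
  y <- rnorm(25, 1.4)
  raw <- two_sample_t(x, y)
  summ <- two_sample_t_summary(mean(x), sd(x), 20, mean(y), sd(y), 25)
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)

  same <- two_sample_t_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
})

test_that("group_compare matches the single-unit test and handles missing values", {
  set.seed(61)
  tbl <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:20),
                            level = "nodal", unit = c("1", "2", "3"))
  tbl$group <- ifelse(as.integer(substr(tbl$subject_id, 2, 3)) <= 10,
                      "control", "patient")
  tbl$value <- rnorm(nrow(tbl)) +
    ifelse(tbl$group == "patient" & tbl$unit == "1", 1.5, 0)
  res <- group_compare(tbl, n_perm = 3000, seed = 3)
  expect_equal(nrow(res), 3)
  u1 <- res[res$unit == "1", ]
  expect_lt(u1$p_two_sided, 0.05)
  expect_gt(u1$observed_diff, 0)

  direct <- permutation_group_test(
    tbl$value[tbl$group == "control" & tbl$unit == "1"],
    tbl$value[tbl$group == "patient" & tbl$unit == "1"],
    n_perm = 3000, seed = 3)
  expect_equal(u1$observed_diff, direct$observed_diff, tolerance = 1e-12)
  expect_lt(abs(u1$p_two_sided - direct$p_two_sided), 0.03)

  tbl$value[tbl$subject_id == "s01" & tbl$unit == "2"] <- NA
  res2 <- group_compare(tbl, n_perm = 500, seed = 3)
  expect_equal(res2$n_missing[res2$unit == "2"], 1L)
  expect_false(anyNA(res2$p_two_sided))
})

test_that("intra-vs-inter paired comparison finds intra more stable when built in", {
  # build a cohort table where intra < inter for every subject by a margin
  set.seed(67)
  subjects <- sprintf("s%02d", 1:12)
  mods <- c("A", "B", "C")
  intra <- tidyr::expand_grid(subject_id = subjects, unit = mods)
  intra$level <- "intra"
  intra$value <- 0.5 + rnorm(nrow(intra), 0, 0.02)
  inter <- tidyr::expand_grid(subject_id = subjects,
                              unit = c("A|B", "A|C", "B|C"))
  inter$level <- "inter"
  inter$value <- 0.8 + rnorm(nrow(inter), 0, 0.02)
  tbl <- dplyr::bind_rows(intra, inter)
  tbl$group <- "control"
  res <- intra_vs_inter(tbl, "control", n_perm = 2000, seed = 2)
  expect_equal(nrow(res), 3)
  expect_true(all(res$observed_diff < 0))
  expect_true(all(res$p_smaller < 0.05))
  expect_true(all(res$p_greater > 0.9))
})
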