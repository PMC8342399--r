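test_that("the hand-computable ANOVA example gives F = 3 with df (2, 6)", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(an$F, 3)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 6)
  expect_equal(an$p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("identical groups give F = 0 and p = 1; zero variance flags Inf", {
  an <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  an2 <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_true(is.infinite(an2$F))
  expect_equal(an2$p, 0)
  expect_equal(an2$flag, "zero_within_variance")
})

test_that("ANOVA agrees with the brute-force oracle on 50 random datasets", {
  set.seed(61)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(i)
      rnorm(sample(3:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3)))
    names(groups) <- paste0("g", seq_len(k))
    mine <- one_way_anova(groups)
    ref <- oracle_anova(groups)
    expect_equal(mine$F, ref$F, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
  }
})

test_that("ANOVA F is invariant to shift and scale of the data", {
  set.seed(62)
  groups <- lapply(1:4, function(i) rnorm(10, i))
  f0 <- one_way_anova(groups)$F
  expect_equal(one_way_anova(lapply(groups, function(g) g + 100))$F, f0,
               tolerance = 1e-9)
  expect_equal(one_way_anova(lapply(groups, function(g) g * 13))$F, f0,
               tolerance = 1e-9)
})

test_that("Tamhane T2 matches an independent Welch + Sidak oracle", {
  set.seed(63)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(i)
      rnorm(sample(3:25, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 4)))
    names(groups) <- paste0("g", seq_len(k))
    mine <- tamhane_t2(groups)$pairs
    ref <- oracle_tamhane(groups)
    expect_equal(mine$welch_t, ref$t, tolerance = 1e-10)
    expect_equal(mine$welch_df, ref$df, tolerance = 1e-10)
    expect_equal(mine$raw_p, ref$p, tolerance = 1e-10)
    expect_equal(mine$adjusted_p, ref$adj, tolerance = 1e-10)
  }
})

test_that("Tamhane T2 edge cases behave as declared", {
  # identical groups: t = 0, adjusted p = 1
  th <- tamhane_t2(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(th$pairs$welch_t, 0)
  expect_equal(th$pairs$adjusted_p, 1)
  # k = 2: a single comparison, so the adjustment changes nothing
  set.seed(64)
  th2 <- tamhane_t2(list(a = rnorm(10), b = rnorm(12, 1)))
  expect_equal(th2$pairs$adjusted_p, th2$pairs$raw_p, tolerance = 1e-12)
  # zero variance in both groups, equal means: p = 1
  th3 <- tamhane_t2(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(th3$pairs$raw_p, 1)
  # adjusted p is monotone in raw p and never smaller
  set.seed(65)
  th4 <- tamhane_t2(lapply(1:5, function(i) rnorm(8, i / 4)))
  o <- order(th4$pairs$raw_p)
  expect_true(all(diff(th4$pairs$adjusted_p[o]) >= -1e-12))
  expect_true(all(th4$pairs$adjusted_p >= th4$pairs$raw_p - 1e-12))
  # Bonferroni option
  th5 <- tamhane_t2(list(a = rnorm(5), b = rnorm(5), c = rnorm(5)),
                    adjust = "bonferroni")
  expect_equal(th5$pairs$adjusted_p, pmin(1, th5$pairs$raw_p * 3),
               tolerance = 1e-12)
})

test_that("Tamhane familywise error stays near alpha under the null", {
  set.seed(66)
  sds <- c(0.5, 1, 2, 4, 8)
  reject <- logical(2000)
  for (r in seq_len(2000)) {
    groups <- lapply(sds, function(s) rnorm(30, 0, s))
    names(groups) <- paste0("g", 1:5)
    reject[r] <- any(tamhane_t2(groups)$pairs$significant)
  }
  expect_lte(mean(reject), 0.06)
})

test_that("Shapiro-Wilk wrapper discriminates normal from exponential", {
  set.seed(67)
  p_norm <- replicate(100, shapiro_wilk(rnorm(500))$p)
  expect_gte(mean(p_norm > 0.05), 0.95)
  p_exp <- replicate(100, shapiro_wilk(rexp(500))$p)
  expect_gte(mean(p_exp < 0.05), 0.95)
})

test_that("Shapiro-Wilk wrapper enforces n >= 3 and subsamples large n", {
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  set.seed(68)
  big <- rnorm(12000)
  r1 <- shapiro_wilk(big)
  r2 <- shapiro_wilk(big)
  expect_equal(r1$n_used, 5000L)
  expect_identical(r1$W, r2$W)  # fixed-seed subsample -> deterministic
  expect_true(shapiro_wilk(rep(1, 10))$degenerate)
})

test_that("compact letter display is consistent with pairwise significance", {
  # no significant pairs: everyone shares "a"
  pairs0 <- expand.grid(group1 = "a", group2 = c("b", "c"))
  pairs0 <- data.frame(group1 = c("g1", "g1", "g2"),
                       group2 = c("g2", "g3", "g3"), significant = FALSE)
  expect_true(all(letters_from_pairs(pairs0) == "a"))
  # all pairs significant: three distinct letters
  pairs1 <- pairs0
  pairs1$significant <- TRUE
  lt <- letters_from_pairs(pairs1)
  expect_equal(sort(unname(lt)), c("a", "b", "c"))
  # random patterns: sharing a letter iff not significantly different
  set.seed(69)
  for (r in 1:50) {
    k <- sample(3:7, 1)
    g <- paste0("g", seq_len(k))
    pr <- t(combn(g, 2))
    pairs <- data.frame(group1 = pr[, 1], group2 = pr[, 2],
                        significant = runif(nrow(pr)) < 0.4)
    lt <- letters_from_pairs(pairs, g)
    share <- function(a, b)
      length(intersect(strsplit(lt[[a]], "")[[1]],
                       strsplit(lt[[b]], "")[[1]])) > 0
    for (i in seq_len(nrow(pairs))) {
      expect_identical(share(pairs$group1[i], pairs$group2[i]),
                       !pairs$significant[i],
                       label = sprintf("rep %d pair %s-%s", r,
                                       pairs$group1[i], pairs$group2[i]))
    }
  }
})

test_that("group validation rejects undersized input", {
  expect_error(one_way_anova(list(a = 1:3)), "at least 2 groups")
  expect_error(one_way_anova(list(a = 1:3, b = 2)), "n >= 2")
  expect_error(tamhane_t2(list(a = c(1, NA, 3), b = 1:3)), "finite")
})
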