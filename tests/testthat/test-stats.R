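test_that("Pearson correlation matches the brute-force formula", {
  expect_equal(pearsonTest(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearsonTest(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  # hand formula oracle: covariance over the product of SDs, t-based p
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t0 <- r0 * sqrt((4 - 2) / (1 - r0^2))
  p0 <- 2 * pt(-abs(t0), df = 2)
  pt_ <- pearsonTest(x, y)
  expect_equal(pt_$r, r0, tolerance = 1e-10)
  expect_equal(pt_$p, p0, tolerance = 1e-10)
  expect_equal(pt_$n, 4L)
  expect_error(pearsonTest(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonTest(1:2, 2:1), "at least 3")
})

test_that("Welch's t-test matches the hand-evaluated formulas", {
  same <- c(1.5, 2.5, 3.5)
  w0 <- welchT(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  va <- var(a) / 3; vb <- var(b) / 3
  t0 <- (mean(a) - mean(b)) / sqrt(va + vb)
  df0 <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  p0 <- 2 * pt(-abs(t0), df0)
  w <- welchT(a, b)
  expect_equal(w$t, t0, tolerance = 1e-10)
  expect_equal(w$df, df0, tolerance = 1e-10)
  expect_equal(w$p, p0, tolerance = 1e-10)
  # swapping groups flips the sign, p unchanged
  w2 <- welchT(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA decomposes sums of squares correctly", {
  g <- rep(c("a", "b", "c"), each = 4)
  expect_equal(anovaOneway(rep(c(1, 2, 3, 4), 3), g)$F, 0)
  set.seed(51)
  y <- rnorm(12) + rep(c(0, 1, 3), each = 4)
  a <- anovaOneway(y, g)
  # brute-force between/within decomposition
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  sst <- sum((y - gm)^2)
  expect_equal(ssb + ssw, sst, tolerance = 1e-10)
  F0 <- (ssb / 2) / (ssw / 9)
  expect_equal(a$F, F0, tolerance = 1e-10)
  expect_equal(a$dfBetween, 2)
  expect_equal(a$dfWithin, 9)
  # two groups: F equals the squared pooled-variance t statistic
  y2 <- rnorm(10); g2 <- rep(c("a", "b"), each = 5)
  a2 <- anovaOneway(y2, g2)
  t2 <- t.test(y2[g2 == "a"], y2[g2 == "b"], var.equal = TRUE)$statistic
  expect_equal(a2$F, unname(t2)^2, tolerance = 1e-10)
  expect_error(anovaOneway(y2, rep("a", 10)), "2 groups")
})

test_that("Pearson p agrees with a permutation p on small samples", {
  set.seed(52)
  x <- rnorm(12)
  y <- 0.6 * x + rnorm(12)
  pt_ <- pearsonTest(x, y)
  B <- 4000L
  rp <- replicate(B, abs(cor(x, sample(y))))
  pPerm <- (1 + sum(rp >= abs(pt_$r))) / (B + 1)
  mc <- 3 * sqrt(pPerm * (1 - pPerm) / B)
  expect_lt(abs(pt_$p - pPerm), mc + 0.01)
})

test_that("association tables flag planted effects and respect strata", {
  sh <- truthShapes(24, seed = 13)
  cov <- sh$cohort$covariates
  al <- gpa(sh$shapes, withScale = TRUE)
  mdl <- buildSSM(assembleShapes(al$aligned, cov$subject_id))
  sc <- projectShapes(mdl, al$aligned)
  tab <- associationTable(sc, cov, modes = 1:3)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(abs(tab$estimate[tab$statistic == "pearson_r"]) <= 1))
  # whole-cohort and sex-stratified n must be consistent
  age1 <- tab[tab$mode == 1 & tab$covariate == "age", ]
  nAll <- age1$n[age1$stratum == "all"]
  expect_equal(nAll, sum(age1$n[age1$stratum != "all"]))
  # the age-planted deformation dominates mode 1 of the scaled model
  r1 <- age1$estimate[age1$stratum == "all"]
  rOthers <- tab$estimate[tab$covariate == "age" & tab$stratum == "all" &
                            tab$mode != 1]
  expect_true(all(abs(r1) > abs(rOthers)))
  # OLS slope consistent with the signed correlation
  expect_equal(sign(age1$slope[age1$stratum == "all"]), sign(r1))
  # BH adjustment only appears on request
  expect_false("pAdjustBH" %in% names(tab))
  expect_true("pAdjustBH" %in%
                names(associationTable(sc, cov, modes = 1, adjust = TRUE)))

  dup <- rbind(cov, cov[1, ])
  expect_error(associationTable(sc, dup), "duplicate")
  covNA <- cov
  covNA$bmi[2] <- NA
  expect_message(tabNA <- associationTable(sc, covNA, modes = 1), "dropped")
  expect_equal(unique(tabNA$n[tabNA$stratum == "all"]), nrow(cov) - 1L)
})

test_that("scores are independent of a permuted covariate", {
  set.seed(53)
  score <- rnorm(40)
  hits <- replicate(400, pearsonTest(score, sample(seq_len(40)))$p < 0.05)
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.11)
})

test_that("group ANOVA wrapper runs over a user-supplied grouping", {
  sh <- truthShapes(20, seed = 14)
  cov <- sh$cohort$covariates
  cov$centre <- ifelse(cov$age >= 50, "older", "younger")
  al <- gpa(sh$shapes, withScale = TRUE)
  sc <- projectShapes(buildSSM(assembleShapes(al$aligned, cov$subject_id)),
                      al$aligned)
  ga <- groupAnova(sc, cov, "centre", modes = 1:2)
  expect_equal(nrow(ga), 2L)
  expect_true(all(ga$p >= 0 & ga$p <= 1))
  expect_error(groupAnova(sc, cov, "nope"), "no such covariate")
})
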