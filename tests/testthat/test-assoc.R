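test_that("identical groups give z = 0 and p ~ 1", {
  rt <- rank_sum_test(c(8, 11), c(8, 11))
  expect_equal(rt$z, 0)
  expect_gte(rt$p, 0.99)
})

test_that("the separated-triples fixture matches the reference implementation", {
  rt <- rank_sum_test(c(8, 8, 8), c(11, 11, 11))
  expect_equal(rt$p, RANK_FIXTURE_P, tolerance = 1e-7)
  ref <- wilcox.test(c(8, 8, 8), c(11, 11, 11), exact = FALSE,
                     correct = TRUE)
  expect_equal(rt$p, ref$p.value, tolerance = 1e-12)
  expect_equal(rt$W, unname(ref$statistic))
})

test_that("normal-approximation p matches wilcox.test across random tied data", {
  set.seed(15)
  for (rep in 1:20) {
    a <- sample(7:16, sample(3:30, 1), replace = TRUE)
    b <- sample(7:16, sample(3:30, 1), replace = TRUE)
    rt <- rank_sum_test(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(rt$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("swapping groups negates z and preserves p", {
  a <- c(8, 8, 9, 11); b <- c(11, 13, 13, 14, 16)
  r1 <- rank_sum_test(a, b); r2 <- rank_sum_test(b, a)
  expect_equal(r1$z, -r2$z)
  expect_equal(r1$p, r2$p)
})

test_that("the test is invariant to strictly monotone transforms", {
  a <- c(8, 8, 9, 11, 14); b <- c(11, 13, 13, 14)
  r1 <- rank_sum_test(a, b)
  r2 <- rank_sum_test(exp(a / 3), exp(b / 3))
  expect_equal(r1$p, r2$p)
  expect_equal(r1$W, r2$W)
})

test_that("exact permutation mode agrees with the normal approximation in rank order", {
  a <- c(8, 8, 9); b <- c(11, 13, 13, 14)
  ex <- rank_sum_test(a, b, mode = "exact")
  expect_equal(ex$mode, "exact")
  expect_true(ex$p > 0 && ex$p <= 1)
  # exact two-sided p for complete separation of 3 vs 4: 2/choose(7,3)
  sep <- rank_sum_test(c(1, 2, 3), c(4, 5, 6, 7), mode = "exact")
  expect_equal(sep$p, 2 / choose(7, 3))
  expect_error(rank_sum_test(1:15, 1:15, mode = "exact"), "n <= 20")
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("clade association has power under Fig 2-like separation", {
  set.seed(16)
  spectra <- test_spectra()
  rejections <- replicate(60, {
    n <- 260
    clade <- sample(c("short", "long"), n, replace = TRUE)
    allele <- ifelse(
      clade == "short",
      as.integer(sample(names(spectra$short), n, TRUE, spectra$short)),
      as.integer(sample(names(spectra$long), n, TRUE, spectra$long)))
    rec <- data.frame(tag_allele = ifelse(clade == "short", "C", "A"),
                      repeat_allele = allele)
    clade_association_test(rec)$p < 0.05
  })
  expect_gte(mean(rejections), 0.9)
})

test_that("a perfectly linear panel gives r^2 = 1 and tau = 1", {
  rec <- data.frame(srcr_diploid_cn = c(20, 24, 28),
                    bands = c("300", "340", "380"),
                    isoform = c("I", "I", "III"),
                    secretor = c("+", "-", "+"))
  fit <- suppressWarnings(isoform_model(rec))  # exact fit warns in summary.lm
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$kendall_tau, 1)
  expect_equal(unname(coef(fit$fit)), c(100, 10))
})

test_that("adding the secretor covariate never decreases r^2", {
  set.seed(18)
  for (rep in 1:10) {
    n <- 10
    rec <- data.frame(
      srcr_diploid_cn = sample(14:30, n, replace = TRUE),
      bands = as.character(round(runif(n, 280, 400))),
      isoform = sample(c("I", "II", "III"), n, replace = TRUE),
      secretor = sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3)))
    if (length(unique(rec$secretor)) < 2 ||
        length(unique(rec$srcr_diploid_cn)) < 2) next
    f0 <- isoform_model(rec)
    f1 <- isoform_model(rec, include_secretor = TRUE)
    expect_gte(f1$r_squared, f0$r_squared - 1e-12)
  }
})

test_that("band encodings differ only for two-band records", {
  rec <- data.frame(srcr_diploid_cn = c(20, 24),
                    bands = c("287,345", "375"),
                    isoform = c("IV", "II"), secretor = c("-", "+"))
  enc <- function(r) dmbtsel:::encode_isoform_response(rec, r)
  expect_equal(enc("mean_band"), c(316, 375))
  expect_equal(enc("largest_band"), c(345, 375))
  expect_equal(enc("smallest_band"), c(287, 375))
  expect_equal(enc("class_rank"), c(1, 3))
})

test_that("degenerate isoform designs error", {
  rec <- data.frame(srcr_diploid_cn = c(20, 20, 20),
                    bands = c("300", "340", "380"),
                    isoform = "I", secretor = "+")
  expect_error(isoform_model(rec), "constant")
  expect_error(isoform_model(rec[1:2, ]), "at least 3")
})

test_that("secretor inference follows the recessive null rule", {
  expect_equal(infer_secretor(c("A/A", "G/A", "G/G", "A|A", NA, "")),
               c("Se-", "Se+", "Se+", "Se-", "unknown", "unknown"))
  expect_equal(infer_secretor("T/T", null_allele = "T"), "Se-")
})

test_that("dosage trend: exact null and exact signal behave correctly", {
  null_rec <- data.frame(dosage = rep(0:2, each = 4),
                         expression = rep(c(1, 2), 6))  # equal group means
  # identical group means: zero slope; p at the null boundary
  dt <- suppressWarnings(dosage_trend_test(null_rec))
  expect_equal(dt$slope, 0)
  expect_gte(dt$trend_p, 0.95)
  sig <- data.frame(dosage = rep(0:2, 2), expression = rep(0:2, 2) +
                      c(0.001, -0.001, 0.001, -0.001, 0.001, -0.001))
  dt2 <- dosage_trend_test(sig)
  expect_lt(dt2$trend_p, 1e-6)
  expect_equal(dt2$slope, 1, tolerance = 0.01)
  expect_equal(dt2$slope_sign, 1)
  expect_lt(dt2$anova_p, 1e-4)
  expect_error(dosage_trend_test(data.frame(dosage = c(1, 1),
                                            expression = c(1, 2))),
               "one genotype class")
})
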