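test_that("sim_config validates probability vectors and ranges", {
  expect_error(sim_config(clade_freq = 0), "strictly between")
  expect_error(sim_config(cnv_spectrum_by_clade = list(
    short = c(`8` = 0.5, `9` = 0.4), long = c(`13` = 1))), "summing to 1")
  expect_error(sim_config(cnv_spectrum_by_clade = list(
    short = c(`3` = 1), long = c(`13` = 1))), "integers in")
  expect_error(sim_config(isoform_slope = -1), "isoform_slope")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
})

test_that("config text round-trips through key = value files", {
  cfg <- sim_config(seed = 9, n_trios = 12, clade_freq = 0.35,
                    cnv_spectrum_by_clade = test_spectra())
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$clade_freq, cfg$clade_freq)
  expect_equal(back$n_trios, cfg$n_trios)
  expect_equal(back$cnv_spectrum_by_clade$short, cfg$cnv_spectrum_by_clade$short)
})

test_that("family simulation is deterministic and conserves alleles", {
  cfg <- sim_config(n_trios = 8, n_pedigrees = 2, cn_measurement_error = 0,
                    cnv_spectrum_by_clade = test_spectra())
  a <- simulate_cnv_and_families(cfg, seed = 17)
  b <- simulate_cnv_and_families(cfg, seed = 17)
  expect_identical(a, b)
  # error-free: observed diploid total = sum of the two truth alleles
  tr <- a$truth
  sums <- tapply(tr$repeat_allele, tr$individual, sum)
  expect_equal(as.vector(sums[a$cn_obs$individual]), a$cn_obs$diploid_total)
  expect_true(all(tr$repeat_allele >= cfg$kmin & tr$repeat_allele <= cfg$kmax))
})

test_that("child haplotypes are copies of parental haplotypes", {
  cfg <- sim_config(n_trios = 10, n_pedigrees = 3, cn_measurement_error = 0,
                    cnv_spectrum_by_clade = test_spectra())
  sim <- simulate_cnv_and_families(cfg, seed = 23)
  tr <- sim$truth
  ped <- sim$pedigree
  kids <- ped[ped$father != "0", ]
  for (i in seq_len(nrow(kids))) {
    for (h in 1:2) {
      parent <- if (h == 1L) kids$father[i] else kids$mother[i]
      child_row <- tr[tr$individual == kids$individual[i] & tr$hap == h, ]
      parent_rows <- tr[tr$individual == parent, ]
      hit <- parent_rows$repeat_allele == child_row$repeat_allele &
        parent_rows$tag_allele == child_row$tag_allele
      expect_true(any(hit))
    }
  }
})

test_that("degenerate point-mass spectra give the planted (tag, allele) pairs", {
  cfg <- sim_config(n_trios = 6, n_pedigrees = 0, cn_measurement_error = 0,
                    cnv_spectrum_by_clade = list(short = c(`8` = 1),
                                                 long = c(`13` = 1)))
  sim <- simulate_cnv_and_families(cfg, seed = 2)
  tr <- sim$truth
  expect_true(all(tr$repeat_allele[tr$tag_allele == "C"] == 8L))
  expect_true(all(tr$repeat_allele[tr$tag_allele == "A"] == 13L))
})

test_that("measurement error perturbs totals by exactly +/-1 at the set rate", {
  cfg <- sim_config(n_trios = 400, n_pedigrees = 0,
                    cn_measurement_error = 0.2,
                    cnv_spectrum_by_clade = test_spectra())
  sim <- simulate_cnv_and_families(cfg, seed = 31)
  delta <- sim$cn_obs$diploid_total - sim$cn_obs$true_total
  expect_true(all(delta %in% c(-1L, 0L, 1L)))
  rate <- mean(delta != 0L)
  n <- nrow(sim$cn_obs)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("pedigree and CN tables round-trip through their writers", {
  cfg <- sim_config(n_trios = 3, n_pedigrees = 1,
                    cnv_spectrum_by_clade = test_spectra())
  sim <- simulate_cnv_and_families(cfg, seed = 1)
  ped_path <- withr::local_tempfile(fileext = ".ped")
  cn_path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(sim$pedigree, ped_path)
  write_cn_table(sim$cn_obs, cn_path)
  ped <- read_pedigree(ped_path)
  expect_equal(ped$individual, sim$pedigree$individual)
  expect_equal(ped$father, sim$pedigree$father)
  cn <- read_cn_table(cn_path)
  expect_equal(cn$diploid_total, sim$cn_obs$diploid_total)
})

test_that("noise-free isoform sizes are exact and perfectly linear", {
  cfg <- sim_config(isoform_intercept = 100, isoform_slope = 10,
                    secretor_effect = 0, isoform_noise_sd = 0,
                    secretor_null_freq = 0)
  panel <- simulate_isoform_panel(c(20, 22, 24, 26, 28), cfg, seed = 3)
  expect_equal(panel$size_kda, 100 + 10 * c(20, 22, 24, 26, 28))
  expect_equal(panel$size_kda[3], 340)
  # a perfectly linear panel gives r^2 = 1 on the continuous sizes
  fit <- lm(size_kda ~ srcr_diploid_cn, data = panel)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1)
})

test_that("isoform classes follow the fixed size thresholds", {
  expect_equal(classify_isoform(c(280, 340, 370, 390)),
               c("IV", "I", "II", "III"))
  expect_equal(classify_isoform(c(287, 345, 375, 389)),
               c("IV", "I", "II", "III"))
})

test_that("isoform slope is recovered from noisy replicate panels", {
  set.seed(41)
  cfg <- sim_config(isoform_intercept = 245, isoform_slope = 5,
                    secretor_effect = 0, isoform_noise_sd = 10,
                    secretor_null_freq = 0)
  slopes <- replicate(100, {
    cns <- sample(seq(14, 34, by = 2), 8, replace = TRUE)
    panel <- simulate_isoform_panel(cns, cfg)
    unname(coef(lm(size_kda ~ srcr_diploid_cn, data = panel))[2])
  })
  expect_lt(abs(mean(slopes) - 5) / 5, 0.10)
})
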