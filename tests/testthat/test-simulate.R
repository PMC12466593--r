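test_that("cohort generation is bit-reproducible for a fixed seed", {
  spec <- heying_cohort_spec()
  a <- simulate_cohort(spec, seed = 601)
  b <- simulate_cohort(spec, seed = 601)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$traits, b$traits)
  c2 <- simulate_cohort(spec, seed = 602)
  expect_false(identical(a$genotypes, c2$genotypes))

  # CSV byte-determinism through the writer
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_genotype_table(a$genotypes, f1)
  write_genotype_table(b$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))

  # seeded draws do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_cohort(spec, seed = 601))
  expect_identical(runif(1), before)
})

test_that("genotype simulation honours the inbreeding parameterization", {
  # f = 1: no heterozygotes, any seed
  calls <- simulate_genotypes(500, p = 0.4, f = 1, alleles = c("C", "A"),
                              seed = 603)
  expect_true(all(calls %in% c("CC", "AA")))

  # f = 0, p = 0.5: HWE proportions 0.25 / 0.5 / 0.25 at large N
  n <- 20000
  calls <- simulate_genotypes(n, p = 0.5, f = 0, alleles = c("A", "B"),
                              seed = 604)
  props <- table(factor(calls, c("AA", "AB", "BB"))) / n
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))

  expect_error(simulate_genotypes(10, p = 0, f = 0), "p > 0")
  expect_error(simulate_genotypes(10, p = 0.5, f = 1.2), "f <= 1")
})

test_that("mean heterozygote deficit matches 2pq(1-f) at the cohort scale", {
  p <- 0.236; f <- 0.26; n <- 176; reps <- 300
  het <- withr::with_seed(605, {
    sapply(seq_len(reps), function(i) {
      mean(simulate_genotypes(n, p = p, f = f,
                              alleles = c("A", "C")) == "AC")
    })
  })
  expected <- 2 * p * (1 - p) * (1 - f)
  se <- sqrt(expected * (1 - expected) / (n * reps))
  expect_lt(abs(mean(het) - expected), 3 * se)
})

test_that("trait simulation is the sampling counterpart of the fitted model", {
  cls <- c("hom_ref", "het", "hom_alt", "het")
  sex <- c("F", "M", "F", "F")
  y <- simulate_traits(cls, sex, mu = 1000, g = c(0, 40, 60),
                       sex_effect = 80, sigma = 0)
  expect_equal(y, c(1000, 1120, 1060, 1040))
  expect_error(simulate_traits(c("hom", "het"), c("F", "M"), 0,
                               c(0, 0, 0), 0, 1),
               "hom_ref/het/hom_alt")

  # CLT check on the preset's live-weight scale
  spec <- heying_cohort_spec()
  grand <- withr::with_seed(606, {
    sapply(1:100, function(i) {
      mean(simulate_cohort(spec, seed = sample.int(2^31 - 1, 1))$
             traits$live_weight)
    })
  })
  ts <- spec$trait_specs[spec$trait_specs$trait == "live_weight", ]
  # expected grand mean: mu + E[g] + sex_effect * P(male)
  p_a <- spec$loci$p_a[1]; f <- spec$loci$f[1]
  probs <- c(p_a^2 + f * p_a * (1 - p_a),
             2 * p_a * (1 - p_a) * (1 - f),
             (1 - p_a)^2 + f * p_a * (1 - p_a))  # AA, het, CC
  eg <- sum(probs * c(ts$g_hom_alt, ts$g_het, ts$g_hom_ref))
  mu_expect <- ts$mu + eg + ts$sex_effect * 43 / 176
  expect_lt(abs(mean(grand) - mu_expect),
            3 * ts$sigma / sqrt(176) / sqrt(100) + 3)
})

test_that("Ct simulation encodes true fold changes recoverably", {
  # noiseless: folds recovered exactly
  ct <- simulate_ct(c(ctrl = 1, hi = 2), n_per_group = 4, sigma_ct = 0,
                    seed = 607)
  rel <- relative_expression(ct, calibrator = "ctrl")
  expect_equal(unique(rel$fold_change[rel$group == "hi"]), 2)
  expect_equal(unique(rel$delta_delta_ct[rel$group == "ctrl"]), 0)

  # noisy: recovered log2 fold unbiased over replicates
  reps <- 200
  lfc <- withr::with_seed(608, {
    sapply(seq_len(reps), function(i) {
      ct <- simulate_ct(c(ctrl = 1, hi = 4), n_per_group = 8,
                        sigma_ct = 0.3)
      rel <- relative_expression(ct, calibrator = "ctrl")
      mean(log2(rel$fold_change[rel$group == "hi"]))
    })
  })
  se <- stats::sd(lfc) / sqrt(reps)
  expect_lt(abs(mean(lfc) - 2), 3 * se)

  expect_error(simulate_ct(c(1, 2), 4), "named")
  expect_error(simulate_ct(c(a = -1), 4), "folds > 0")
})

test_that("simulated allele frequencies round-trip through the diversity module", {
  spec <- heying_cohort_spec()
  cohort <- simulate_cohort(spec, seed = 609)
  cts <- count_genotypes(cohort$genotypes, heying_loci())
  af <- allele_frequencies(cts)
  # focal (alt) allele frequency at each locus within 3 binomial SE
  for (i in seq_len(nrow(spec$loci))) {
    p <- spec$loci$p_a[i]
    est <- af$freq[af$locus == spec$loci$locus[i] & af$role == "alt"]
    se <- sqrt(p * (1 - p) / (2 * 176))
    expect_lt(abs(est - p), 3 * se)
  }
})

test_that("cohort_spec validates its parameters", {
  loci <- heying_loci()
  loci$p_a <- c(0.5, 0.5, 0.5, 1.2)
  loci$f <- 0
  ts <- heying_cohort_spec()$trait_specs
  expect_error(cohort_spec(10, 10, loci, ts), "strictly in \\(0, 1\\)")
  loci$p_a <- 0.5
  loci$f <- c(0, 0, 0, -0.1)
  expect_error(cohort_spec(10, 10, loci, ts), "\\[0, 1\\]")
  loci$f <- 0
  ts_bad <- dplyr::mutate(ts, locus = "nope")
  expect_error(cohort_spec(10, 10, loci, ts_bad), "unknown loci")
})
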