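balanced_cells <- function(g_eff = c(A = 0, B = 40, C = 60),
                           s_eff = c(F = 0, M = 80), mu = 1000,
                           n_cell = 4) {
  grid <- expand.grid(genotype = names(g_eff), sex = names(s_eff),
                      rep = seq_len(n_cell), stringsAsFactors = FALSE)
  tibble::tibble(
    genotype = grid$genotype, sex = grid$sex,
    y = mu + g_eff[grid$genotype] + s_eff[grid$sex]
  )
}

test_that("zero-noise additive data are recovered exactly with mse 0", {
  d <- balanced_cells()
  fit <- fit_trait_model(d, y, genotype_levels = c("A", "B", "C"))
  expect_equal(fit$mse, 0, tolerance = 1e-20)
  co <- stats::coef(fit$model)
  expect_equal(unname(co[["(Intercept)"]]), 1000)
  expect_equal(unname(co[["genotypeB"]]), 40)
  expect_equal(unname(co[["genotypeC"]]), 60)
  expect_equal(unname(co[["sexM"]]), 80)
})

test_that("OLS coefficients match the brute-force normal-equations solve", {
  set.seed(404)
  for (i in 1:100) {
    d <- random_design(n = sample(12:30, 1))
    fit <- fit_trait_model(d, y, genotype_levels = c("A", "B", "C"))
    X <- stats::model.matrix(fit$model)
    beta_brute <- ols_brute(X, d$y)
    expect_equal(unname(stats::coef(fit$model)), c(beta_brute),
                 tolerance = 1e-8)
  }
})

test_that("the genotype F is the Type III partial F (car oracle)", {
  skip_if_not_installed("car")
  set.seed(405)
  d <- random_design(60)
  d$y <- d$y + c(A = 0, B = 5, C = 9)[d$genotype] +
    c(F = 0, M = 6)[d$sex]
  fit <- fit_trait_model(d, y, genotype_levels = c("A", "B", "C"))
  m <- stats::lm(y ~ genotype + sex, data = d,
                 contrasts = list(genotype = "contr.sum", sex = "contr.sum"))
  a3 <- car::Anova(m, type = 3)
  expect_equal(fit$genotype_F, a3["genotype", "F value"],
               tolerance = 1e-10)
  expect_equal(fit$genotype_p, a3["genotype", "Pr(>F)"],
               tolerance = 1e-10)
})

test_that("balanced designs give the classical two-way ANOVA F", {
  set.seed(406)
  d <- balanced_cells(n_cell = 6)
  d$y <- d$y + stats::rnorm(nrow(d), 0, 30)
  fit <- fit_trait_model(d, y, genotype_levels = c("A", "B", "C"))
  a <- stats::anova(stats::lm(y ~ sex + genotype, data = d))
  expect_equal(fit$genotype_F, a["genotype", "F value"], tolerance = 1e-10)
})

test_that("degenerate designs error, naming the offending factor", {
  d <- balanced_cells()
  expect_error(
    fit_trait_model(dplyr::filter(d, genotype == "A"), y),
    "genotype.*single level"
  )
  expect_error(
    fit_trait_model(dplyr::filter(d, sex == "F"), y),
    "sex.*single level"
  )
  expect_error(
    fit_trait_model(dplyr::mutate(d, sex = "X"), y),
    "sex codes"
  )
})

test_that("pairwise comparisons honour the single-contrast identity and adjustments", {
  set.seed(407)
  d <- random_design(40, k_geno = 2)
  fit <- fit_trait_model(d, y, genotype_levels = c("A", "B"))
  cmp <- pairwise_genotype_comparisons(fit, method = "lsd")
  # with two groups the unadjusted pairwise p equals the genotype F p
  expect_equal(cmp$p_raw, fit$genotype_p, tolerance = 1e-12)
  expect_equal(cmp$p_adj, cmp$p_raw)

  d3 <- random_design(60, k_geno = 3)
  fit3 <- fit_trait_model(d3, y, genotype_levels = c("A", "B", "C"))
  bon <- pairwise_genotype_comparisons(fit3, method = "bonferroni")
  lsd <- pairwise_genotype_comparisons(fit3, method = "lsd")
  expect_equal(bon$p_adj, pmin(1, 3 * lsd$p_raw))
  tuk <- pairwise_genotype_comparisons(fit3, method = "tukey")
  expect_true(all(tuk$p_adj >= lsd$p_raw - 1e-12))
  expect_error(pairwise_genotype_comparisons(fit3, method = "duncan"))
})

test_that("pairwise comparisons agree with emmeans contrasts", {
  skip_if_not_installed("emmeans")
  set.seed(408)
  d <- random_design(80)
  d$y <- d$y + c(A = 0, B = 8, C = 3)[d$genotype]
  fit <- fit_trait_model(d, y, genotype_levels = c("A", "B", "C"))
  cmp <- pairwise_genotype_comparisons(fit, method = "lsd")
  em <- as.data.frame(
    emmeans::contrast(emmeans::emmeans(fit$model, "genotype"),
                      "pairwise", adjust = "none")
  )
  expect_equal(cmp$diff, em$estimate, tolerance = 1e-10)
  expect_equal(cmp$se, em$SE, tolerance = 1e-10)
  expect_equal(cmp$p_raw, em$p.value, tolerance = 1e-10)
})

test_that("a strongly shifted group separates from both others", {
  set.seed(409)
  d <- random_design(90)
  d$y <- d$y + ifelse(d$genotype == "B", 5 * 10, 0)  # 5 pooled SDs
  fit <- fit_trait_model(d, y, genotype_levels = c("A", "B", "C"))
  cmp <- pairwise_genotype_comparisons(fit, "lsd")
  involving_b <- cmp$genotype_a == "B" | cmp$genotype_b == "B"
  expect_true(all(cmp$p_adj[involving_b] < 0.01))
})

test_that("letter displays reproduce the published table patterns", {
  # higher-mean pair indistinguishable, both above the low group
  cmp <- tibble::tibble(
    genotype_a = c("CA", "CA", "AA"),
    genotype_b = c("AA", "CC", "CC"),
    p_adj = c(0.60, 0.02, 0.03)
  )
  cld <- compact_letter_display(
    cmp, c(CC = 1171.67, CA = 1230.11, AA = 1255.39)
  )
  lt <- stats::setNames(cld$letters, cld$genotype)
  expect_equal(lt[["AA"]], "a")
  expect_equal(lt[["CA"]], "a")
  expect_equal(lt[["CC"]], "b")

  # middle group shares a letter with both ends: b / ab / a
  cmp2 <- tibble::tibble(
    genotype_a = c("AA", "AA", "CA"),
    genotype_b = c("CA", "CC", "CC"),
    p_adj = c(0.40, 0.04, 0.30)
  )
  cld2 <- compact_letter_display(
    cmp2, c(CC = 22.12, CA = 23.17, AA = 23.74)
  )
  lt2 <- stats::setNames(cld2$letters, cld2$genotype)
  expect_equal(lt2[["AA"]], "a")
  expect_equal(lt2[["CA"]], "ab")
  expect_equal(lt2[["CC"]], "b")

  # all non-significant -> single shared letter; upper case at 0.01
  cmp3 <- dplyr::mutate(cmp2, p_adj = 0.5)
  cld3 <- compact_letter_display(cmp3, c(CC = 1, CA = 2, AA = 3),
                                 alpha = 0.01, case = "upper")
  expect_equal(unique(cld3$letters), "A")

  expect_error(
    compact_letter_display(cmp2[1:2, ], c(CC = 1, CA = 2, AA = 3)),
    "cover"
  )
})

test_that("letters satisfy share-a-letter iff non-significant on random p-matrices", {
  set.seed(410)
  for (i in 1:500) {
    k <- sample(3:6, 1)
    groups <- paste0("G", seq_len(k))
    p_mat <- matrix(0, k, k, dimnames = list(groups, groups))
    p_mat[upper.tri(p_mat)] <- stats::runif(k * (k - 1) / 2)
    p_mat <- p_mat + t(p_mat)
    means <- stats::setNames(stats::rnorm(k), groups)
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    cld <- compact_letter_display(pmat_to_comparisons(p_mat), means,
                                  alpha = alpha)
    lt <- stats::setNames(strsplit(cld$letters, ""), cld$genotype)
    expect_true(all(lengths(lt) >= 1))
    for (a in groups) for (b in groups) {
      if (a < b) {
        share <- length(intersect(lt[[a]], lt[[b]])) > 0
        expect_equal(share, p_mat[a, b] >= alpha)
      }
    }
    # 'a' always annotates the highest observed mean
    top <- names(which.max(means))
    expect_true("a" %in% lt[[top]])
  }
})

test_that("trait summaries carry raw means, dual-alpha letters and display strings", {
  spec <- heying_cohort_spec()
  cohort <- simulate_cohort(spec, seed = 411)
  d <- dplyr::inner_join(cohort$genotypes, cohort$traits, by = "sample_id")
  d$genotype <- d[["g.57337C>A"]]
  fit <- fit_trait_model(d, live_weight,
                         genotype_levels = c("CC", "AC", "AA"))
  summ <- summarize_trait_by_genotype(fit)
  expect_equal(summ$genotype, c("CC", "AC", "AA"))
  expect_equal(sum(summ$n), fit$n_used)
  # raw group means, not model-adjusted
  raw <- d |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(m = mean(live_weight))
  expect_equal(summ$mean, raw$m[match(summ$genotype, raw$genotype)])
  expect_match(summ$display[1], "^\\d+\\.\\d{2} ± \\d+\\.\\d{2}")
  expect_error(summarize_trait_by_genotype(fit, alpha_high = 0.5),
               "alpha_high")

  # constant trait: all genotypes share a letter, SD renders 0.00
  d$const <- 100
  fitc <- fit_trait_model(d, const, genotype_levels = c("CC", "AC", "AA"))
  # lm warns about the numerically perfect fit; the summary is still defined
  summc <- suppressWarnings(summarize_trait_by_genotype(fitc))
  expect_equal(unique(summc$letters_005), "a")
  expect_match(summc$display[1], "100.00 ± 0.00", fixed = TRUE)
})

test_that("genotype effects are recovered without bias at the cohort shape", {
  # 176 birds, 133/43 sex split, true effects on published gram scales
  spec <- heying_cohort_spec()
  reps <- 120
  est <- withr::with_seed(412, {
    sapply(seq_len(reps), function(i) {
      cohort <- simulate_cohort(spec, seed = sample.int(2^31 - 1, 1))
      d <- dplyr::inner_join(cohort$genotypes, cohort$traits,
                             by = "sample_id")
      d$genotype <- d[["g.57337C>A"]]
      fit <- fit_trait_model(d, live_weight,
                             genotype_levels = c("CC", "AC", "AA"))
      co <- stats::coef(fit$model)
      c(het = unname(co[["genotypeAC"]]),
        hom_alt = unname(co[["genotypeAA"]]),
        sex = unname(co[["sexM"]]))
    })
  })
  truth <- c(het = 80, hom_alt = 100, sex = 250)
  bias <- rowMeans(est) - truth
  mc_se <- apply(est, 1, stats::sd) / sqrt(reps)
  expect_true(all(abs(bias) < 3.5 * mc_se))
})

test_that("null genotype-F p-values are uniform", {
  spec <- heying_cohort_spec()
  null_spec <- spec
  null_spec$trait_specs <- tibble::tibble(
    trait = "flat", mu = 1400, g_hom_ref = 0, g_het = 0, g_hom_alt = 0,
    sex_effect = 0, sigma = 240, locus = "g.57337C>A"
  )
  reps <- 400
  pvals <- withr::with_seed(413, {
    sapply(seq_len(reps), function(i) {
      cohort <- simulate_cohort(null_spec, seed = sample.int(2^31 - 1, 1))
      d <- dplyr::inner_join(cohort$genotypes, cohort$traits,
                             by = "sample_id")
      d$genotype <- d[["g.57337C>A"]]
      fit_trait_model(d, flat,
                      genotype_levels = c("CC", "AC", "AA"))$genotype_p
    })
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("associate_traits assembles the per-locus association table", {
  cohort <- simulate_cohort(heying_cohort_spec(), seed = 414)
  out <- associate_traits(cohort$genotypes, cohort$traits,
                          trait_cols = c("live_weight", "heart_weight"))
  expect_true(all(c("locus", "trait", "genotype", "n", "mean", "sd",
                    "letters_005", "letters_001", "display",
                    "genotype_F", "genotype_p") %in% names(out)))
  expect_setequal(unique(out$trait), c("live_weight", "heart_weight"))
  # per locus x trait, group ns sum to the fitted N
  sums <- out |>
    dplyr::summarise(n = sum(n), .by = c(locus, trait))
  expect_true(all(sums$n <= 176))
  rounded <- render_association_report(out)
  expect_equal(rounded$mean, round_half_up(out$mean, 2))
})
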