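#' Specify a synthetic cohort
#'
#' Collects the ground-truth parameters of a simulated candidate-gene
#' cohort: the sex split, per-locus allele frequencies with a
#' Hardy-Weinberg departure parameter, and per-trait additive model
#' parameters. [simulate_cohort()] samples from it.
#'
#' The Hardy-Weinberg departure is a single inbreeding coefficient `f` per
#' locus: genotype-class probabilities are `p^2 + f p q` (hom for the
#' focal allele), `2 p q (1 - f)` (het) and `q^2 + f p q`, so positive `f`
#' produces the heterozygote deficit seen at disequilibrated loci.
#'
#' @param n_female,n_male Cohort sex counts.
#' @param loci A locus manifest ([locus_table()]) with two extra columns:
#'   `p_a` — the frequency of `allele_a` (see below) — and `f` — the
#'   inbreeding coefficient in `[0, 1]`.
#' @param allele_a_col Which manifest column names the focal allele that
#'   `p_a` refers to (default `"allele_alt"`).
#' @param trait_specs Tibble with one row per trait: `trait`, `mu` (grand
#'   mean, grams, at the reference female), `g_hom_ref`, `g_het`,
#'   `g_hom_alt` (genotype effects, grams), `sex_effect` (male minus
#'   female, grams), `sigma` (residual SD, grams), and `locus` naming the
#'   causal locus whose genotype carries the effects.
#' @return An object of class `cohort_spec` (a named list).
#' @seealso [heying_cohort_spec()] for the packaged preset.
#' @export
cohort_spec <- function(n_female, n_male, loci, trait_specs,
                        allele_a_col = c("allele_alt", "allele_ref")) {
  allele_a_col <- match.arg(allele_a_col)
  stopifnot(n_female >= 0, n_male >= 0, n_female + n_male > 0)
  needed <- c("locus", "allele_ref", "allele_alt", "p_a", "f")
  if (!all(needed %in% names(loci))) {
    stop("`loci` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(loci$p_a <= 0 | loci$p_a >= 1)) {
    stop("allele frequencies p_a must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (any(loci$f < 0 | loci$f > 1)) {
    stop("inbreeding coefficients f must lie in [0, 1]", call. = FALSE)
  }
  tneed <- c("trait", "mu", "g_hom_ref", "g_het", "g_hom_alt",
             "sex_effect", "sigma", "locus")
  if (!all(tneed %in% names(trait_specs))) {
    stop("`trait_specs` needs columns: ", paste(tneed, collapse = ", "),
         call. = FALSE)
  }
  if (any(!trait_specs$locus %in% loci$locus)) {
    stop("trait_specs reference unknown loci", call. = FALSE)
  }
  if (any(trait_specs$sigma < 0)) {
    stop("residual sigma must be >= 0", call. = FALSE)
  }
  structure(
    list(n_female = as.integer(n_female), n_male = as.integer(n_male),
         loci = tibble::as_tibble(loci), allele_a_col = allele_a_col,
         trait_specs = tibble::as_tibble(trait_specs)),
    class = "cohort_spec"
  )
}

#' Preset cohort specification mirroring the motivating chicken study
#'
#' A 176-bird cohort (133 hens, 43 roosters) genotyped at the four FTO exon
#' SNPs of [heying_loci()], with allele frequencies matching the published
#' genotype counts (allele frequency pairs 0.236/0.764, 0.261/0.739,
#' 0.952/0.048, 0.949/0.051) and heterozygote-deficit inbreeding
#' coefficients at the two
#' disequilibrated loci (f = 0.26; the two near-equilibrium loci use
#' f = 0). Six representative traits on published gram scales (16-week
#' slaughter, live, breast-muscle, leg-muscle, heart weights and 8-week
#' body weight) carry additive genotype effects at the first locus chosen
#' to qualitatively reproduce the published letter patterns; sex effects
#' reflect the rooster-hen weight gap.
#'
#' @return A `cohort_spec`.
#' @examples
#' spec <- heying_cohort_spec()
#' cohort <- simulate_cohort(spec, seed = 42)
#' @export
heying_cohort_spec <- function() {
  loci <- heying_loci()
  # focal allele = first allele listed in the published frequency table:
  # A (alt), T (ref), G (ref), G (ref); expressed here on the alt allele
  # so p_a is the alt-allele frequency at every locus
  loci$p_a <- c(0.236, 1 - 0.261, 1 - 0.952, 1 - 0.949)
  loci$f <- c(0.26, 0.26, 0, 0)
  trait_specs <- tibble::tribble(
    ~trait,            ~mu,  ~g_hom_ref, ~g_het, ~g_hom_alt, ~sex_effect, ~sigma, ~locus,
    "slaughter_weight", 1150,  0,          60,     85,         230,         210,   "g.57337C>A",
    "live_weight",      1330,  0,          80,     100,        250,         220,   "g.57337C>A",
    "breast_muscle",    62,    0,          8,      8,          10,          11,    "g.57337C>A",
    "leg_muscle",       88,    0,          9,      10,         18,          20,    "g.57337C>A",
    "heart_weight",     5.9,   0,          1.1,    1.0,        1.4,         1.9,   "g.57337C>A",
    "body_weight_8w",   615,   0,          65,     45,         90,          95,    "g.57337C>A"
  )
  cohort_spec(133, 43, loci, trait_specs, allele_a_col = "allele_alt")
}

#' Simulate genotype calls at one biallelic locus
#'
#' Draws `n` genotype calls with class probabilities
#' `(p^2 + f p q, 2 p q (1 - f), q^2 + f p q)` for the homozygote of the
#' first allele, the heterozygote, and the homozygote of the second allele
#' (`q = 1 - p`; `f = 0` is exact Hardy-Weinberg equilibrium, `f = 1`
#' eliminates heterozygotes).
#'
#' @param n Number of individuals.
#' @param p Frequency of `alleles[1]`, strictly in (0, 1).
#' @param f Inbreeding coefficient in `[0, 1]`.
#' @param alleles Two allele symbols.
#' @param seed Optional seed (local to this call).
#' @return Character vector of canonical two-letter calls.
#' @examples
#' table(simulate_genotypes(100, p = 0.5, f = 0, seed = 1))
#' @export
simulate_genotypes <- function(n, p, f = 0, alleles = c("A", "B"),
                               seed = NULL) {
  stopifnot(n >= 0, p > 0, p < 1, f >= 0, f <= 1, length(alleles) == 2)
  q <- 1 - p
  probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  classes <- c(
    paste(sort(c(alleles[1], alleles[1])), collapse = ""),
    paste(sort(alleles), collapse = ""),
    paste(sort(c(alleles[2], alleles[2])), collapse = "")
  )
  draw <- function() sample(classes, n, replace = TRUE, prob = probs)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate trait values under the additive genotype + sex model
#'
#' `Y = mu + g[genotype class] + sex_effect * (sex == "M") +
#' Normal(0, sigma^2)`, independent across individuals — the sampling
#' counterpart of the model fitted by [fit_trait_model()].
#'
#' @param genotype_class Character vector of classes `"hom_ref"`, `"het"`,
#'   `"hom_alt"` (or a factor with those levels).
#' @param sex Character vector of `"F"`/`"M"`, same length.
#' @param mu Grand mean (reference female, grams).
#' @param g Named or positional numeric vector of the three genotype
#'   effects `(hom_ref, het, hom_alt)` in grams.
#' @param sex_effect Male minus female effect (grams).
#' @param sigma Residual SD (grams), `>= 0`.
#' @param seed Optional seed (local to this call).
#' @return Numeric vector of trait values.
#' @examples
#' simulate_traits(c("hom_ref", "het"), c("F", "M"), mu = 1400,
#'                 g = c(0, 40, 60), sex_effect = 80, sigma = 0, seed = 1)
#' @export
simulate_traits <- function(genotype_class, sex, mu, g, sex_effect, sigma,
                            seed = NULL) {
  stopifnot(length(genotype_class) == length(sex), length(g) == 3,
            sigma >= 0)
  idx <- match(as.character(genotype_class),
               c("hom_ref", "het", "hom_alt"))
  if (anyNA(idx)) {
    stop("genotype_class values must be hom_ref/het/hom_alt",
         call. = FALSE)
  }
  mean_part <- mu + unname(g)[idx] + sex_effect * (sex == "M")
  draw <- function() mean_part + stats::rnorm(length(idx), 0, sigma)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Generates per-sample target and reference Ct values such that the
#' true expression of each group, relative to the group with fold 1
#' (the intended calibrator), equals the requested fold change:
#' reference `Ct ~ Normal(mu_ref, sigma_ct^2)` and target
#' `Ct = mu_target - log2(fold) + Normal(0, sigma_ct^2)`, so the recovered
#' fold change is unbiased on the log2 scale.
#'
#' @param folds Named positive numeric vector: true fold change per group
#'   (names are group labels; use 1 for the calibrator group).
#' @param n_per_group Samples per group.
#' @param mu_target,mu_ref Baseline mean Ct of the target and reference
#'   gene (cycles).
#' @param sigma_ct Per-measurement Ct SD (cycles), `>= 0`.
#' @param seed Optional seed (local to this call).
#' @return A tidy Ct table (`sample_id`, `group`, `gene_role`,
#'   `replicate`, `ct`) accepted by [delta_ct()].
#' @examples
#' simulate_ct(c(W1 = 1, W16 = 4), n_per_group = 3, sigma_ct = 0, seed = 1)
#' @export
simulate_ct <- function(folds, n_per_group, mu_target = 25, mu_ref = 20,
                        sigma_ct = 0.3, seed = NULL) {
  stopifnot(length(folds) >= 1, all(folds > 0), n_per_group >= 1,
            sigma_ct >= 0)
  if (is.null(names(folds)) || any(!nzchar(names(folds)))) {
    stop("`folds` must be named by group", call. = FALSE)
  }
  draw <- function() {
    purrr::imap_dfr(folds, function(fold, grp) {
      ids <- sprintf("%s_%02d", grp, seq_len(n_per_group))
      tibble::tibble(
        sample_id = rep(ids, 2),
        group = grp,
        gene_role = rep(c("target", "reference"), each = n_per_group),
        replicate = 1L,
        ct = c(
          mu_target - log2(fold) + stats::rnorm(n_per_group, 0, sigma_ct),
          mu_ref + stats::rnorm(n_per_group, 0, sigma_ct)
        )
      )
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full cohort from a specification
#'
#' Samples sexes, genotype calls at every locus, and trait values for each
#' individual of a [cohort_spec()]. Generation is deterministic given
#' `seed` (identical spec + seed reproduce the tables exactly) and leaves
#' the caller's RNG state untouched.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @return A list with elements `genotypes` (tibble: `sample_id`, `sex`,
#'   one call column per locus), `traits` (tibble: `sample_id` + one
#'   numeric column per trait), and `spec` (the ground truth used).
#' @examples
#' cohort <- simulate_cohort(heying_cohort_spec(), seed = 7)
#' head(cohort$genotypes)
#' @export
simulate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_female + spec$n_male
    sample_id <- sprintf("bird_%03d", seq_len(n))
    sex <- sample(rep(c("F", "M"), c(spec$n_female, spec$n_male)))
    geno <- tibble::tibble(sample_id = sample_id, sex = sex)
    class_by_locus <- list()
    for (i in seq_len(nrow(spec$loci))) {
      row <- spec$loci[i, ]
      allele_a <- row[[spec$allele_a_col]]
      allele_b <- if (spec$allele_a_col == "allele_alt") row$allele_ref
                  else row$allele_alt
      calls <- simulate_genotypes(n, p = row$p_a, f = row$f,
                                  alleles = c(allele_a, allele_b))
      geno[[row$locus]] <- calls
      class_by_locus[[row$locus]] <- classify_calls(
        calls, sample_id, row$locus, row$allele_ref, row$allele_alt
      )
    }
    traits <- tibble::tibble(sample_id = sample_id)
    for (i in seq_len(nrow(spec$trait_specs))) {
      ts <- spec$trait_specs[i, ]
      traits[[ts$trait]] <- simulate_traits(
        class_by_locus[[ts$locus]], sex, mu = ts$mu,
        g = c(ts$g_hom_ref, ts$g_het, ts$g_hom_alt),
        sex_effect = ts$sex_effect, sigma = ts$sigma
      )
    }
    list(genotypes = geno, traits = traits, spec = spec)
  })
}
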