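#' Fit the fixed-effects trait model (genotype + sex)
#'
#' Fits the two-factor fixed-effects linear model
#' `Y = mu + genotype + sex + error` by ordinary least squares on complete
#' cases. The model has no interaction term; sex enters as a fixed factor
#' with `F` (female) as the reference level, genotype with the first level
#' of `genotype_levels` as reference. The genotype F statistic is the
#' partial (each-term-last, i.e. Type III) F for genotype given sex, the
#' appropriate test when the design is sex-unbalanced.
#'
#' @param data Data frame with one row per individual, containing the trait
#'   column, a genotype column and a sex column (`"F"`/`"M"`).
#' @param trait Bare name of the numeric trait column (grams in the
#'   motivating application).
#' @param genotype,sex Bare names of the genotype and sex columns (defaults
#'   `genotype`, `sex`).
#' @param genotype_levels Optional character vector fixing the genotype
#'   level order (canonical order hom-ref, het, hom-alt); defaults to order
#'   of first appearance.
#' @return An object of class `trait_fit`: the underlying `lm` fit plus the
#'   trait name, genotype level order, per-genotype sample sizes, residual
#'   mean square, and the genotype partial F and its p-value. Methods:
#'   [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot], `print()`.
#' @examples
#' cohort <- simulate_cohort(heying_cohort_spec(), seed = 1)
#' d <- dplyr::inner_join(cohort$genotypes, cohort$traits, "sample_id")
#' d$genotype <- d[["g.57337C>A"]]
#' fit <- fit_trait_model(d, live_weight, genotype_levels = c("CC", "AC", "AA"))
#' glance(fit)
#' @export
fit_trait_model <- function(data, trait, genotype = genotype, sex = sex,
                            genotype_levels = NULL) {
  stopifnot(is.data.frame(data))
  trait_name <- rlang::as_label(rlang::enquo(trait))
  df <- dplyr::transmute(
    data,
    y = {{ trait }},
    genotype = as.character({{ genotype }}),
    sex = as.character({{ sex }})
  )
  if (!is.numeric(df$y)) {
    stop("trait column `", trait_name, "` must be numeric", call. = FALSE)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0) stop("no complete cases", call. = FALSE)
  bad_sex <- setdiff(unique(df$sex), c("F", "M"))
  if (length(bad_sex)) {
    stop("sex codes must be F or M, got: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  if (is.null(genotype_levels)) genotype_levels <- unique(df$genotype)
  extra <- setdiff(unique(df$genotype), genotype_levels)
  if (length(extra)) {
    stop("genotype value(s) outside genotype_levels: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  genotype_levels <- intersect(genotype_levels, unique(df$genotype))
  if (length(genotype_levels) < 2) {
    stop("degenerate design: factor `genotype` has a single level",
         call. = FALSE)
  }
  if (length(unique(df$sex)) < 2) {
    stop("degenerate design: factor `sex` has a single level", call. = FALSE)
  }
  df$genotype <- factor(df$genotype, levels = genotype_levels)
  df$sex <- factor(df$sex, levels = c("F", "M"))

  fit <- stats::lm(y ~ genotype + sex, data = df)
  X <- stats::model.matrix(fit)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient design (aliased genotype and sex levels)",
         call. = FALSE)
  }
  reduced <- stats::lm(y ~ sex, data = df)
  cmp <- stats::anova(reduced, fit)
  rdf <- fit$df.residual
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(
      model = fit,
      data = tibble::as_tibble(df),
      trait = trait_name,
      genotype_levels = genotype_levels,
      group_ns = table(df$genotype),
      n_used = nrow(df),
      residual_df = rdf,
      mse = rss / rdf,
      genotype_F = cmp$F[2],
      genotype_p = cmp$`Pr(>F)`[2]
    ),
    class = "trait_fit"
  )
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("Fixed-effects trait model: ", x$trait,
      " ~ genotype + sex\n", sep = "")
  cat("  n =", x$n_used, "(",
      paste(sprintf("%s:%d", names(x$group_ns), as.integer(x$group_ns)),
            collapse = ", "), ")\n")
  cat(sprintf("  genotype F = %.3f, p = %.4g (partial F, df = %d, %d)\n",
              x$genotype_F, x$genotype_p,
              length(x$genotype_levels) - 1L, x$residual_df))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a trait model fit
#'
#' @param x A `trait_fit` from [fit_trait_model()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (broom convention).
#' @method tidy trait_fit
#' @export
tidy.trait_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, 1],
    std.error = co[, 2],
    statistic = co[, 3],
    p.value = co[, 4]
  )
}

#' One-row model summary of a trait model fit
#'
#' @inheritParams tidy.trait_fit
#' @return A one-row tibble: `trait`, `n`, `residual_df`, `mse`,
#'   `r.squared`, `genotype_F`, `genotype_p`.
#' @method glance trait_fit
#' @export
glance.trait_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    n = x$n_used,
    residual_df = x$residual_df,
    mse = x$mse,
    r.squared = summary(x$model)$r.squared,
    genotype_F = x$genotype_F,
    genotype_p = x$genotype_p
  )
}

#' Pairwise genotype comparisons on a fitted trait model
#'
#' Model-adjusted genotype contrasts: for each genotype pair the difference
#' of genotype coefficients, its standard error from the pooled residual
#' mean square, a two-sided t test on the residual degrees of freedom, and
#' a multiplicity adjustment. `"lsd"` (Fisher's least significant
#' difference, the default) leaves the p-value unadjusted; `"tukey"` uses
#' the studentized-range distribution; `"bonferroni"` multiplies by the
#' number of pairs (capped at 1).
#'
#' @param fit A `trait_fit`.
#' @param method `"lsd"`, `"tukey"` or `"bonferroni"`.
#' @return A tibble with one row per unordered pair: `genotype_a`,
#'   `genotype_b`, `diff` (a minus b, model-adjusted), `se`, `t`, `df`,
#'   `p_raw`, `p_adj`, `method`.
#' @export
pairwise_genotype_comparisons <- function(fit,
                                          method = c("lsd", "tukey",
                                                     "bonferroni")) {
  stopifnot(inherits(fit, "trait_fit"))
  method <- match.arg(method)
  lev <- fit$genotype_levels
  k <- length(lev)
  V <- stats::vcov(fit$model)
  beta <- stats::coef(fit$model)
  coef_of <- function(g) paste0("genotype", g)  # reference level -> absent
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    cvec <- stats::setNames(numeric(length(beta)), names(beta))
    if (coef_of(a) %in% names(cvec)) cvec[coef_of(a)] <- 1
    if (coef_of(b) %in% names(cvec)) cvec[coef_of(b)] <- -1
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    p_raw <- 2 * stats::pt(-abs(tval), df = fit$residual_df)
    p_adj <- switch(method,
      lsd = p_raw,
      tukey = stats::ptukey(sqrt(2) * abs(tval), nmeans = k,
                            df = fit$residual_df, lower.tail = FALSE),
      bonferroni = min(1, m * p_raw)
    )
    tibble::tibble(
      genotype_a = a, genotype_b = b,
      diff = est, se = se, t = tval, df = fit$residual_df,
      p_raw = p_raw, p_adj = p_adj, method = method
    )
  })
}

#' Compact letter display for pairwise comparisons
#'
#' Insert-and-absorb letter assignment: groups are ordered by descending
#' observed mean (ties broken by the order of `means`), the letter `a` (or
#' `A`) seeds at the highest mean, and letters are assigned so that two
#' groups share at least one letter if and only if their pairwise
#' comparison is non-significant at `alpha`. Lower-case letters are the
#' convention at `alpha = 0.05`, upper-case at `alpha = 0.01`.
#'
#' @param comparisons A tibble of pairwise comparisons
#'   ([pairwise_genotype_comparisons()]); must cover every pair of the
#'   groups in `means`. Column `p_adj` is compared with `alpha`.
#' @param means Named numeric vector of observed group means; names define
#'   the groups and the tie-break order.
#' @param alpha Significance level.
#' @param case `"lower"` or `"upper"`.
#' @return A tibble with `genotype`, `mean`, `letters`, ordered as `means`.
#' @examples
#' cmp <- tibble::tibble(genotype_a = c("AA", "AA", "CA"),
#'                       genotype_b = c("CA", "CC", "CC"),
#'                       p_adj = c(0.6, 0.01, 0.02))
#' compact_letter_display(cmp, c(CC = 1171, CA = 1230, AA = 1255))
#' @export
compact_letter_display <- function(comparisons, means, alpha = 0.05,
                                   case = c("lower", "upper")) {
  case <- match.arg(case)
  groups <- names(means)
  if (is.null(groups) || anyDuplicated(groups)) {
    stop("`means` must be a uniquely named numeric vector", call. = FALSE)
  }
  have <- paste(pmin(comparisons$genotype_a, comparisons$genotype_b),
                pmax(comparisons$genotype_a, comparisons$genotype_b))
  need_pairs <- utils::combn(groups, 2)
  need <- paste(pmin(need_pairs[1, ], need_pairs[2, ]),
                pmax(need_pairs[1, ], need_pairs[2, ]))
  if (!all(need %in% have)) {
    stop("comparisons do not cover all group pairs: missing ",
         paste(setdiff(need, have), collapse = "; "), call. = FALSE)
  }
  # order groups by descending mean, ties by input order
  ord <- order(-means, seq_along(means))
  groups <- groups[ord]
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (r in seq_len(nrow(comparisons))) {
    a <- comparisons$genotype_a[r]; b <- comparisons$genotype_b[r]
    if (a %in% groups && b %in% groups) {
      s <- comparisons$p_adj[r] < alpha
      sig[a, b] <- sig[b, a] <- s
    }
  }
  cols <- list(seq_len(k))  # one column holding all groups
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!sig[i, j]) next
      newcols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          newcols <- c(newcols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb: drop empty columns and columns contained in another column
      newcols <- Filter(length, newcols)
      keep <- rep(TRUE, length(newcols))
      for (u in seq_along(newcols)) {
        for (v in seq_along(newcols)) {
          if (u != v && keep[v] &&
              all(newcols[[u]] %in% newcols[[v]]) &&
              !(length(newcols[[u]]) == length(newcols[[v]]) && u < v)) {
            keep[u] <- FALSE
            break
          }
        }
      }
      cols <- newcols[keep]
    }
  }
  # letter columns ordered lexicographically by member rank so the letter
  # 'a' seeds at the highest-mean group and, among columns sharing it,
  # the one covering the next-highest groups comes first
  key <- vapply(cols, function(col)
    paste(sprintf("%03d", sort(col)), collapse = ""), character(1))
  cols <- cols[order(key)]
  if (length(cols) > 26) stop("more than 26 letter columns", call. = FALSE)
  alphabet <- if (case == "lower") letters else LETTERS
  lab <- vapply(seq_len(k), function(g) {
    paste(alphabet[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  tibble::tibble(genotype = groups, mean = as.numeric(means[groups]),
                 letters = lab)
}

#' Per-genotype trait summary with significance letters
#'
#' The table row of a candidate-gene association report: raw (unadjusted)
#' per-genotype mean, SD and sample size, annotated with compact letter
#' displays from the model-based pairwise comparisons at two significance
#' levels (lower-case at `alpha`, upper-case at `alpha_high`). The printed
#' `display` string follows the field's convention of `mean +/- SD` with a
#' letter superscript: upper-case letters are shown when the comparisons
#' separate the genotypes at `alpha_high`, otherwise lower-case letters
#' when they separate at `alpha`, otherwise no letters.
#'
#' @param fit A `trait_fit`.
#' @param method Multiple-comparison method, see
#'   [pairwise_genotype_comparisons()].
#' @param alpha,alpha_high The two significance levels (defaults 0.05 and
#'   0.01; `alpha_high` must be below `alpha`).
#' @return A tibble with one row per genotype: `trait`, `genotype`, `n`,
#'   `mean`, `sd`, `letters_005` (at `alpha`), `letters_001` (at
#'   `alpha_high`), `display`, plus the model-level `genotype_F` and
#'   `genotype_p`.
#' @export
summarize_trait_by_genotype <- function(fit, method = "lsd",
                                        alpha = 0.05, alpha_high = 0.01) {
  stopifnot(inherits(fit, "trait_fit"))
  if (!(alpha_high < alpha)) {
    stop("`alpha_high` must be smaller than `alpha`", call. = FALSE)
  }
  raw <- fit$data |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                     sd = stats::sd(.data$y), .groups = "drop") |>
    dplyr::mutate(genotype = as.character(.data$genotype)) |>
    dplyr::arrange(match(.data$genotype, fit$genotype_levels))
  means <- stats::setNames(raw$mean, raw$genotype)
  cmp <- pairwise_genotype_comparisons(fit, method = method)
  low <- compact_letter_display(cmp, means, alpha = alpha, case = "lower")
  high <- compact_letter_display(cmp, means, alpha = alpha_high,
                                 case = "upper")
  out <- raw |>
    dplyr::left_join(dplyr::select(low, "genotype", letters_005 = "letters"),
                     by = "genotype") |>
    dplyr::left_join(dplyr::select(high, "genotype", letters_001 = "letters"),
                     by = "genotype")
  sep_high <- length(unique(out$letters_001)) > 1
  sep_low <- length(unique(out$letters_005)) > 1
  out |>
    dplyr::mutate(
      trait = fit$trait,
      display = paste0(
        sprintf("%.2f ± %.2f", .data$mean, .data$sd),
        if (sep_high) paste0(" ", .data$letters_001)
        else if (sep_low) paste0(" ", .data$letters_005)
        else ""
      ),
      genotype_F = fit$genotype_F,
      genotype_p = fit$genotype_p
    ) |>
    dplyr::select("trait", "genotype", "n", "mean", "sd",
                  "letters_005", "letters_001", "display",
                  "genotype_F", "genotype_p")
}

#' Genotype-trait association across loci and traits
#'
#' Umbrella over the association module: joins a genotype table and a trait
#' table on `sample_id`, and for every (locus, trait) combination fits the
#' genotype + sex fixed-effects model, runs pairwise genotype comparisons,
#' and assembles the per-genotype summary with dual-alpha letters. Genotype
#' classes absent from the data are dropped; a locus left with fewer than
#' two classes is skipped with a warning.
#'
#' @param genotypes Genotype table (`sample_id`, `sex`, one call column per
#'   locus).
#' @param traits Trait table (`sample_id` + numeric trait columns, grams).
#' @param loci Locus manifest ([locus_table()]).
#' @param trait_cols Character vector of trait columns; default all numeric
#'   columns of `traits` except `sample_id`.
#' @inheritParams summarize_trait_by_genotype
#' @return A tibble with one row per locus x trait x genotype, columns as
#'   [summarize_trait_by_genotype()] plus `locus`.
#' @examples
#' cohort <- simulate_cohort(heying_cohort_spec(), seed = 1)
#' associate_traits(cohort$genotypes, cohort$traits,
#'                  trait_cols = "live_weight")
#' @export
associate_traits <- function(genotypes, traits, loci = heying_loci(),
                             trait_cols = NULL, method = "lsd",
                             alpha = 0.05, alpha_high = 0.01) {
  stopifnot(is.data.frame(genotypes), is.data.frame(traits))
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                               logical(1))], "sample_id")
  }
  data <- dplyr::inner_join(genotypes, traits, by = "sample_id")
  loci <- loci[loci$locus %in% names(genotypes), , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    locus <- loci$locus[i]
    labels <- genotype_labels(loci$allele_ref[i], loci$allele_alt[i])
    cls <- classify_calls(data[[locus]], data$sample_id, locus,
                          loci$allele_ref[i], loci$allele_alt[i])
    geno <- labels[match(cls, c("hom_ref", "het", "hom_alt"))]
    levels_present <- labels[labels %in% unique(stats::na.omit(geno))]
    purrr::map_dfr(trait_cols, function(tr) {
      d <- dplyr::mutate(data, .genotype = geno)
      fit <- tryCatch(
        fit_trait_model(d, trait = !!rlang::sym(tr),
                        genotype = .data$.genotype,
                        genotype_levels = levels_present),
        error = function(e) {
          warning("skipping ", locus, " x ", tr, ": ", conditionMessage(e),
                  call. = FALSE)
          NULL
        }
      )
      if (is.null(fit)) return(NULL)
      summarize_trait_by_genotype(fit, method = method, alpha = alpha,
                                  alpha_high = alpha_high) |>
        dplyr::mutate(trait = tr, locus = locus, .before = 1)
    })
  })
  out
}
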