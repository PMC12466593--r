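#' Expected (average) heterozygosity from allele frequencies
#'
#' `H = 1 - sum(p_i^2)`: the probability that two alleles drawn at random
#' are different, i.e. the heterozygosity expected under random mating.
#' Written over any number of alleles although the rest of the pipeline is
#' biallelic.
#'
#' @param freqs Numeric vector of allele frequencies; must be non-negative
#'   and sum to 1 (tolerance 1e-9).
#' @return A single value in `[0, 1 - 1/n]`.
#' @examples
#' heterozygosity(c(0.5, 0.5))   # 0.5, the biallelic maximum
#' @seealso [pic()], [effective_allele_number()], [marker_diversity()]
#' @export
heterozygosity <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

#' Polymorphism information content (PIC)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, a marker-informativeness
#' statistic. For a biallelic locus this reduces to `2pq - 2p^2q^2`, so
#' `0 <= PIC <= H` always. Conventional interpretation: below 0.25 the
#' marker is lowly polymorphic, between 0.25 and 0.5 moderately, above 0.5
#' highly.
#'
#' @inheritParams heterozygosity
#' @return A single value in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  sq <- freqs^2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum sq)^2 - sum(sq^2), since the square of
  # the sum counts each ordered pair once and the diagonal once
  pair_term <- sum(sq)^2 - sum(sq^2)
  1 - sum(sq) - pair_term
}

#' Effective number of alleles
#'
#' `Ne = 1 / sum(p_i^2)`: the number of equifrequent alleles that would give
#' the locus its observed homozygosity. Equals `1 / (1 - H)`.
#'
#' @inheritParams heterozygosity
#' @return A value in `[1, n]` where `n` is the number of alleles.
#' @examples
#' effective_allele_number(c(0.5, 0.5))  # 2
#' @export
effective_allele_number <- function(freqs) {
  check_freqs(freqs)
  1 / sum(freqs^2)
}

check_freqs <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) < 1) {
    stop("`freqs` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(freqs) || any(freqs < 0)) {
    stop("allele frequencies must be non-negative and non-missing",
         call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  invisible(freqs)
}

polymorphism_class <- function(pic_value) {
  dplyr::case_when(
    pic_value < 0.25 ~ "low",
    pic_value <= 0.5 ~ "moderate",
    TRUE ~ "high"
  )
}

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' Tests the observed genotype-class counts of each biallelic locus against
#' the Hardy-Weinberg expectations `N * (p^2, 2pq, q^2)`, with `p` computed
#' at full precision from the same counts. All three classes enter the
#' chi-square sum even when the observed count is zero.
#'
#' The degrees of freedom are configurable because published candidate-gene
#' tables are not consistent about them: `df_mode = "paper"` uses df = 2
#' (treating all three class proportions as free), which reproduces the
#' p-values printed in the motivating study; `df_mode = "standard"` uses the
#' conventional df = 1 (three classes, one allele frequency estimated).
#' df = 2 is conservative: its rejection rate under exact equilibrium falls
#' below the nominal level.
#'
#' @param counts A genotype count table ([count_genotypes()] /
#'   [genotype_counts()]).
#' @param df_mode `"paper"` (df = 2, default) or `"standard"` (df = 1).
#' @return A tibble with one row per locus: `locus`, expected counts
#'   (`exp_hom_ref`, `exp_het`, `exp_hom_alt`), `chi2`, `df`, `p_value`,
#'   `monomorphic`. A monomorphic locus (an allele absent) has `chi2 = 0`,
#'   `p_value = 1` and `monomorphic = TRUE`.
#' @examples
#' genotype_counts("snp1", 111, 47, 18, "C", "A") |> hwe_test()
#' @export
hwe_test <- function(counts, df_mode = c("paper", "standard")) {
  df_mode <- match.arg(df_mode)
  check_count_table(counts)
  df <- if (df_mode == "paper") 2L else 1L
  purrr::pmap_dfr(
    counts[c("locus", "n_hom_ref", "n_het", "n_hom_alt", "n_total")],
    function(locus, n_hom_ref, n_het, n_hom_alt, n_total) {
      p <- (2 * n_hom_ref + n_het) / (2 * n_total)
      q <- 1 - p
      expected <- n_total * c(p^2, 2 * p * q, q^2)
      mono <- p == 0 || q == 0
      chi2 <- if (mono) 0 else {
        obs <- c(n_hom_ref, n_het, n_hom_alt)
        sum((obs - expected)^2 / expected)
      }
      tibble::tibble(
        locus = locus,
        exp_hom_ref = expected[1],
        exp_het = expected[2],
        exp_hom_alt = expected[3],
        chi2 = chi2,
        df = df,
        p_value = if (mono) 1 else
          stats::pchisq(chi2, df = df, lower.tail = FALSE),
        monomorphic = mono
      )
    }
  )
}

#' Per-locus marker diversity summary
#'
#' One-call computation of the full marker-informativeness panel for each
#' locus of a count table: ref-allele frequency, expected heterozygosity
#' `H`, polymorphism information content `PIC` with its low/moderate/high
#' class, effective allele number `Ne`, and the Hardy-Weinberg chi-square
#' test. All statistics are computed at full precision;
#' [render_diversity_report()] applies display rounding.
#'
#' @inheritParams hwe_test
#' @return A tibble with one row per locus: `locus`, `freq_ref`, `freq_alt`,
#'   `H`, `PIC`, `Ne`, `polymorphism_class`, `chi2`, `df`, `p_value`,
#'   `monomorphic`.
#' @examples
#' genotype_counts("snp1", 111, 47, 18, "C", "A") |> marker_diversity()
#' @export
marker_diversity <- function(counts, df_mode = c("paper", "standard")) {
  df_mode <- match.arg(df_mode)
  check_count_table(counts)
  freqs <- allele_frequencies(counts) |>
    dplyr::select("locus", "role", "freq") |>
    tidyr::pivot_wider(names_from = "role", values_from = "freq",
                       names_prefix = "freq_")
  stats_tbl <- purrr::map_dfr(seq_len(nrow(freqs)), function(i) {
    fr <- c(freqs$freq_ref[i], freqs$freq_alt[i])
    tibble::tibble(
      locus = freqs$locus[i],
      H = heterozygosity(fr),
      PIC = pic(fr),
      Ne = effective_allele_number(fr)
    )
  })
  freqs |>
    dplyr::left_join(stats_tbl, by = "locus") |>
    dplyr::mutate(polymorphism_class = polymorphism_class(.data$PIC)) |>
    dplyr::left_join(hwe_test(counts, df_mode = df_mode) |>
                       dplyr::select(-dplyr::starts_with("exp_")),
                     by = "locus")
}
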