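# shared fixtures and independent oracles, built in code

# the four published per-locus genotype count rows (counts as printed;
# hom-ref is the homozygote of the reference allele of the locus name)
published_counts <- function() {
  genotype_counts(
    locus = c("g.57337C>A", "g.64757T>G", "g.97213G>A", "g.220985G>A"),
    n_hom_ref = c(111, 21, 159, 158),
    n_het = c(47, 50, 17, 18),
    n_hom_alt = c(18, 105, 0, 0),
    allele_ref = c("C", "T", "G", "G"),
    allele_alt = c("A", "G", "A", "A")
  )
}

# brute-force PIC: explicit double loop over i < j allele pairs
pic_brute <- function(freqs) {
  n <- length(freqs)
  pair <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        pair <- pair + 2 * freqs[i]^2 * freqs[j]^2
      }
    }
  }
  1 - sum(freqs^2) - pair
}

# brute-force OLS via the normal equations
ols_brute <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# small random genotype+sex design with guaranteed >= 2 levels per factor
random_design <- function(n, k_geno = 3) {
  levels_g <- LETTERS[seq_len(k_geno)]
  repeat {
    g <- sample(levels_g, n, replace = TRUE)
    s <- sample(c("F", "M"), n, replace = TRUE)
    if (length(unique(g)) == k_geno && length(unique(s)) == 2) break
  }
  tibble::tibble(
    genotype = g, sex = s,
    y = stats::rnorm(n, 100, 10)
  )
}

# tiny three-group comparison table from a symmetric p matrix
pmat_to_comparisons <- function(p_mat) {
  groups <- rownames(p_mat)
  pairs <- utils::combn(groups, 2)
  tibble::tibble(
    genotype_a = pairs[1, ],
    genotype_b = pairs[2, ],
    p_adj = p_mat[t(pairs)]
  )
}
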