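#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of
#' SPSS-style report tables), unlike base [round()] which rounds ties to
#' even. Used only at report-rendering time; all statistics are computed
#' at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.0915, 3)  # 0.092
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values stored just under a .5 boundary
  # (binary representation) still round up
  sign(x) * trunc(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Read a genotype table from CSV
#'
#' Expected header: `sample_id,sex,<locus1>,<locus2>,...` with sex `F`/`M`
#' and genotype cells of two allele characters (empty = missing). Calls
#' are canonicalized to unordered allele pairs (`"CA"` and `"AC"` become
#' the same call) and validated against the locus manifest.
#'
#' @param path CSV file path.
#' @param loci Locus manifest; validation is limited to manifest loci
#'   present in the header.
#' @return A tibble of sample records.
#' @export
read_genotype_table <- function(path, loci = heying_loci()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if (!all(c("sample_id", "sex") %in% names(raw))) {
    stop("genotype CSV must start with sample_id,sex columns",
         call. = FALSE)
  }
  dup <- duplicated(raw$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id at row(s) ",
         paste(which(dup), collapse = ", "), ": ",
         paste(unique(raw$sample_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- !raw$sex %in% c("F", "M")
  if (any(bad_sex)) {
    stop("invalid sex code at row(s) ",
         paste(which(bad_sex), collapse = ", "), " (must be F or M)",
         call. = FALSE)
  }
  present <- intersect(loci$locus, names(raw))
  if (!length(present)) {
    stop("no manifest locus columns found in ", path, call. = FALSE)
  }
  for (lc in present) {
    i <- match(lc, loci$locus)
    raw[[lc]] <- canonicalize_calls(raw[[lc]])
    # classification errors name sample and locus
    invisible(classify_calls(raw[[lc]], raw$sample_id, lc,
                             loci$allele_ref[i], loci$allele_alt[i]))
  }
  raw
}

#' Read a trait table from CSV
#'
#' Expected header: `sample_id,<trait1>,<trait2>,...` with numeric,
#' non-negative trait values (grams).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_trait_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!"sample_id" %in% names(raw)) {
    stop("trait CSV must have a sample_id column", call. = FALSE)
  }
  vals <- as.matrix(raw[setdiff(names(raw), "sample_id")])
  if (any(vals < 0, na.rm = TRUE) || any(is.infinite(vals))) {
    stop("trait values must be finite and >= 0", call. = FALSE)
  }
  raw
}

#' Read a qPCR Ct table from CSV
#'
#' Expected header: `sample_id,group,gene_role,replicate,ct` (replicate
#' optional).
#'
#' @param path CSV file path.
#' @return A tibble validated for [delta_ct()].
#' @export
read_ct_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    gene_role = readr::col_character(),
    ct = readr::col_double(),
    .default = readr::col_guess()
  ))
  check_ct_table(raw)
  raw
}

#' Import genotype calls from a biallelic-SNP VCF
#'
#' Maps per-sample GT fields of a VCF to allele-pair calls using the
#' record's REF/ALT symbols: `0/0` to homozygous reference, `0/1`/`1/0`
#' to heterozygous, `1/1` to homozygous alternate, `./.` to missing.
#' Phased separators (`|`) are accepted. Multi-allelic records are
#' rejected. Sample sex comes from a sidecar CSV (`sample_id,sex`)
#' because VCF carries none.
#'
#' @param path VCF file path (plain or bgzipped; parsed with the vcfR
#'   package).
#' @param sex_sidecar CSV path with columns `sample_id`, `sex`; every VCF
#'   sample must appear.
#' @param id_field Which VCF column names the locus: `"ID"` (default,
#'   falling back to `CHROM:POS` where ID is `.`).
#' @return A list: `genotypes` (tibble `sample_id`, `sex`, one column per
#'   locus) and `loci` (manifest inferred from REF/ALT).
#' @export
import_vcf <- function(path, sex_sidecar, id_field = "ID") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required for VCF import", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stop("multi-allelic record(s) rejected at ",
         paste(sprintf("%s:%s", fix$CHROM[multi], fix$POS[multi]),
               collapse = ", "), call. = FALSE)
  }
  if (any(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)) {
    stop("only single-nucleotide records are supported", call. = FALSE)
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s:%s", fix$CHROM, fix$POS)[
    is.na(ids) | ids == "."]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  sex_tbl <- readr::read_csv(sex_sidecar, col_types = readr::cols(
    sample_id = readr::col_character(), sex = readr::col_character()
  ))
  missing_sex <- setdiff(samples, sex_tbl$sample_id)
  if (length(missing_sex)) {
    stop("sample(s) in VCF missing from sex sidecar: ",
         paste(missing_sex, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = samples,
    sex = sex_tbl$sex[match(samples, sex_tbl$sample_id)]
  )
  if (any(!out$sex %in% c("F", "M"))) {
    stop("sex sidecar codes must be F or M", call. = FALSE)
  }
  for (r in seq_along(ids)) {
    alleles <- c(fix$REF[r], fix$ALT[r])
    codes <- gsub("\\|", "/", gt[r, ])
    call <- dplyr::case_when(
      is.na(codes) | codes == "./." ~ NA_character_,
      codes == "0/0" ~ paste0(alleles[1], alleles[1]),
      codes %in% c("0/1", "1/0") ~ paste0(alleles[1], alleles[2]),
      codes == "1/1" ~ paste0(alleles[2], alleles[2]),
      TRUE ~ "bad"
    )
    if (any(call == "bad", na.rm = TRUE)) {
      stop("unsupported GT code(s) at ", ids[r], ": ",
           paste(unique(codes[call == "bad"]), collapse = ", "),
           call. = FALSE)
    }
    out[[ids[r]]] <- canonicalize_calls(call)
  }
  list(
    genotypes = out,
    loci = locus_table(ids, fix$REF, fix$ALT)
  )
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]; missing calls become empty cells.
#'
#' @param genotypes Tibble of sample records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  readr::write_csv(genotypes, path, na = "")
  invisible(path)
}

#' Render the marker-diversity report table
#'
#' Long-format display table mirroring the conventional candidate-gene
#' polymorphism summary: one row per locus x genotype class carrying the
#' genotype count and frequency, the allele and its frequency, and (on the
#' locus's first row) the Hardy-Weinberg chi-square, p, H, PIC and Ne.
#' Display rounding (half away from zero): frequencies, p, H, PIC and Ne
#' to 3 decimals, chi-square to 2. Computation stays at full precision in
#' [marker_diversity()]; with `round = FALSE` the same layout is emitted
#' unrounded.
#'
#' @param counts A genotype count table.
#' @param df_mode Degrees-of-freedom mode for the HWE test ([hwe_test()]).
#' @param round Apply display rounding (default `TRUE`).
#' @return A tibble with columns `locus`, `genotype`, `N`,
#'   `genotypic_freq`, `allele`, `allelic_freq`, `chi2`, `p`, `H`, `PIC`,
#'   `Ne`, `polymorphism_class`.
#' @examples
#' genotype_counts("snp1", 111, 47, 18, "C", "A") |>
#'   render_diversity_report()
#' @export
render_diversity_report <- function(counts, df_mode = c("paper", "standard"),
                                    round = TRUE) {
  df_mode <- match.arg(df_mode)
  div <- marker_diversity(counts, df_mode = df_mode)
  gf <- genotype_frequencies(counts)
  af <- allele_frequencies(counts)
  rnd <- function(x, d) if (round) round_half_up(x, d) else x
  purrr::map_dfr(div$locus, function(lc) {
    g <- gf[gf$locus == lc, ]
    a <- af[af$locus == lc, ]
    d <- div[div$locus == lc, ]
    nrow_out <- nrow(g)
    tibble::tibble(
      locus = c(lc, rep("", nrow_out - 1)),
      genotype = g$genotype,
      N = g$n,
      genotypic_freq = rnd(g$freq, 3),
      allele = c(a$allele, rep("", nrow_out - nrow(a))),
      allelic_freq = c(rnd(a$freq, 3), rep(NA, nrow_out - nrow(a))),
      chi2 = c(rnd(d$chi2, 2), rep(NA, nrow_out - 1)),
      p = c(rnd(d$p_value, 3), rep(NA, nrow_out - 1)),
      H = c(rnd(d$H, 3), rep(NA, nrow_out - 1)),
      PIC = c(rnd(d$PIC, 3), rep(NA, nrow_out - 1)),
      Ne = c(rnd(d$Ne, 3), rep(NA, nrow_out - 1)),
      polymorphism_class = c(d$polymorphism_class, rep("", nrow_out - 1))
    )
  })
}

#' Render the association report table
#'
#' Display layer over [associate_traits()] output: means and SDs rounded
#' to 2 decimals, F to 2, p to 3 (half away from zero); the `display`
#' string is already formatted. With `round = FALSE`, full precision is
#' passed through.
#'
#' @param assoc Output of [associate_traits()].
#' @param round Apply display rounding (default `TRUE`).
#' @return A tibble with display-rounded columns.
#' @export
render_association_report <- function(assoc, round = TRUE) {
  if (!round) return(assoc)
  assoc |>
    dplyr::mutate(
      mean = round_half_up(.data$mean, 2),
      sd = round_half_up(.data$sd, 2),
      genotype_F = round_half_up(.data$genotype_F, 2),
      genotype_p = round_half_up(.data$genotype_p, 3)
    )
}
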