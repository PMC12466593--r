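#' @importFrom rlang .data
NULL

# canonicalize a vector of two-character genotype calls: unordered allele
# pairs, so "CA" and "AC" collapse to one class; "" and NA are missing
canonicalize_calls <- function(calls) {
  calls <- as.character(calls)
  calls[!is.na(calls) & !nzchar(trimws(calls))] <- NA_character_
  calls <- trimws(calls)
  ok <- !is.na(calls)
  if (any(nchar(calls[ok]) != 2L)) {
    bad <- calls[ok][nchar(calls[ok]) != 2L]
    stop("genotype calls must be two allele characters, got: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  out <- calls
  out[ok] <- vapply(
    calls[ok],
    function(g) paste(sort(strsplit(g, "")[[1]]), collapse = ""),
    character(1),
    USE.NAMES = FALSE
  )
  out
}

# classify canonical calls at one locus into hom_ref / het / hom_alt;
# errors name the offending samples
classify_calls <- function(calls, sample_id, locus, allele_ref, allele_alt) {
  canon <- canonicalize_calls(calls)
  hom_ref <- paste(sort(c(allele_ref, allele_ref)), collapse = "")
  het     <- paste(sort(c(allele_ref, allele_alt)), collapse = "")
  hom_alt <- paste(sort(c(allele_alt, allele_alt)), collapse = "")
  cls <- rep(NA_character_, length(canon))
  cls[!is.na(canon) & canon == hom_ref] <- "hom_ref"
  cls[!is.na(canon) & canon == het]     <- "het"
  cls[!is.na(canon) & canon == hom_alt] <- "hom_alt"
  unknown <- !is.na(canon) & is.na(cls)
  if (any(unknown)) {
    stop(sprintf(
      "call(s) with alleles outside {%s,%s} at locus %s for sample(s): %s",
      allele_ref, allele_alt, locus,
      paste(sample_id[unknown], collapse = ", ")
    ), call. = FALSE)
  }
  cls
}

#' Tabulate genotype counts per locus
#'
#' Counts the three genotype classes of each biallelic locus (homozygous
#' reference, heterozygous, homozygous alternate) over a sample table.
#' Heterozygote orientation is collapsed (`"CA"` and `"AC"` are the same
#' class) and missing calls are dropped per locus before counting, so
#' `n_total` can differ between loci.
#'
#' @param data A data frame with one row per sample, a `sample_id` column,
#'   and one genotype-call column per locus named as in `loci$locus`.
#' @param loci A locus manifest from [locus_table()]; defaults to all
#'   manifest loci present as columns of `data`.
#'
#' @return A tibble with one row per locus: `locus`, `allele_ref`,
#'   `allele_alt`, `n_hom_ref`, `n_het`, `n_hom_alt`, `n_total`.
#' @examples
#' geno <- tibble::tibble(
#'   sample_id = c("s1", "s2", "s3"),
#'   "g.57337C>A" = c("CC", "CA", "AC")
#' )
#' count_genotypes(geno, heying_loci()[1, ])
#' @export
count_genotypes <- function(data, loci = heying_loci()) {
  stopifnot(is.data.frame(data))
  if (!"sample_id" %in% names(data)) {
    stop("`data` must have a sample_id column", call. = FALSE)
  }
  present <- loci$locus %in% names(data)
  if (!any(present)) {
    stop("none of the manifest loci are columns of `data`", call. = FALSE)
  }
  loci <- loci[present, , drop = FALSE]
  purrr::pmap_dfr(
    loci[c("locus", "allele_ref", "allele_alt")],
    function(locus, allele_ref, allele_alt) {
      cls <- classify_calls(data[[locus]], data$sample_id,
                            locus, allele_ref, allele_alt)
      tibble::tibble(
        locus = locus,
        allele_ref = allele_ref,
        allele_alt = allele_alt,
        n_hom_ref = sum(cls == "hom_ref", na.rm = TRUE),
        n_het     = sum(cls == "het", na.rm = TRUE),
        n_hom_alt = sum(cls == "hom_alt", na.rm = TRUE),
        n_total   = sum(!is.na(cls))
      )
    }
  )
}

#' Construct a genotype count table directly from counts
#'
#' Convenience constructor for the per-locus count table consumed by
#' [allele_frequencies()], [genotype_frequencies()] and [marker_diversity()],
#' for when genotype class counts are already known (e.g. from a published
#' table) rather than tabulated from sample-level calls.
#'
#' @param locus Locus identifier(s).
#' @param n_hom_ref,n_het,n_hom_alt Non-negative integer genotype-class
#'   counts.
#' @param allele_ref,allele_alt Allele symbols (defaults `"A"`/`"B"`).
#' @return A tibble in the format of [count_genotypes()].
#' @examples
#' genotype_counts("g.57337C>A", 111, 47, 18, allele_ref = "C", allele_alt = "A")
#' @export
genotype_counts <- function(locus, n_hom_ref, n_het, n_hom_alt,
                            allele_ref = "A", allele_alt = "B") {
  counts <- cbind(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  tibble::tibble(
    locus = as.character(locus),
    allele_ref = as.character(allele_ref),
    allele_alt = as.character(allele_alt),
    n_hom_ref = as.integer(n_hom_ref),
    n_het = as.integer(n_het),
    n_hom_alt = as.integer(n_hom_alt),
    n_total = as.integer(n_hom_ref + n_het + n_hom_alt)
  )
}

#' Allele frequencies from genotype counts
#'
#' Computes the frequency of each allele by direct allele counting:
#' `freq = (2 * homozygote count + heterozygote count) / (2 * n_total)`,
#' at full double precision (rounding is a report-rendering concern, see
#' [render_diversity_report()]).
#'
#' @param counts A genotype count table from [count_genotypes()] or
#'   [genotype_counts()].
#' @return A tibble with one row per locus and allele: `locus`, `allele`,
#'   `role` (`"ref"`/`"alt"`), `allele_count`, `freq`. Frequencies sum to 1
#'   per locus.
#' @examples
#' genotype_counts("snp1", 111, 47, 18, "C", "A") |> allele_frequencies()
#' @export
allele_frequencies <- function(counts) {
  check_count_table(counts)
  purrr::pmap_dfr(
    counts[c("locus", "allele_ref", "allele_alt",
             "n_hom_ref", "n_het", "n_hom_alt", "n_total")],
    function(locus, allele_ref, allele_alt,
             n_hom_ref, n_het, n_hom_alt, n_total) {
      ac <- c(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
      tibble::tibble(
        locus = locus,
        allele = c(allele_ref, allele_alt),
        role = c("ref", "alt"),
        allele_count = ac,
        freq = ac / (2 * n_total)
      )
    }
  )
}

#' Genotype-class frequencies from genotype counts
#'
#' @inheritParams allele_frequencies
#' @return A tibble with one row per locus and genotype class: `locus`,
#'   `genotype` (e.g. `"CC"`, `"CA"`, `"AA"`), `class`
#'   (`hom_ref`/`het`/`hom_alt`), `n`, `freq`. Frequencies sum to 1 per
#'   locus.
#' @examples
#' genotype_counts("snp1", 111, 47, 18, "C", "A") |> genotype_frequencies()
#' @export
genotype_frequencies <- function(counts) {
  check_count_table(counts)
  purrr::pmap_dfr(
    counts[c("locus", "allele_ref", "allele_alt",
             "n_hom_ref", "n_het", "n_hom_alt", "n_total")],
    function(locus, allele_ref, allele_alt,
             n_hom_ref, n_het, n_hom_alt, n_total) {
      n <- c(n_hom_ref, n_het, n_hom_alt)
      tibble::tibble(
        locus = locus,
        genotype = genotype_labels(allele_ref, allele_alt),
        class = c("hom_ref", "het", "hom_alt"),
        n = n,
        freq = n / n_total
      )
    }
  )
}

check_count_table <- function(counts) {
  needed <- c("locus", "allele_ref", "allele_alt",
              "n_hom_ref", "n_het", "n_hom_alt", "n_total")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols)) {
    stop("count table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(counts$n_total == 0)) {
    stop("locus with no non-missing calls: ",
         paste(counts$locus[counts$n_total == 0], collapse = ", "),
         call. = FALSE)
  }
  tot <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
  if (any(tot != counts$n_total)) {
    stop("genotype counts do not sum to n_total", call. = FALSE)
  }
  invisible(counts)
}
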