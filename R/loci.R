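#' Build a validated locus manifest
#'
#' A locus manifest declares the biallelic SNPs a genotype table may contain:
#' one row per locus with its identifier, the two allele symbols, and an
#' optional free-text region label (e.g. `"exon 5"`). All downstream
#' tabulation validates genotype calls against this manifest.
#'
#' @param locus Character vector of unique, non-empty locus identifiers
#'   (e.g. `"g.57337C>A"`).
#' @param allele_ref,allele_alt Single-character allele symbols; the reference
#'   and alternate allele of each locus. Must differ within a locus.
#' @param region Optional character vector of region labels (recycled `NA`
#'   if omitted).
#'
#' @return A tibble with columns `locus`, `allele_ref`, `allele_alt`,
#'   `region`.
#' @examples
#' locus_table("g.57337C>A", "C", "A", "exon 5")
#' @export
locus_table <- function(locus, allele_ref, allele_alt, region = NA_character_) {
  locus <- as.character(locus)
  allele_ref <- as.character(allele_ref)
  allele_alt <- as.character(allele_alt)
  if (length(locus) == 0) {
    stop("locus manifest must contain at least one locus", call. = FALSE)
  }
  if (anyNA(locus) || any(!nzchar(locus))) {
    stop("locus identifiers must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(locus)) {
    stop("duplicate locus identifiers: ",
         paste(unique(locus[duplicated(locus)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(allele_ref) != 1L) || any(nchar(allele_alt) != 1L)) {
    stop("allele symbols must be single characters", call. = FALSE)
  }
  bad <- allele_ref == allele_alt
  if (any(bad)) {
    stop("allele_ref and allele_alt must differ at locus ",
         paste(locus[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    locus = locus,
    allele_ref = allele_ref,
    allele_alt = allele_alt,
    region = rep_len(as.character(region), length(locus))
  )
}

#' Preset locus manifest for the four chicken FTO exon SNPs
#'
#' The four biallelic exonic SNPs of the chicken fat-mass-and-obesity
#' associated (FTO) gene used throughout the package examples. Genomic
#' coordinates in the identifiers are treated as opaque labels.
#'
#' @return A four-row locus manifest (see [locus_table()]).
#' @examples
#' heying_loci()
#' @export
heying_loci <- function() {
  locus_table(
    locus      = c("g.57337C>A", "g.64757T>G", "g.97213G>A", "g.220985G>A"),
    allele_ref = c("C", "T", "G", "G"),
    allele_alt = c("A", "G", "A", "A"),
    region     = c("exon 5", "exon 7", "exon 8", "exon 9")
  )
}

# genotype-class labels in canonical order (hom-ref, het, hom-alt),
# het printed ref-allele first, e.g. "CC", "CA", "AA" for a C>A locus
genotype_labels <- function(allele_ref, allele_alt) {
  c(paste0(allele_ref, allele_ref),
    paste0(allele_ref, allele_alt),
    paste0(allele_alt, allele_alt))
}
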