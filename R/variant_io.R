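#' Write a multi-sample VCF of allele depths
#'
#' Emits a minimal VCF 4.2 with one biallelic SNV record per site and
#' per-sample `AD` (ref,alt) and `DP` genotype fields, the format consumed
#' by [read_vcf()]. Sites are sorted by (`chrom`, `pos`); the sample column
#' order is the order of first appearance in `ad`.
#'
#' @param ad Long allele-depth tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `alt_count`, `total_depth`).
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ad, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "sample",
                  "alt_count", "total_depth") %in% names(ad)))
  if (any(ad$alt_count > ad$total_depth)) {
    abort("alt_count exceeds total_depth; invalid allele-depth table")
  }
  samples <- unique(ad$sample)
  sites <- ad |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridscar",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(sites) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  key <- paste(ad$chrom, ad$pos, ad$sample, sep = "\r")
  ref_n <- ad$total_depth - ad$alt_count
  cell <- setNames(paste0(ref_n, ",", ad$alt_count, ":", ad$total_depth), key)
  gt <- vapply(samples, function(s) {
    k <- paste(sites$chrom, sites$pos, s, sep = "\r")
    out <- unname(cell[k])
    out[is.na(out)] <- "0,0:0"
    out
  }, character(nrow(sites)))
  gt <- matrix(gt, nrow = nrow(sites))
  records <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                   ".", ".", ".", "AD:DP",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a multi-sample VCF into an allele-depth table
#'
#' Parses a VCF (via \pkg{vcfR}) and returns the long allele-depth tibble
#' used throughout the package. Multi-allelic records and non-SNV records
#' (indels, symbolic alleles, missing ALT) are dropped; the number dropped
#' is reported as the `n_dropped` attribute and a message. A sample with a
#' missing `AD` entry at a site is recorded as depth 0.
#'
#' @param path VCF path.
#' @param region Optional filter, a list or tibble row with `chrom` and
#'   optionally `start`/`end` (1-based inclusive) restricting the sites
#'   returned.
#'
#' @return Allele-depth tibble (`chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `alt_count`, `total_depth`) with attribute `n_dropped`.
#' @export
read_vcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) { # single-record VCFs come back as a bare vector
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  }
  fix <- tibble::as_tibble(as.data.frame(fixm, stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          sample = character(), alt_count = integer(),
                          total_depth = integer())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fmt <- vcf@gt[, "FORMAT", drop = TRUE]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    abort("VCF records lack the AD genotype field; unsupported format")
  }
  snv <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_dropped <- sum(!snv)
  if (n_dropped > 0L) {
    message(n_dropped, " multi-allelic or non-SNV record(s) dropped")
  }
  ad_mat <- vcfR::extract.gt(vcf, element = "AD")[snv, , drop = FALSE]
  sites <- fix[snv, ]
  out <- tibble::tibble(
    chrom = rep(sites$CHROM, ncol(ad_mat)),
    pos = rep(as.integer(sites$POS), ncol(ad_mat)),
    ref = rep(sites$REF, ncol(ad_mat)),
    alt = rep(sites$ALT, ncol(ad_mat)),
    sample = rep(colnames(ad_mat), each = nrow(sites)),
    ad = as.vector(ad_mat)
  ) |>
    tidyr::separate("ad", into = c("ref_count", "alt_count"),
                    sep = ",", fill = "right", convert = TRUE) |>
    dplyr::mutate(
      ref_count = dplyr::coalesce(as.integer(.data$ref_count), 0L),
      alt_count = dplyr::coalesce(as.integer(.data$alt_count), 0L),
      total_depth = .data$ref_count + .data$alt_count
    ) |>
    dplyr::select(-"ref_count")
  if (!is.null(region)) {
    out <- dplyr::filter(out, .data$chrom == region$chrom)
    if (!is.null(region$start)) out <- dplyr::filter(out, .data$pos >= region$start)
    if (!is.null(region$end)) out <- dplyr::filter(out, .data$pos <= region$end)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read or write a strain catalog as TSV
#'
#' The catalog format is a four-column TSV (`chrom`, `pos`, `ref`, `alt`),
#' with an optional header line.
#'
#' @param path File path.
#' @return For `read_catalog`, a catalog tibble sorted by (`chrom`, `pos`).
#' @export
read_catalog <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  cls <- c("character", "integer", "character", "character")
  df <- if (has_header) {
    utils::read.table(path, header = TRUE, sep = "\t", colClasses = cls)
  } else {
    utils::read.table(path, header = FALSE, sep = "\t", colClasses = cls,
                      col.names = c("chrom", "pos", "ref", "alt"))
  }
  names(df) <- c("chrom", "pos", "ref", "alt")
  out <- dplyr::arrange(tibble::as_tibble(df), .data$chrom, .data$pos)
  validate_catalog(out)
  out
}

#' @rdname read_catalog
#' @param catalog A catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog[, c("chrom", "pos", "ref", "alt")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_sorted_sites <- function(sites, what) {
  ok <- sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos))
  if (!all(ok$sorted)) {
    abort(paste0(what, " must be sorted by (chrom, pos)"))
  }
  invisible(TRUE)
}

#' Match called variants against a known-strain catalog
#'
#' A catalog site counts as rediscovered only when a called site matches
#' its chromosome, position, reference and alternate allele exactly --
#' allele identity, not mere position, is what makes the site
#' strain-informative. Called variants absent from the catalog are retained
#' and flagged, since they feed the germline/somatic classifier.
#'
#' @param sites Tibble of called sites (`chrom`, `pos`, `ref`, `alt`;
#'   duplicates from a long allele-depth table are tolerated), sorted by
#'   (`chrom`, `pos`).
#' @param catalog Catalog tibble, sorted likewise and non-empty.
#'
#' @return An object of class `catalog_match`: a list with `sites` (the
#'   distinct called sites plus a logical `in_catalog` column), `n_catalog`,
#'   `n_rediscovered` and `rediscovery_rate`. `glance()` returns the
#'   summary as a one-row tibble.
#' @export
match_catalog <- function(sites, catalog) {
  if (nrow(catalog) == 0L) abort("empty catalog: rediscovery rate undefined")
  sites <- dplyr::distinct(sites, .data$chrom, .data$pos, .data$ref, .data$alt)
  check_sorted_sites(sites, "called sites")
  check_sorted_sites(catalog, "catalog")
  key_sites <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  key_cat <- paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  in_catalog <- key_sites %in% key_cat
  n_re <- sum(key_cat %in% key_sites)
  structure(
    list(sites = dplyr::mutate(sites, in_catalog = in_catalog),
         n_catalog = nrow(catalog),
         n_rediscovered = n_re,
         rediscovery_rate = n_re / nrow(catalog)),
    class = "catalog_match"
  )
}

#' @export
print.catalog_match <- function(x, ...) {
  cat("Catalog match: ", x$n_rediscovered, "/", x$n_catalog,
      " catalog sites rediscovered (",
      sprintf("%.1f%%", 100 * x$rediscovery_rate), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.catalog_match <- function(x, ...) {
  tibble::tibble(n_catalog = x$n_catalog, n_rediscovered = x$n_rediscovered,
                 rediscovery_rate = x$rediscovery_rate)
}

#' @exportS3Method generics::tidy
tidy.catalog_match <- function(x, ...) x$sites
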