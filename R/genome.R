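#' Define a genome model for simulation
#'
#' A genome model lists the chromosomes over which F2 embryos are simulated,
#' with physical lengths (bp) and genetic map lengths (Morgans). The default
#' is a deliberately compact genome -- five 100 Mb chromosomes of one Morgan
#' each -- which keeps simulations fast while preserving the features that
#' matter downstream: multiple independently segregating chromosomes and
#' recombinant ancestry mosaics with segment sizes in the tens of megabases,
#' as seen in real inter-strain mouse crosses.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length_bp Positive integer vector of chromosome lengths in bp
#'   (recycled to `length(chrom)`).
#' @param map_length_morgans Positive numeric vector of genetic map lengths
#'   in Morgans (recycled likewise).
#'
#' @return A tibble with columns `chrom`, `length_bp`, `map_length_morgans`.
#' @examples
#' genome_model()
#' genome_model(c("chr1", "chrX"), c(2e8, 1.7e8), c(1.1, 0.9))
#' @export
genome_model <- function(chrom = paste0("chr", 1:5),
                         length_bp = 1e8,
                         map_length_morgans = 1) {
  if (anyDuplicated(chrom) > 0L) abort("chromosome names must be unique")
  g <- tibble::tibble(
    chrom = as.character(chrom),
    length_bp = as.numeric(length_bp),
    map_length_morgans = as.numeric(map_length_morgans)
  )
  if (any(g$length_bp <= 0) || any(is.na(g$length_bp))) {
    abort("chromosome lengths must be positive")
  }
  if (any(g$map_length_morgans < 0) || any(is.na(g$map_length_morgans))) {
    abort("map lengths must be non-negative")
  }
  g
}

#' Simulate a strain-informative variant catalog
#'
#' Draws biallelic SNV sites at which the two inbred parental strains carry
#' fixed, different alleles (the reference strain carries `ref`, the
#' alternate strain carries `alt`). These are the positions where the
#' variant allele fraction reads out local ancestry and copy state.
#' Positions are strictly increasing within each chromosome; the number of
#' sites per chromosome is proportional to its physical length.
#'
#' @param genome A [genome_model()] tibble.
#' @param n_sites Total number of catalog sites across the genome.
#' @param strain_name Label for the alternate strain.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt` sorted by
#'   (`chrom`, `pos`), with attribute `strain_name`.
#' @export
simulate_catalog <- function(genome, n_sites = 20000L, strain_name = "129S1",
                             seed = NULL) {
  stopifnot(n_sites > 0)
  with_seed(seed, {
    n_per <- pmax(1L, round(n_sites * genome$length_bp / sum(genome$length_bp)))
    bases <- c("A", "C", "G", "T")
    cat_tbl <- purrr::map2_dfr(genome$chrom, seq_len(nrow(genome)), function(ch, i) {
      n <- n_per[i]
      pos <- sort(sample.int(genome$length_bp[i], n, replace = FALSE))
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
      tibble::tibble(chrom = ch, pos = as.integer(pos), ref = ref,
                     alt = unname(alt))
    })
    attr(cat_tbl, "strain_name") <- strain_name
    cat_tbl
  })
}

validate_catalog <- function(catalog) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(catalog)))
  ok <- catalog |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos, strictly = TRUE))
  if (!all(ok$sorted)) abort("catalog positions must be strictly increasing per chromosome")
  if (any(catalog$ref == catalog$alt)) abort("catalog ref and alt alleles must differ")
  invisible(catalog)
}
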