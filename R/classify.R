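#' Configuration for the germline/somatic triage rule
#'
#' The triage rule works on per-site VAFs ranked across embryos: a variant
#' whose highest VAF is at most `vaf_min` is excluded as noise; otherwise,
#' if the second-highest VAF exceeds `second_to_max_ratio` times the
#' highest, the variant is shared across embryos and called
#' germline-or-false; else it is private to one embryo and called somatic.
#' Boundary semantics are strict on both thresholds: a top VAF of exactly
#' `vaf_min` is excluded ("above 0.05"), and a second VAF of exactly
#' `second_to_max_ratio * v1` is somatic ("more than 40%").
#'
#' The cluster parameters govern a follow-up filter: somatic calls that
#' pile up in a genomic window in a single embryo are almost always
#' residual germline haplotype variation, and are relabeled.
#'
#' @param vaf_min Exclusion threshold on the highest VAF (default 0.05).
#' @param second_to_max_ratio Germline sharing threshold on v2/v1
#'   (default 0.40).
#' @param cluster_window_bp Window within which same-carrier somatic calls
#'   count as a cluster (default 1 Mb).
#' @param cluster_min_count Minimum same-carrier calls in a window to form
#'   a cluster (default 3).
#'
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(vaf_min = 0.05, second_to_max_ratio = 0.40,
                              cluster_window_bp = 1e6, cluster_min_count = 3L) {
  stopifnot(vaf_min > 0, vaf_min < 1,
            second_to_max_ratio > 0, second_to_max_ratio < 1,
            cluster_window_bp > 0, cluster_min_count >= 2)
  structure(
    list(vaf_min = vaf_min, second_to_max_ratio = second_to_max_ratio,
         cluster_window_bp = cluster_window_bp,
         cluster_min_count = as.integer(cluster_min_count)),
    class = "classifier_config"
  )
}

#' Compute variant allele fractions from an allele-depth table
#'
#' `VAF = alt_count / total_depth`. A sample with zero depth at a site gets
#' VAF 0 and is flagged `missing`: the triage rule is stated purely on
#' VAFs, and absence of reads is treated as absence of the variant.
#'
#' @param ad Allele-depth tibble.
#' @return `ad` with added columns `vaf` and `missing`.
#' @export
vaf_matrix <- function(ad) {
  if (any(ad$alt_count > ad$total_depth)) {
    abort("alt_count exceeds total_depth; invalid allele-depth table")
  }
  dplyr::mutate(ad,
                vaf = ifelse(.data$total_depth > 0,
                             .data$alt_count / .data$total_depth, 0),
                missing = .data$total_depth == 0L)
}

#' Classify one site from its VAFs across embryos
#'
#' @param vafs Numeric vector of one site's VAFs across at least two
#'   samples.
#' @param cfg A [classifier_config()].
#' @return One of `"EXCLUDED"`, `"GERMLINE_OR_FALSE"`, `"SOMATIC"`.
#' @examples
#' classify_site(c(0.52, 0.48, 0, 0)) # shared -> germline or false
#' classify_site(c(0.30, 0.05, 0))    # private -> somatic
#' @export
classify_site <- function(vafs, cfg = classifier_config()) {
  if (length(vafs) < 2L) abort("classification needs VAFs from at least 2 samples")
  v <- sort(vafs, decreasing = TRUE)
  if (v[1] <= cfg$vaf_min) return("EXCLUDED")
  if (v[2] > cfg$second_to_max_ratio * v[1]) return("GERMLINE_OR_FALSE")
  "SOMATIC"
}

# Vectorized per-site rule over a summarised table with v1, v2.
rule_label <- function(v1, v2, cfg) {
  dplyr::case_when(
    v1 <= cfg$vaf_min ~ "EXCLUDED",
    v2 > cfg$second_to_max_ratio * v1 ~ "GERMLINE_OR_FALSE",
    TRUE ~ "SOMATIC"
  )
}

#' Relabel clusters of same-carrier somatic calls
#'
#' Somatic variants appearing in clusters in only one embryo are likely
#' germline haplotype variation missed by the sharing rule. Any run of at
#' least `cluster_min_count` somatic sites with the same single carrier
#' embryo whose positions fit inside `cluster_window_bp` is relabeled
#' `CLUSTER_REMOVED`; sites whose carrier is ambiguous (tied top VAF in
#' two embryos) are not "in only one embryo" and are never removed.
#'
#' @param sites Tibble with `chrom`, `pos`, `label`, `carrier_sample`
#'   (NA for ties), sorted by (`chrom`, `pos`).
#' @param cfg A [classifier_config()].
#' @return `sites` with qualifying `SOMATIC` labels replaced by
#'   `CLUSTER_REMOVED`.
#' @export
remove_single_embryo_clusters <- function(sites, cfg = classifier_config()) {
  check_sorted_sites(sites, "somatic sites")
  m <- cfg$cluster_min_count
  w <- cfg$cluster_window_bp
  sites$.row <- seq_len(nrow(sites))
  som <- sites[sites$label == "SOMATIC" & !is.na(sites$carrier_sample), ]
  removed <- logical(nrow(sites))
  if (nrow(som) > 0L) {
    grp <- split(som, paste(som$chrom, som$carrier_sample, sep = "\r"))
    for (g in grp) {
      k <- nrow(g)
      if (k < m) next
      p <- g$pos
      hit <- logical(k)
      for (j in seq_len(k - m + 1L)) {
        if (p[j + m - 1L] - p[j] < w) hit[j:(j + m - 1L)] <- TRUE
      }
      removed[g$.row[hit]] <- TRUE
    }
  }
  sites$label[removed] <- "CLUSTER_REMOVED"
  sites$.row <- NULL
  sites
}

#' Triage every variant site as germline-or-false, somatic, or excluded
#'
#' Runs the full per-site procedure over a multi-embryo allele-depth table:
#' known catalog sites are pre-labeled `GERMLINE_OR_FALSE` (they are known
#' strain germline variants and bypass the rule), remaining sites get the
#' ranked-VAF rule of [classify_site()], and somatic calls are then passed
#' through the single-embryo cluster filter. The result is a partition:
#' every site carries exactly one label.
#'
#' @param ad Allele-depth tibble covering at least two samples.
#' @param cfg A [classifier_config()].
#' @param catalog Optional strain catalog; matching sites (exact
#'   chrom/pos/ref/alt) are pre-labeled.
#'
#' @return A tibble of class `variant_classification` with one row per
#'   site: `chrom`, `pos`, `ref`, `alt`, `label`, `v1`, `v2`,
#'   `carrier_sample` (sample with the top VAF; NA on ties), and
#'   `in_catalog`. `glance()` returns the per-label counts.
#' @export
classify_all <- function(ad, cfg = classifier_config(), catalog = NULL) {
  if (length(unique(ad$sample)) < 2L) {
    abort("classification needs at least 2 samples")
  }
  v <- vaf_matrix(ad)
  per_site <- v |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      v1 = max(.data$vaf),
      v2 = sort(.data$vaf, decreasing = TRUE)[2],
      carrier_sample = if (sum(.data$vaf == max(.data$vaf)) == 1L) {
        .data$sample[which.max(.data$vaf)]
      } else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  per_site$in_catalog <- FALSE
  if (!is.null(catalog)) {
    key <- paste(per_site$chrom, per_site$pos, per_site$ref, per_site$alt)
    ckey <- paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
    per_site$in_catalog <- key %in% ckey
  }
  per_site$label <- rule_label(per_site$v1, per_site$v2, cfg)
  per_site$label[per_site$in_catalog] <- "GERMLINE_OR_FALSE"
  per_site <- remove_single_embryo_clusters(per_site, cfg)
  out <- per_site[, c("chrom", "pos", "ref", "alt", "label", "v1", "v2",
                      "carrier_sample", "in_catalog")]
  class(out) <- c("variant_classification", class(out))
  out
}

#' @exportS3Method generics::glance
glance.variant_classification <- function(x, ...) {
  lv <- c("EXCLUDED", "GERMLINE_OR_FALSE", "SOMATIC", "CLUSTER_REMOVED")
  counts <- table(factor(x$label, levels = lv))
  tibble::tibble(
    n_sites = nrow(x),
    n_excluded = unname(counts["EXCLUDED"]),
    n_germline_or_false = unname(counts["GERMLINE_OR_FALSE"]),
    n_somatic = unname(counts["SOMATIC"]),
    n_cluster_removed = unname(counts["CLUSTER_REMOVED"])
  )
}
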