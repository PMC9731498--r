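#' Three-state model for strain-origin segmentation
#'
#' At a strain-informative catalog site the read-level VAF is binomial with
#' a success probability set by the local genotype state: about `e` in
#' segments homozygous for the reference strain (only error reads carry the
#' alternate allele), 0.5 in heterozygous segments, and `1 - e` in segments
#' homozygous for the alternate strain. Between neighbouring sites the
#' state switches with probability `1 - (1 - t)^gap`, a per-base switch
#' rate that makes recombination breakpoints rare on the megabase scale.
#'
#' @param e Emission error rate (default 0.005); must be in `[0, 0.5)`.
#' @param t Per-base state-switch probability (default 1e-7).
#' @return A list of class `state_model`.
#' @export
state_model <- function(e = 0.005, t = 1e-7) {
  stopifnot(e >= 0, e < 0.5, t > 0, t < 1)
  structure(list(e = e, t = t,
                 p_emit = c(HOM_REF = e, HET = 0.5, HOM_ALT = 1 - e)),
            class = "state_model")
}

state_levels <- c("HOM_REF", "HET", "HOM_ALT")

# Viterbi decoding of one chromosome: alt/depth counts at increasing
# positions, binomial emissions, distance-scaled switch probability split
# evenly between the two other states. Returns the integer state path.
viterbi_chrom <- function(pos, alt, depth, model) {
  n <- length(pos)
  p_emit <- model$p_emit
  log_emit <- vapply(p_emit, function(p) dbinom(alt, depth, p, log = TRUE),
                     numeric(n))
  log_emit <- matrix(log_emit, nrow = n) # sites x 3
  log_emit[depth == 0L, ] <- 0 # uncovered sites are uninformative
  delta <- log(1 / 3) + log_emit[1L, ]
  back <- matrix(NA_integer_, n, 3L)
  if (n > 1L) {
    for (i in 2L:n) {
      gap <- max(pos[i] - pos[i - 1L], 1)
      log_stay <- gap * log1p(-model$t)
      switch_p <- -expm1(log_stay)
      log_switch <- log(pmax(switch_p / 2, .Machine$double.xmin))
      for (s in 1:3) {
        cand <- delta + ifelse(seq_len(3) == s, log_stay, log_switch)
        back[i, s] <- which.max(cand)
        log_emit[i, s] <- log_emit[i, s] + max(cand)
      }
      delta <- log_emit[i, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (i in n:2L) path[i - 1L] <- back[i, path[i]]
  }
  path
}

#' Segment one sample's catalog VAFs into strain-origin states
#'
#' Assigns each covered catalog site of one embryo to `HOM_REF`, `HET` or
#' `HOM_ALT` by most-probable-path decoding of the three-state model, then
#' merges consecutive same-state sites into half-open segments. The result
#' is the segment-level picture of the genome: long runs of homozygosity
#' for either strain and heterozygous runs in between.
#'
#' @param ad Allele-depth tibble for a single sample (or pass `sample` to
#'   select one from a multi-sample table), at catalog sites.
#' @param model A [state_model()].
#' @param sample Optional sample id to select.
#'
#' @return An object of class `state_track`: list with `sites` (tibble
#'   `chrom`, `pos`, `alt_count`, `total_depth`, `vaf`, `state`) and
#'   `segments` (tibble `chrom`, `start`, `end`, `state`, `n_sites`).
#'   `tidy()` returns the segments.
#' @export
assign_states <- function(ad, model = state_model(), sample = NULL) {
  if (!is.null(sample)) ad <- ad[ad$sample == sample, ]
  ids <- unique(ad$sample)
  if (length(ids) != 1L) {
    abort("assign_states expects a single sample; use `sample=` to select one")
  }
  ad <- dplyr::arrange(ad, .data$chrom, .data$pos)
  sites <- purrr::map_dfr(split(ad, ad$chrom), function(d) {
    if (nrow(d) < 2L) {
      warn(paste0("chromosome ", d$chrom[1],
                  " has fewer than 2 covered catalog sites"))
    }
    path <- viterbi_chrom(d$pos, d$alt_count, d$total_depth, model)
    dplyr::mutate(d, state = state_levels[path])
  })
  sites <- dplyr::mutate(sites,
                         vaf = ifelse(.data$total_depth > 0,
                                      .data$alt_count / .data$total_depth, NA_real_))
  segments <- sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(c(1L, diff(match(.data$state, state_levels)) != 0L))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos) + 1,
                     state = .data$state[1], n_sites = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$chrom, .data$start)
  structure(list(sample = ids,
                 sites = sites[, c("chrom", "pos", "alt_count",
                                   "total_depth", "vaf", "state")],
                 segments = segments),
            class = "state_track")
}

#' @export
print.state_track <- function(x, ...) {
  cat("Strain-origin state track for sample ", x$sample, ": ",
      nrow(x$sites), " sites, ", nrow(x$segments), " segments\n", sep = "")
  print(x$segments, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.state_track <- function(x, ...) x$segments

#' @exportS3Method generics::glance
glance.state_track <- function(x, ...) {
  tibble::tibble(sample = x$sample, n_sites = nrow(x$sites),
                 n_segments = nrow(x$segments),
                 frac_het = mean(x$sites$state == "HET"))
}

#' State track from the simulator's ancestry truth
#'
#' Converts an embryo's two true haplotype mosaics into the state track its
#' germline implies at catalog sites (BB -> `HOM_REF`, mixed -> `HET`,
#' SS -> `HOM_ALT`). This defines the heterozygous territory independently
#' of the embryo's own reads, which matters when clonal events (cell
#' fraction 1) have pushed heterozygous-site VAFs to 0 or 1: read-based
#' segmentation would no longer see those segments as heterozygous.
#'
#' @param hap1,hap2 Ancestry mosaics from [simulate_f1_gamete()] (the
#'   `hap1`/`hap2` list columns of a litter row).
#' @param catalog Strain catalog tibble.
#' @param sample Sample id recorded on the track.
#' @return A `state_track` whose `vaf` column is NA (no reads involved).
#' @export
ancestry_track <- function(hap1, hap2, catalog, sample = "truth") {
  s1 <- strain_at(hap1, catalog$chrom, catalog$pos)
  s2 <- strain_at(hap2, catalog$chrom, catalog$pos)
  state <- dplyr::case_when(
    s1 == "B" & s2 == "B" ~ "HOM_REF",
    s1 == "S" & s2 == "S" ~ "HOM_ALT",
    TRUE ~ "HET"
  )
  sites <- tibble::tibble(chrom = catalog$chrom, pos = catalog$pos,
                          alt_count = NA_integer_, total_depth = NA_integer_,
                          vaf = NA_real_, state = state)
  segments <- sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(c(1L, diff(match(.data$state, state_levels)) != 0L))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos) + 1,
                     state = .data$state[1], n_sites = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select(-"run")
  structure(list(sample = sample, sites = sites, segments = segments),
            class = "state_track")
}

#' Score allelic imbalance over heterozygous territory
#'
#' The readout of genomic instability: over catalog sites assigned `HET`
#' and covered to at least `min_depth`, the mean absolute deviation of VAF
#' from 0.5 (`mad_score`, in `[0, 0.5]`) and the fraction of sites whose
#' VAF falls outside `[0.5 - delta, 0.5 + delta]` (`outlier_fraction`).
#' A balanced euploid genome keeps both near their binomial-sampling
#' baseline; copy-neutral LOH, deletions and chromosome gains inflate them.
#'
#' @param ad Allele-depth tibble for the scored sample (single sample, or
#'   pass `sample`).
#' @param track A `state_track` defining the HET territory -- either
#'   [assign_states()] output or, in simulations with clonal events,
#'   [ancestry_track()] truth.
#' @param min_depth Minimum depth for a site to be scored (default 10).
#' @param delta Half-width of the balanced band for `outlier_fraction`
#'   (default 0.15).
#' @param sample Optional sample id to select from `ad`.
#'
#' @return An object of class `instability_report`: list with `overall`
#'   (one-row tibble: `sample`, `n_het_sites`, `mad_score`,
#'   `outlier_fraction`) and `by_chrom` (the same per chromosome).
#'   Zero qualifying sites yields NA scores with a warning. `glance()`
#'   returns `overall`; `tidy()` returns `by_chrom`.
#' @export
instability_score <- function(ad, track, min_depth = 10, delta = 0.15,
                              sample = NULL) {
  stopifnot(min_depth >= 1, delta > 0, delta < 0.5)
  if (!is.null(sample)) ad <- ad[ad$sample == sample, ]
  ids <- unique(ad$sample)
  if (length(ids) != 1L) abort("instability_score expects a single sample")
  het <- track$sites[track$sites$state == "HET", c("chrom", "pos")]
  d <- dplyr::inner_join(ad, het, by = c("chrom", "pos")) |>
    dplyr::filter(.data$total_depth >= min_depth) |>
    dplyr::mutate(vaf = .data$alt_count / .data$total_depth,
                  dev = abs(.data$vaf - 0.5))
  if (nrow(d) == 0L) {
    warn("no heterozygous sites meet the depth threshold; scores undefined")
    overall <- tibble::tibble(sample = ids, n_het_sites = 0L,
                              mad_score = NA_real_, outlier_fraction = NA_real_)
    by_chrom <- overall[0, ]
  } else {
    overall <- tibble::tibble(
      sample = ids, n_het_sites = nrow(d),
      mad_score = mean(d$dev),
      outlier_fraction = mean(d$dev > delta)
    )
    by_chrom <- d |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(sample = ids, n_het_sites = dplyr::n(),
                       mad_score = mean(.data$dev),
                       outlier_fraction = mean(.data$dev > delta),
                       .groups = "drop")
  }
  structure(list(overall = overall, by_chrom = by_chrom,
                 min_depth = min_depth, delta = delta),
            class = "instability_report")
}

#' @export
print.instability_report <- function(x, ...) {
  cat("Allelic-imbalance report (min depth ", x$min_depth,
      ", balanced band +/-", x$delta, ")\n", sep = "")
  print(x$overall, ...)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.instability_report <- function(x, ...) x$overall

#' @exportS3Method generics::tidy
tidy.instability_report <- function(x, ...) x$by_chrom

#' Histogram density of VAFs on the unit interval
#'
#' @param vafs Numeric vector of VAFs in `[0, 1]`; must be non-empty.
#' @param n_bins Number of equal-width bins.
#' @return A tibble with `bin_low`, `bin_high`, `mid`, `density`; the
#'   Riemann sum of `density` times bin width is 1.
#' @export
vaf_density <- function(vafs, n_bins = 40L) {
  if (length(vafs) == 0L) abort("cannot compute a density from no VAFs")
  if (any(vafs < 0 | vafs > 1, na.rm = TRUE)) abort("VAFs must lie in [0, 1]")
  vafs <- vafs[!is.na(vafs)]
  edges <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(vafs, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  width <- 1 / n_bins
  tibble::tibble(bin_low = edges[-length(edges)], bin_high = edges[-1L],
                 mid = (edges[-1L] + edges[-length(edges)]) / 2,
                 density = counts / (sum(counts) * width))
}
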