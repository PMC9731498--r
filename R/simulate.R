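#' Simulation configuration for the synthetic F2 cross
#'
#' Bundles every tunable of the read-count simulator. Defaults emulate the
#' design under study: exome sequencing at mean depth 80x, a small base
#' error rate, Poisson depth (set `depth_dispersion > 0` for a
#' negative-binomial law), and two unlinked knockout loci segregating in a
#' double-heterozygote intercross with half of the double knockouts dying
#' between midgestation and weaning.
#'
#' @param mean_depth Mean sequencing depth at a diploid site.
#' @param depth_dispersion Overdispersion of depth; 0 gives Poisson depth,
#'   a value k > 0 gives negative binomial with variance mu + k * mu^2.
#' @param base_error_rate Per-read probability of reading the wrong allele,
#'   in `[0, 0.5)`.
#' @param lethality Named numeric vector of death probabilities applied
#'   after embryonic day E12.5, keyed by two-locus genotype written as
#'   `"<fancd2> <smad3>"` with each locus one of `+/+`, `+/-`, `-/-`.
#'   Genotypes not named survive. The default kills half of the double
#'   knockouts, reproducing the halving of weaned double knockouts relative
#'   to the midgestation Mendelian ratio.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mean_depth = 80,
                       depth_dispersion = 0,
                       base_error_rate = 0.001,
                       lethality = c("-/- -/-" = 0.5)) {
  stopifnot(mean_depth > 0, depth_dispersion >= 0,
            base_error_rate >= 0, base_error_rate < 0.5)
  if (length(lethality) && (any(lethality < 0) || any(lethality > 1))) {
    abort("lethality probabilities must lie in [0, 1]")
  }
  structure(
    list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
         base_error_rate = base_error_rate, lethality = lethality),
    class = "sim_config"
  )
}

#' Simulate one recombinant F1 gamete
#'
#' An F1 hybrid carries one full chromosome from each inbred strain, so a
#' gamete is an alternating mosaic of the two parental haplotypes. Crossover
#' counts per chromosome are Poisson with mean equal to the genetic map
#' length in Morgans, breakpoint positions are uniform, and the strain at
#' the start of each chromosome is a fair coin; no crossover interference
#' is modelled.
#'
#' @param genome A [genome_model()] tibble.
#' @param seed Optional integer seed.
#'
#' @return A tibble of half-open ancestry segments with columns `chrom`,
#'   `start`, `end`, `strain` (`"B"` for the reference strain, `"S"` for the
#'   alternate strain), tiling `[1, length_bp + 1)` on every chromosome.
#' @examples
#' simulate_f1_gamete(genome_model(), seed = 1)
#' @export
simulate_f1_gamete <- function(genome, seed = NULL) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(genome)), function(i) {
      len <- genome$length_bp[i]
      n_break <- rpois(1L, genome$map_length_morgans[i])
      breaks <- sort(unique(ceiling(runif(n_break, 1, len))))
      breaks <- breaks[breaks > 1 & breaks <= len]
      bounds <- c(1, breaks, len + 1)
      first <- sample(c("B", "S"), 1L)
      strains <- rep(c(first, setdiff(c("B", "S"), first)),
                     length.out = length(bounds) - 1L)
      tibble::tibble(chrom = genome$chrom[i],
                     start = bounds[-length(bounds)],
                     end = bounds[-1L],
                     strain = strains)
    })
  })
}

#' Simulate a litter of F2 embryos
#'
#' Each embryo inherits two independent F1 gametes (its maternal and
#' paternal recombinant haplotypes) and, independently, a genotype at each
#' of two unlinked knockout loci (Fancd2 and Smad3) with Mendelian
#' probabilities 1/4 : 1/2 : 1/4 for `-/-` : `+/-` : `+/+`. All embryos are
#' alive at E12.5; survival to weaning is Bernoulli with the
#' genotype-specific lethality from the configuration.
#'
#' @param genome A [genome_model()] tibble.
#' @param n_embryos Number of embryos to simulate.
#' @param config A [sim_config()].
#' @param seed Integer seed; gamete draws and genotype/survival draws use
#'   named substreams of it, so they are independently reproducible.
#' @param prefix Sample-name prefix for embryo ids.
#' @param haplotypes If `FALSE`, skip simulating ancestry mosaics (the
#'   `hap1`/`hap2` columns are NULL). Useful for large breeding-statistics
#'   litters where only the locus genotypes matter.
#'
#' @return A tibble with one row per embryo: `id`, `fancd2`, `smad3`,
#'   `genotype` (two-locus string), `alive_e12`, `alive_weaned`, list
#'   columns `hap1` and `hap2` (ancestry mosaics), and `events` (an empty
#'   instability-event tibble to be filled by [simulate_instability_events()]
#'   or [add_instability_event()]).
#' @export
simulate_litter <- function(genome, n_embryos, config = sim_config(),
                            seed = NULL, prefix = "embryo",
                            haplotypes = TRUE) {
  stopifnot(n_embryos > 0)
  gam_seed <- if (is.null(seed)) NULL else substream_seed(seed, "gametes")
  lit_seed <- if (is.null(seed)) NULL else substream_seed(seed, "litters")
  haps <- if (haplotypes) {
    with_seed(gam_seed, {
      purrr::map(seq_len(2L * n_embryos), function(i) simulate_f1_gamete(genome))
    })
  } else NULL
  with_seed(lit_seed, {
    geno_levels <- c("+/+", "+/-", "-/-")
    fancd2 <- sample(geno_levels, n_embryos, replace = TRUE, prob = c(1, 2, 1) / 4)
    smad3 <- sample(geno_levels, n_embryos, replace = TRUE, prob = c(1, 2, 1) / 4)
    genotype <- paste(fancd2, smad3)
    death_p <- unname(ifelse(genotype %in% names(config$lethality),
                             config$lethality[genotype], 0))
    alive_weaned <- runif(n_embryos) >= death_p
    tibble::tibble(
      id = sprintf("%s%02d", prefix, seq_len(n_embryos)),
      fancd2 = fancd2, smad3 = smad3, genotype = genotype,
      alive_e12 = TRUE, alive_weaned = alive_weaned,
      hap1 = if (haplotypes) haps[seq(1L, by = 2L, length.out = n_embryos)] else list(NULL),
      hap2 = if (haplotypes) haps[seq(2L, by = 2L, length.out = n_embryos)] else list(NULL),
      events = purrr::map(seq_len(n_embryos), function(i) empty_events())
    )
  })
}

empty_events <- function() {
  tibble::tibble(kind = character(), chrom = character(),
                 start = numeric(), end = numeric(),
                 retained_haplotype = character(), cell_fraction = numeric())
}

event_kinds <- c("CN_LOH", "DELETION", "DUPLICATION", "CHR_GAIN", "CHR_LOSS")

#' Attach an instability event to one embryo of a litter
#'
#' Events model clonal or mosaic genomic lesions arising in utero:
#' copy-neutral loss of heterozygosity (`CN_LOH`), focal `DELETION` or
#' `DUPLICATION`, and whole-chromosome `CHR_GAIN` / `CHR_LOSS`.
#' `retained_haplotype` names the parental haplotype that is retained
#' (`CN_LOH`, `DELETION`, `CHR_LOSS`) or gained (`DUPLICATION`, `CHR_GAIN`);
#' `cell_fraction` is the fraction of cells carrying the lesion, mixing
#' linearly into expected allele copy numbers under the bulk-sequencing
#' assumption.
#'
#' @param litter A litter tibble from [simulate_litter()].
#' @param id Embryo id to modify.
#' @param kind One of `"CN_LOH"`, `"DELETION"`, `"DUPLICATION"`,
#'   `"CHR_GAIN"`, `"CHR_LOSS"`.
#' @param chrom,start,end Half-open genomic interval of the event; for
#'   whole-chromosome kinds pass the full chromosome span.
#' @param retained_haplotype `"B"` or `"S"`.
#' @param cell_fraction In `(0, 1]`.
#'
#' @return The litter with the event appended to that embryo's `events`.
#' @export
add_instability_event <- function(litter, id, kind, chrom, start, end,
                                  retained_haplotype = "S",
                                  cell_fraction = 1) {
  kind <- match.arg(kind, event_kinds)
  stopifnot(end > start, cell_fraction > 0, cell_fraction <= 1,
            retained_haplotype %in% c("B", "S"))
  i <- match(id, litter$id)
  if (is.na(i)) abort(paste0("no embryo with id ", id))
  ev <- tibble::tibble(kind = kind, chrom = chrom, start = start, end = end,
                       retained_haplotype = retained_haplotype,
                       cell_fraction = cell_fraction)
  litter$events[[i]] <- dplyr::bind_rows(litter$events[[i]], ev)
  litter
}

#' Simulate genotype-dependent instability events
#'
#' Draws a Poisson number of lesions per embryo with a mean that depends on
#' its two-locus genotype, emulating the elevated genomic instability of
#' repair-deficient embryos. Event intervals cover a random fraction of a
#' random chromosome; kinds are drawn uniformly from `kinds`.
#'
#' @param litter A litter tibble.
#' @param genome The [genome_model()] used to simulate it.
#' @param rate_by_genotype Named numeric vector: mean number of events keyed
#'   by two-locus genotype (as in [sim_config()]'s `lethality`); unnamed
#'   genotypes get 0. The default gives Fancd2-null embryos (single or
#'   double knockout) two expected lesions each.
#' @param kinds Event kinds to draw from.
#' @param cell_fraction Cell fraction of every drawn event.
#' @param span_range Fraction of the chromosome covered by a focal event,
#'   drawn uniformly from this range.
#' @param seed Optional integer seed.
#'
#' @return The litter with `events` filled in.
#' @export
simulate_instability_events <- function(litter, genome,
                                        rate_by_genotype = c("-/- +/+" = 2, "-/- +/-" = 2,
                                                             "-/- -/-" = 4),
                                        kinds = event_kinds,
                                        cell_fraction = 1,
                                        span_range = c(0.2, 0.5),
                                        seed = NULL) {
  with_seed(seed, {
    for (i in seq_len(nrow(litter))) {
      lambda <- ifelse(litter$genotype[i] %in% names(rate_by_genotype),
                       rate_by_genotype[litter$genotype[i]], 0)
      n_ev <- rpois(1L, unname(lambda))
      if (n_ev == 0L) next
      for (k in seq_len(n_ev)) {
        ci <- sample.int(nrow(genome), 1L)
        len <- genome$length_bp[ci]
        kind <- sample(kinds, 1L)
        if (kind %in% c("CHR_GAIN", "CHR_LOSS")) {
          start <- 1; end <- len + 1
        } else {
          span <- runif(1L, span_range[1], span_range[2]) * len
          start <- ceiling(runif(1L, 1, len - span))
          end <- start + ceiling(span)
        }
        litter <- add_instability_event(
          litter, litter$id[i], kind, genome$chrom[ci], start, end,
          retained_haplotype = sample(c("B", "S"), 1L),
          cell_fraction = cell_fraction
        )
      }
    }
    litter
  })
}

# Strain carried by a mosaic haplotype at given positions of one chromosome.
strain_at <- function(hap, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    seg <- hap[hap$chrom == ch, ]
    sel <- chrom == ch
    if (nrow(seg) == 0L) abort(paste0("haplotype has no segments on ", ch))
    idx <- findInterval(pos[sel], seg$start)
    out[sel] <- seg$strain[idx]
  }
  out
}

# Expected per-strain allele copy numbers at sites, after applying the
# embryo's instability events with linear cell-fraction mixing. `sites`
# needs chrom, pos; hap1/hap2 are ancestry mosaics. Returns sites with
# n_ref (reference-strain copies), n_alt (alternate-strain copies).
site_copy_numbers <- function(sites, hap1, hap2, events = NULL) {
  s1 <- strain_at(hap1, sites$chrom, sites$pos)
  s2 <- strain_at(hap2, sites$chrom, sites$pos)
  n_ref <- (s1 == "B") + (s2 == "B")
  n_alt <- (s1 == "S") + (s2 == "S")
  if (!is.null(events) && nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      hit <- sites$chrom == ev$chrom & sites$pos >= ev$start & sites$pos < ev$end
      if (!any(hit)) next
      upd <- apply_event(n_ref[hit], n_alt[hit], ev$kind, ev$retained_haplotype)
      cf <- ev$cell_fraction
      n_ref[hit] <- (1 - cf) * n_ref[hit] + cf * upd$n_ref
      n_alt[hit] <- (1 - cf) * n_alt[hit] + cf * upd$n_alt
    }
  }
  dplyr::mutate(sites, n_ref = n_ref, n_alt = n_alt)
}

# Copy-number transform of one event on the affected cell population.
# Retained/gained haplotype is identified by strain; in regions homozygous
# for the other strain the dosage change still applies to the resident
# haplotype (a deletion removes a copy whatever its ancestry), while CN-LOH
# is a no-op there (already homozygous, copy neutral).
apply_event <- function(n_ref, n_alt, kind, retained) {
  tot <- n_ref + n_alt
  r_is_alt <- retained == "S"
  ret <- if (r_is_alt) n_alt else n_ref
  oth <- if (r_is_alt) n_ref else n_alt
  switch(kind,
    CN_LOH = {
      new_ret <- ifelse(ret > 0, tot, ret)
      new_oth <- ifelse(ret > 0, 0, oth)
    },
    DELETION = ,
    CHR_LOSS = {
      # fractional copy numbers arise from earlier mosaic events; a
      # deletion removes at most what is there
      new_oth <- ifelse(oth > 0, pmax(oth - 1, 0), oth)
      new_ret <- ifelse(oth > 0, ret, pmax(ret - 1, 0))
    },
    DUPLICATION = ,
    CHR_GAIN = {
      new_ret <- ifelse(ret > 0, ret + 1, ret)
      new_oth <- ifelse(ret > 0, oth, ifelse(oth > 0, oth + 1, oth))
    },
    abort(paste0("unknown event kind ", kind))
  )
  if (r_is_alt) list(n_ref = new_oth, n_alt = new_ret)
  else list(n_ref = new_ret, n_alt = new_oth)
}

#' Expected variant allele fraction at a site
#'
#' Computes the expected VAF of the alternate-strain allele given a germline
#' diplotype, any overlapping instability events, and a per-read base error
#' rate `e`. Copy numbers of the two parental alleles are mixed linearly
#' across the event cell fractions, then
#' `VAF = (alt_copies * (1 - e) + ref_copies * e) / (alt_copies + ref_copies)`.
#' A balanced heterozygote returns exactly 0.5 for any `e`, because the
#' error contributions of the two alleles cancel.
#'
#' @param diplotype One of `"BB"`, `"BS"`, `"SS"` (`B` reference strain,
#'   `S` alternate strain).
#' @param events Optional event tibble (see [add_instability_event()]); all
#'   rows are assumed to overlap the site.
#' @param e Base error rate in `[0, 0.5)`.
#'
#' @return Expected VAF in `[0, 1]`, or `NA` if all copies are lost
#'   (homozygous deletion: the site has no coverage).
#' @examples
#' expected_vaf("BS") # 0.5
#' @export
expected_vaf <- function(diplotype, events = NULL, e = 0) {
  stopifnot(diplotype %in% c("BB", "BS", "SB", "SS"))
  n_ref <- sum(strsplit(diplotype, "")[[1]] == "B")
  n_alt <- 2 - n_ref
  if (!is.null(events) && nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      upd <- apply_event(n_ref, n_alt, ev$kind, ev$retained_haplotype)
      cf <- ev$cell_fraction
      n_ref <- (1 - cf) * n_ref + cf * upd$n_ref
      n_alt <- (1 - cf) * n_alt + cf * upd$n_alt
    }
  }
  tot <- n_ref + n_alt
  if (tot == 0) return(NA_real_)
  (n_alt * (1 - e) + n_ref * e) / tot
}

#' Sample sequencing read counts for a litter
#'
#' For every embryo alive at the sampling stage and every catalog site,
#' draws a total depth from a Poisson law (negative binomial if
#' `depth_dispersion > 0`) with mean `mean_depth * total_copies / 2`, then
#' an alternate-allele count from `Binomial(depth, expected VAF)`. Sites
#' where all copies are lost get depth 0.
#'
#' @param litter A litter tibble (with any events attached).
#' @param catalog A strain catalog tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param config A [sim_config()].
#' @param seed Integer seed (read sampling uses the `"reads"` substream).
#' @param stage Survival column gating which embryos are sequenced.
#'
#' @return A long allele-depth tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `sample`, `alt_count`, `total_depth` -- the substrate of all
#'   VAF computation downstream.
#' @export
sample_reads <- function(litter, catalog, config = sim_config(), seed = NULL,
                         stage = "alive_e12") {
  validate_catalog(catalog)
  alive <- litter[litter[[stage]], , drop = FALSE]
  if (nrow(alive) == 0L) abort("no embryos alive at the sampling stage")
  read_seed <- if (is.null(seed)) NULL else substream_seed(seed, "reads")
  with_seed(read_seed, {
    purrr::map_dfr(seq_len(nrow(alive)), function(i) {
      st <- site_copy_numbers(catalog[, c("chrom", "pos")],
                              alive$hap1[[i]], alive$hap2[[i]],
                              alive$events[[i]])
      tot <- st$n_ref + st$n_alt
      e <- config$base_error_rate
      vaf <- ifelse(tot > 0, (st$n_alt * (1 - e) + st$n_ref * e) / pmax(tot, 1), 0)
      mu <- config$mean_depth * tot / 2
      depth <- if (config$depth_dispersion > 0) {
        rnbinom(nrow(st), mu = mu, size = 1 / config$depth_dispersion)
      } else {
        rpois(nrow(st), mu)
      }
      depth[tot == 0] <- 0L
      alt_count <- rbinom(nrow(st), depth, vaf)
      tibble::tibble(chrom = catalog$chrom, pos = catalog$pos,
                     ref = catalog$ref, alt = catalog$alt,
                     sample = alive$id[i],
                     alt_count = as.integer(alt_count),
                     total_depth = as.integer(depth))
    })
  })
}

#' Spike private somatic variants into an allele-depth table
#'
#' Adds `n_per_sample` somatic SNVs per embryo at positions absent from the
#' existing site list. Each somatic variant is private to one carrier
#' embryo, with expected VAF drawn uniformly from `vaf_range` (subclonal
#' lesions in a bulk sample); non-carrier embryos see only base error.
#'
#' @param ad Allele-depth tibble from [sample_reads()].
#' @param genome The [genome_model()].
#' @param config A [sim_config()].
#' @param n_per_sample Somatic variants per embryo.
#' @param vaf_range Range of true somatic VAFs.
#' @param seed Optional integer seed.
#'
#' @return A list with `ad` (the augmented table, sorted by chrom/pos) and
#'   `truth` (tibble of spiked sites: `chrom`, `pos`, `ref`, `alt`,
#'   `carrier`, `true_vaf`).
#' @export
add_somatic_variants <- function(ad, genome, config = sim_config(),
                                 n_per_sample = 20, vaf_range = c(0.2, 0.4),
                                 seed = NULL) {
  samples <- unique(ad$sample)
  used <- unique(paste(ad$chrom, ad$pos))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    n_tot <- n_per_sample * length(samples)
    ci <- sample.int(nrow(genome), 4L * n_tot, replace = TRUE)
    pos <- ceiling(runif(4L * n_tot, 1, genome$length_bp[ci]))
    keep <- !(paste(genome$chrom[ci], pos) %in% used) &
      !duplicated(paste(genome$chrom[ci], pos))
    if (sum(keep) < n_tot) abort("could not place somatic variants at free positions")
    ci <- ci[keep][seq_len(n_tot)]
    pos <- pos[keep][seq_len(n_tot)]
    ref <- sample(bases, n_tot, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    truth <- tibble::tibble(
      chrom = genome$chrom[ci], pos = as.integer(pos), ref = ref,
      alt = unname(alt),
      carrier = rep(samples, each = n_per_sample),
      true_vaf = runif(n_tot, vaf_range[1], vaf_range[2])
    )
    rows <- tidyr::crossing(truth, sample = samples)
    depth <- rpois(nrow(rows), config$mean_depth)
    p <- ifelse(rows$sample == rows$carrier, rows$true_vaf,
                config$base_error_rate)
    rows$alt_count <- as.integer(rbinom(nrow(rows), depth, p))
    rows$total_depth <- as.integer(depth)
    out <- dplyr::bind_rows(
      ad, rows[, c("chrom", "pos", "ref", "alt", "sample",
                   "alt_count", "total_depth")]
    ) |>
      dplyr::arrange(.data$chrom, .data$pos, .data$sample)
    list(ad = out, truth = dplyr::arrange(truth, .data$chrom, .data$pos))
  })
}
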