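# Exhaustive most-probable-path search over all 3^n state sequences,
# mirroring the model's emission and distance-scaled transition laws.
brute_force_path <- function(pos, alt, depth, model) {
  n <- length(pos)
  states <- 1:3
  p_emit <- model$p_emit
  grid <- as.matrix(expand.grid(rep(list(states), n)))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    ll <- log(1 / 3)
    for (i in seq_len(n)) {
      if (depth[i] > 0) {
        ll <- ll + dbinom(alt[i], depth[i], p_emit[path[i]], log = TRUE)
      }
      if (i > 1) {
        gap <- max(pos[i] - pos[i - 1], 1)
        stay <- (1 - model$t)^gap
        ll <- ll + if (path[i] == path[i - 1]) log(stay) else log((1 - stay) / 2)
      }
    }
    if (ll > best) {
      best <- ll
      best_path <- path
    }
  }
  best_path
}

ad_one_sample <- function(pos, alt_n, depth_n, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
                 sample = "s1", alt_count = as.integer(alt_n),
                 total_depth = as.integer(depth_n))
}

test_that("dynamic programming equals exhaustive path search on small inputs", {
  model <- state_model()
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    pos <- sort(sample(1:1e7, n))
    truth_p <- sample(c(0.02, 0.5, 0.98), n, replace = TRUE)
    depth <- rpois(n, 30)
    alt <- rbinom(n, depth, truth_p)
    dp <- hybridscar:::viterbi_chrom(pos, alt, depth, model)
    bf <- brute_force_path(pos, alt, depth, model)
    expect_equal(dp, unname(bf))
  }
})

test_that("emission dominance drives obvious state calls", {
  pos <- (1:50) * 1e5
  track <- assign_states(ad_one_sample(pos, rep(50, 50), rep(100, 50)))
  expect_true(all(track$sites$state == "HET"))
  expect_equal(nrow(track$segments), 1L) # single HET segment

  track <- assign_states(ad_one_sample(pos, rep(0, 50), rep(100, 50)))
  expect_true(all(track$sites$state == "HOM_REF"))
})

test_that("segmentation recovers simulated ancestry and breakpoints", {
  g <- genome_model(paste0("chr", 1:4), 1e8, 1)
  catalog <- simulate_catalog(g, 8000, seed = 33)
  cfg <- sim_config(mean_depth = 80)
  litter <- simulate_litter(g, 1, cfg, seed = 33)
  ad <- sample_reads(litter, catalog, cfg, seed = 33)
  track <- assign_states(ad)
  truth <- ancestry_track(litter$hap1[[1]], litter$hap2[[1]], catalog)

  agree <- mean(track$sites$state ==
                  truth$sites$state[match(paste(track$sites$chrom, track$sites$pos),
                                          paste(truth$sites$chrom, truth$sites$pos))])
  expect_gte(agree, 0.99)

  # every true breakpoint is recovered within 2 catalog sites
  for (ch in unique(truth$segments$chrom)) {
    true_bp <- truth$segments$start[truth$segments$chrom == ch][-1]
    call_bp <- track$segments$start[track$segments$chrom == ch][-1]
    cat_pos <- sort(catalog$pos[catalog$chrom == ch])
    for (bp in true_bp) {
      idx_true <- findInterval(bp - 1, cat_pos)
      idx_call <- findInterval(call_bp - 1, cat_pos)
      expect_true(any(abs(idx_call - idx_true) <= 2))
    }
  }
})

test_that("instability scores hit their analytic extremes", {
  pos <- (1:30) * 1e5
  ad <- ad_one_sample(pos, rep(20, 30), rep(40, 30))
  track <- assign_states(ad)
  rep0 <- instability_score(ad, track)
  expect_equal(glance(rep0)$mad_score, 0) # all VAFs exactly 0.5

  # all qualifying VAFs at 1.0 attain the 0.5 bound (HET track from truth)
  ad1 <- ad_one_sample(pos, rep(40, 30), rep(40, 30))
  rep1 <- instability_score(ad1, track)
  expect_equal(glance(rep1)$mad_score, 0.5)
  expect_equal(glance(rep1)$outlier_fraction, 1)
})

test_that("scores are undefined without qualifying sites", {
  pos <- (1:5) * 1e5
  ad <- ad_one_sample(pos, rep(2, 5), rep(5, 5)) # depth below min_depth
  track <- assign_states(ad)
  expect_warning(r <- instability_score(ad, track, min_depth = 10), "undefined|depth")
  expect_true(is.na(glance(r)$mad_score))
})

test_that("euploid mad_score matches the exact binomial expectation", {
  d <- 80
  g <- genome_model("chr1", 1e8, 0)
  catalog <- simulate_catalog(g, 10000, seed = 41)
  cfg <- sim_config(mean_depth = d, base_error_rate = 0)
  litter <- simulate_litter(g, 1, cfg, seed = 41)
  litter$hap1[[1]]$strain <- "B"
  litter$hap2[[1]]$strain <- "S"
  ad <- sample_reads(litter, catalog, cfg, seed = 41)
  track <- assign_states(ad)
  rep <- instability_score(ad, track, min_depth = 1)
  scored <- dplyr::filter(ad, total_depth >= 1)
  expected <- mean(vapply(scored$total_depth, expected_abs_dev, numeric(1)))
  dev <- abs(scored$alt_count / scored$total_depth - 0.5)
  se <- stats::sd(dev) / sqrt(length(dev))
  expect_lt(abs(glance(rep)$mad_score - expected), 3 * se)
})

test_that("mad_score is invariant under strain relabeling", {
  set.seed(51)
  pos <- (1:200) * 1e5
  depth <- rpois(200, 60)
  alt <- rbinom(200, depth, 0.5)
  ad <- ad_one_sample(pos, alt, depth)
  flipped <- dplyr::mutate(ad, alt_count = total_depth - alt_count)
  track <- assign_states(ad)
  s1 <- glance(instability_score(ad, track))$mad_score
  s2 <- glance(instability_score(flipped, track))$mad_score
  expect_equal(s1, s2)
})

test_that("clonal CN-LOH inflates mad_score over the truth-defined territory", {
  g <- genome_model(paste0("chr", 1:3), 1e8, 1)
  catalog <- simulate_catalog(g, 6000, seed = 61)
  cfg <- sim_config(mean_depth = 80)
  wins <- 0L
  for (rep in 1:20) {
    litter <- simulate_litter(g, 2, cfg, seed = 1000 + rep)
    # engineer fully heterozygous genomes so the event hits het territory
    for (i in 1:2) {
      litter$hap1[[i]]$strain <- "B"
      litter$hap2[[i]]$strain <- "S"
    }
    # clonal CN-LOH over ~30% of embryo 1's genome (one full chromosome)
    litter <- add_instability_event(litter, "embryo01", "CN_LOH",
                                    "chr2", 1, 1e8 + 1,
                                    retained_haplotype = "S", cell_fraction = 1)
    ad <- sample_reads(litter, catalog, cfg, seed = 2000 + rep)
    t1 <- ancestry_track(litter$hap1[[1]], litter$hap2[[1]], catalog)
    t2 <- ancestry_track(litter$hap1[[2]], litter$hap2[[2]], catalog)
    s_aff <- glance(instability_score(ad[ad$sample == "embryo01", ], t1))$mad_score
    s_eu <- glance(instability_score(ad[ad$sample == "embryo02", ], t2))$mad_score
    if (s_aff > s_eu) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("vaf_density integrates to one with mass where the data sit", {
  set.seed(71)
  vafs <- rbinom(10000, 80, 0.5) / 80
  d <- vaf_density(vafs, n_bins = 40)
  width <- d$bin_high[1] - d$bin_low[1]
  expect_equal(sum(d$density) * width, 1)
  expect_true(d$mid[which.max(d$density)] > 0.45 &&
                d$mid[which.max(d$density)] < 0.55)

  d2 <- vaf_density(rep(0.25, 10), n_bins = 20)
  expect_equal(sum(d2$density > 0), 1L)

  for (n in c(10, 100)) {
    d3 <- vaf_density(runif(n), n_bins = 17)
    expect_equal(sum(d3$density) / 17, 1)
  }
  expect_error(vaf_density(numeric(0)), "no VAFs")
})
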