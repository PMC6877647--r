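test_that("simulation is fully reproducible from the seed", {
  p <- small_sim(seed = 99L)
  s1 <- simulate_transcriptome(p)
  s2 <- simulate_transcriptome(p)
  expect_identical(s1, s2)
  t1 <- simulate_merip_tracks(s1$txs, s1$truth, p, "ctrl", 1)
  t2 <- simulate_merip_tracks(s2$txs, s2$truth, p, "ctrl", 1)
  expect_identical(t1, t2)
  r1 <- simulate_ribo_track(s1$txs, s1$truth, p, "kd")
  r2 <- simulate_ribo_track(s2$txs, s2$truth, p, "kd")
  expect_identical(r1, r2)
  x1 <- simulate_reactivity(s1$txs, s1$truth, p)
  x2 <- simulate_reactivity(s2$txs, s2$truth, p)
  expect_identical(x1, x2)
  # different replicates / conditions draw differently
  expect_false(identical(t1, simulate_merip_tracks(s1$txs, s1$truth, p, "ctrl", 2)))
  expect_false(identical(r1, simulate_ribo_track(s1$txs, s1$truth, p, "ctrl")))
})

test_that("planted ground truth is consistent with the sequences", {
  sim <- simulate_transcriptome(small_sim(seed = 5L))
  expect_gt(nrow(sim$truth$sites), 0)
  for (i in seq_len(nrow(sim$truth$sites))) {
    tx <- sim$txs[sim$txs$transcript_id == sim$truth$sites$transcript_id[i], ]
    # every planted site is the A of an RRAC motif
    expect_true(sim$truth$sites$pos[i] %in% find_rrac_sites(tx$sequence))
    # in CDS, outside the exclusion zones
    expect_equal(classify_position(tx, sim$truth$sites$pos[i]), "CDS")
  }
  # zero requested sites -> empty truth
  sim0 <- simulate_transcriptome(small_sim(seed = 5L,
                                           n_methylated_sites = 0L))
  expect_equal(nrow(sim0$truth$sites), 0)
  # impossible geometry errors out
  expect_error(
    simulate_transcriptome(sim_params(n_transcripts = 2L,
                                      n_methylated_sites = 2L,
                                      cds_range = c(150L, 180L), seed = 1L)),
    "too short"
  )
})

test_that("tracks are length-matched, integer-valued counts or [0,1] reactivities", {
  p <- small_sim(seed = 21L)
  sim <- simulate_transcriptome(p)
  tr <- simulate_merip_tracks(sim$txs, sim$truth, p)
  rb <- simulate_ribo_track(sim$txs, sim$truth, p)
  rx <- simulate_reactivity(sim$txs, sim$truth, p)
  for (i in seq_len(nrow(sim$txs))) {
    tid <- sim$txs$transcript_id[i]
    len <- sim$txs$length[i]
    for (x in list(tr$ip[[tid]], tr$input[[tid]], rb[[tid]])) {
      expect_length(x, len)
      expect_true(all(x >= 0 & x == round(x)))
    }
    expect_length(rx[[tid]], len)
    expect_true(all(rx[[tid]] >= 0 & rx[[tid]] <= 1))
  }
})

test_that("IP enrichment of 1 leaves IP and input exchangeable", {
  p <- small_sim(seed = 31L, ip_enrichment = 1)
  sim <- simulate_transcriptome(p)
  tr <- simulate_merip_tracks(sim$txs, sim$truth, p)
  ip_all <- unlist(tr$ip); in_all <- unlist(tr$input)
  expect_gt(length(ip_all), 5e3)
  expect_lt(abs(mean(ip_all) - mean(in_all)) / mean(in_all), 0.05)
})

test_that("planted IP/input fold is recovered at the site over replicates", {
  p <- sim_params(n_transcripts = 4L, n_methylated_sites = 4L,
                  n_structured_regions = 0L, n_relief_regions = 0L,
                  ip_enrichment = 8, dispersion = 0.05, seed = 13L)
  sim <- simulate_transcriptome(p)
  ip_at <- 0; in_at <- 0
  for (r in 1:25) {
    tr <- simulate_merip_tracks(sim$txs, sim$truth, p, "ctrl", r)
    for (i in seq_len(nrow(sim$truth$sites))) {
      tid <- sim$truth$sites$transcript_id[i]
      s <- sim$truth$sites$pos[i]
      ip_at <- ip_at + tr$ip[[tid]][s + 1L]
      in_at <- in_at + tr$input[[tid]][s + 1L]
    }
  }
  expect_lt(abs(ip_at / in_at - 8), 0.8)  # Monte-Carlo vs generative fold
})

test_that("zero-abundance transcripts yield all-zero MeRIP tracks", {
  p <- small_sim(seed = 41L)
  sim <- simulate_transcriptome(p)
  sim$truth$abundance[1] <- 0
  tr <- simulate_merip_tracks(sim$txs, sim$truth, p)
  tid <- names(sim$truth$abundance)[1]
  expect_true(all(tr$ip[[tid]] == 0))
  expect_true(all(tr$input[[tid]] == 0))
})

test_that("uniform dwell gives a flat ribosome profile over codon positions", {
  p <- sim_params(n_transcripts = 3L, n_methylated_sites = 0L,
                  n_structured_regions = 0L, n_relief_regions = 0L,
                  pause_factor = 1, mean_footprints = 4e4, seed = 17L)
  sim <- simulate_transcriptome(p)
  rb <- simulate_ribo_track(sim$txs, sim$truth, p)
  # chi-square against uniform allocation over eligible codons
  i <- 1L
  tid <- sim$txs$transcript_id[i]
  cs <- seq(sim$txs$cds_start[i], sim$txs$cds_end[i] - 3L, by = 3L)
  cs <- cs[cs - p$a_site_offset >= 0L]
  obs <- rb[[tid]][cs - p$a_site_offset + 1L]
  expect_gt(sum(obs), 1e4)
  pval <- chisq.test(obs)$p.value
  expect_gt(pval, 0.01)
  # all reads sit at codon starts minus the offset
  expect_equal(sum(obs), sum(rb[[tid]]))
})

test_that("planted dwell ratio at methylated codons approaches pause_factor", {
  p <- sim_params(n_transcripts = 10L, n_methylated_sites = 10L,
                  n_structured_regions = 0L, n_relief_regions = 0L,
                  pause_factor = 3, mean_footprints = 2e4, seed = 19L)
  sim <- simulate_transcriptome(p)
  rb <- simulate_ribo_track(sim$txs, sim$truth, p)
  ratios <- vapply(seq_len(nrow(sim$truth$sites)), function(i) {
    tid <- sim$truth$sites$transcript_id[i]
    c0 <- sim$truth$sites$codon_start[i]
    cs <- seq(sim$txs$cds_start[sim$txs$transcript_id == tid],
              sim$txs$cds_end[sim$txs$transcript_id == tid] - 3L, by = 3L)
    cs <- cs[cs - p$a_site_offset >= 0L]
    cnt <- rb[[tid]][cs - p$a_site_offset + 1L]
    cnt[cs == c0] / mean(cnt[cs != c0])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.45)
  # knockdown with full loss of methylation removes the pause
  p0 <- sim_params(n_transcripts = 10L, n_methylated_sites = 10L,
                   n_structured_regions = 0L, n_relief_regions = 0L,
                   pause_factor = 3, kd_enrichment_scale = 0,
                   mean_footprints = 2e4, seed = 19L)
  rb0 <- simulate_ribo_track(sim$txs, sim$truth, p0, "kd")
  ratios0 <- vapply(seq_len(nrow(sim$truth$sites)), function(i) {
    tid <- sim$truth$sites$transcript_id[i]
    c0 <- sim$truth$sites$codon_start[i]
    cs <- seq(sim$txs$cds_start[sim$txs$transcript_id == tid],
              sim$txs$cds_end[sim$txs$transcript_id == tid] - 3L, by = 3L)
    cs <- cs[cs - p$a_site_offset >= 0L]
    cnt <- rb0[[tid]][cs - p$a_site_offset + 1L]
    cnt[cs == c0] / mean(cnt[cs != c0])
  }, numeric(1))
  expect_lt(abs(mean(ratios0) - 1), 0.3)
})

test_that("reactivity is elevated by the planted offset over methylated regions", {
  p <- sim_params(n_transcripts = 12L, n_methylated_sites = 12L,
                  n_structured_regions = 0L, n_relief_regions = 0L,
                  react_baseline = 0.4, react_methylated = 0.6, seed = 23L)
  sim <- simulate_transcriptome(p)
  rx <- simulate_reactivity(sim$txs, sim$truth, p)
  meth <- numeric(0); base <- numeric(0)
  for (i in seq_len(nrow(sim$txs))) {
    tid <- sim$txs$transcript_id[i]
    x <- rx[[tid]]
    s <- sim$truth$sites$pos[sim$truth$sites$transcript_id == tid]
    idx <- unlist(lapply(s, function(a) max(0, a - 400):min(length(x) - 1, a + 100)))
    meth <- c(meth, x[idx + 1])
    base <- c(base, x[setdiff(seq_along(x) - 1, idx) + 1])
  }
  expect_lt(abs((mean(meth) - mean(base)) - 0.2), 0.03)
  # equal means -> no difference
  p0 <- sim_params(n_transcripts = 6L, n_methylated_sites = 6L,
                   n_structured_regions = 0L, n_relief_regions = 0L,
                   react_baseline = 0.5, react_methylated = 0.5, seed = 29L)
  sim0 <- simulate_transcriptome(p0)
  rx0 <- simulate_reactivity(sim0$txs, sim0$truth, p0)
  agg <- aggregate_reactivity(rx0, sim0$truth$sites[, c("transcript_id", "pos")],
                              flank = 100L)
  expect_lt(abs(mean(agg$profile$mean) - 0.5), 0.03)
})
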