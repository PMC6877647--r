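flat_track <- function(tid = "t1", len = 400L, value = 1) {
  coverage_track(setNames(list(rep(value, len)), tid), "RIBO")
}

test_that("metagene of a uniform region is flat at 1/121", {
  rb <- flat_track()
  prof <- metagene_profile(rb, data.frame(transcript_id = "t1", pos = 200L))
  expect_equal(prof$n_regions, 1)
  expect_equal(prof$mean_density, rep(1 / 121, 121))
  expect_equal(sum(prof$mean_density), 1)
})

test_that("metagene excludes low-read regions and edge anchors", {
  x <- numeric(400); x[171:231] <- 0.12  # total ~ 7.3 < 20
  rb <- coverage_track(list(t1 = x), "RIBO")
  expect_error(metagene_profile(rb, data.frame(transcript_id = "t1", pos = 200L)),
               "no usable regions")
  # exactly 20 reads passes (strict < 20 exclusion)
  y <- numeric(400); y[200] <- 20
  rb2 <- coverage_track(list(t1 = y), "RIBO")
  prof <- metagene_profile(rb2, data.frame(transcript_id = "t1", pos = 200L))
  expect_equal(prof$n_regions, 1)
  # 19 reads fails
  y[200] <- 19
  rb3 <- coverage_track(list(t1 = y), "RIBO")
  expect_error(metagene_profile(rb3, data.frame(transcript_id = "t1", pos = 200L)))
  # anchors too close to the ends are skipped and counted
  prof2 <- metagene_profile(flat_track(), data.frame(
    transcript_id = c("t1", "t1"), pos = c(30L, 200L)))
  expect_equal(prof2$n_regions, 1)
  expect_equal(prof2$n_skipped_edge, 1)
})

test_that("metagene equals the hand-averaged normalized tracks and is order-invariant", {
  x <- numeric(500); x[101:400] <- 2; x[200] <- 50   # spike near anchor 1
  y <- numeric(500); y[101:400] <- 1; y[350] <- 30   # spike near anchor 2
  rb <- coverage_track(list(a = x, b = y), "RIBO")
  anchors <- data.frame(transcript_id = c("a", "b"), pos = c(210L, 340L))
  prof <- metagene_profile(rb, anchors)
  wa <- x[(210 - 60 + 1):(210 + 60 + 1)]; wa <- wa / sum(wa)
  wb <- y[(340 - 60 + 1):(340 + 60 + 1)]; wb <- wb / sum(wb)
  expect_equal(prof$mean_density, (wa + wb) / 2)
  prof_rev <- metagene_profile(rb, anchors[2:1, ])
  expect_equal(prof$mean_density, prof_rev$mean_density)
})

test_that("A-site pause score is 1 on flat profiles and reads off planted ratios", {
  prof <- metagene_profile(flat_track(),
                           data.frame(transcript_id = "t1", pos = 200L))
  expect_equal(pause_score_at_a_site(prof), 1)
  # profile with the -15 offset exactly 3x the in-frame background
  md <- rep(0, 121); names(md) <- -60:60
  md[seq(1, 121, by = 3)] <- 1  # offsets -60, -57, ..., +60 (frame of -15)
  md[match(-15, -60:60)] <- 3
  fake <- structure(list(offsets = -60:60, mean_density = md / sum(md),
                         n_regions = 10L), class = "metagene_profile")
  expect_equal(pause_score_at_a_site(fake), 3, tolerance = 1e-12)
  # without frame matching the zero out-of-frame offsets dilute the background
  expect_gt(pause_score_at_a_site(fake, frame_matched = FALSE), 6)
})

test_that("codon-grouped pausing separates codons with different planted dwell", {
  # two transcripts: GAA sites dwell 3x, GAC sites dwell 1x
  p <- sim_params(n_transcripts = 8L, n_methylated_sites = 8L,
                  n_structured_regions = 0L, n_relief_regions = 0L,
                  pause_factor = 3, mean_footprints = 2e4, seed = 77L)
  sim <- simulate_transcriptome(p)
  rb <- simulate_ribo_track(sim$txs, sim$truth, p)
  sites <- sim$truth$sites
  out <- codon_specific_pausing(rb, sites[, c("transcript_id", "pos")],
                                sim$txs, min_group_n = 3L)
  gac <- out[out$codon == "GAC" & out$position_in_codon == 2, ]
  expect_equal(nrow(gac), 1)
  expect_gt(gac$pause_score, 2.3)
  expect_false(gac$low_n)
})

test_that("upstream/downstream ratio excludes the anchor and detects asymmetry", {
  x <- rep(2, 400)
  rb <- coverage_track(list(t1 = x), "RIBO")
  expect_equal(upstream_downstream_ratio(rb, "t1", 200L), 1)
  x2 <- x; x2[(200 - 60 + 1):200] <- 4  # double the upstream flank
  rb2 <- coverage_track(list(t1 = x2), "RIBO")
  expect_equal(upstream_downstream_ratio(rb2, "t1", 200L), 2)
  # anchor value itself is ignored
  x3 <- x; x3[201] <- 1e6
  rb3 <- coverage_track(list(t1 = x3), "RIBO")
  expect_equal(upstream_downstream_ratio(rb3, "t1", 200L), 1)
  # anchors too close to an end are NA, as is a zero downstream sum
  expect_true(is.na(upstream_downstream_ratio(rb, "t1", 30L)))
  x4 <- x; x4[202:400] <- 0
  rb4 <- coverage_track(list(t1 = x4), "RIBO")
  expect_true(is.na(upstream_downstream_ratio(rb4, "t1", 200L)))
})

test_that("pausing scan matches brute force and labels Inc/Dec correctly", {
  withr::with_seed(303, {
    for (i in 1:15) {
      len <- sample(200:1000, 1)
      tx <- random_test_tx(len)
      ctrl <- random_test_track(len)
      kd <- random_test_track(len)
      tracks_c <- coverage_track(setNames(list(ctrl), tx$transcript_id), "RIBO")
      tracks_k <- coverage_track(setNames(list(kd), tx$transcript_id), "RIBO",
                                 condition = "kd")
      got <- detect_pausing_regions(tracks_c, tracks_k, tx)
      bf <- bf_pausing_windows(ctrl, kd, tx$cds_start, tx$cds_end)
      expect_equal(got$windows$start, bf$start)
      expect_equal(got$windows$fold_change, bf$fold_change, tolerance = 1e-12)
      expect_true(all(got$windows$fold_change[got$windows$label %in% "Inc"] > 3))
      expect_true(all(got$windows$fold_change[got$windows$label %in% "Dec"] < 1 / 3))
    }
  })
})

test_that("identical tracks produce no pausing regions; fold changes scale-invariant", {
  tx <- random_test_tx(600)
  x <- random_test_track(600)
  tr <- coverage_track(setNames(list(x), tx$transcript_id), "RIBO")
  out <- detect_pausing_regions(tr, tr, tx)
  expect_equal(nrow(out$regions), 0)
  expect_true(all(abs(out$windows$fold_change - 1) < 1e-12))
  # doubling both tracks leaves fold changes exactly unchanged with pseudo = 0
  y <- random_test_track(600)
  tr2 <- coverage_track(setNames(list(y), tx$transcript_id), "RIBO")
  tr_d <- coverage_track(setNames(list(2 * x), tx$transcript_id), "RIBO")
  tr2_d <- coverage_track(setNames(list(2 * y), tx$transcript_id), "RIBO")
  a <- detect_pausing_regions(tr, tr2, tx, pseudo = 0)
  b <- detect_pausing_regions(tr_d, tr2_d, tx, pseudo = 0)
  expect_equal(a$windows$fold_change, b$windows$fold_change, tolerance = 1e-12)
})

test_that("planted knockdown pausing windows are labelled Inc at ~4x", {
  x <- rep(5, 900); k <- x
  k[301:390] <- 20  # 4x over a 90-nt span
  tx <- tx_table("t", "g", strrep("ACGU", 225), 0L, 900L)
  tr_c <- coverage_track(list(t = x), "RIBO")
  tr_k <- coverage_track(list(t = k), "RIBO", condition = "kd")
  out <- detect_pausing_regions(tr_c, tr_k, tx)
  inc <- out$regions[out$regions$label == "Inc", ]
  expect_equal(nrow(inc), 1)
  expect_true(inc$start <= 300 + 30 && inc$end >= 390 - 30)
  expect_gt(inc$fold_change, 3)
  # the mirrored contrast gives Dec
  out2 <- detect_pausing_regions(tr_k, tr_c, tx)
  expect_equal(out2$regions$label, "Dec")
})

test_that("structure summary ranks hairpin-hosted Inc regions below plain Dec regions", {
  stem <- "GGCGCCGGGCCUUU"
  hairpin <- paste0(stem, "GAAA", chartr("ACGU", "UGCA",
                                         paste(rev(strsplit(stem, "")[[1]]),
                                               collapse = "")))
  plain <- strrep("AUCAAUGGAAUCAAUGCAAUAGCAAUUCAAUG", 2)
  seqs <- paste0(strrep("ACGU", 30), hairpin, strrep("AUGC", 30),
                 substr(plain, 1, 32), strrep("GUCA", 20))
  len <- nchar(seqs)
  tx <- tx_table("t", "g", seqs, 0L, len - len %% 3L)
  regions <- data.frame(
    transcript_id = "t",
    start = c(120L, 272L), end = c(152L, 304L),
    fold_change = c(4, 0.2), label = c("Inc", "Dec"),
    stringsAsFactors = FALSE
  )
  out <- pausing_region_structure_summary(regions, tx, backend = "nussinov")
  expect_lt(out$per_region$mfe[1], out$per_region$mfe[2])
  expect_true(isTRUE(attr(out$test, "low_n")))
  # identical MFE lists across labels are non-significant
  r2 <- rbind(regions, regions)
  r2$label <- c("Inc", "Inc", "Dec", "Dec")
  r2$start <- rep(c(120L, 272L), 2); r2$end <- rep(c(152L, 304L), 2)
  out2 <- pausing_region_structure_summary(r2, tx, backend = "nussinov")
  expect_false(isTRUE(out2$test$p.value < 0.3))
})
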