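#' Metagene ribosome-density profile around anchors
#'
#' For each anchor (transcript, 0-based position) the 5'-end counts over the
#' window `anchor - halfwidth .. anchor + halfwidth` are normalized by the
#' window's total reads; windows with total reads below `min_region_reads`
#' (strict `<`) and anchors too close to a transcript end are excluded. The
#' profile is the positionwise mean of the normalized windows, so it sums to 1
#' and is invariant to the order of regions.
#'
#' @param ribo a [coverage_track()] of 5'-end counts.
#' @param anchors `data.frame` with columns `transcript_id`, `pos`.
#' @param halfwidth window half-width in nt (default 60: offsets −60..+60).
#' @param min_region_reads exclusion threshold on window totals.
#' @return list of class `metagene_profile`: `offsets` (−halfwidth..
#'   +halfwidth), `mean_density`, `n_regions`, `n_skipped_edge`,
#'   `n_skipped_low`.
#' @export
metagene_profile <- function(ribo, anchors, halfwidth = 60L,
                             min_region_reads = 20) {
  offs <- seq.int(-halfwidth, halfwidth)
  acc <- numeric(length(offs))
  n_regions <- 0L; n_edge <- 0L; n_low <- 0L
  for (i in seq_len(nrow(anchors))) {
    x <- ribo[[anchors$transcript_id[i]]]
    if (is.null(x)) next
    a <- anchors$pos[i]
    if (a - halfwidth < 0L || a + halfwidth > length(x) - 1L) {
      n_edge <- n_edge + 1L
      next
    }
    win <- x[(a - halfwidth + 1L):(a + halfwidth + 1L)]
    tot <- sum(win)
    if (tot < min_region_reads) {
      n_low <- n_low + 1L
      next
    }
    acc <- acc + win / tot
    n_regions <- n_regions + 1L
  }
  if (n_regions == 0L) stop("no usable regions for metagene profile")
  structure(
    list(offsets = offs, mean_density = acc / n_regions,
         n_regions = n_regions, n_skipped_edge = n_edge, n_skipped_low = n_low),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> offsets %d..%d over %d regions\n",
              min(x$offsets), max(x$offsets), x$n_regions))
  invisible(x)
}

#' A-site pause score from a metagene profile
#'
#' Ratio of the profile value at the A-site offset (default −15 for 5'-end
#' counts) to the mean profile over flank background offsets (default
#' −60..−30 and +30..+60). Because 5'-end Ribo-seq counts are 3-nt periodic,
#' the background is by default restricted to flank offsets in the same
#' reading frame as the A-site offset (`frame_matched = TRUE`); an all-offset
#' background would dilute the denominator with out-of-frame positions.
#'
#' @param profile a [metagene_profile()].
#' @param a_site_offset offset of the pause position.
#' @param background_offsets offsets forming the background.
#' @param frame_matched restrict the background to offsets congruent to
#'   `a_site_offset` modulo 3.
#' @return the pause score, or `NA` if the background mean is 0.
#' @export
pause_score_at_a_site <- function(profile, a_site_offset = -15L,
                                  background_offsets = c(-60:-30, 30:60),
                                  frame_matched = TRUE) {
  stopifnot(a_site_offset %in% profile$offsets,
            all(background_offsets %in% profile$offsets))
  if (frame_matched) {
    background_offsets <- background_offsets[
      background_offsets %% 3L == a_site_offset %% 3L]
  }
  num <- profile$mean_density[match(a_site_offset, profile$offsets)]
  bg <- mean(profile$mean_density[match(background_offsets, profile$offsets)])
  if (bg == 0) return(NA_real_)
  unname(num / bg)
}

#' Codon-resolved pausing profiles
#'
#' Groups anchor sites by their codon identity and intra-codon position
#' (from [codon_context()]), builds one metagene profile per group anchored
#' at the codon's first nucleotide, and scores each with
#' [pause_score_at_a_site()]. Groups contributing fewer than `min_group_n`
#' regions are flagged `low_n`.
#'
#' @param ribo a [coverage_track()] of 5'-end counts.
#' @param sites `data.frame` with `transcript_id`, `pos` (the anchor
#'   adenosine).
#' @param txs a [tx_table()].
#' @param halfwidth,min_region_reads passed to [metagene_profile()].
#' @param min_group_n minimum regions for a group not to be flagged.
#' @param ... passed to [pause_score_at_a_site()].
#' @return `data.frame` with `codon`, `position_in_codon`, `n_sites`,
#'   `n_regions`, `pause_score`, `low_n`; profiles in attribute `profiles`.
#' @export
codon_specific_pausing <- function(ribo, sites, txs, halfwidth = 60L,
                                   min_region_reads = 20, min_group_n = 10L,
                                   ...) {
  ctx <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    tx <- tx_row(txs, sites$transcript_id[i])
    cc <- codon_context(tx, sites$pos[i])
    cc$transcript_id <- sites$transcript_id[i]
    cc
  }))
  ctx <- ctx[ctx$in_cds, , drop = FALSE]
  key <- paste(ctx$codon, ctx$position_in_codon)
  profiles <- list()
  rows <- lapply(unique(key), function(k) {
    sub <- ctx[key == k, , drop = FALSE]
    anchors <- data.frame(transcript_id = sub$transcript_id,
                          pos = sub$codon_start)
    prof <- tryCatch(
      metagene_profile(ribo, anchors, halfwidth, min_region_reads),
      error = function(e) NULL
    )
    profiles[[k]] <<- prof
    data.frame(
      codon = sub$codon[1], position_in_codon = sub$position_in_codon[1],
      n_sites = nrow(sub),
      n_regions = if (is.null(prof)) 0L else prof$n_regions,
      pause_score = if (is.null(prof)) NA_real_
                    else pause_score_at_a_site(prof, ...),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$low_n <- out$n_regions < min_group_n
  attr(out, "profiles") <- profiles
  out
}

#' Upstream/downstream ribosome-density ratio around an anchor
#'
#' Sum of counts over `[anchor - flank, anchor)` divided by the sum over
#' `(anchor, anchor + flank]`; the anchor position itself is excluded.
#'
#' @param ribo a [coverage_track()].
#' @param transcript_id,pos the anchor.
#' @param flank flank width in nt.
#' @return the ratio, or `NA` when the downstream sum is 0 or the anchor is
#'   closer than `flank` to a transcript end.
#' @export
upstream_downstream_ratio <- function(ribo, transcript_id, pos, flank = 60L) {
  x <- ribo[[transcript_id]]
  if (is.null(x)) return(NA_real_)
  if (pos - flank < 0L || pos + flank > length(x) - 1L) return(NA_real_)
  up <- sum(x[(pos - flank + 1L):pos])
  down <- sum(x[(pos + 2L):(pos + flank + 1L)])
  if (down == 0) return(NA_real_)
  up / down
}

pausing_windows_tx <- function(ctrl, kd, cds_start, cds_end, window, step,
                               pseudo) {
  n <- length(ctrl)
  cds_mean_c <- mean(ctrl[(cds_start + 1L):cds_end])
  cds_mean_k <- mean(kd[(cds_start + 1L):cds_end])
  if (cds_mean_c == 0 || cds_mean_k == 0) return(NULL)
  if (n < window) return(NULL)
  starts <- seq.int(0L, n - window, by = step)
  csc <- cumsum(c(0, ctrl)); csk <- cumsum(c(0, kd))
  dc <- ((csc[starts + window + 1L] - csc[starts + 1L]) + pseudo) / window
  dk <- ((csk[starts + window + 1L] - csk[starts + 1L]) + pseudo) / window
  fc <- (dk / cds_mean_k) / (dc / cds_mean_c)
  data.frame(start = starts, end = starts + window, fold_change = fc)
}

#' Detect differential ribosome pausing regions between conditions
#'
#' Scans each transcript with a sliding window (default 30 nt, step 3 nt);
#' per window and condition the read density (window sum plus a pseudo-count,
#' divided by the window length) is normalized by that condition's mean CDS
#' density, and the knockdown/control ratio of the normalized densities is
#' the window's fold change. Windows with fold change above `fc_hi` are
#' labelled `Inc`, below `fc_lo` labelled `Dec`; overlapping same-label
#' windows are merged for reporting with the most extreme fold change
#' retained. Transcripts with zero CDS reads in either condition are skipped.
#' With `pseudo = 0`, fold changes are exactly invariant to scaling both
#' tracks.
#'
#' @param ribo_ctrl,ribo_kd [coverage_track()]s of 5'-end counts.
#' @param txs a [tx_table()].
#' @param window,step scan geometry in nt.
#' @param fc_hi,fc_lo strict thresholds for `Inc` / `Dec`.
#' @param pseudo pseudo-count added to each window sum.
#' @return list with `windows` (all scanned windows with `fold_change` and
#'   `label`, `NA` label for unremarkable windows) and `regions` (merged
#'   labelled regions: `transcript_id`, `start`, `end`, `fold_change`,
#'   `label`).
#' @export
detect_pausing_regions <- function(ribo_ctrl, ribo_kd, txs, window = 30L,
                                   step = 3L, fc_hi = 3, fc_lo = 1 / 3,
                                   pseudo = 0.5) {
  win_rows <- list(); reg_rows <- list()
  for (i in seq_len(nrow(txs))) {
    tid <- txs$transcript_id[i]
    ctrl <- ribo_ctrl[[tid]]; kd <- ribo_kd[[tid]]
    if (is.null(ctrl) || is.null(kd)) next
    w <- pausing_windows_tx(ctrl, kd, txs$cds_start[i], txs$cds_end[i],
                            window, step, pseudo)
    if (is.null(w)) {
      message("transcript ", tid, " skipped (no CDS reads in a condition)")
      next
    }
    w$transcript_id <- tid
    w$label <- ifelse(w$fold_change > fc_hi, "Inc",
                      ifelse(w$fold_change < fc_lo, "Dec", NA_character_))
    win_rows[[tid]] <- w
    for (lab in c("Inc", "Dec")) {
      sub <- w[!is.na(w$label) & w$label == lab, , drop = FALSE]
      if (!nrow(sub)) next
      m <- merge_spans(sub$start, sub$end)
      m$fold_change <- vapply(seq_len(nrow(m)), function(j) {
        inside <- sub$start >= m$start[j] & sub$end <= m$end[j]
        if (lab == "Inc") max(sub$fold_change[inside])
        else min(sub$fold_change[inside])
      }, numeric(1))
      m$transcript_id <- tid
      m$label <- lab
      reg_rows[[paste(tid, lab)]] <- m
    }
  }
  windows <- do.call(rbind, win_rows)
  regions <- do.call(rbind, reg_rows)
  cols <- c("transcript_id", "start", "end", "fold_change", "label")
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), fold_change = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (is.null(regions)) regions <- empty
  if (is.null(windows)) windows <- empty
  rownames(windows) <- rownames(regions) <- NULL
  list(windows = windows[, cols], regions = regions[, cols])
}

#' Secondary-structure summary of pausing regions
#'
#' Computes, per detected pausing region, the mean sliding-window MFE over
#' its span (see [sliding_mfe()]) and compares the MFE distributions of
#' `Inc` vs `Dec` regions with a Wilcoxon rank-sum test.
#'
#' @param regions the `regions` table from [detect_pausing_regions()].
#' @param txs a [tx_table()].
#' @param window,step folding-window geometry.
#' @param backend folding backend, see [sliding_mfe()].
#' @return list with `per_region` (regions plus `mfe`), `summary` (per-label
#'   n/median/mean), and `test` (`htest` from [stats::wilcox.test()], `NULL`
#'   when a label is empty).
#' @export
pausing_region_structure_summary <- function(regions, txs, window = 30L,
                                             step = 3L, backend = "auto") {
  mfe <- vapply(seq_len(nrow(regions)), function(i) {
    tx <- tx_row(txs, regions$transcript_id[i])
    s <- substring(tx$sequence, regions$start[i] + 1L, regions$end[i])
    prof <- sliding_mfe(s, window = window, step = step, backend = backend)
    mean(prof$mfe)
  }, numeric(1))
  per_region <- regions
  per_region$mfe <- mfe
  summary <- do.call(rbind, lapply(split(per_region, per_region$label),
                                   function(d) {
    data.frame(label = d$label[1], n = nrow(d), median_mfe = stats::median(d$mfe),
               mean_mfe = mean(d$mfe), stringsAsFactors = FALSE)
  }))
  test <- NULL
  inc <- per_region$mfe[per_region$label == "Inc"]
  dec <- per_region$mfe[per_region$label == "Dec"]
  if (length(inc) && length(dec)) {
    # ties are routine for discretized MFE values; the exact-p warning is noise
    test <- suppressWarnings(stats::wilcox.test(inc, dec))
    if (length(inc) < 3L || length(dec) < 3L) {
      attr(test, "low_n") <- TRUE
    }
  }
  list(per_region = per_region, summary = summary, test = test)
}
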