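#' Simulation parameters
#'
#' Bundles the study conditions for the synthetic transcriptome and its assay
#' tracks. Defaults mirror the conditions the pipeline is validated under:
#' 8-fold IP enrichment over a negative-binomial background with ~20
#' reads/nt, a 3-fold A-site dwell at methylated codons, knockdown scaling of
#' enrichment to 0.3 and of methylated-transcript translational output to
#' 0.75, and a 4-fold elongation block over structured spans that form when
#' methylation is lost. The seed fully determines every downstream draw.
#'
#' @param n_transcripts number of genes/transcripts (one isoform per gene).
#' @param utr5_range,cds_range,utr3_range integer length ranges; CDS lengths
#'   are rounded to multiples of 3.
#' @param gc_content background GC fraction of simulated sequences.
#' @param n_methylated_sites number of planted m6A sites (RRAC adenosines in
#'   CDS, outside the start/stop exclusion zones; at most one per transcript
#'   until all transcripts carry one).
#' @param ip_enrichment IP/input fold at a planted site's summit (>= 1).
#' @param peak_halfwidth half-width (nt) of the triangular enrichment kernel.
#' @param background_mean expected input reads per nucleotide for a
#'   transcript of average abundance.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @param pause_factor A-site dwell multiplier at methylated codons (>= 1).
#' @param kd_enrichment_scale fraction in `[0,1]`: knockdown scales both the
#'   excess IP enrichment and the excess m6A dwell by this factor.
#' @param structure_pause_factor dwell multiplier over codons at and just
#'   upstream of structured spans in the knockdown condition.
#' @param n_structured_regions GC-rich hairpin spans planted in CDS; these
#'   pause elongation under knockdown (fold-change "Inc" truth).
#' @param n_relief_regions plain-sequence spans paused in the control
#'   condition only, emulating regions whose ribosome occupancy drops after
#'   knockdown (fold-change "Dec" truth).
#' @param mean_footprints expected ribosome footprints per transcript of
#'   average abundance.
#' @param kd_te_scale multiplicative change of methylated transcripts'
#'   footprint totals under knockdown (0.75 = 25% TE loss).
#' @param a_site_offset 5'-end offset of the footprint relative to the A-site
#'   codon's first nucleotide (reads placed at codon_start - a_site_offset).
#' @param react_baseline,react_methylated mean reactivity outside / inside
#'   methylated regions (-400..+100 nt of planted sites).
#' @param react_concentration Beta concentration of reactivity draws.
#' @param seed integer master seed (< 2^31).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_transcripts = 50L,
                       utr5_range = c(150L, 250L),
                       cds_range = c(900L, 1500L),
                       utr3_range = c(200L, 350L),
                       gc_content = 0.5,
                       n_methylated_sites = 30L,
                       ip_enrichment = 8,
                       peak_halfwidth = 50L,
                       background_mean = 20,
                       dispersion = 0.1,
                       pause_factor = 3,
                       kd_enrichment_scale = 0.3,
                       structure_pause_factor = 4,
                       n_structured_regions = 20L,
                       n_relief_regions = 20L,
                       mean_footprints = 2000,
                       kd_te_scale = 0.75,
                       a_site_offset = 15L,
                       react_baseline = 0.4,
                       react_methylated = 0.6,
                       react_concentration = 8,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$n_transcripts >= 1L, p$gc_content > 0, p$gc_content < 1,
    p$ip_enrichment >= 1, p$pause_factor >= 1,
    p$kd_enrichment_scale >= 0, p$kd_enrichment_scale <= 1,
    all(c(p$utr5_range, p$cds_range, p$utr3_range) > 0),
    p$seed == as.integer(p$seed), abs(p$seed) < 2^31
  )
  structure(p, class = "sim_params")
}

sub_seed <- function(params, k) (params$seed * 97L + k) %% .Machine$integer.max

random_seq <- function(n, gc) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

splice_in <- function(seq, start0, insert) {
  # overwrite seq at 0-based start0 with `insert`
  paste0(substring(seq, 1L, start0), insert,
         substring(seq, start0 + nchar(insert) + 1L))
}

revcomp_rna <- function(s) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulate a transcriptome with planted m6A sites and structured spans
#'
#' Generates random transcript sequences at the requested GC content, plants
#' RRAC motifs (written as `GGAC` with the adenosine at codon position 2) at
#' in-frame CDS positions outside the start/stop exclusion zones, plants
#' GC-rich hairpins for the structured spans and marks plain spans as
#' control-paused "relief" regions, and records everything as ground truth.
#'
#' @param params a [sim_params()].
#' @return list with `txs` (a [tx_table()]) and `truth`, a list holding
#'   `sites` (transcript_id, pos, codon_start), `structured`
#'   (transcript_id, start, end, paused_in = "kd"), `relief`
#'   (transcript_id, start, end, paused_in = "ctrl") and `abundance`
#'   (named relative abundances, mean 1).
#' @export
simulate_transcriptome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(sub_seed(params, 1L), {
    p <- params
    n <- p$n_transcripts
    u5 <- sample(p$utr5_range[1]:p$utr5_range[2], n, replace = TRUE)
    cds <- sample(p$cds_range[1]:p$cds_range[2], n, replace = TRUE)
    cds <- cds - cds %% 3L
    u3 <- sample(p$utr3_range[1]:p$utr3_range[2], n, replace = TRUE)
    ids <- sprintf("tx%04d", seq_len(n))
    genes <- sprintf("g%04d", seq_len(n))
    seqs <- vapply(u5 + cds + u3, random_seq, character(1), gc = p$gc_content)
    names(seqs) <- ids
    cds_start <- u5
    cds_end <- u5 + cds

    # eligible in-frame codon starts: outside start zone (+100) / stop zone
    # (-100), clear of transcript ends for metagene/structure windows
    margin <- 120L
    pick_codons <- function(i, k, min_gap) {
      lo <- cds_start[i] + 102L
      hi <- cds_end[i] - 102L - 3L
      cand <- seq.int(lo + (3L - (lo - cds_start[i]) %% 3L) %% 3L, hi, by = 3L)
      cand <- cand[cand >= margin & cand + 3L <= (u5 + cds + u3)[i] - margin]
      if (length(cand) < k) return(NULL)
      chosen <- integer(0)
      for (c0 in sample(cand)) {
        if (all(abs(c0 - chosen) >= min_gap)) chosen <- c(chosen, c0)
        if (length(chosen) == k) break
      }
      if (length(chosen) < k) NULL else sort(chosen)
    }

    n_sites <- p$n_methylated_sites
    if (n_sites > 0 && min(p$cds_range) < 210L) {
      stop("cds_range too short to host methylated sites outside exclusion zones")
    }
    site_tx <- if (n_sites > 0) {
      rep(seq_len(n), length.out = n_sites)[order(rep(seq_len(n),
                                                      length.out = n_sites))]
    } else integer(0)
    sites <- NULL
    for (i in unique(site_tx)) {
      k <- sum(site_tx == i)
      cs <- pick_codons(i, k, min_gap = 250L)
      if (is.null(cs)) stop("cds_range too short to host requested sites")
      for (c0 in cs) {
        # previous codon's last base -> G, codon -> GAC: plants GGAC, A at c0+1
        seqs[i] <- splice_in(seqs[i], c0 - 1L, "GGAC")
        sites <- rbind(sites, data.frame(transcript_id = ids[i], pos = c0 + 1L,
                                         codon_start = c0,
                                         stringsAsFactors = FALSE))
      }
    }

    plant_spans <- function(n_spans, make_insert, used) {
      out <- NULL
      if (n_spans <= 0) return(list(spans = out, used = used))
      tx_cycle <- rep(sample(n), length.out = 4L * n_spans)
      planted <- 0L
      for (i in tx_cycle) {
        if (planted == n_spans) break
        cs <- pick_codons(i, 1L, min_gap = 1L)
        if (is.null(cs)) next
        c0 <- cs[1]
        ins <- make_insert()
        span <- c(c0, c0 + nchar(ins))
        prior <- used[used$transcript_id == ids[i], , drop = FALSE]
        clear <- !nrow(prior) ||
          all(span[1] >= prior$end + 60L | span[2] + 60L <= prior$start)
        if (!clear) next
        seqs[i] <<- splice_in(seqs[i], c0, ins)
        out <- rbind(out, data.frame(transcript_id = ids[i], start = span[1],
                                     end = span[2], stringsAsFactors = FALSE))
        used <- rbind(used, out[nrow(out), ])
        planted <- planted + 1L
      }
      if (planted < n_spans) stop("could not place all structured spans")
      list(spans = out, used = used)
    }

    used <- if (is.null(sites)) {
      data.frame(transcript_id = character(0), start = integer(0),
                 end = integer(0), stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = sites$transcript_id,
                 start = sites$pos - 60L, end = sites$pos + 60L,
                 stringsAsFactors = FALSE)
    }
    hairpin <- function() {
      stem <- random_seq(10L, gc = 0.9)
      paste0(stem, "GAAA", revcomp_rna(stem))
    }
    plain <- function() random_seq(24L, gc = p$gc_content)
    st <- plant_spans(p$n_structured_regions, hairpin, used)
    rl <- plant_spans(p$n_relief_regions, plain, st$used)

    structured <- st$spans
    relief <- rl$spans
    if (!is.null(structured)) structured$paused_in <- "kd"
    if (!is.null(relief)) relief$paused_in <- "ctrl"

    abundance <- stats::rgamma(n, shape = 4, rate = 4)
    names(abundance) <- ids

    txs <- tx_table(ids, genes, seqs, cds_start, cds_end)
    if (is.null(sites)) {
      sites <- data.frame(transcript_id = character(0), pos = integer(0),
                          codon_start = integer(0), stringsAsFactors = FALSE)
    }
    empty_span <- data.frame(transcript_id = character(0), start = integer(0),
                             end = integer(0), paused_in = character(0),
                             stringsAsFactors = FALSE)
    list(txs = txs,
         truth = list(sites = sites,
                      structured = if (is.null(structured)) empty_span else structured,
                      relief = if (is.null(relief)) empty_span else relief,
                      abundance = abundance))
  })
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

enrichment_profile <- function(len, sites, fold, halfwidth) {
  prof <- rep(1, len)
  for (s in sites) {
    d <- abs(seq_len(len) - 1L - s)
    prof <- pmax(prof, 1 + (fold - 1) * pmax(0, 1 - d / halfwidth))
  }
  prof
}

#' Simulate MeRIP (m6A-seq) IP and input tracks
#'
#' Input counts are negative-binomial with per-transcript abundance scaling;
#' IP counts multiply the local input mean by a triangular enrichment kernel
#' peaking at `ip_enrichment` over each planted site (half-width
#' `peak_halfwidth`). Under `condition = "kd"` the excess enrichment is scaled
#' by `kd_enrichment_scale`. Each replicate is an independent draw.
#'
#' @param txs,truth output of [simulate_transcriptome()].
#' @param params the same [sim_params()].
#' @param condition `"ctrl"` or `"kd"`.
#' @param replicate replicate index (enters the sub-seed).
#' @return list with [coverage_track()]s `ip` and `input`.
#' @export
simulate_merip_tracks <- function(txs, truth, params, condition = c("ctrl", "kd"),
                                  replicate = 1L) {
  condition <- match.arg(condition)
  fold <- if (condition == "kd") {
    1 + (params$ip_enrichment - 1) * params$kd_enrichment_scale
  } else params$ip_enrichment
  withr::with_seed(sub_seed(params, 1000L + 10L * replicate +
                              (condition == "kd")), {
    ip <- list(); input <- list()
    for (i in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[i]
      len <- txs$length[i]
      mu <- params$background_mean * truth$abundance[[tid]]
      if (mu == 0) {
        input[[tid]] <- numeric(len); ip[[tid]] <- numeric(len)
        next
      }
      sites <- truth$sites$pos[truth$sites$transcript_id == tid]
      input[[tid]] <- rnbinom_mu(len, mu, params$dispersion)
      ip[[tid]] <- rnbinom_mu(
        len, mu * enrichment_profile(len, sites, fold, params$peak_halfwidth),
        params$dispersion
      )
    }
    list(ip = coverage_track(ip, "IP", condition, replicate),
         input = coverage_track(input, "INPUT", condition, replicate))
  })
}

#' Simulate an RNA-seq abundance track
#'
#' Same generative model as the MeRIP input library (negative-binomial counts
#' proportional to transcript abundance), labelled as the `RNA` assay.
#'
#' @inheritParams simulate_merip_tracks
#' @return a [coverage_track()].
#' @export
simulate_rna_track <- function(txs, truth, params, condition = "ctrl",
                               replicate = 1L) {
  withr::with_seed(sub_seed(params, 3000L + 10L * replicate +
                              (condition == "kd")), {
    counts <- list()
    for (i in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[i]
      mu <- params$background_mean * truth$abundance[[tid]]
      counts[[tid]] <- rnbinom_mu(txs$length[i], mu, params$dispersion)
    }
    coverage_track(counts, "RNA", condition, replicate)
  })
}

#' Simulate a ribosome-footprint 5'-end track
#'
#' Per-codon dwell weights are uniform over the CDS except: methylated codons
#' dwell `pause_factor` times longer (control; under knockdown the excess
#' dwell is scaled by `kd_enrichment_scale`); codons at or up to 15 nt
#' upstream of a structured hairpin span dwell `structure_pause_factor`
#' longer in the condition where that span blocks elongation ("kd" for
#' structured spans, "ctrl" for relief spans). Footprint totals are
#' proportional to abundance (methylated transcripts scaled by `kd_te_scale`
#' under knockdown); reads are allocated multinomially over codons and each
#' read's 5' end is placed at `codon_start - a_site_offset`.
#'
#' @inheritParams simulate_merip_tracks
#' @return a [coverage_track()] of 5'-end counts.
#' @export
simulate_ribo_track <- function(txs, truth, params, condition = c("ctrl", "kd"),
                                replicate = 1L) {
  condition <- match.arg(condition)
  p <- params
  withr::with_seed(sub_seed(p, 2000L + 10L * replicate + (condition == "kd")), {
    counts <- list()
    m6a_pause <- if (condition == "kd") {
      1 + (p$pause_factor - 1) * p$kd_enrichment_scale
    } else p$pause_factor
    for (i in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[i]
      len <- txs$length[i]
      counts[[tid]] <- numeric(len)
      codon_starts <- seq.int(txs$cds_start[i], txs$cds_end[i] - 3L, by = 3L)
      # reads must fit on the transcript after the 5'-end shift
      ok <- codon_starts - p$a_site_offset >= 0L
      codon_starts <- codon_starts[ok]
      if (!length(codon_starts)) next
      w <- rep(1, length(codon_starts))
      sites <- truth$sites[truth$sites$transcript_id == tid, , drop = FALSE]
      w[codon_starts %in% sites$codon_start] <- m6a_pause
      spans <- rbind(truth$structured, truth$relief)
      spans <- spans[spans$transcript_id == tid &
                       spans$paused_in == condition, , drop = FALSE]
      for (j in seq_len(nrow(spans))) {
        hit <- codon_starts + 3L > spans$start[j] - 15L &
          codon_starts < spans$end[j]
        w[hit] <- w[hit] * p$structure_pause_factor
      }
      total <- p$mean_footprints * truth$abundance[[tid]]
      if (condition == "kd" && tid %in% truth$sites$transcript_id) {
        total <- total * p$kd_te_scale
      }
      n_reads <- stats::rpois(1, total)
      if (n_reads == 0) next
      alloc <- stats::rmultinom(1, n_reads, w)[, 1]
      pos5 <- codon_starts - p$a_site_offset
      counts[[tid]][pos5 + 1L] <- counts[[tid]][pos5 + 1L] + alloc
    }
    coverage_track(counts, "RIBO", condition, replicate)
  })
}

#' Simulate an icSHAPE-like reactivity track
#'
#' Per-nucleotide reactivities are Beta draws with mean `react_baseline`,
#' elevated to `react_methylated` over methylated regions (−400..+100 nt of
#' each planted site) — methylation keeps these regions single-stranded in
#' the wild type.
#'
#' @inheritParams simulate_merip_tracks
#' @return a [coverage_track()] with values in `[0,1]`.
#' @export
simulate_reactivity <- function(txs, truth, params, replicate = 1L) {
  p <- params
  withr::with_seed(sub_seed(p, 4000L + replicate), {
    counts <- list()
    rbeta_mean <- function(n, m) {
      stats::rbeta(n, m * p$react_concentration, (1 - m) * p$react_concentration)
    }
    for (i in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[i]
      len <- txs$length[i]
      x <- rbeta_mean(len, p$react_baseline)
      sites <- truth$sites$pos[truth$sites$transcript_id == tid]
      for (s in sites) {
        span <- max(0L, s - 400L):min(len - 1L, s + 100L)
        x[span + 1L] <- rbeta_mean(length(span), p$react_methylated)
      }
      counts[[tid]] <- pmin(1, pmax(0, x))
    }
    coverage_track(counts, "REACTIVITY", "ctrl", replicate)
  })
}

#' Write a full simulated dataset to a directory
#'
#' Emits the transcript FASTA, the transcript table, ground-truth TSVs and
#' bedGraph-like tracks for both conditions and the requested number of MeRIP
#' replicates.
#'
#' @param params a [sim_params()].
#' @param out_dir output directory (created if needed).
#' @param n_replicates MeRIP replicates per condition.
#' @return invisibly, the simulation (`txs`, `truth`).
#' @export
write_simulation <- function(params, out_dir, n_replicates = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_transcriptome(params)
  seqs <- Biostrings::BStringSet(stats::setNames(sim$txs$sequence,
                                                 sim$txs$transcript_id))
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "transcripts.fa"))
  write_tx_table(sim$txs, file.path(out_dir, "transcripts.tsv"))
  utils::write.table(sim$truth$sites, file.path(out_dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(sim$truth$structured, sim$truth$relief),
                     file.path(out_dir, "truth_spans.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in c("ctrl", "kd")) {
    for (r in seq_len(n_replicates)) {
      tr <- simulate_merip_tracks(sim$txs, sim$truth, params, cond, r)
      write_track_tsv(tr$ip, file.path(out_dir, sprintf("ip_%s_rep%d.tsv", cond, r)))
      write_track_tsv(tr$input, file.path(out_dir, sprintf("input_%s_rep%d.tsv", cond, r)))
    }
    write_track_tsv(simulate_ribo_track(sim$txs, sim$truth, params, cond),
                    file.path(out_dir, sprintf("ribo_%s.tsv", cond)))
    write_track_tsv(simulate_rna_track(sim$txs, sim$truth, params, cond),
                    file.path(out_dir, sprintf("rna_%s.tsv", cond)))
  }
  write_track_tsv(simulate_reactivity(sim$txs, sim$truth, params),
                  file.path(out_dir, "reactivity.tsv"))
  invisible(sim)
}
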