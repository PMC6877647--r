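#' Peak-over-median scores for one coverage vector
#'
#' Slides a fixed window (default 50 nt, step 25 nt) over the transcript and
#' scores each window whose maximum coverage exceeds `min_window_max` with
#' POM = mean(window) / median(whole transcript). The median is taken over all
#' positions including zeros; a transcript whose median is 0 yields no windows
#' (no finite POM exists) and is reported via attribute `skipped`. Only
#' full-length windows are emitted. POM is scale-invariant: multiplying the
#' track by any positive constant leaves every score unchanged.
#'
#' @param counts numeric vector of per-nucleotide coverage.
#' @param window,step window length and step in nt.
#' @param min_window_max windows whose maximum coverage is not strictly above
#'   this value are not scored.
#' @return `data.frame` with columns `start`, `end` (0-based half-open),
#'   `pom`, `max_cov`; attribute `skipped = TRUE` when the transcript median
#'   was 0.
#' @export
pom_scores <- function(counts, window = 50L, step = 25L, min_window_max = 10) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      pom = numeric(0), max_cov = numeric(0))
  n <- length(counts)
  if (n < window) return(empty)
  med <- stats::median(counts)
  if (med == 0) {
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  starts <- seq.int(0L, n - window, by = step)
  cs <- cumsum(c(0, counts))
  means <- (cs[starts + window + 1L] - cs[starts + 1L]) / window
  maxs <- vapply(starts, function(s) max(counts[(s + 1L):(s + window)]),
                 numeric(1))
  keep <- maxs > min_window_max
  data.frame(start = starts[keep], end = starts[keep] + window,
             pom = means[keep] / med, max_cov = maxs[keep])
}

merge_spans <- function(start, end) {
  # merge half-open intervals that overlap by >= 1 nt; returns a data.frame
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] < me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Call m6A peaks on one transcript from IP and input tracks
#'
#' The peak-over-median / peak-over-input caller: IP windows with POM above
#' `pom_threshold` are retained; any retained window overlapping (by >= 1 nt)
#' an input window that itself passes the POM threshold is eliminated;
#' survivors are merged into maximal overlapping clusters; POM is recomputed
#' over each full cluster span in both IP and input and their ratio is the
#' cluster's POI. Clusters with POI above `poi_threshold` become peaks. The
#' summit is the position of maximum IP coverage in the cluster (leftmost on
#' ties) and the m6A residue is the adenosine of the RRAC motif nearest the
#' summit (upstream preferred on distance ties); the residue's mRNA region is
#' assigned with [classify_position()]. Thresholds are strict (`>`), matching
#' the "higher than" rule.
#'
#' @param ip,input numeric coverage vectors, length-matched to `tx`.
#' @param tx one row of a [tx_table()].
#' @param window,step,min_window_max window parameters, see [pom_scores()].
#' @param pom_threshold,poi_threshold strict lower bounds for window POM and
#'   cluster POI.
#' @param input_filter `"overlap"` drops IP windows overlapping an
#'   above-threshold input window; `"transcript"` drops all IP windows when
#'   the input track has any above-threshold window anywhere on the
#'   transcript.
#' @return `data.frame` with one row per peak: `transcript_id`,
#'   `cluster_start`, `cluster_end`, `summit`, `m6a_residue`, `pom_ip`,
#'   `pom_input`, `poi`, `region`. `m6a_residue` is `NA` (with a message)
#'   when the transcript has no RRAC motif.
#' @export
call_peaks <- function(ip, input, tx, window = 50L, step = 25L,
                       min_window_max = 10, pom_threshold = 3,
                       poi_threshold = 3,
                       input_filter = c("overlap", "transcript")) {
  input_filter <- match.arg(input_filter)
  stopifnot(nrow(tx) == 1L, length(ip) == tx$length, length(input) == tx$length)
  empty <- data.frame(
    transcript_id = character(0), cluster_start = integer(0),
    cluster_end = integer(0), summit = integer(0), m6a_residue = integer(0),
    pom_ip = numeric(0), pom_input = numeric(0), poi = numeric(0),
    region = character(0), stringsAsFactors = FALSE
  )
  w_ip <- pom_scores(ip, window, step, min_window_max)
  if (isTRUE(attr(w_ip, "skipped")) || !nrow(w_ip)) return(empty)
  w_ip <- w_ip[w_ip$pom > pom_threshold, , drop = FALSE]
  if (!nrow(w_ip)) return(empty)

  w_in <- pom_scores(input, window, step, min_window_max)
  w_in <- w_in[w_in$pom > pom_threshold, , drop = FALSE]
  if (nrow(w_in)) {
    if (input_filter == "transcript") {
      return(empty)
    }
    drop <- vapply(seq_len(nrow(w_ip)), function(i) {
      any(w_ip$start[i] < w_in$end & w_in$start < w_ip$end[i])
    }, TRUE)
    w_ip <- w_ip[!drop, , drop = FALSE]
  }
  if (!nrow(w_ip)) return(empty)

  cl <- merge_spans(w_ip$start, w_ip$end)
  med_ip <- stats::median(ip)
  med_in <- stats::median(input)
  rrac <- find_rrac_sites(tx$sequence)

  rows <- lapply(seq_len(nrow(cl)), function(i) {
    s <- cl$start[i]; e <- cl$end[i]
    pom_ip <- mean(ip[(s + 1L):e]) / med_ip
    if (med_in == 0) {
      message("input median 0 on ", tx$transcript_id, "; cluster dropped")
      return(NULL)
    }
    pom_input <- mean(input[(s + 1L):e]) / med_in
    poi <- if (pom_input > 0) pom_ip / pom_input else Inf
    if (!(poi > poi_threshold)) return(NULL)
    summit <- s + which.max(ip[(s + 1L):e]) - 1L
    residue <- nearest_rrac(rrac, summit)
    if (is.na(residue)) {
      message("no RRAC motif on ", tx$transcript_id,
              "; peak emitted without m6A residue")
    }
    data.frame(
      transcript_id = tx$transcript_id, cluster_start = s, cluster_end = e,
      summit = summit, m6a_residue = residue, pom_ip = pom_ip,
      pom_input = pom_input, poi = poi,
      region = if (is.na(residue)) NA_character_
               else classify_position(tx, residue),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

nearest_rrac <- function(rrac, summit) {
  if (!length(rrac)) return(NA_integer_)
  d <- abs(rrac - summit)
  cand <- rrac[d == min(d)]
  # upstream (smaller coordinate) preferred on distance ties
  as.integer(min(cand))
}

#' Call peaks across a whole transcript table
#'
#' @param ip,input [coverage_track()]s keyed by transcript id.
#' @param txs a [tx_table()].
#' @param ... passed to [call_peaks()].
#' @return row-bound peak `data.frame` over all transcripts.
#' @export
call_peaks_all <- function(ip, input, txs, ...) {
  rows <- lapply(seq_len(nrow(txs)), function(i) {
    tx <- txs[i, , drop = FALSE]
    tid <- tx$transcript_id
    if (is.null(ip[[tid]]) || is.null(input[[tid]])) return(NULL)
    call_peaks(ip[[tid]], input[[tid]], tx, ...)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      transcript_id = character(0), cluster_start = integer(0),
      cluster_end = integer(0), summit = integer(0), m6a_residue = integer(0),
      pom_ip = numeric(0), pom_input = numeric(0), poi = numeric(0),
      region = character(0), stringsAsFactors = FALSE
    )
  }
  out
}

#' Keep peaks reproduced in all replicates
#'
#' A replicate-1 peak is retained iff its cluster span overlaps (>= 1 nt, same
#' transcript) a cluster in every other replicate; coordinates and scores of
#' the retained peak are those of replicate 1.
#'
#' @param peak_lists list of peak `data.frame`s, one per replicate (>= 1).
#' @return peak `data.frame` (subset of replicate 1).
#' @export
intersect_replicates <- function(peak_lists) {
  stopifnot(length(peak_lists) >= 1L)
  ref <- peak_lists[[1]]
  if (length(peak_lists) == 1L || !nrow(ref)) return(ref)
  keep <- rep(TRUE, nrow(ref))
  for (other in peak_lists[-1]) {
    keep <- keep & vapply(seq_len(nrow(ref)), function(i) {
      same <- other$transcript_id == ref$transcript_id[i]
      any(same & ref$cluster_start[i] < other$cluster_end &
            other$cluster_start < ref$cluster_end[i])
    }, TRUE)
  }
  ref[keep, , drop = FALSE]
}

#' Flag knockdown-sensitive peaks
#'
#' A wild-type peak is methylation-writer sensitive when its POI drops by at
#' least `min_decrease` (default 50%) in the knockdown: for each WT peak the
#' overlapping KD cluster with the largest overlap supplies the KD POI; a WT
#' peak with no overlapping KD cluster is treated as having KD POI 0 (fully
#' lost, hence sensitive).
#'
#' @param peaks_wt,peaks_kd peak `data.frame`s called with identical
#'   parameters.
#' @param min_decrease minimal fractional POI decrease.
#' @return `peaks_wt` with logical column `sensitive` and numeric
#'   `poi_kd` appended.
#' @export
classify_sensitivity <- function(peaks_wt, peaks_kd, min_decrease = 0.5) {
  if (!nrow(peaks_wt)) {
    peaks_wt$sensitive <- logical(0); peaks_wt$poi_kd <- numeric(0)
    return(peaks_wt)
  }
  poi_kd <- vapply(seq_len(nrow(peaks_wt)), function(i) {
    same <- peaks_kd$transcript_id == peaks_wt$transcript_id[i]
    ov <- pmin(peaks_kd$cluster_end, peaks_wt$cluster_end[i]) -
      pmax(peaks_kd$cluster_start, peaks_wt$cluster_start[i])
    hit <- which(same & ov > 0)
    if (!length(hit)) 0 else peaks_kd$poi[hit[which.max(ov[hit])]]
  }, numeric(1))
  peaks_wt$poi_kd <- poi_kd
  peaks_wt$sensitive <- (peaks_wt$poi - poi_kd) / peaks_wt$poi >= min_decrease
  peaks_wt
}

#' Regional census of called peaks
#'
#' Counts peaks and distinct genes per mRNA region (5'UTR / CDS / 3'UTR).
#' Start- and stop-proximal peaks are excluded from the three primary classes
#' and tallied separately. Also returns per-transcript region membership for
#' Venn-style summaries.
#'
#' @param peaks peak `data.frame` carrying `m6a_residue` and `region`.
#' @param txs a [tx_table()] (for the gene mapping).
#' @return list with `census` (region, n_peaks, n_genes) and `membership`
#'   (transcript_id, region).
#' @export
regional_census <- function(peaks, txs) {
  peaks <- peaks[!is.na(peaks$region), , drop = FALSE]
  gene <- txs$gene_id[match(peaks$transcript_id, txs$transcript_id)]
  regions <- c("FIVE_UTR", "CDS", "THREE_UTR", "START_PROXIMAL", "STOP_PROXIMAL")
  census <- do.call(rbind, lapply(regions, function(r) {
    sel <- peaks$region == r
    if (!any(sel)) return(NULL)
    data.frame(region = r, n_peaks = sum(sel),
               n_genes = length(unique(gene[sel])), stringsAsFactors = FALSE)
  }))
  if (is.null(census)) {
    census <- data.frame(region = character(0), n_peaks = integer(0),
                         n_genes = integer(0))
  }
  membership <- unique(data.frame(transcript_id = peaks$transcript_id,
                                  region = peaks$region,
                                  stringsAsFactors = FALSE))
  list(census = census, membership = membership)
}

#' Write peaks as BED6+ (plus a score/annotation block)
#'
#' Standard BED columns use 0-based half-open spans; `thickStart` carries the
#' summit. Extra columns: `pom_ip`, `pom_input`, `poi`, `m6a_residue`,
#' `region`, `sensitive`.
#'
#' @param peaks peak `data.frame`.
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# m6A peaks; BED 0-based half-open; extra cols: ",
                    "pom_ip pom_input poi m6a_residue region sensitive"), con)
  sens <- if ("sensitive" %in% names(peaks)) peaks$sensitive else NA
  df <- data.frame(
    chrom = peaks$transcript_id, chromStart = peaks$cluster_start,
    chromEnd = peaks$cluster_end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = round(pmin(1000, peaks$poi * 100)), strand = "+",
    thickStart = peaks$summit,
    pom_ip = peaks$pom_ip, pom_input = peaks$pom_input, poi = peaks$poi,
    m6a_residue = peaks$m6a_residue, region = peaks$region, sensitive = sens
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
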