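#' Reads per kilobase per million mapped reads
#'
#' `10^9 * count / (length * library_size)`.
#'
#' @param count mapped reads on the feature.
#' @param length feature length in nt (> 0).
#' @param library_size total mapped reads (> 0).
#' @return numeric RPKM (vectorised).
#' @examples
#' rpkm(100, 2000, 1e7)  # 5
#' @export
rpkm <- function(count, length, library_size) {
  if (any(length <= 0) || any(library_size <= 0)) {
    stop("length and library_size must be positive")
  }
  1e9 * count / (length * library_size)
}

#' Translation efficiency per transcript
#'
#' Ribosome density is the footprint RPKM; TE is footprint RPKM divided by
#' mRNA RPKM. Transcripts with RPKM below `min_rpkm` in either assay are
#' excluded. Library sizes default to the column sums of the supplied counts.
#'
#' @param ribo_counts,rna_counts named numeric vectors of per-transcript read
#'   totals (e.g. from [track_totals()] applied to a [coverage_track()]), or
#'   [coverage_track()]s.
#' @param txs a [tx_table()] supplying transcript lengths.
#' @param min_rpkm inclusion threshold (entries with RPKM < `min_rpkm` in
#'   either assay are dropped).
#' @param ribo_library,rna_library optional explicit library sizes.
#' @return `data.frame` with `transcript_id`, `ribo_rpkm`, `rna_rpkm`, `te`.
#' @export
compute_te <- function(ribo_counts, rna_counts, txs, min_rpkm = 1,
                       ribo_library = NULL, rna_library = NULL) {
  if (inherits(ribo_counts, "coverage_track")) ribo_counts <- track_totals(ribo_counts)
  if (inherits(rna_counts, "coverage_track")) rna_counts <- track_totals(rna_counts)
  ids <- intersect(names(ribo_counts), names(rna_counts))
  ids <- intersect(ids, txs$transcript_id)
  len <- txs$length[match(ids, txs$transcript_id)]
  if (is.null(ribo_library)) ribo_library <- sum(ribo_counts)
  if (is.null(rna_library)) rna_library <- sum(rna_counts)
  rr <- rpkm(ribo_counts[ids], len, ribo_library)
  nr <- rpkm(rna_counts[ids], len, rna_library)
  keep <- rr >= min_rpkm & nr >= min_rpkm
  data.frame(transcript_id = ids[keep], ribo_rpkm = unname(rr[keep]),
             rna_rpkm = unname(nr[keep]), te = unname(rr[keep] / nr[keep]),
             stringsAsFactors = FALSE)
}

#' k-nearest-neighbour non-methylated controls
#'
#' For each methylated target transcript, selects up to `k` non-methylated
#' transcripts whose baseline density lies within `tolerance` (default ±10%)
#' of the target's, ranked by absolute difference; the mean of the matched
#' controls' values is the control level. Targets with no in-tolerance
#' candidate are returned unmatched. Matching is on wild-type TE by default,
#' or on raw footprint RPKM.
#'
#' @param te_table output of [compute_te()] for the baseline condition.
#' @param methylated_ids transcript ids of the methylated (m6A-positive) set.
#' @param k maximum controls per target.
#' @param tolerance relative half-width of the matching band.
#' @param match_on `"te"` or `"ribo_rpkm"`.
#' @return `data.frame` with `transcript_id`, `controls`
#'   (comma-separated ids), `n_controls`, `control_value`, `matched`.
#' @export
knn_controls <- function(te_table, methylated_ids, k = 3L, tolerance = 0.10,
                         match_on = c("te", "ribo_rpkm")) {
  match_on <- match.arg(match_on)
  v <- te_table[[match_on]]
  is_m <- te_table$transcript_id %in% methylated_ids
  pool_v <- v[!is_m]
  pool_id <- te_table$transcript_id[!is_m]
  rows <- lapply(which(is_m), function(i) {
    d <- abs(pool_v - v[i])
    ok <- which(d <= tolerance * v[i])
    ok <- ok[order(d[ok])]
    ok <- utils::head(ok, k)
    data.frame(
      transcript_id = te_table$transcript_id[i],
      controls = paste(pool_id[ok], collapse = ","),
      n_controls = length(ok),
      control_value = if (length(ok)) mean(pool_v[ok]) else NA_real_,
      matched = length(ok) > 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), controls = character(0),
                      n_controls = integer(0), control_value = numeric(0),
                      matched = logical(0), stringsAsFactors = FALSE)
  }
  out
}

#' Translation-efficiency fold changes between conditions
#'
#' Per-transcript log2 fold change of TE (condition b over condition a) for
#' transcripts quantified in both conditions, with empirical CDFs per group
#' (for cumulative-fraction plots) and Wilcoxon rank-sum comparisons between
#' the two groups (two-sided plus both one-sided alternatives; groups are
#' taken in radix/byte sort order and the `"less"` alternative asks whether
#' the first group's fold changes are shifted downward).
#'
#' @param te_a,te_b [compute_te()] tables for the two conditions.
#' @param groups named character or factor vector keyed by transcript id
#'   (e.g. `"m6A+"` / `"m6A-"`); transcripts without a group are dropped.
#' @return list: `table` (`transcript_id`, `group`, `te_a`, `te_b`, `log2fc`),
#'   `ecdf` (`group`, `log2fc`, `cum_fraction`), `tests` (list of `htest`:
#'   `two.sided`, `less`, `greater`).
#' @export
te_fold_changes <- function(te_a, te_b, groups) {
  ids <- intersect(te_a$transcript_id, te_b$transcript_id)
  ids <- ids[ids %in% names(groups)]
  a <- te_a$te[match(ids, te_a$transcript_id)]
  b <- te_b$te[match(ids, te_b$transcript_id)]
  tab <- data.frame(transcript_id = ids, group = as.character(groups[ids]),
                    te_a = a, te_b = b, log2fc = log2(b / a),
                    stringsAsFactors = FALSE)
  gl <- sort(unique(tab$group), method = "radix")  # locale-independent order
  ecdf_tab <- do.call(rbind, lapply(gl, function(g) {
    x <- sort(tab$log2fc[tab$group == g])
    data.frame(group = g, log2fc = x,
               cum_fraction = seq_along(x) / length(x),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(gl) == 2L) {
    x <- tab$log2fc[tab$group == gl[1]]
    y <- tab$log2fc[tab$group == gl[2]]
    tests <- list(
      two.sided = stats::wilcox.test(x, y),
      less = stats::wilcox.test(x, y, alternative = "less"),
      greater = stats::wilcox.test(x, y, alternative = "greater")
    )
  }
  list(table = tab, ecdf = ecdf_tab, tests = tests)
}

#' Cumulative-fraction plot of TE fold changes
#'
#' @param fc output of [te_fold_changes()].
#' @return a ggplot object.
#' @export
plot_te_ecdf <- function(fc) {
  ggplot2::ggplot(fc$ecdf,
                  ggplot2::aes(x = log2fc, y = cum_fraction, colour = group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "log2 TE fold change", y = "cumulative fraction") +
    ggplot2::theme_classic()
}

#' Metagene profile plot
#'
#' @param profile a [metagene_profile()].
#' @return a ggplot object.
#' @export
plot_metagene <- function(profile) {
  df <- data.frame(offset = profile$offsets, density = profile$mean_density)
  ggplot2::ggplot(df, ggplot2::aes(x = offset, y = density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from anchor (nt)",
                  y = "mean normalized footprint density") +
    ggplot2::theme_classic()
}
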