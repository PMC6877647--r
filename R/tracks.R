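#' Per-nucleotide coverage tracks
#'
#' A coverage track holds one numeric vector per transcript, length-matched to
#' the transcript, with non-negative counts (or reactivities in `[0,1]` for
#' the `REACTIVITY` assay, where `NA` marks missing values — never 0).
#'
#' @param counts named list of non-negative numeric vectors, one per
#'   transcript.
#' @param assay one of `"IP"`, `"INPUT"`, `"RIBO"`, `"RNA"`, `"REACTIVITY"`.
#' @param condition free-text condition label (e.g. `"ctrl"`, `"kd"`).
#' @param replicate integer replicate index.
#' @return the list with class `coverage_track` and assay metadata attached.
#' @export
coverage_track <- function(counts, assay = c("IP", "INPUT", "RIBO", "RNA",
                                             "REACTIVITY"),
                           condition = "ctrl", replicate = 1L) {
  assay <- match.arg(assay)
  stopifnot(is.list(counts), !is.null(names(counts)))
  if (assay == "REACTIVITY") {
    ok <- vapply(counts, function(x) all(is.na(x) | (x >= 0 & x <= 1)), TRUE)
    if (!all(ok)) stop("reactivity values must lie in [0,1] (NA = missing)")
  } else {
    ok <- vapply(counts, function(x) all(x >= 0) && !anyNA(x), TRUE)
    if (!all(ok)) stop("counts must be non-negative and complete")
  }
  structure(counts, class = "coverage_track", assay = assay,
            condition = condition, replicate = as.integer(replicate))
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> assay=%s condition=%s replicate=%d, %d transcripts\n",
              attr(x, "assay"), attr(x, "condition"), attr(x, "replicate"),
              length(x)))
  invisible(x)
}

#' Total mapped reads per transcript in a track
#'
#' @param track a [coverage_track()].
#' @return named numeric vector of per-transcript totals (`NA`s ignored).
#' @export
track_totals <- function(track) {
  vapply(track, function(x) sum(x, na.rm = TRUE), numeric(1))
}

#' Write a coverage track as bedGraph-like TSV
#'
#' Runs of equal counts are collapsed; coordinates are 0-based half-open
#' (bedGraph convention), as stated in the header.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_track_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coverage track assay=%s condition=%s replicate=%d; 0-based half-open",
                     attr(track, "assay"), attr(track, "condition"),
                     attr(track, "replicate")), con)
  writeLines("transcript_id\tstart\tend\tcount", con)
  for (tid in names(track)) {
    x <- track[[tid]]
    x[is.na(x)] <- -1  # sentinel for missing reactivity
    r <- rle(x)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", tid, s[keep], e[keep],
                       format(r$values[keep], trim = TRUE, scientific = FALSE)),
               con)
  }
}

#' Read a coverage track from bedGraph-like TSV
#'
#' @param path file written by [write_track_tsv()] or any 4-column TSV
#'   (`transcript_id`, `start`, `end`, `count`; 0-based half-open).
#' @param lengths named integer vector of transcript lengths (positions not
#'   covered by any interval get 0, or `NA` for the reactivity assay where the
#'   file's `-1` sentinel also decodes to `NA`).
#' @param assay,condition,replicate metadata for the returned track.
#' @return a [coverage_track()].
#' @export
read_track_tsv <- function(path, lengths, assay = "IP", condition = "ctrl",
                           replicate = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  counts <- lapply(names(lengths), function(tid) numeric(lengths[[tid]]))
  names(counts) <- names(lengths)
  for (tid in unique(tab$transcript_id)) {
    if (is.null(counts[[tid]])) next
    sub <- tab[tab$transcript_id == tid, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      counts[[tid]][(sub$start[i] + 1L):sub$end[i]] <- sub$count[i]
    }
  }
  if (assay == "REACTIVITY") {
    counts <- lapply(counts, function(x) { x[x < 0] <- NA_real_; x })
  }
  coverage_track(counts, assay = assay, condition = condition,
                 replicate = replicate)
}

#' Count 5'-ends from a BAM file into a coverage track
#'
#' Counts the 5'-most aligned position of each plus-strand read per reference
#' (transcript) — the convention used for ribosome-footprint tracks here.
#'
#' @param path indexed BAM aligned to transcript references.
#' @param lengths named integer vector of transcript lengths.
#' @param assay,condition,replicate metadata for the returned track.
#' @return a [coverage_track()].
#' @export
read_track_bam <- function(path, lengths, assay = "RIBO", condition = "ctrl",
                           replicate = 1L) {
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isMinusStrand = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  counts <- lapply(lengths, function(n) numeric(n))
  tid <- as.character(b$rname)
  for (id in unique(tid)) {
    if (is.null(counts[[id]])) next
    tb <- table(b$pos[tid == id])  # pos is 1-based leftmost
    idx <- as.integer(names(tb))
    ok <- idx >= 1L & idx <= lengths[[id]]
    counts[[id]][idx[ok]] <- as.numeric(tb)[ok]
  }
  coverage_track(counts, assay = assay, condition = condition,
                 replicate = replicate)
}

#' Read a single-nucleotide m6A site list (BED-like)
#'
#' Accepts miCLIP-style single-nucleotide site lists: a BED file whose
#' intervals are 1 nt wide (`chrom` = transcript id), or any TSV with
#' `transcript_id` and 0-based `start` columns. Returned positions anchor the
#' metagene and structure analyses exactly like caller-derived m6A residues.
#'
#' @param path input file (comment lines starting with `#` ignored).
#' @return `data.frame` with columns `transcript_id`, `pos` (0-based).
#' @export
read_sites_bed <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           header = FALSE)
  if (is.character(tab[[2]])) {  # had a header after all
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    return(data.frame(transcript_id = tab$transcript_id,
                      pos = as.integer(tab$start)))
  }
  data.frame(transcript_id = as.character(tab[[1]]),
             pos = as.integer(tab[[2]]))
}
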