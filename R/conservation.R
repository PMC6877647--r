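#' Pairwise ortholog alignment
#'
#' Container for one aligned ortholog pair (e.g. from Muscle, read as aligned
#' FASTA). Gap columns use `-`; degapping either row recovers the original
#' transcript sequence.
#'
#' @param id_a,id_b transcript ids of the two orthologs.
#' @param aligned_a,aligned_b gapped sequences of equal length.
#' @return list of class `ortholog_alignment`.
#' @export
ortholog_alignment <- function(id_a, id_b, aligned_a, aligned_b) {
  aligned_a <- toupper(aligned_a); aligned_b <- toupper(aligned_b)
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  structure(list(id_a = id_a, id_b = id_b,
                 aligned_a = aligned_a, aligned_b = aligned_b),
            class = "ortholog_alignment")
}

#' Read one pairwise alignment from aligned FASTA
#'
#' The file must contain exactly two records of equal aligned length.
#'
#' @param path aligned FASTA file.
#' @return an [ortholog_alignment()].
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 2L) stop("expected exactly 2 records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  ortholog_alignment(ids[1], ids[2], as.character(set[[1]]),
                     as.character(set[[2]]))
}

aln_maps <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  list(a_gap = a == "-", b_gap = b == "-",
       a_idx = cumsum(a != "-") - 1L,  # degapped coord at each column
       b_idx = cumsum(b != "-") - 1L)
}

#' Map a transcript position through an ortholog alignment
#'
#' Returns the coordinate in the partner transcript of the alignment column
#' holding the query position, or `NA` when that column is a gap in the
#' partner. Mapping is strictly monotone over positions that map, and
#' round-trips (`a -> b -> a`) whenever both directions map.
#'
#' @param aln an [ortholog_alignment()].
#' @param pos 0-based position(s) in the `from` sequence (degapped).
#' @param from `"a"` or `"b"`.
#' @return integer vector of 0-based partner positions (`NA` = gap).
#' @export
map_position <- function(aln, pos, from = c("a", "b")) {
  from <- match.arg(from)
  m <- aln_maps(aln)
  if (from == "a") {
    src_gap <- m$a_gap; src_idx <- m$a_idx
    dst_gap <- m$b_gap; dst_idx <- m$b_idx
  } else {
    src_gap <- m$b_gap; src_idx <- m$b_idx
    dst_gap <- m$a_gap; dst_idx <- m$a_idx
  }
  n_src <- sum(!src_gap)
  if (any(pos < 0L | pos >= n_src)) stop("position outside degapped sequence")
  cols <- which(!src_gap)[pos + 1L]
  out <- dst_idx[cols]
  out[dst_gap[cols]] <- NA_integer_
  as.integer(out)
}

#' Classify m6A peaks as conserved or non-conserved between species
#'
#' Each species-a peak summit is lifted into species-b coordinates through
#' the pairwise ortholog alignment; the peak is `conserved` when a species-b
#' peak summit on the ortholog lies within `tolerance` nt of the mapped
#' position (with `tolerance = 0` this is strict same-column matching), and
#' `non-conserved` otherwise. Peaks on transcripts without a one-to-one
#' ortholog alignment are excluded from the analysis (not labelled).
#'
#' @param peaks_a,peaks_b peak tables with `transcript_id` and `summit`
#'   (any `data.frame`; only those two columns are used).
#' @param alignments list of [ortholog_alignment()]s; matched to peaks by
#'   `id_a` / `id_b`.
#' @param tolerance matching half-width in nt.
#' @return `peaks_a` rows that have an ortholog, with columns `mapped_summit`
#'   and `conserved` appended.
#' @export
classify_conserved <- function(peaks_a, peaks_b, alignments, tolerance = 25L) {
  by_a <- stats::setNames(alignments,
                          vapply(alignments, `[[`, character(1), "id_a"))
  keep <- peaks_a$transcript_id %in% names(by_a)
  out <- peaks_a[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$mapped_summit <- integer(0); out$conserved <- logical(0)
    return(out)
  }
  mapped <- integer(nrow(out)); cons <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    aln <- by_a[[out$transcript_id[i]]]
    # a summit aligned to a gap in b cannot match any b position
    mp <- tryCatch(map_position(aln, out$summit[i], from = "a"),
                   error = function(e) NA_integer_)
    mapped[i] <- mp
    if (is.na(mp)) { cons[i] <- FALSE; next }
    b_summits <- peaks_b$summit[peaks_b$transcript_id == aln$id_b]
    cons[i] <- length(b_summits) > 0 && any(abs(b_summits - mp) <= tolerance)
  }
  out$mapped_summit <- mapped
  out$conserved <- cons
  rownames(out) <- NULL
  out
}
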