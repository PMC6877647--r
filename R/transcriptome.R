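#' Build a transcript table
#'
#' The transcript table is the coordinate backbone of the package: one row per
#' transcript with its sequence and the transcript-coordinate CDS span.
#' Internally all coordinates are 0-based half-open; file writers emit 1-based
#' inclusive coordinates and say so in their headers.
#'
#' @param transcript_id character vector of transcript identifiers (unique).
#' @param gene_id character vector of gene identifiers.
#' @param sequence character vector of transcript sequences over
#'   `{A,C,G,U/T,N}`; normalised to the RNA alphabet (`T -> U`, uppercase)
#'   on construction.
#' @param cds_start 0-based transcript coordinate of the first CDS nucleotide.
#' @param cds_end 0-based exclusive coordinate one past the last nucleotide of
#'   the stop codon.
#' @return A `data.frame` of class `tx_table` with columns `transcript_id`,
#'   `gene_id`, `sequence`, `cds_start`, `cds_end`, `length`.
#' @examples
#' tx_table("t1", "g1", paste(rep("AUGGCU", 20), collapse = ""), 0L, 120L)
#' @export
tx_table <- function(transcript_id, gene_id, sequence, cds_start, cds_end) {
  sequence <- normalize_rna(sequence)
  len <- nchar(sequence)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  stopifnot(
    !anyDuplicated(transcript_id),
    all(cds_start >= 0L), all(cds_start < cds_end), all(cds_end <= len),
    all((cds_end - cds_start) %% 3L == 0L)
  )
  structure(
    data.frame(
      transcript_id = as.character(transcript_id),
      gene_id = as.character(gene_id),
      sequence = sequence,
      cds_start = cds_start,
      cds_end = cds_end,
      length = len,
      stringsAsFactors = FALSE
    ),
    class = c("tx_table", "data.frame")
  )
}

#' Normalise a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and replaces `T` with `U`. `U` and `T` inputs are therefore
#' equivalent everywhere in the package.
#'
#' @param x character vector of sequences.
#' @return character vector over `{A,C,G,U,N}`.
#' @export
normalize_rna <- function(x) {
  chartr("Tt", "Uu", toupper(as.character(x)))
}

tx_row <- function(txs, transcript_id) {
  i <- match(transcript_id, txs$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  txs[i, , drop = FALSE]
}

#' Select one representative isoform per gene
#'
#' For each gene the isoform with the longest CDS is chosen; CDS-length ties
#' are broken by the longest transcript, remaining ties lexicographically by
#' transcript id, making the choice deterministic.
#'
#' @param txs a [tx_table()].
#' @return named character vector mapping `gene_id` to the representative
#'   `transcript_id`.
#' @export
select_representative_transcripts <- function(txs) {
  stopifnot(inherits(txs, "tx_table") || is.data.frame(txs))
  cds_len <- txs$cds_end - txs$cds_start
  ord <- order(txs$gene_id, -cds_len, -txs$length, txs$transcript_id)
  o <- txs[ord, , drop = FALSE]
  keep <- !duplicated(o$gene_id)
  stats::setNames(o$transcript_id[keep], o$gene_id[keep])
}

#' Classify a transcript position into mRNA regions
#'
#' Positions fall into `FIVE_UTR`, `CDS` or `THREE_UTR`; positions inside the
#' start-codon zone (default −15..+100 nt around the first CDS nucleotide) or
#' the stop-codon zone (default −100..+15 nt around the last nucleotide of the
#' stop codon) are labelled `START_PROXIMAL` / `STOP_PROXIMAL` instead, and are
#' excluded from region-level m6A analyses. Both zones are closed intervals
#' and clipped to the transcript.
#'
#' @param tx one row of a [tx_table()] (or the table plus a `transcript_id`).
#' @param pos integer vector of 0-based transcript positions.
#' @param start_zone,stop_zone length-2 integer offsets defining the closed
#'   exclusion intervals around the start codon's first and the stop codon's
#'   last nucleotide.
#' @return character vector of region labels, one per `pos`.
#' @export
classify_position <- function(tx, pos, start_zone = c(-15L, 100L),
                              stop_zone = c(-100L, 15L)) {
  stopifnot(nrow(tx) == 1L)
  len <- tx$length
  if (any(pos < 0L | pos >= len)) stop("position out of transcript bounds")
  cs <- tx$cds_start
  ce <- tx$cds_end
  stop_anchor <- ce - 1L  # last nucleotide of the stop codon
  lab <- ifelse(pos < cs, "FIVE_UTR", ifelse(pos < ce, "CDS", "THREE_UTR"))
  in_stop <- pos >= stop_anchor + stop_zone[1] & pos <= stop_anchor + stop_zone[2]
  in_start <- pos >= cs + start_zone[1] & pos <= cs + start_zone[2]
  lab[in_stop] <- "STOP_PROXIMAL"
  lab[in_start] <- "START_PROXIMAL"  # start zone wins if the two overlap
  lab
}

#' Find RRAC motif adenosines
#'
#' Scans a sequence for the m6A consensus motif RRAC (R = A/G) and returns the
#' 0-based positions of the methylatable adenosine (third motif position).
#' Overlapping motifs are all reported; `N` never matches; `U`/`T` are
#' equivalent.
#'
#' @param sequence a single sequence string.
#' @return sorted integer vector of 0-based A positions (empty if none).
#' @examples
#' find_rrac_sites("GGACU")  # 2
#' @export
find_rrac_sites <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  s <- normalize_rna(sequence)
  m <- gregexpr("(?=[AG][AG]AC)", s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) + 1L  # 1-based motif start -> 0-based A position
}

#' Codon context of a transcript position
#'
#' For a CDS position, reports the in-frame codon containing it and the
#' 1-based position of the nucleotide within that codon; positions outside the
#' CDS get `in_cds = FALSE`.
#'
#' @param tx one row of a [tx_table()].
#' @param pos 0-based transcript position(s).
#' @return `data.frame` with columns `pos`, `in_cds`, `codon`,
#'   `position_in_codon`, `codon_start` (0-based first nucleotide of the
#'   codon, `NA` outside the CDS).
#' @export
codon_context <- function(tx, pos) {
  stopifnot(nrow(tx) == 1L)
  if (any(pos < 0L | pos >= tx$length)) stop("position out of transcript bounds")
  in_cds <- pos >= tx$cds_start & pos < tx$cds_end
  frame <- ifelse(in_cds, (pos - tx$cds_start) %% 3L, NA_integer_)
  codon_start <- ifelse(in_cds, pos - frame, NA_integer_)
  codon <- rep(NA_character_, length(pos))
  if (any(in_cds)) {
    codon[in_cds] <- substring(tx$sequence, codon_start[in_cds] + 1L,
                               codon_start[in_cds] + 3L)
  }
  data.frame(
    pos = as.integer(pos), in_cds = in_cds, codon = codon,
    position_in_codon = as.integer(frame) + 1L,
    codon_start = as.integer(codon_start)
  )
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file of transcript sequences; names up to the first
#'   whitespace are taken as transcript ids.
#' @return named character vector of RNA-normalised sequences.
#' @export
read_transcript_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(normalize_rna(as.character(set)), ids)
}

#' Read a transcript table from a TSV plus FASTA
#'
#' The TSV has 4 columns (`transcript_id`, `gene_id`, `cds_start`, `cds_end`;
#' 0-based half-open CDS span) with a header; sequences come from the FASTA.
#'
#' @param tsv path to the transcript table.
#' @param fasta path to the transcript FASTA.
#' @return a [tx_table()].
#' @export
read_tx_table <- function(tsv, fasta) {
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE, comment.char = "#")
  seqs <- read_transcript_fasta(fasta)
  missing <- setdiff(tab$transcript_id, names(seqs))
  if (length(missing)) stop("transcripts missing from FASTA: ",
                            paste(utils::head(missing), collapse = ", "))
  tx_table(tab$transcript_id, tab$gene_id, seqs[tab$transcript_id],
           tab$cds_start, tab$cds_end)
}

#' Write a transcript table to TSV
#'
#' @param txs a [tx_table()].
#' @param path output path. Coordinates are written 0-based half-open, as
#'   stated in the header comment.
#' @export
write_tx_table <- function(txs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# transcript table; cds_start/cds_end are 0-based half-open", con)
  utils::write.table(
    txs[, c("transcript_id", "gene_id", "cds_start", "cds_end")],
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
}

#' Build a transcript table from a GTF/GFF annotation
#'
#' Uses `exon` and `CDS` features to place each transcript's CDS into
#' transcript coordinates (5'→3' on the annotated strand). The stop codon is
#' assumed included in the CDS features; if the resulting span is not a
#' multiple of 3 and `stop_codon` features are present they are appended.
#' Transcripts without CDS features are dropped with a warning.
#'
#' @param gtf path to a GTF/GFF3 file readable by [rtracklayer::import()].
#' @param sequences named character vector of transcript sequences (as from
#'   [read_transcript_fasta()]).
#' @return a [tx_table()].
#' @export
read_tx_table_gtf <- function(gtf, sequences) {
  gr <- rtracklayer::import(gtf)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  txid <- as.character(meta$transcript_id)
  gid <- as.character(meta$gene_id)

  exons <- gr[type == "exon"]
  cds <- gr[type %in% c("CDS", "stop_codon")]
  if (!length(cds)) stop("no CDS features in ", gtf)

  per_tx <- split(seq_along(exons), txid[type == "exon"])
  cds_tx <- split(seq_along(cds), as.character(S4Vectors::mcols(cds)$transcript_id))

  rows <- lapply(names(cds_tx), function(tid) {
    ei <- per_tx[[tid]]
    if (is.null(ei)) return(NULL)
    ex <- exons[ei]
    minus <- as.character(BiocGenerics::strand(ex))[1] == "-"
    ex <- ex[order(BiocGenerics::start(ex), decreasing = minus)]
    starts <- BiocGenerics::start(ex); ends <- BiocGenerics::end(ex)
    offs <- cumsum(c(0L, ends - starts + 1L))  # tx offset of each exon start
    g2t <- function(gpos) {  # genomic position -> 0-based transcript coord
      k <- which(gpos >= starts & gpos <= ends)[1]
      if (is.na(k)) return(NA_integer_)
      if (minus) offs[k] + (ends[k] - gpos) else offs[k] + (gpos - starts[k])
    }
    cr <- cds[cds_tx[[tid]]]
    gpos <- c(BiocGenerics::start(cr), BiocGenerics::end(cr))
    tpos <- vapply(gpos, g2t, integer(1))
    if (anyNA(tpos)) return(NULL)
    data.frame(
      transcript_id = tid,
      gene_id = as.character(S4Vectors::mcols(cr)$gene_id)[1],
      cds_start = min(tpos), cds_end = max(tpos) + 1L,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  dropped <- setdiff(unique(txid[!is.na(txid)]), tab$transcript_id)
  if (length(dropped)) {
    warning(length(dropped), " transcript(s) without usable CDS dropped")
  }
  tab <- tab[tab$transcript_id %in% names(sequences), , drop = FALSE]
  tx_table(tab$transcript_id, tab$gene_id, sequences[tab$transcript_id],
           tab$cds_start, tab$cds_end)
}
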