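#' Minimum free energy of one RNA sequence
#'
#' Pluggable folding backend. `"vienna"` shells out to the `RNAfold` binary
#' (thermodynamic nearest-neighbour model, kcal/mol); `"nussinov"` is a
#' built-in base-pair-maximization folder (Watson-Crick plus G:U wobble,
#' minimum hairpin loop of 3 nt, a fixed −1 pseudo-energy per pair) that
#' keeps the package self-contained and deterministic; `"auto"` picks
#' `"vienna"` when the binary is on the `PATH`, else `"nussinov"`. Both
#' backends return values <= 0 and are invariant under U/T relabeling.
#'
#' @param sequences character vector of sequences.
#' @param backend `"auto"`, `"vienna"` or `"nussinov"`.
#' @return numeric vector of MFE values (<= 0); attribute `backend` records
#'   the backend actually used.
#' @export
fold_mfe <- function(sequences, backend = c("auto", "vienna", "nussinov")) {
  backend <- match.arg(backend)
  if (backend == "auto") {
    backend <- if (nzchar(Sys.which("RNAfold"))) "vienna" else "nussinov"
  }
  sequences <- normalize_rna(sequences)
  out <- switch(backend,
    vienna = vienna_mfe(sequences),
    nussinov = vapply(sequences, nussinov_mfe, numeric(1), USE.NAMES = FALSE)
  )
  structure(out, backend = backend)
}

vienna_mfe <- function(sequences) {
  if (!length(sequences)) return(numeric(0))
  res <- suppressWarnings(
    system2("RNAfold", args = c("--noPS"), input = sequences, stdout = TRUE)
  )
  vals <- regmatches(res, regexpr("\\(\\s*-?[0-9]+\\.[0-9]+\\)$", res))
  if (length(vals) != length(sequences)) {
    stop("RNAfold returned ", length(vals), " energies for ",
         length(sequences), " sequences")
  }
  as.numeric(gsub("[()\\s]", "", vals, perl = TRUE))
}

pairable <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

nussinov_mfe <- function(sequence, min_loop = 3L, pair_energy = -1) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < min_loop + 2L) return(0)
  dp <- matrix(0L, n, n)
  for (l in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - l)) {
      j <- i + l
      best <- dp[i, j - 1L]
      # j pairs with some k in [i, j - min_loop - 1]
      ks <- i:(j - min_loop - 1L)
      ks <- ks[pairable(s[ks], s[j])]
      if (length(ks)) {
        left <- ifelse(ks > i, dp[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == i] <- 0L
        inner <- dp[cbind(ks + 1L, j - 1L)]
        inner[ks + 1L > j - 1L] <- 0L
        best <- max(best, max(left + inner + 1L))
      }
      dp[i, j] <- best
    }
  }
  pair_energy * dp[1L, n]
}

#' Sliding-window MFE profile along a sequence
#'
#' Folds every window of `window` nt (default 30) at `step` nt intervals
#' (default 3); the window's central position (`start + window %/% 2`) is the
#' alignment coordinate of each MFE value.
#'
#' @param sequence one sequence string (length >= `window`).
#' @param window,step window geometry in nt.
#' @param backend see [fold_mfe()].
#' @return `data.frame` with `start`, `end` (0-based half-open), `center`,
#'   `mfe`; attribute `backend`.
#' @export
sliding_mfe <- function(sequence, window = 30L, step = 3L, backend = "auto") {
  s <- normalize_rna(sequence)
  n <- nchar(s)
  if (n < window) stop("sequence shorter than the folding window")
  starts <- seq.int(0L, n - window, by = step)
  seqs <- substring(s, starts + 1L, starts + window)
  mfe <- fold_mfe(seqs, backend)
  structure(
    data.frame(start = starts, end = starts + window,
               center = starts + window %/% 2L, mfe = as.numeric(mfe)),
    backend = attr(mfe, "backend")
  )
}

#' Dinucleotide-preserving sequence shuffles
#'
#' Generates `n` random shuffles of a sequence that each conserve the exact
#' dinucleotide count vector of the input (and hence the mononucleotide
#' counts and terminal residues), using an Eulerian-path
#' (Altschul-Erickson-style) shuffle: the sequence is a walk on the
#' first-order transition multigraph, the last outgoing edge of each vertex
#' is chosen so the remaining edges still admit a full walk, and all other
#' edge orders are permuted uniformly. Sequences of length < 2 are returned
#' unchanged.
#'
#' @param sequence one sequence string.
#' @param n number of shuffles.
#' @param seed integer seed making the output deterministic.
#' @return character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n = 30L, seed = 1L) {
  s <- strsplit(normalize_rna(sequence), "")[[1]]
  if (length(s) < 2L) return(rep(paste(s, collapse = ""), n))
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) euler_shuffle(s), character(1))
  })
}

euler_shuffle <- function(s) {
  n <- length(s)
  first <- s[1]; last <- s[n]
  verts <- unique(s)
  adj <- split(s[-1], factor(s[-n], levels = verts))
  nonempty <- names(adj)[lengths(adj) > 0]
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last || !length(adj[[v]])) NA_character_
      else adj[[v]][sample.int(length(adj[[v]]), 1L)]
    }, character(1))
    names(last_edge) <- verts
    ok <- TRUE
    for (v in nonempty) {
      if (v == last) next
      cur <- v; steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        if (is.na(cur)) break
        steps <- steps + 1L
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  walk_adj <- lapply(verts, function(v) {
    e <- adj[[v]]
    if (!length(e)) return(character(0))
    if (v != last) {
      drop <- which(e == last_edge[[v]])[1]
      rest <- e[-drop]
      c(rest[sample.int(length(rest))], last_edge[[v]])
    } else {
      e[sample.int(length(e))]
    }
  })
  names(walk_adj) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- walk_adj[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide count vector of a sequence
#'
#' @param sequence one sequence string.
#' @return named integer vector of overlapping dinucleotide counts.
#' @export
dinucleotide_counts <- function(sequence) {
  s <- strsplit(normalize_rna(sequence), "")[[1]]
  if (length(s) < 2L) return(integer(0))
  table(paste0(s[-length(s)], s[-1]))
}

#' Shuffle z-score of a sequence's folding energy
#'
#' Folds the native sequence and `n` dinucleotide-preserving shuffles with
#' the same backend; z = (native − mean(shuffles)) / sd(shuffles). A strongly
#' negative z indicates more structure than expected from the sequence's
#' dinucleotide composition. When the shuffle MFEs are all equal (sd 0) the
#' z-score is undefined and returned as `NA`.
#'
#' @param sequence one sequence string.
#' @param n number of shuffles.
#' @param seed shuffle seed.
#' @param backend see [fold_mfe()].
#' @return list with `native_mfe`, `shuffle_mean`, `shuffle_sd`, `z`.
#' @export
mfe_zscore <- function(sequence, n = 30L, seed = 1L, backend = "auto") {
  native <- as.numeric(fold_mfe(sequence, backend))
  shuf <- dinucleotide_shuffle(sequence, n = n, seed = seed)
  sm <- as.numeric(fold_mfe(shuf, backend))
  sdv <- stats::sd(sm)
  list(native_mfe = native, shuffle_mean = mean(sm), shuffle_sd = sdv,
       z = if (is.na(sdv) || sdv == 0) NA_real_ else (native - mean(sm)) / sdv)
}

#' Sliding-window GC-content profile
#'
#' @param sequence one sequence string (length >= `window`).
#' @param window,step window geometry in nt.
#' @return `data.frame` with `start`, `end`, `center`, `gc` (fraction in
#'   `[0,1]`).
#' @export
gc_profile <- function(sequence, window = 30L, step = 3L) {
  s <- strsplit(normalize_rna(sequence), "")[[1]]
  n <- length(s)
  if (n < window) stop("sequence shorter than the window")
  is_gc <- cumsum(c(0L, s %in% c("G", "C")))
  starts <- seq.int(0L, n - window, by = step)
  data.frame(start = starts, end = starts + window,
             center = starts + window %/% 2L,
             gc = (is_gc[starts + window + 1L] - is_gc[starts + 1L]) / window)
}

#' Aggregate reactivity around anchors
#'
#' Positionwise mean reactivity over `-flank..+flank` relative to each
#' anchor, ignoring missing values (`NA`); offsets falling outside a
#' transcript contribute nothing (clipping is counted). Also returns the
#' per-anchor mean reactivity for group comparisons.
#'
#' @param reactivity a `REACTIVITY` [coverage_track()] (values in `[0,1]`,
#'   `NA` = missing).
#' @param anchors `data.frame` with `transcript_id`, `pos`.
#' @param flank window half-width in nt.
#' @return list: `profile` (`offset`, `mean`, `n`), `region_means`
#'   (`transcript_id`, `pos`, `mean`, `n_clipped` attribute on the list).
#' @export
aggregate_reactivity <- function(reactivity, anchors, flank = 500L) {
  offs <- seq.int(-flank, flank)
  acc <- numeric(length(offs))
  cnt <- integer(length(offs))
  region_means <- numeric(nrow(anchors))
  n_clipped <- 0L
  for (i in seq_len(nrow(anchors))) {
    x <- reactivity[[anchors$transcript_id[i]]]
    if (is.null(x)) { region_means[i] <- NA_real_; next }
    a <- anchors$pos[i]
    idx <- a + offs
    inside <- idx >= 0L & idx <= length(x) - 1L
    if (!all(inside)) n_clipped <- n_clipped + 1L
    vals <- rep(NA_real_, length(offs))
    vals[inside] <- x[idx[inside] + 1L]
    use <- !is.na(vals)
    acc[use] <- acc[use] + vals[use]
    cnt[use] <- cnt[use] + 1L
    region_means[i] <- if (any(use)) mean(vals[use]) else NA_real_
  }
  profile <- data.frame(offset = offs,
                        mean = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
                        n = cnt)
  out <- list(profile = profile,
              region_means = data.frame(transcript_id = anchors$transcript_id,
                                        pos = anchors$pos, mean = region_means,
                                        stringsAsFactors = FALSE))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Gini index of a non-negative signal
#'
#' Mean absolute difference divided by twice the mean, computed from the
#' sorted closed form; ranges from 0 (perfect equality) to `1 - 1/n` (all
#' signal at one position). All-zero input has no defined inequality and
#' yields `NA`. Missing values are dropped.
#'
#' @param values non-negative numeric vector (n >= 1).
#' @return the Gini coefficient.
#' @examples
#' gini(c(0, 1))  # 0.5
#' @export
gini <- function(values) {
  x <- values[!is.na(values)]
  stopifnot(length(x) >= 1L, all(x >= 0))
  if (all(x == 0)) return(NA_real_)
  n <- length(x)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs) / (n * sum(xs))) - (n + 1) / n
}

#' Methylated-region windows around m6A anchors
#'
#' The methylated region of a site spans −`upstream`..+`downstream` nt
#' (default −400..+100) around the methylated position, clipped to the
#' transcript. Control spans are built the same way around the non-methylated
#' RRAC adenosines of the same transcripts; transcripts with no
#' non-methylated RRAC contribute no control (reported via attribute
#' `n_without_control`).
#'
#' @param anchors `data.frame` with `transcript_id`, `pos` (methylated
#'   adenosines).
#' @param txs a [tx_table()].
#' @param upstream,downstream span extents in nt.
#' @return list with `methylated` and `control` span tables
#'   (`transcript_id`, `anchor`, `start`, `end`; 0-based half-open).
#' @export
methylated_region_windows <- function(anchors, txs, upstream = 400L,
                                      downstream = 100L) {
  span_of <- function(tid, pos) {
    len <- txs$length[match(tid, txs$transcript_id)]
    data.frame(transcript_id = tid, anchor = pos,
               start = pmax(0L, pos - upstream),
               end = pmin(len, pos + downstream + 1L),
               stringsAsFactors = FALSE)
  }
  meth <- span_of(anchors$transcript_id, anchors$pos)
  ctrl_rows <- list()
  n_without <- 0L
  for (tid in unique(anchors$transcript_id)) {
    tx <- tx_row(txs, tid)
    m_pos <- anchors$pos[anchors$transcript_id == tid]
    other <- setdiff(find_rrac_sites(tx$sequence), m_pos)
    if (!length(other)) {
      n_without <- n_without + 1L
      message("no non-methylated RRAC on ", tid, "; no control span")
      next
    }
    ctrl_rows[[tid]] <- span_of(rep(tid, length(other)), other)
  }
  ctrl <- do.call(rbind, ctrl_rows)
  if (is.null(ctrl)) ctrl <- meth[0, , drop = FALSE]
  rownames(meth) <- rownames(ctrl) <- NULL
  out <- list(methylated = meth, control = ctrl)
  attr(out, "n_without_control") <- n_without
  out
}
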