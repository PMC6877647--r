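# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as direct nested loops with no shared code
# with the package internals.

bf_find_rrac <- function(sequence) {
  s <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  hits <- integer(0)
  if (length(s) >= 4) {
    for (i in 1:(length(s) - 3)) {
      if (s[i] %in% c("A", "G") && s[i + 1] %in% c("A", "G") &&
          s[i + 2] == "A" && s[i + 3] == "C") {
        hits <- c(hits, i + 1L)  # 0-based position of the A
      }
    }
  }
  hits
}

bf_pom_windows <- function(x, window = 50L, step = 25L, minmax = 10) {
  out <- list()
  if (length(x) < window) return(out)
  med <- median(x)
  if (med == 0) return(out)
  s <- 0L
  while (s + window <= length(x)) {
    w <- x[(s + 1):(s + window)]
    if (max(w) > minmax) {
      out[[length(out) + 1]] <- list(start = s, end = s + window,
                                     pom = mean(w) / med)
    }
    s <- s + step
  }
  out
}

bf_call_peaks <- function(ip, input, tx, window = 50L, step = 25L,
                          minmax = 10, pom_thr = 3, poi_thr = 3) {
  w_ip <- Filter(function(w) w$pom > pom_thr,
                 bf_pom_windows(ip, window, step, minmax))
  w_in <- Filter(function(w) w$pom > pom_thr,
                 bf_pom_windows(input, window, step, minmax))
  survivors <- list()
  for (w in w_ip) {
    killed <- FALSE
    for (v in w_in) {
      if (length(intersect(seq(w$start, w$end - 1), seq(v$start, v$end - 1)))) {
        killed <- TRUE
      }
    }
    if (!killed) survivors[[length(survivors) + 1]] <- w
  }
  if (!length(survivors)) return(NULL)
  # cluster by repeated pairwise merging of overlapping spans
  spans <- lapply(survivors, function(w) c(w$start, w$end))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(spans)) {
      for (j in seq_along(spans)) {
        if (i >= j || is.null(spans[[i]]) || is.null(spans[[j]])) next
        a <- spans[[i]]; b <- spans[[j]]
        if (length(intersect(seq(a[1], a[2] - 1), seq(b[1], b[2] - 1)))) {
          spans[[i]] <- c(min(a[1], b[1]), max(a[2], b[2]))
          spans[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  spans <- Filter(Negate(is.null), spans)
  spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
  med_ip <- median(ip); med_in <- median(input)
  rrac <- bf_find_rrac(tx$sequence)
  rows <- list()
  for (sp in spans) {
    idx <- (sp[1] + 1):sp[2]
    pom_ip <- mean(ip[idx]) / med_ip
    if (med_in == 0) next
    pom_in <- mean(input[idx]) / med_in
    poi <- if (pom_in > 0) pom_ip / pom_in else Inf
    if (!(poi > poi_thr)) next
    summit <- idx[which.max(ip[idx])] - 1L
    residue <- NA_integer_
    if (length(rrac)) {
      d <- abs(rrac - summit)
      residue <- min(rrac[d == min(d)])
    }
    rows[[length(rows) + 1]] <- data.frame(
      cluster_start = sp[1], cluster_end = sp[2], summit = summit,
      m6a_residue = residue, pom_ip = pom_ip, pom_input = pom_in, poi = poi
    )
  }
  if (!length(rows)) NULL else do.call(rbind, rows)
}

bf_pausing_windows <- function(ctrl, kd, cds_start, cds_end, window = 30L,
                               step = 3L, pseudo = 0.5) {
  mc <- mean(ctrl[(cds_start + 1):cds_end])
  mk <- mean(kd[(cds_start + 1):cds_end])
  if (mc == 0 || mk == 0 || length(ctrl) < window) return(NULL)
  rows <- list()
  s <- 0L
  while (s + window <= length(ctrl)) {
    dc <- (sum(ctrl[(s + 1):(s + window)]) + pseudo) / window / mc
    dk <- (sum(kd[(s + 1):(s + window)]) + pseudo) / window / mk
    rows[[length(rows) + 1]] <- data.frame(start = s, fold_change = dk / dc)
    s <- s + step
  }
  do.call(rbind, rows)
}

bf_gini <- function(x) {
  n <- length(x)
  if (all(x == 0)) return(NA_real_)
  tot <- 0
  for (i in 1:n) for (j in 1:n) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

# random-track generator for oracle-equivalence tests: NB background plus
# occasional planted box spikes so all caller branches are exercised
random_test_track <- function(len) {
  x <- rnbinom(len, mu = runif(1, 2, 30), size = 5)
  if (runif(1) < 0.7) {
    for (k in seq_len(sample(1:2, 1))) {
      w <- sample(20:min(80, len - 10), 1)
      s <- sample(0:(len - w), 1)
      x[(s + 1):(s + w)] <- x[(s + 1):(s + w)] + rpois(w, runif(1, 10, 60))
    }
  }
  as.numeric(x)
}

random_test_tx <- function(len) {
  cds_len <- max(3L, (len %/% 2) - (len %/% 2) %% 3L)
  cds_start <- min(len - cds_len, len %/% 4)
  tx_table(paste0("rt", sample.int(1e6, 1)), "g",
           paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                 collapse = ""),
           cds_start, cds_start + cds_len)
}

# random gapped pairwise alignment with no all-gap columns
random_alignment <- function(n_cols = 120) {
  a <- character(n_cols); b <- character(n_cols)
  for (i in seq_len(n_cols)) {
    r <- runif(1)
    na <- sample(c("A", "C", "G", "U"), 1)
    nb <- sample(c("A", "C", "G", "U"), 1)
    if (r < 0.15) { a[i] <- "-"; b[i] <- nb }
    else if (r < 0.3) { a[i] <- na; b[i] <- "-" }
    else { a[i] <- na; b[i] <- nb }
  }
  if (all(a == "-")) a[1] <- "A"
  if (all(b == "-")) b[1] <- "A"
  ortholog_alignment("txA", "txB", paste(a, collapse = ""),
                     paste(b, collapse = ""))
}

small_sim <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(n_transcripts = 8L, n_methylated_sites = 5L,
         n_structured_regions = 2L, n_relief_regions = 2L,
         cds_range = c(600L, 900L), seed = seed),
    list(...)
  )
  do.call(sim_params, args)
}
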