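# Sliding-window POM/POI peak calling.
#
# POM (peak over median): mean coverage in a 50-nt window divided by the
# median coverage of the whole transcript (zeros included).  POI (peak over
# input): POM of the IP sample over POM of the input sample at the same
# window.  Windows slide in 25-nt steps; the terminal window is truncated at
# the transcript end.

#' Default m6A motif set
#'
#' The three sequence motifs reported for bacterial mRNA m6A. Matching is
#' exact and strand-aware (transcript sense). \code{"UGGCAG"} circulates as a
#' variant spelling of the second motif in parts of the literature; the
#' default here is \code{"UGCCAG"} and the set is user-configurable
#' everywhere it is consumed.
#'
#' @return Character vector of RNA-alphabet motifs.
#' @export
m6a_motifs <- function() c("GCCAU", "UGCCAG", "CAGAUC")

# Window start positions for a transcript of length len: 0, 25, 50, ...
# A new window opens only while the previous one has not yet reached the
# transcript end, so the final window is truncated rather than followed by a
# sliver (length 60 -> [0,50) and [25,60), not [50,60)).
.window_starts <- function(len, w = 50L, step = 25L) {
  if (len <= 0) return(integer(0))
  starts <- integer(0)
  s <- 0L
  repeat {
    starts <- c(starts, s)
    if (s + w >= len) break
    s <- s + step
  }
  starts
}

#' Compute peak-over-median (POM) scores for one coverage track
#'
#' Slides a window of \code{w} nt in steps of \code{step} nt along a
#' transcript-oriented depth vector and scores each window as the ratio of
#' its mean coverage to the transcript-wide median coverage (zeros included).
#' The terminal window is truncated at the transcript end; windows shorter
#' than \code{min_window} nt are skipped. Transcripts whose median coverage
#' is 0 have no defined POM: under the default \code{"drop"} policy all their
#' windows are excluded; under \code{"pseudo"} the smallest positive per-base
#' depth stands in for the median.
#'
#' @param depth Numeric vector of non-negative per-base depths,
#'   transcript-oriented.
#' @param w Window width in nt (default 50).
#' @param step Slide step in nt (default 25).
#' @param min_window Minimum scored window width in nt (default 10).
#' @param zero_median_policy \code{"drop"} (default) or \code{"pseudo"}.
#' @param transcript_id Optional id recorded in the result.
#' @return data.frame with columns \code{transcript_id}, \code{start},
#'   \code{end} (half-open transcript coords), \code{mean_cov},
#'   \code{median_cov}, \code{pom}.
#' @examples
#' compute_pom(rep(20, 200))$pom          # all 1: mean equals median
#' compute_pom(c(rep(90, 50), rep(10, 150)))$pom[1]  # 9
#' @export
compute_pom <- function(depth, w = 50L, step = 25L, min_window = 10L,
                        zero_median_policy = c("drop", "pseudo"),
                        transcript_id = NA_character_) {
  zero_median_policy <- match.arg(zero_median_policy)
  stopifnot(all(depth >= 0))
  len <- length(depth)
  starts <- .window_starts(len, w, step)
  ends <- pmin(starts + w, len)
  keep <- (ends - starts) >= min_window
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), mean_cov = numeric(0),
                      median_cov = numeric(0), pom = numeric(0)))
  }
  med <- median(depth)
  if (med == 0) {
    pos <- depth[depth > 0]
    if (zero_median_policy == "pseudo" && length(pos) > 0) {
      med <- min(pos)
    } else {
      return(data.frame(transcript_id = character(0), start = integer(0),
                        end = integer(0), mean_cov = numeric(0),
                        median_cov = numeric(0), pom = numeric(0)))
    }
  }
  means <- vapply(seq_along(starts),
                  function(i) mean(depth[(starts[i] + 1L):ends[i]]),
                  numeric(1))
  data.frame(transcript_id = transcript_id, start = as.integer(starts),
             end = as.integer(ends), mean_cov = means, median_cov = med,
             pom = means / med, stringsAsFactors = FALSE)
}

#' Filter window scores on coverage and POM
#'
#' A window is retained only if its mean coverage is at least
#' \code{min_cov} \emph{and} its POM score is at least \code{min_pom};
#' failing either criterion discards it. "Coverage" is the window mean, the
#' unit used throughout the calling procedure.
#'
#' @param scores data.frame from \code{\link{compute_pom}}.
#' @param min_cov Minimum window mean coverage (default 10).
#' @param min_pom Minimum POM score (default 3).
#' @return The retained rows.
#' @export
filter_windows <- function(scores, min_cov = 10, min_pom = 3) {
  scores[scores$mean_cov >= min_cov & scores$pom >= min_pom, , drop = FALSE]
}

.empty_peaks <- function() {
  pk <- data.frame(transcript_id = character(0), start = integer(0),
                   end = integer(0), pom_ip = numeric(0),
                   pom_input = numeric(0), poi = numeric(0),
                   replicates = character(0), motifs = character(0),
                   stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  pk
}

# Coalesce retained windows (data.frame with start/end and scores) on one
# transcript into peaks; the reported scores are those of the max-POI window.
.coalesce_windows <- function(wins, tx) {
  ir <- IRanges::IRanges(start = wins$start + 1L, end = wins$end)
  red <- IRanges::reduce(ir)
  ov <- IRanges::findOverlaps(ir, red)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  out <- lapply(seq_along(red), function(j) {
    sub <- wins[grp == j, , drop = FALSE]
    best <- which.max(sub$poi)
    data.frame(transcript_id = tx,
               start = IRanges::start(red)[j] - 1L,
               end = IRanges::end(red)[j],
               pom_ip = sub$pom_ip[best], pom_input = sub$pom_input[best],
               poi = max(sub$poi), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call enrichment peaks from matched IP and input coverage (one replicate)
#'
#' Implements the POM/POI procedure: (1) score 50-nt windows (25-nt step) by
#' POM separately in IP and input; (2) candidate windows are those passing
#' the coverage/POM filter in the IP sample; (3) windows that also pass the
#' filter in the input sample are discarded as shared background; (4) the
#' peak-over-input score POI = POM_IP / POM_input is computed on the
#' survivors using the raw input POM for that window, whatever its magnitude
#' (candidates whose input POM is 0 or undefined are dropped with a warning
#' rather than assigned infinite POI); (5) windows with POI strictly greater
#' than \code{min_poi} are retained and overlapping or adjacent retained
#' windows on a transcript are coalesced into one peak scored by its maximum
#' window POI. Transcripts shorter than \code{step} are skipped.
#'
#' @param ip,input \code{coverage_set} objects over the same transcripts.
#' @param w,step Window width and slide step (nt).
#' @param min_cov,min_pom Window filter thresholds (see
#'   \code{\link{filter_windows}}).
#' @param min_poi POI retention threshold; strictly greater than (default 3).
#' @param zero_median_policy Passed to \code{\link{compute_pom}}.
#' @param quiet Suppress per-transcript messages.
#' @return A \code{peak_set} data.frame: \code{transcript_id}, \code{start},
#'   \code{end}, \code{pom_ip}, \code{pom_input}, \code{poi},
#'   \code{replicates}, \code{motifs}.
#' @export
call_peaks <- function(ip, input, w = 50L, step = 25L, min_cov = 10,
                       min_pom = 3, min_poi = 3,
                       zero_median_policy = c("drop", "pseudo"),
                       quiet = TRUE) {
  zero_median_policy <- match.arg(zero_median_policy)
  stopifnot(inherits(ip, "coverage_set"), inherits(input, "coverage_set"))
  txs <- sort(intersect(names(ip$depth), names(input$depth)))
  peaks <- list()
  for (tx in txs) {
    dip <- ip$depth[[tx]]
    din <- input$depth[[tx]]
    if (length(dip) != length(din)) {
      stop("IP and input depth vectors differ in length for ", tx)
    }
    if (length(dip) < step) {
      if (!quiet) message("skipping ", tx, ": shorter than window step")
      next
    }
    sip <- compute_pom(dip, w, step, zero_median_policy = zero_median_policy,
                       transcript_id = tx)
    if (nrow(sip) == 0) next
    sin_ <- compute_pom(din, w, step, zero_median_policy = zero_median_policy,
                        transcript_id = tx)
    cand <- filter_windows(sip, min_cov, min_pom)
    if (nrow(cand) == 0) next
    shared_in <- filter_windows(sin_, min_cov, min_pom)
    shared <- cand$start %in% shared_in$start
    cand <- cand[!shared, , drop = FALSE]
    if (nrow(cand) == 0) next
    pin <- sin_$pom[match(cand$start, sin_$start)]
    undef <- is.na(pin) | pin == 0
    if (any(undef)) {
      warning("dropping ", sum(undef), " candidate window(s) with undefined ",
              "input POM on ", tx, call. = FALSE)
      cand <- cand[!undef, , drop = FALSE]
      pin <- pin[!undef]
    }
    if (nrow(cand) == 0) next
    cand$pom_ip <- cand$pom
    cand$pom_input <- pin
    cand$poi <- cand$pom_ip / cand$pom_input
    cand <- cand[cand$poi > min_poi, , drop = FALSE]
    if (nrow(cand) == 0) next
    peaks[[tx]] <- .coalesce_windows(cand, tx)
  }
  if (length(peaks) == 0) return(.empty_peaks())
  pk <- do.call(rbind, peaks)
  rownames(pk) <- NULL
  pk$replicates <- ip$replicate_id
  pk$motifs <- NA_character_
  class(pk) <- c("peak_set", "data.frame")
  pk
}

#' Merge peak sets from biological replicates into one set of unique peaks
#'
#' Takes the union of per-replicate peaks; overlapping or adjacent intervals
#' on a transcript are coalesced into one peak that carries the union of the
#' contributing replicate ids and the maximum POI.
#'
#' @param peaksets List of \code{peak_set} objects from the same condition.
#' @return A merged \code{peak_set}.
#' @export
merge_replicates <- function(peaksets) {
  stopifnot(is.list(peaksets), length(peaksets) >= 1)
  all_pk <- do.call(rbind, lapply(peaksets, as.data.frame))
  if (is.null(all_pk) || nrow(all_pk) == 0) return(.empty_peaks())
  out <- list()
  for (tx in sort(unique(all_pk$transcript_id))) {
    sub <- all_pk[all_pk$transcript_id == tx, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    merged <- lapply(seq_along(red), function(j) {
      s <- sub[grp == j, , drop = FALSE]
      best <- which.max(s$poi)
      reps <- sort(unique(unlist(strsplit(s$replicates[!is.na(s$replicates)], ","))))
      data.frame(transcript_id = tx,
                 start = IRanges::start(red)[j] - 1L,
                 end = IRanges::end(red)[j],
                 pom_ip = s$pom_ip[best], pom_input = s$pom_input[best],
                 poi = max(s$poi),
                 replicates = paste(reps, collapse = ","),
                 motifs = NA_character_, stringsAsFactors = FALSE)
    })
    out[[tx]] <- do.call(rbind, merged)
  }
  pk <- do.call(rbind, out)
  rownames(pk) <- NULL
  class(pk) <- c("peak_set", "data.frame")
  pk
}

#' Scan a transcript sequence for exact motif occurrences
#'
#' Exact, overlap-tolerant matching of RNA motifs against the transcript
#' sense strand. T is transliterated to U before matching.
#'
#' @param sequence Character scalar over \{A,C,G,U\} (or T, transliterated).
#' @param motifs Character vector of motifs (default \code{\link{m6a_motifs}}).
#' @return data.frame with columns \code{motif} and \code{offset} (0-based),
#'   sorted by offset.
#' @examples
#' scan_motifs("UGCCAUGCCAU", "GCCAU")  # offsets 1 and 6, overlapping
#' @export
scan_motifs <- function(sequence, motifs = m6a_motifs()) {
  stopifnot(length(sequence) == 1)
  seq_u <- chartr("Tt", "Uu", toupper(sequence))
  if (grepl("[^ACGU]", seq_u)) {
    stop("sequence contains characters outside the A/C/G/U alphabet")
  }
  subject <- Biostrings::RNAString(seq_u)
  hits <- lapply(motifs, function(m) {
    mm <- Biostrings::matchPattern(Biostrings::RNAString(chartr("Tt", "Uu", toupper(m))),
                                   subject)
    if (length(mm) == 0) return(NULL)
    data.frame(motif = m, offset = Biostrings::start(mm) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(motif = character(0), offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$motif), , drop = FALSE]
}

#' Restrict a peak set to motif-containing peaks
#'
#' A peak is retained only when at least one motif occurrence lies entirely
#' within its half-open interval \code{[start, end)}; a motif straddling a
#' peak boundary does not count. Matched motifs and offsets are recorded on
#' the retained peaks.
#'
#' @param peaks A \code{peak_set} in transcript coordinates.
#' @param sequences Named character vector of transcript sequences (RNA
#'   alphabet; see \code{\link{transcript_sequences}}).
#' @param motifs Motif set (default \code{\link{m6a_motifs}}).
#' @return The motif-containing subset, with a filled \code{motifs} column
#'   (\code{"motif@offset"} entries, semicolon-separated).
#' @export
filter_peaks_by_motif <- function(peaks, sequences, motifs = m6a_motifs()) {
  if (nrow(peaks) == 0) return(peaks)
  missing_tx <- setdiff(unique(peaks$transcript_id), names(sequences))
  if (length(missing_tx) > 0) {
    stop("no sequence available for transcript(s): ",
         paste(missing_tx, collapse = ", "))
  }
  hits_by_tx <- lapply(
    setNames(nm = unique(peaks$transcript_id)),
    function(tx) scan_motifs(sequences[[tx]], motifs))
  keep <- logical(nrow(peaks))
  ann <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    h <- hits_by_tx[[peaks$transcript_id[i]]]
    inside <- h[h$offset >= peaks$start[i] &
                  h$offset + nchar(h$motif) <= peaks$end[i], , drop = FALSE]
    keep[i] <- nrow(inside) > 0
    if (keep[i]) {
      ann[i] <- paste(paste0(inside$motif, "@", inside$offset), collapse = ";")
    }
  }
  out <- peaks[keep, , drop = FALSE]
  out$motifs <- ann[keep]
  rownames(out) <- NULL
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x), " peak(s) on ",
      length(unique(x$transcript_id)), " transcript(s)\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
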