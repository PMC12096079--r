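# Cross-cutting statistics: replicate overlap, cross-method concordance,
# metagene motif-ratio profiles, expression normalization/grouping, and
# recovery metrics against planted truth.

#' Overlap of two transcript-id sets with percent shared
#'
#' percent_shared = 100 * |intersection| / |total|. The denominator is, by
#' default, the union of the two sets (a symmetric statistic); per-set
#' denominators are available for reproducing asymmetric reports.
#'
#' @param set_a,set_b Character vectors of transcript ids.
#' @param denominator \code{"union"} (default), \code{"first"} or
#'   \code{"second"}.
#' @return List with \code{n_a}, \code{n_b}, \code{n_shared}, \code{n_union},
#'   \code{percent_shared} (NA when both sets are empty).
#' @export
transcript_overlap <- function(set_a, set_b,
                               denominator = c("union", "first", "second")) {
  denominator <- match.arg(denominator)
  a <- unique(set_a); b <- unique(set_b)
  shared <- intersect(a, b)
  uni <- union(a, b)
  denom <- switch(denominator, union = length(uni), first = length(a),
                  second = length(b))
  list(n_a = length(a), n_b = length(b), n_shared = length(shared),
       n_union = length(uni),
       percent_shared = if (denom == 0) NA_real_
                        else 100 * length(shared) / denom)
}

#' Count peaks encompassing base-resolution sites
#'
#' Cross-method concordance: a site lies in a peak when
#' \code{start <= pos < end} on the same transcript (half-open convention;
#' a site exactly at the peak end is outside). A peak holding several sites
#' counts once in \code{n_peaks_with_site} and once per site in
#' \code{n_sites_in_peaks}.
#'
#' @param peaks A \code{peak_set} (typically the unfiltered replicate-merged
#'   set, i.e. all POI > 3 peaks before motif selection).
#' @param sites An \code{etam_sites} table (called sites are used) or a
#'   data.frame with \code{transcript_id} and \code{pos}.
#' @return List with \code{n_peaks_with_site} and \code{n_sites_in_peaks}.
#' @export
peaks_encompassing_sites <- function(peaks, sites) {
  if ("called" %in% names(sites)) sites <- sites[sites$called, , drop = FALSE]
  if (nrow(peaks) == 0 || nrow(sites) == 0) {
    return(list(n_peaks_with_site = 0L, n_sites_in_peaks = 0L))
  }
  n_peaks <- 0L; n_sites <- 0L
  for (i in seq_len(nrow(peaks))) {
    s <- sites[sites$transcript_id == peaks$transcript_id[i] &
                 sites$pos >= peaks$start[i] & sites$pos < peaks$end[i], ,
               drop = FALSE]
    if (nrow(s) > 0) {
      n_peaks <- n_peaks + 1L
      n_sites <- n_sites + nrow(s)
    }
  }
  list(n_peaks_with_site = n_peaks, n_sites_in_peaks = n_sites)
}

# Motif occurrences with transcript-relative positions and modified flag.
# A motif is "modified" when it lies entirely inside a called peak.
.motif_positions <- function(peaks, sequences, annotation,
                             motifs = m6a_motifs()) {
  lens <- setNames(annotation$length, annotation$transcript_id)
  rows <- lapply(names(sequences), function(tx) {
    if (!tx %in% names(lens)) return(NULL)
    h <- scan_motifs(sequences[[tx]], motifs)
    if (nrow(h) == 0) return(NULL)
    pk <- peaks[peaks$transcript_id == tx, , drop = FALSE]
    mod <- vapply(seq_len(nrow(h)), function(k) {
      any(pk$start <= h$offset[k] &
            h$offset[k] + nchar(h$motif[k]) <= pk$end)
    }, logical(1))
    data.frame(transcript_id = tx, motif = h$motif, offset = h$offset,
               rel_pos = h$offset / lens[[tx]], modified = mod,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), motif = character(0),
                      offset = integer(0), rel_pos = numeric(0),
                      modified = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Metagene motif-ratio profile
#'
#' Rescales each transcript to unit length, splits it into \code{n_bins}
#' equal bins, and reports, per bin, the ratio of modified motif occurrences
#' (those lying inside a called peak) to all motif occurrences, pooled over
#' transcripts. A motif at relative position p falls in bin
#' \code{floor(p * n_bins) + 1}.
#'
#' @param peaks A \code{peak_set} in transcript coordinates.
#' @param sequences Named RNA-alphabet transcript sequences.
#' @param annotation A \code{tx_annotation} (provides transcript lengths).
#' @param motifs Motif set.
#' @param n_bins Number of bins (default 10).
#' @return List with \code{ratio} (length \code{n_bins}; NA for motif-free
#'   bins), \code{n_modified}, \code{n_total} (per-bin pooled counts), and
#'   \code{positions}, the underlying per-motif table (columns
#'   \code{rel_pos}, \code{modified}, ...) used for rank-sum testing.
#' @export
metagene_profile <- function(peaks, sequences, annotation,
                             motifs = m6a_motifs(), n_bins = 10L) {
  mp <- .motif_positions(peaks, sequences, annotation, motifs)
  bin <- pmin(floor(mp$rel_pos * n_bins) + 1L, n_bins)
  n_total <- tabulate(bin, nbins = n_bins)
  n_modified <- tabulate(bin[mp$modified], nbins = n_bins)
  ratio <- ifelse(n_total == 0, NA_real_, n_modified / n_total)
  list(ratio = ratio, n_modified = n_modified, n_total = n_total,
       positions = mp)
}

#' Compare positional distributions of modified motifs between conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the transcript-relative
#' positions of modified motifs under two conditions (\code{unit =
#' "positions"}, the default) or on the 10 per-bin ratios (\code{unit =
#' "bins"}). Small tie-free samples are tested exactly; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param profile_a,profile_b Outputs of \code{\link{metagene_profile}}, or,
#'   with \code{unit = "positions"}, bare numeric vectors of positions.
#' @param unit Sampling unit for the test.
#' @return Two-sided p-value; NA (with a warning) when either sample has
#'   fewer than 2 observations.
#' @export
compare_profiles <- function(profile_a, profile_b,
                             unit = c("positions", "bins")) {
  unit <- match.arg(unit)
  pull <- function(p) {
    if (is.numeric(p)) return(p)
    if (unit == "positions") p$positions$rel_pos[p$positions$modified]
    else p$ratio[!is.na(p$ratio)]
  }
  xa <- pull(profile_a); xb <- pull(profile_b)
  if (length(xa) < 2 || length(xb) < 2) {
    warning("fewer than 2 observations in a sample; p-value undefined")
    return(NA_real_)
  }
  suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))$p.value
}

#' RPKM expression normalization
#'
#' rpkm = count / ((length / 1000) * (library_size / 1e6)).
#'
#' @param counts Named integer vector of per-gene raw counts.
#' @param lengths Named vector of gene lengths (nt), covering all genes in
#'   \code{counts}.
#' @param library_size Total mapped reads of the sample (> 0).
#' @return data.frame with \code{gene}, \code{count}, \code{rpkm},
#'   \code{log2_rpkm} (\code{-Inf} for zero counts; see
#'   \code{\link{expression_comparison}} for the pseudocount policy).
#' @export
compute_rpkm <- function(counts, lengths, library_size) {
  if (library_size <= 0) stop("library_size must be positive")
  if (!all(names(counts) %in% names(lengths))) {
    stop("lengths missing for some genes")
  }
  rpkm <- counts / ((lengths[names(counts)] / 1000) * (library_size / 1e6))
  data.frame(gene = names(counts), count = as.numeric(counts),
             rpkm = as.numeric(rpkm), log2_rpkm = log2(as.numeric(rpkm)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split genes into equally sized expression groups
#'
#' Genes are sorted by expression (ascending, ties broken by gene id for
#' determinism) and split into \code{k} contiguous groups whose sizes differ
#' by at most 1; when the count does not divide evenly the remainder goes to
#' the lowest group(s). With the default k = 3 the groups are labelled
#' \code{low}, \code{mid}, \code{high}.
#'
#' @param log2_rpkm Named numeric vector of log2 RPKM values, one condition.
#' @param k Number of groups (default 3).
#' @return Named character vector gene -> group label.
#' @export
expression_groups <- function(log2_rpkm, k = 3L) {
  n <- length(log2_rpkm)
  if (n < k) stop("fewer genes than groups")
  ord <- order(log2_rpkm, names(log2_rpkm))
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  labels <- if (k == 3) c("low", "mid", "high") else paste0("g", seq_len(k))
  grp <- rep(labels, times = sizes)
  setNames(grp, names(log2_rpkm)[ord])[names(log2_rpkm)]
}

#' Per-gene expression comparison between two conditions
#'
#' Computes log2 fold changes (stress minus control, on RPKM + pseudocount),
#' flags differential expression at |log2FC| >= \code{de_threshold}, and the
#' Pearson correlation of log2 RPKM over the shared gene universe.
#'
#' @param ctrl,stress Outputs of \code{\link{compute_rpkm}}.
#' @param pseudocount RPKM added before taking logs (default 0.01).
#' @param de_threshold |log2FC| flag threshold (default 1).
#' @return List with \code{table} (gene, log2fc, de_flag) and
#'   \code{pearson_r}.
#' @export
expression_comparison <- function(ctrl, stress, pseudocount = 0.01,
                                  de_threshold = 1) {
  shared <- intersect(ctrl$gene, stress$gene)
  if (length(shared) == 0) stop("no shared genes between conditions")
  rc <- ctrl$rpkm[match(shared, ctrl$gene)] + pseudocount
  rs <- stress$rpkm[match(shared, stress$gene)] + pseudocount
  log2fc <- log2(rs) - log2(rc)
  list(table = data.frame(gene = shared, log2fc = log2fc,
                          de_flag = abs(log2fc) >= de_threshold,
                          stringsAsFactors = FALSE),
       pearson_r = cor(log2(rc), log2(rs), method = "pearson"))
}

#' Methylation status by expression group
#'
#' A transcript is "methylated" when it carries at least one peak (peak
#' identity, not position, is the unit). Reports methylated counts per
#' expression group and, for an optional tracked subset (e.g. the high-group
#' methylated transcripts of a reference condition), how many remain
#' methylated under the comparison condition and how they redistribute over
#' groups.
#'
#' @param peaks A \code{peak_set} for the condition under study.
#' @param groups Named gene -> group vector from
#'   \code{\link{expression_groups}}.
#' @param tracked Optional character vector of transcript ids to follow.
#' @return List with \code{methylated_by_group} (table over group labels),
#'   \code{n_methylated}, and when \code{tracked} is given:
#'   \code{n_tracked}, \code{n_retained}, \code{n_lost},
#'   \code{retained_by_group}.
#' @export
methylation_by_expression <- function(peaks, groups, tracked = NULL) {
  methylated <- unique(peaks$transcript_id)
  labs <- intersect(c("low", "mid", "high", sort(unique(groups))),
                    unique(groups))
  tab <- vapply(labs, function(g) {
    sum(names(groups)[groups == g] %in% methylated)
  }, integer(1))
  out <- list(methylated_by_group = tab,
              n_methylated = sum(methylated %in% names(groups)))
  if (!is.null(tracked)) {
    retained <- intersect(tracked, methylated)
    out$n_tracked <- length(tracked)
    out$n_retained <- length(retained)
    out$n_lost <- length(tracked) - length(retained)
    out$retained_by_group <- vapply(labs, function(g) {
      sum(names(groups)[groups == g] %in% retained)
    }, integer(1))
  }
  out
}

#' Precision and recall of calls against planted truth
#'
#' For peaks, a called peak is a true positive when it overlaps a truth
#' interval on the same transcript by at least 1 nt; recall counts truth
#' intervals overlapped by at least one call. For sites, matching is exact
#' (transcript_id, position) identity.
#'
#' @param called A \code{peak_set}, or an \code{etam_sites} table (called
#'   rows are used).
#' @param truth Truth table: planted peaks (\code{transcript_id},
#'   \code{start}, \code{end}) or planted sites (\code{transcript_id},
#'   \code{position}).
#' @return List with \code{precision}, \code{recall} (NA where undefined),
#'   \code{n_called}, \code{n_truth}, \code{n_tp}.
#' @export
recovery_metrics <- function(called, truth) {
  is_sites <- "position" %in% names(truth) && !"end" %in% names(truth)
  if (is_sites) {
    if ("called" %in% names(called)) called <- called[called$called, , drop = FALSE]
    key_c <- paste(called$transcript_id, called$pos, sep = ":")
    key_t <- paste(truth$transcript_id, truth$position, sep = ":")
    tp <- sum(key_c %in% key_t)
    matched_truth <- sum(key_t %in% key_c)
    n_called <- length(key_c)
  } else {
    n_called <- nrow(called)
    tp_flags <- vapply(seq_len(n_called), function(i) {
      any(truth$transcript_id == called$transcript_id[i] &
            truth$start < called$end[i] & called$start[i] < truth$end)
    }, logical(1))
    tp <- sum(tp_flags)
    matched_truth <- sum(vapply(seq_len(nrow(truth)), function(j) {
      any(called$transcript_id == truth$transcript_id[j] &
            called$start < truth$end[j] & truth$start[j] < called$end)
    }, logical(1)))
  }
  list(precision = if (n_called == 0) NA_real_ else tp / n_called,
       recall = if (nrow(truth) == 0) NA_real_ else matched_truth / nrow(truth),
       n_called = n_called, n_truth = nrow(truth), n_tp = tp)
}
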