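#' @importFrom stats median rnorm rnbinom rpois rbinom runif setNames
#'   complete.cases cor wilcox.test pbinom quantile
#' @importFrom utils read.delim write.table
NULL

# Internal coordinate convention, used everywhere in this package:
# 0-based, half-open [start, end), transcript-oriented (5'->3' on the coding
# strand).  GFF3 input (1-based closed) and BED output (0-based half-open)
# are converted at the boundary and nowhere else.

#' Read a transcript annotation from GFF3
#'
#' Parses a GFF3 file and returns the records of one feature type (by default
#' \code{CDS}, the transcription unit on which windows, motifs and metagene
#' bins are defined) as a transcript annotation table. GFF3 1-based closed
#' coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to retain (default \code{"CDS"}).
#' @param id_attribute GFF3 attribute used as the transcript identifier
#'   (default \code{"ID"}).
#' @return A \code{data.frame} of class \code{"tx_annotation"} with columns
#'   \code{transcript_id}, \code{seqid}, \code{start}, \code{end},
#'   \code{strand} and \code{length} (nt). \code{start}/\code{end} are
#'   0-based half-open genomic coordinates.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tCDS\t11\t20\t.\t+\t0\tID=txA"), gff)
#' ann <- read_annotation(gff)
#' ann$start  # 10: GFF 1-based start 11 becomes 0-based 10
#' @export
read_annotation <- function(path, feature_type = "CDS", id_attribute = "ID") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  .validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(.empty_annotation())
  keep <- as.character(gr$type) == feature_type
  gr <- gr[keep]
  if (length(gr) == 0) return(.empty_annotation())
  ids <- as.character(S4Vectors::mcols(gr)[[id_attribute]])
  if (is.null(ids) || anyNA(ids)) {
    stop("GFF3 records of type '", feature_type,
         "' lack the '", id_attribute, "' attribute")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate transcript_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ann <- data.frame(
    transcript_id = ids,
    seqid  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  ann$length <- ann$end - ann$start
  stopifnot(all(ann$start >= 0), all(ann$start < ann$end))
  class(ann) <- c("tx_annotation", "data.frame")
  ann
}

.empty_annotation <- function() {
  ann <- data.frame(transcript_id = character(), seqid = character(),
                    start = integer(), end = integer(),
                    strand = character(), length = integer(),
                    stringsAsFactors = FALSE)
  class(ann) <- c("tx_annotation", "data.frame")
  ann
}

# Syntax pre-check so parse errors can name the offending line, which
# rtracklayer's importer does not do.
.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9) {
      stop("malformed GFF3 at line ", i, ": expected 9 tab-separated fields, found ", nf)
    }
  }
  invisible(TRUE)
}

#' Read per-base coverage from a bedGraph file
#'
#' Extracts a per-base read-depth vector for every annotated transcript.
#' Positions absent from the bedGraph receive depth 0; minus-strand
#' transcripts are reversed at load time so that every depth vector runs
#' 5' to 3' in transcript orientation and downstream windowing is
#' strand-agnostic.
#'
#' @param path Path to a bedGraph file (4 columns, 0-based half-open).
#' @param annotation A \code{tx_annotation}.
#' @param sample_role \code{"IP"} or \code{"input"}.
#' @param replicate_id Replicate label, e.g. \code{"rep1"}.
#' @param seqlengths Optional named vector of sequence lengths; when given,
#'   intervals extending past a seqid's bounds raise an error.
#' @return A \code{coverage_set}: list with elements \code{depth} (named list
#'   of integer vectors, one per transcript, transcript-oriented),
#'   \code{sample_role}, \code{replicate_id}.
#' @export
read_coverage <- function(path, annotation, sample_role = "IP",
                          replicate_id = "rep1", seqlengths = NULL) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 0 && any(gr$score < 0)) {
    stop("negative coverage value in bedGraph: ", path)
  }
  if (!is.null(seqlengths)) {
    sq <- as.character(GenomicRanges::seqnames(gr))
    known <- sq %in% names(seqlengths)
    if (any(known & GenomicRanges::end(gr) > seqlengths[sq])) {
      stop("bedGraph interval extends past seqid bounds in: ", path)
    }
  }
  covrle <- GenomicRanges::coverage(gr, weight = "score")
  depth <- vector("list", nrow(annotation))
  names(depth) <- annotation$transcript_id
  for (i in seq_len(nrow(annotation))) {
    sq <- annotation$seqid[i]
    s <- annotation$start[i]; e <- annotation$end[i]
    if (sq %in% names(covrle)) {
      rl <- covrle[[sq]]
      n <- length(rl)
      lo <- min(s + 1L, n + 1L); hi <- min(e, n)
      v <- if (lo <= hi) as.numeric(S4Vectors::window(rl, lo, hi)) else numeric(0)
      if (length(v) < e - s) v <- c(v, numeric(e - s - length(v)))
    } else {
      v <- numeric(e - s)
    }
    if (annotation$strand[i] == "-") v <- rev(v)
    depth[[i]] <- v
  }
  coverage_set(depth, sample_role = sample_role, replicate_id = replicate_id)
}

#' Construct a coverage set
#'
#' @param depth Named list of non-negative numeric vectors (per-transcript,
#'   transcript-oriented read depths).
#' @param sample_role \code{"IP"} or \code{"input"}.
#' @param replicate_id Replicate label.
#' @return An object of class \code{"coverage_set"}.
#' @export
coverage_set <- function(depth, sample_role = "IP", replicate_id = "rep1") {
  stopifnot(is.list(depth), !is.null(names(depth)))
  if (any(vapply(depth, function(v) any(v < 0), logical(1)))) {
    stop("coverage depths must be non-negative")
  }
  structure(list(depth = depth,
                 sample_role = match.arg(sample_role, c("IP", "input")),
                 replicate_id = replicate_id),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat("<coverage_set> ", x$sample_role, "/", x$replicate_id, ": ",
      length(x$depth), " transcripts\n", sep = "")
  invisible(x)
}

# Transcript-space [start, end) -> genomic-space [start, end) for one
# transcript row of the annotation.
.tx_to_genomic <- function(ann_row, start, end) {
  if (ann_row$strand == "+") {
    c(ann_row$start + start, ann_row$start + end)
  } else {
    c(ann_row$end - end, ann_row$end - start)
  }
}

#' Write a peak set to BED6
#'
#' Projects transcript-space peaks to genomic coordinates (BED 0-based
#' half-open) and writes one line per peak. The score column is the
#' peak-over-input (POI) score rounded to 3 decimals.
#'
#' @param peaks A \code{peak_set} (see \code{\link{call_peaks}}).
#' @param annotation The \code{tx_annotation} the peaks were called on.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_peaks_bed <- function(peaks, annotation, path) {
  rows <- character(0)
  if (nrow(peaks) > 0) {
    idx <- match(peaks$transcript_id, annotation$transcript_id)
    if (anyNA(idx)) {
      stop("peaks reference transcripts missing from the annotation: ",
           paste(unique(peaks$transcript_id[is.na(idx)]), collapse = ", "))
    }
    rows <- vapply(seq_len(nrow(peaks)), function(i) {
      a <- annotation[idx[i], , drop = FALSE]
      g <- .tx_to_genomic(a, peaks$start[i], peaks$end[i])
      paste(a$seqid, g[1], g[2],
            paste0(peaks$transcript_id[i], ":", peaks$start[i], "-", peaks$end[i]),
            sprintf("%.3f", peaks$poi[i]), a$strand, sep = "\t")
    }, character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track name="m6a_peaks" description="POI peaks, 0-based half-open"',
             con)
  if (length(rows)) writeLines(rows, con)
  invisible(path)
}

#' Read peaks back from a BED6 file written by \code{write_peaks_bed}
#'
#' @param path BED6 path.
#' @return A \code{peak_set} in transcript coordinates (recovered from the
#'   name column), with \code{poi} at 3-decimal precision.
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") & lines != ""]
  if (length(lines) == 0) return(.empty_peaks())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  nm <- strsplit(f[, 4], "[:-]")
  pk <- data.frame(
    transcript_id = vapply(nm, `[`, character(1), 1),
    start = as.integer(vapply(nm, `[`, character(1), 2)),
    end   = as.integer(vapply(nm, `[`, character(1), 3)),
    pom_ip = NA_real_, pom_input = NA_real_,
    poi = as.numeric(f[, 5]),
    replicates = NA_character_, motifs = NA_character_,
    stringsAsFactors = FALSE
  )
  class(pk) <- c("peak_set", "data.frame")
  pk
}

#' Write a peak set as a TSV table
#'
#' Transcript-space table with all scores, replicate provenance and motif
#' annotations; the genomic projection is available via
#' \code{\link{write_peaks_bed}}.
#'
#' @param peaks A \code{peak_set}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_peaks_tsv <- function(peaks, path) {
  df <- as.data.frame(peaks)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak TSV written by \code{write_peaks_tsv}
#' @param path TSV path.
#' @return A \code{peak_set}.
#' @export
read_peaks_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(transcript_id = "character"))
  need <- c("transcript_id", "start", "end", "pom_ip", "pom_input", "poi")
  if (!all(need %in% names(df))) stop("not a peak table: ", path)
  if (!"replicates" %in% names(df)) df$replicates <- NA_character_
  if (!"motifs" %in% names(df)) df$motifs <- NA_character_
  df$replicates <- as.character(df$replicates)
  df$motifs <- as.character(df$motifs)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a deamination pileup TSV
#'
#' Expected columns: \code{transcript_id}, \code{pos} (0-based), \code{ref},
#' \code{a_count}, \code{g_count}, \code{other_count}. Only reference-A rows
#' are meaningful downstream; non-A rows are dropped with a message.
#'
#' @param path TSV path.
#' @param replicate_id Replicate label attached to every row.
#' @return A data.frame of pileup rows.
#' @export
read_etam_pileup <- function(path, replicate_id = "rep1") {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(transcript_id = "character"))
  need <- c("transcript_id", "pos", "ref", "a_count", "g_count", "other_count")
  if (!all(need %in% names(df))) {
    stop("pileup TSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$a_count < 0 | df$g_count < 0 | df$other_count < 0)) {
    stop("negative counts in pileup: ", path)
  }
  nonA <- df$ref != "A"
  if (any(nonA)) {
    message("dropping ", sum(nonA), " non-A reference rows from ", path)
    df <- df[!nonA, , drop = FALSE]
  }
  df$replicate_id <- replicate_id
  df
}

#' Write transcript sequences as FASTA
#' @param seqs Named character vector of sequences (RNA or DNA alphabet).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  dna <- chartr("Uu", "Tt", seqs)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(dna, names(seqs))), path)
  invisible(path)
}

#' Read FASTA sequences as RNA-alphabet character strings
#'
#' T is transliterated to U on load; motif matching throughout the package is
#' in the RNA alphabet.
#'
#' @param path FASTA path.
#' @return Named character vector over \{A,C,G,U\}.
#' @export
read_fasta_rna <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(chartr("Tt", "Uu", toupper(as.character(ss))), names(ss))
}

#' Extract transcript-oriented sequences from a genome
#'
#' @param genome Named character vector of chromosome sequences (DNA or RNA
#'   alphabet) or a single unnamed sequence.
#' @param annotation A \code{tx_annotation}.
#' @return Named character vector of RNA-alphabet transcript sequences
#'   (minus-strand transcripts reverse-complemented).
#' @export
transcript_sequences <- function(genome, annotation) {
  if (is.null(names(genome)) && length(genome) == 1) {
    names(genome) <- unique(annotation$seqid)[1]
  }
  dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt", genome))
  out <- character(nrow(annotation))
  names(out) <- annotation$transcript_id
  for (i in seq_len(nrow(annotation))) {
    s <- Biostrings::subseq(dna[[annotation$seqid[i]]],
                            start = annotation$start[i] + 1L,
                            end = annotation$end[i])
    if (annotation$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- chartr("T", "U", as.character(s))
  }
  out
}

#' Write per-transcript coverage to a genomic bedGraph
#'
#' Inverse of \code{\link{read_coverage}} for non-overlapping transcripts:
#' transcript-oriented depth vectors are projected back to genome coordinates
#' (minus-strand vectors reversed) and run-length encoded.
#'
#' @param cov A \code{coverage_set}.
#' @param annotation A \code{tx_annotation}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_coverage_bedgraph <- function(cov, annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ord <- order(annotation$seqid, annotation$start)
  for (i in ord) {
    tx <- annotation$transcript_id[i]
    v <- cov$depth[[tx]]
    if (is.null(v)) next
    if (annotation$strand[i] == "-") v <- rev(v)
    r <- rle(v)
    ends <- annotation$start[i] + cumsum(r$lengths)
    starts <- c(annotation$start[i], ends[-length(ends)])
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(paste(annotation$seqid[i], starts[keep], ends[keep],
                       format(r$values[keep], scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a GFF3 annotation file
#'
#' Internal 0-based half-open coordinates are converted to GFF3 1-based
#' closed on output.
#'
#' @param annotation A \code{tx_annotation}.
#' @param path Output path.
#' @param feature_type Feature type column value (default \code{"CDS"}).
#' @param source Source column value.
#' @return Invisibly, the path.
#' @export
write_annotation_gff3 <- function(annotation, path, feature_type = "CDS",
                                  source = "stochm6a") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotation) > 0) {
    writeLines(paste(annotation$seqid, source, feature_type,
                     annotation$start + 1L, annotation$end, ".",
                     annotation$strand, "0",
                     paste0("ID=", annotation$transcript_id), sep = "\t"), con)
  }
  invisible(path)
}
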