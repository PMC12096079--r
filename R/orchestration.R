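# Workflow orchestration: wires the stages into the three end-to-end
# analyses (simulate -> call -> evaluate; condition comparison; peak/site
# concordance), with config provenance, a filter-funnel log and a checksum
# manifest per run.

#' Pipeline configuration with all calling thresholds
#'
#' Collects every threshold of the analysis with its standard default:
#' 50-nt windows in 25-nt steps, window filter coverage >= 10 and POM >= 3,
#' POI > 3, the three-motif set, persistence >= 0.5 at depth >= 20 for
#' persistent-A calls, 10 metagene bins, |log2FC| >= 1 for differential
#' expression, and 3 expression groups.
#'
#' @param ... Overrides of the defaults (unknown names are an error).
#' @return Named list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(w = 50L, step = 25L, min_cov = 10, min_pom = 3, min_poi = 3,
              motifs = m6a_motifs(), min_frac = 0.5, min_depth = 20,
              n_bins = 10L, de_threshold = 1, k_groups = 3L,
              zero_median_policy = "drop", etam_denominator = "ag",
              seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown pipeline_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

.write_manifest <- function(files, outdir) {
  files <- files[file.exists(files)]
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

.save_config <- function(config, outdir) {
  cfg <- unclass(config)
  cfg <- lapply(cfg, function(v) if (is.numeric(v) && any(is.infinite(v)))
    as.character(v) else v)
  jsonlite::write_json(cfg, file.path(outdir, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Peak calling workflow over replicate file pairs
#'
#' Reads coverage for each replicate, calls POM/POI peaks, merges replicates
#' into one unique-peak set, and (optionally) restricts to motif-containing
#' peaks. Logs the count funnel (windows, post-filter candidates, peaks per
#' stage) at message level.
#'
#' @param ip_paths,input_paths Equal-length vectors of bedGraph paths,
#'   paired by position.
#' @param gff_path GFF3 annotation path.
#' @param fasta_path Genome FASTA path.
#' @param outdir Output directory.
#' @param config A \code{\link{pipeline_config}}.
#' @param motif_filter Apply motif restriction (default TRUE); the
#'   pre-restriction merged set is always written too, as the "unfiltered"
#'   set used in cross-method concordance.
#' @return List with \code{merged} (unfiltered \code{peak_set}),
#'   \code{motif_filtered} (or NULL), \code{per_replicate}, \code{manifest}.
#' @export
run_callpeaks <- function(ip_paths, input_paths, gff_path, fasta_path,
                          outdir, config = pipeline_config(),
                          motif_filter = TRUE) {
  stopifnot(length(ip_paths) == length(input_paths), length(ip_paths) >= 1)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- read_annotation(gff_path)
  seqs <- transcript_sequences(read_fasta_rna(fasta_path), ann)
  per_rep <- vector("list", length(ip_paths))
  names(per_rep) <- paste0("rep", seq_along(ip_paths))
  for (r in seq_along(ip_paths)) {
    rid <- names(per_rep)[r]
    ip <- read_coverage(ip_paths[r], ann, "IP", rid)
    inp <- read_coverage(input_paths[r], ann, "input", rid)
    pk <- call_peaks(ip, inp, w = config$w, step = config$step,
                     min_cov = config$min_cov, min_pom = config$min_pom,
                     min_poi = config$min_poi,
                     zero_median_policy = config$zero_median_policy)
    message("[callpeaks] ", rid, ": ", nrow(pk), " peak(s) (POI > ",
            config$min_poi, ")")
    per_rep[[r]] <- pk
  }
  merged <- merge_replicates(per_rep)
  message("[callpeaks] merged across ", length(per_rep), " replicate(s): ",
          nrow(merged), " unique peak(s)")
  files <- character(0)
  write_peaks_tsv(merged, file.path(outdir, "peaks_unfiltered.tsv"))
  write_peaks_bed(merged, ann, file.path(outdir, "peaks_unfiltered.bed"))
  files <- c(files, file.path(outdir, c("peaks_unfiltered.tsv",
                                        "peaks_unfiltered.bed")))
  motif_set <- NULL
  if (motif_filter) {
    motif_set <- filter_peaks_by_motif(merged, seqs, config$motifs)
    message("[callpeaks] motif-restricted: ", nrow(motif_set), " peak(s)")
    write_peaks_tsv(motif_set, file.path(outdir, "peaks_motif.tsv"))
    write_peaks_bed(motif_set, ann, file.path(outdir, "peaks_motif.bed"))
    files <- c(files, file.path(outdir, c("peaks_motif.tsv",
                                          "peaks_motif.bed")))
  }
  .save_config(config, outdir)
  files <- c(files, file.path(outdir, "config_used.json"))
  manifest <- .write_manifest(files, outdir)
  list(merged = merged, motif_filtered = motif_set, per_replicate = per_rep,
       manifest = manifest)
}

#' Persistent-A calling workflow over replicate pileups
#'
#' @param pileup_paths Vector of pileup TSV paths (one per replicate).
#' @param outdir Output directory.
#' @param config A \code{\link{pipeline_config}}.
#' @param controls Optional control-site data.frame
#'   (\code{transcript_id}, \code{pos}).
#' @return List with \code{tables} (per-replicate \code{etam_sites}),
#'   \code{consensus} (for the first two replicates, when >= 2), and
#'   \code{control_report}.
#' @export
run_etam_call <- function(pileup_paths, outdir, config = pipeline_config(),
                          controls = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- vector("list", length(pileup_paths))
  names(tabs) <- paste0("rep", seq_along(pileup_paths))
  files <- character(0)
  for (r in seq_along(pileup_paths)) {
    pu <- read_etam_pileup(pileup_paths[r], names(tabs)[r])
    tabs[[r]] <- call_persistent_sites(pu, min_frac = config$min_frac,
                                       min_depth = config$min_depth,
                                       denominator = config$etam_denominator)
    message("[etam] ", names(tabs)[r], ": ", sum(tabs[[r]]$called),
            " persistent site(s) of ", nrow(tabs[[r]]), " A positions")
    f <- file.path(outdir, paste0("etam_sites_", names(tabs)[r], ".tsv"))
    write.table(tabs[[r]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  consensus <- NULL
  if (length(tabs) >= 2) {
    consensus <- replicate_consensus(tabs[[1]], tabs[[2]])
    message("[etam] replicate consensus: ", consensus$n1, " / ",
            consensus$n2, " called, ", consensus$n_overlap, " overlap")
  }
  control_report <- NULL
  if (!is.null(controls) && nrow(controls) > 0) {
    control_report <- check_control_sites(tabs[[1]], controls)
    message("[etam] controls detected: ", control_report$n_detected, "/",
            control_report$n_controls)
  }
  summary <- list(
    per_replicate_called = vapply(tabs, function(t) sum(t$called), integer(1)),
    consensus = if (is.null(consensus)) NULL
                else consensus[c("n1", "n2", "n_overlap")],
    controls = if (is.null(control_report)) NULL
               else control_report[c("n_controls", "n_detected", "ok")])
  jsonlite::write_json(summary, file.path(outdir, "etam_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .save_config(config, outdir)
  files <- c(files, file.path(outdir, c("etam_summary.json",
                                        "config_used.json")))
  .write_manifest(files, outdir)
  list(tables = tabs, consensus = consensus, control_report = control_report)
}

#' Peak / persistent-site concordance workflow
#'
#' Counts peaks encompassing called sites using the unfiltered merged peak
#' set, the comparison in which motif restriction is deliberately switched
#' off.
#'
#' @param peaks_tsv Path to a peak TSV (\code{\link{write_peaks_tsv}}).
#' @param sites_tsv Path to an \code{etam_sites} TSV (from
#'   \code{\link{run_etam_call}}).
#' @param outdir Output directory.
#' @return The concordance list of \code{\link{peaks_encompassing_sites}}.
#' @export
run_concordance <- function(peaks_tsv, sites_tsv, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  peaks <- read_peaks_tsv(peaks_tsv)
  sites <- read.delim(sites_tsv, stringsAsFactors = FALSE,
                      colClasses = c(transcript_id = "character"))
  conc <- peaks_encompassing_sites(peaks, sites)
  n_sites <- if ("called" %in% names(sites)) sum(sites$called) else nrow(sites)
  report <- c(conc, list(n_peaks = nrow(peaks), n_sites = n_sites))
  jsonlite::write_json(report, file.path(outdir, "concordance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("[concordance] ", conc$n_peaks_with_site, " peak(s) encompass ",
          conc$n_sites_in_peaks, " site(s)")
  conc
}

#' Dispatch one named workflow
#'
#' Thin dispatcher used by the command-line wrapper: \code{"simulate"}
#' (writes a full synthetic dataset), \code{"callpeaks"},
#' \code{"etam-call"}, \code{"concordance"}. Arguments are forwarded to the
#' corresponding \code{run_*}/\code{simulate_dataset} function.
#'
#' @param name Workflow name.
#' @param ... Forwarded arguments.
#' @return The workflow's return value.
#' @export
run_workflow <- function(name, ...) {
  switch(name,
         simulate = simulate_dataset(...),
         callpeaks = run_callpeaks(...),
         "etam-call" = run_etam_call(...),
         concordance = run_concordance(...),
         stop("unknown workflow: ", name))
}
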