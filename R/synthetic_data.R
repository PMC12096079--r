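# Synthetic transcriptome / coverage / pileup generator with planted ground
# truth.  Everything is deterministic under the config seed: transcriptome
# structure is drawn at `seed`, coverage at `seed + 1`, pileups at
# `seed + 2`, so stages can be regenerated independently yet reproducibly.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with its default.
#' Defaults describe the reference scenario used throughout the package's
#' evaluation: 200 transcripts, mean input depth 20x, 50 planted single
#' 50-nt enrichment windows at 8-fold IP enrichment, two replicates, 99\%
#' deamination conversion, and planted persistent sites at persistence 0.95.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_transcripts Number of mRNA-like transcripts.
#' @param transcript_length_range Min/max transcript length (nt).
#' @param expression_log_mean,expression_log_sd Mean and sd of per-transcript
#'   expression on the log2-RPKM scale; coverage scales as
#'   \code{2^(log2rpkm - expression_log_mean)} so the typical transcript sits
#'   at \code{base_depth}.
#' @param planted_peak_count Number of planted IP-enrichment windows.
#' @param enrichment IP fold-increase over input inside planted windows
#'   (rho > 1; rho = 1 disables enrichment for null calibration).
#' @param nb_dispersion Negative-binomial size parameter of the per-base
#'   count noise; \code{Inf} gives the Poisson limit.
#' @param base_depth Mean input coverage of a typical transcript.
#' @param conversion_rate Probability an unmethylated A reads as G after
#'   deamination (default 0.99).
#' @param persistent_fraction Read fraction remaining A at planted/control
#'   sites (default 0.95).
#' @param pileup_depth_mean Mean read depth of the deamination pileup
#'   (Poisson; default 100).
#' @param planted_site_count Number of planted persistent-A sites.
#' @param n_replicates Biological replicates per sample role.
#' @param peak_width Planted peak width (nt); default one 50-nt window so
#'   truth-to-call matching is unambiguous.
#' @param motifs Motif set planted at peak centres.
#' @param with_control Add an rRNA-like control transcript carrying two
#'   always-persistent positions (1-based 1618 and 2030).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 200L,
                       transcript_length_range = c(300L, 1500L),
                       expression_log_mean = 5,
                       expression_log_sd = 1.5,
                       planted_peak_count = 50L,
                       enrichment = 8,
                       nb_dispersion = 10,
                       base_depth = 20,
                       conversion_rate = 0.99,
                       persistent_fraction = 0.95,
                       pileup_depth_mean = 100,
                       planted_site_count = 50L,
                       n_replicates = 2L,
                       peak_width = 50L,
                       motifs = m6a_motifs(),
                       with_control = TRUE) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              transcript_length_range = as.integer(transcript_length_range),
              expression_log_mean = expression_log_mean,
              expression_log_sd = expression_log_sd,
              planted_peak_count = as.integer(planted_peak_count),
              enrichment = enrichment, nb_dispersion = nb_dispersion,
              base_depth = base_depth, conversion_rate = conversion_rate,
              persistent_fraction = persistent_fraction,
              pileup_depth_mean = pileup_depth_mean,
              planted_site_count = as.integer(planted_site_count),
              n_replicates = as.integer(n_replicates),
              peak_width = as.integer(peak_width),
              motifs = motifs, with_control = isTRUE(with_control))
  if (cfg$enrichment < 1) stop("enrichment must be >= 1")
  if (cfg$conversion_rate <= 0 || cfg$conversion_rate > 1) {
    stop("conversion_rate must be in (0, 1]")
  }
  if (diff(cfg$transcript_length_range) < 0 ||
      cfg$transcript_length_range[1] < max(60L, cfg$peak_width + 10L)) {
    stop("transcripts too short to host a planted window plus flanks")
  }
  if (cfg$planted_peak_count > cfg$n_transcripts) {
    stop("more planted peaks than transcripts")
  }
  class(cfg) <- "sim_config"
  cfg
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Control transcript mimicking 23S rRNA: two always-persistent positions at
# 1-based 1618 and 2030 (0-based 1617 and 2029).
.CONTROL_ID <- "rrl_like"
.CONTROL_POS0 <- c(1617L, 2029L)
.CONTROL_LEN <- 2904L

#' Simulate an annotated toy transcriptome
#'
#' Draws random transcript sequences, lays them head-to-tail (random strand,
#' 100-nt spacers) on one synthetic chromosome, plants
#' \code{planted_peak_count} single-window enrichment regions each centred
#' on a motif, and records every motif occurrence. Motifs also occur by
#' chance in the random background. When \code{with_control} is set, an
#' rRNA-like transcript with two designated always-persistent adenosines is
#' appended; it never receives planted peaks.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{annotation} (\code{tx_annotation}),
#'   \code{genome} (named DNA string), \code{sequences} (named RNA strings,
#'   transcript-oriented), and \code{truth}: \code{planted_peaks}
#'   (transcript_id, start, end, motif, enrichment), \code{planted_sites}
#'   (filled by \code{\link{simulate_etam_pileup}} planning),
#'   \code{control_sites}, \code{motif_inventory}.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  lens <- sample(seq(config$transcript_length_range[1],
                     config$transcript_length_range[2]), n, replace = TRUE)
  ids <- sprintf("tx%03d", seq_len(n))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- vapply(lens, .rand_seq, character(1))
  names(seqs) <- ids

  # plant peaks: window-grid-aligned [s, s+width) with a motif at the centre
  planted <- .empty_truth_peaks()
  if (config$planted_peak_count > 0) {
    host <- sort(sample(n, config$planted_peak_count))
    rows <- vector("list", length(host))
    for (k in seq_along(host)) {
      i <- host[k]
      wstarts <- seq(0L, lens[i] - config$peak_width, by = 25L)
      s <- if (length(wstarts) == 1) wstarts else sample(wstarts, 1)
      motif <- sample(config$motifs, 1)
      off <- s + (config$peak_width - nchar(motif)) %/% 2
      substr(seqs[[i]], off + 1L, off + nchar(motif)) <- motif
      rows[[k]] <- data.frame(transcript_id = ids[i], start = s,
                              end = s + config$peak_width, motif = motif,
                              enrichment = config$enrichment,
                              stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, rows)
  }

  # plant persistent-A sites on existing A positions (outside nothing in
  # particular: concordance with peaks is a measured outcome, not an input)
  sites <- data.frame(transcript_id = character(0), position = integer(0),
                      stringsAsFactors = FALSE)
  if (config$planted_site_count > 0) {
    a_pool <- do.call(rbind, lapply(seq_len(n), function(i) {
      pos <- which(strsplit(seqs[[i]], "")[[1]] == "A") - 1L
      if (length(pos) == 0) return(NULL)
      data.frame(transcript_id = ids[i], position = pos,
                 stringsAsFactors = FALSE)
    }))
    pick <- sample(nrow(a_pool), min(config$planted_site_count, nrow(a_pool)))
    sites <- a_pool[sort(pick), , drop = FALSE]
    rownames(sites) <- NULL
  }

  control_sites <- data.frame(transcript_id = character(0),
                              position = integer(0), stringsAsFactors = FALSE)
  if (config$with_control) {
    ctrl_seq <- .rand_seq(.CONTROL_LEN)
    for (p in .CONTROL_POS0) substr(ctrl_seq, p + 1L, p + 1L) <- "A"
    seqs <- c(seqs, setNames(ctrl_seq, .CONTROL_ID))
    ids <- c(ids, .CONTROL_ID)
    lens <- c(lens, .CONTROL_LEN)
    strands <- c(strands, "+")
    control_sites <- data.frame(transcript_id = .CONTROL_ID,
                                position = .CONTROL_POS0,
                                stringsAsFactors = FALSE)
  }

  # assemble a genome: transcripts separated by 100-nt spacers
  gap <- 100L
  gstart <- cumsum(c(gap, utils::head(lens, -1) + gap))
  ann <- data.frame(transcript_id = ids, seqid = "chrS",
                    start = gstart, end = gstart + lens,
                    strand = strands, length = lens,
                    stringsAsFactors = FALSE)
  class(ann) <- c("tx_annotation", "data.frame")

  total_len <- ann$end[nrow(ann)] + gap
  genome <- rep("T", total_len)  # spacer filler
  for (i in seq_len(nrow(ann))) {
    dna <- chartr("U", "T", seqs[[i]])
    if (ann$strand[i] == "-") {
      dna <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    }
    genome[(ann$start[i] + 1L):ann$end[i]] <- strsplit(dna, "")[[1]]
  }
  genome <- setNames(paste(genome, collapse = ""), "chrS")

  inventory <- do.call(rbind, lapply(ids, function(tx) {
    h <- scan_motifs(seqs[[tx]], config$motifs)
    if (nrow(h) == 0) return(NULL)
    cbind(data.frame(transcript_id = tx, stringsAsFactors = FALSE), h)
  }))
  if (is.null(inventory)) {
    inventory <- data.frame(transcript_id = character(0), motif = character(0),
                            offset = integer(0), stringsAsFactors = FALSE)
  }

  list(annotation = ann, genome = genome, sequences = seqs,
       truth = list(planted_peaks = planted, planted_sites = sites,
                    control_sites = control_sites,
                    motif_inventory = inventory),
       config = config)
}

.empty_truth_peaks <- function() {
  data.frame(transcript_id = character(0), start = integer(0),
             end = integer(0), motif = character(0), enrichment = numeric(0),
             stringsAsFactors = FALSE)
}

.rcounts <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

#' Simulate IP and input coverage with planted enrichment
#'
#' Input depth at each base is a negative-binomial draw around an
#' expression-scaled mean; IP depth uses the same mean multiplied by the
#' enrichment factor inside planted windows and 1 elsewhere, re-sampled
#' independently per replicate. The control transcript (if any) receives
#' background coverage only.
#'
#' @param sim Output of \code{\link{simulate_transcriptome}}.
#' @param config Optional override of \code{sim$config}.
#' @param exact If \code{TRUE}, depths are set to their means (noise off),
#'   for expectation checks.
#' @return List of replicates; each element is
#'   \code{list(ip = coverage_set, input = coverage_set)}. The expression
#'   multipliers used are attached as attribute \code{"expression_log2rpkm"}.
#' @export
simulate_coverage <- function(sim, config = sim$config, exact = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ann <- sim$annotation
  log2rpkm <- rnorm(nrow(ann), config$expression_log_mean,
                    config$expression_log_sd)
  names(log2rpkm) <- ann$transcript_id
  mu_tx <- config$base_depth * 2^(log2rpkm - config$expression_log_mean)
  truth <- sim$truth$planted_peaks
  reps <- vector("list", config$n_replicates)
  names(reps) <- paste0("rep", seq_len(config$n_replicates))
  for (r in seq_len(config$n_replicates)) {
    depth_in <- depth_ip <- vector("list", nrow(ann))
    names(depth_in) <- names(depth_ip) <- ann$transcript_id
    for (i in seq_len(nrow(ann))) {
      tx <- ann$transcript_id[i]
      len <- ann$length[i]
      mu <- rep(mu_tx[i], len)
      mu_ip <- mu
      tp <- truth[truth$transcript_id == tx, , drop = FALSE]
      if (nrow(tp) > 0) {
        for (j in seq_len(nrow(tp))) {
          idx <- (tp$start[j] + 1L):tp$end[j]
          mu_ip[idx] <- mu_ip[idx] * config$enrichment
        }
      }
      if (exact) {
        depth_in[[i]] <- mu
        depth_ip[[i]] <- mu_ip
      } else {
        depth_in[[i]] <- .rcounts(len, mu, config$nb_dispersion)
        depth_ip[[i]] <- .rcounts(len, mu_ip, config$nb_dispersion)
      }
    }
    reps[[r]] <- list(
      ip = coverage_set(depth_ip, "IP", names(reps)[r]),
      input = coverage_set(depth_in, "input", names(reps)[r]))
  }
  attr(reps, "expression_log2rpkm") <- log2rpkm
  reps
}

#' Simulate deamination pileups with planted persistent sites
#'
#' For every reference A in every transcript: total read depth is Poisson
#' around \code{pileup_depth_mean}; the A count is binomial with success
#' probability \code{1 - conversion_rate} at unplanted positions and
#' \code{persistent_fraction} at planted and control positions; remaining
#' reads are G. Planted sites are validated to sit on reference adenosines.
#'
#' @param sim Output of \code{\link{simulate_transcriptome}}.
#' @param config Optional override of \code{sim$config}.
#' @param n_replicates Number of pileup replicates (default
#'   \code{config$n_replicates}).
#' @return List of data.frames (one per replicate) with columns
#'   \code{transcript_id}, \code{pos}, \code{ref}, \code{a_count},
#'   \code{g_count}, \code{other_count}, \code{replicate_id}.
#' @export
simulate_etam_pileup <- function(sim, config = sim$config,
                                 n_replicates = config$n_replicates) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  seqs <- sim$sequences
  persistent <- rbind(
    sim$truth$planted_sites,
    sim$truth$control_sites
  )
  # planted sites must be reference adenosines
  for (k in seq_len(nrow(persistent))) {
    ch <- substr(seqs[[persistent$transcript_id[k]]],
                 persistent$position[k] + 1L, persistent$position[k] + 1L)
    if (ch != "A") {
      stop("planted persistent site on non-A base: ",
           persistent$transcript_id[k], ":", persistent$position[k])
    }
  }
  pkey <- paste(persistent$transcript_id, persistent$position, sep = ":")
  out <- vector("list", n_replicates)
  names(out) <- paste0("rep", seq_len(n_replicates))
  for (r in seq_len(n_replicates)) {
    rows <- lapply(names(seqs), function(tx) {
      pos <- which(strsplit(seqs[[tx]], "")[[1]] == "A") - 1L
      if (length(pos) == 0) return(NULL)
      total <- rpois(length(pos), config$pileup_depth_mean)
      p <- ifelse(paste(tx, pos, sep = ":") %in% pkey,
                  config$persistent_fraction, 1 - config$conversion_rate)
      a <- rbinom(length(pos), total, p)
      data.frame(transcript_id = tx, pos = pos, ref = "A",
                 a_count = a, g_count = total - a, other_count = 0L,
                 replicate_id = names(out)[r], stringsAsFactors = FALSE)
    })
    out[[r]] <- do.call(rbind, rows)
    rownames(out[[r]]) <- NULL
  }
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Generates transcriptome, coverage and pileups under \code{config} and
#' writes genome FASTA, GFF3 annotation, per-replicate IP/input bedGraphs,
#' per-replicate pileup TSVs, a truth JSON and the serialized config, plus a
#' manifest with md5 checksums of every file.
#'
#' @param config A \code{\link{sim_config}}.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the manifest as a named list of checksums.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_transcriptome(config)
  covs <- simulate_coverage(sim)
  pileups <- simulate_etam_pileup(sim)
  files <- character(0)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$genome, p("genome.fa")); files <- c(files, p("genome.fa"))
  write_annotation_gff3(sim$annotation, p("annotation.gff3"))
  files <- c(files, p("annotation.gff3"))
  for (r in names(covs)) {
    write_coverage_bedgraph(covs[[r]]$ip, sim$annotation,
                            p(paste0(r, "_ip.bedGraph")))
    write_coverage_bedgraph(covs[[r]]$input, sim$annotation,
                            p(paste0(r, "_input.bedGraph")))
    files <- c(files, p(paste0(r, "_ip.bedGraph")),
               p(paste0(r, "_input.bedGraph")))
  }
  for (r in names(pileups)) {
    write.table(pileups[[r]], p(paste0("etam_", r, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, p(paste0("etam_", r, ".tsv")))
  }
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg <- unclass(config)
  cfg$nb_dispersion <- if (is.infinite(cfg$nb_dispersion)) "Inf" else cfg$nb_dispersion
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p("truth.json"), p("config.json"))
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
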