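# Base-resolution persistent-adenosine calling from deamination pileups.
#
# In eTAM-style sequencing an evolved deaminase converts unmethylated A to
# inosine (read as G); adenosines that stay A in the read pileup
# ("persistent A") mark methylated or conversion-resistant positions.  No
# demethylase-treated control branch is modelled here: in bacteria that
# control is not available, so called sites are the union of m6A and
# structured (conversion-resistant) adenosines.

#' Call persistent-A sites from a deamination pileup
#'
#' A reference adenosine is called persistent when its read depth is at
#' least \code{min_depth} and the fraction of reads still supporting A is at
#' least \code{min_frac}; both thresholds are inclusive. The persistence
#' denominator is, by default, the reads supporting A or G at the site
#' (A-to-G conversion being the signal axis; other bases are treated as
#' sequencing noise); set \code{denominator = "total"} to divide by all
#' reads instead. Rows whose denominator is 0 are excluded rather than
#' divided.
#'
#' @param pileup data.frame with columns \code{transcript_id}, \code{pos}
#'   (0-based), \code{ref}, \code{a_count}, \code{g_count},
#'   \code{other_count} (see \code{\link{read_etam_pileup}}).
#' @param min_frac Minimum persistence fraction (default 0.5).
#' @param min_depth Minimum read depth (default 20).
#' @param denominator \code{"ag"} (default) or \code{"total"}.
#' @param replicate_id Replicate label if the pileup lacks one.
#' @return An \code{etam_sites} data.frame: \code{transcript_id}, \code{pos},
#'   \code{ref}, \code{a_count}, \code{total_count}, \code{persistence},
#'   \code{called}, \code{replicate_id}. Rows are all depth-positive
#'   reference-A positions; \code{called} flags the persistent ones.
#' @export
call_persistent_sites <- function(pileup, min_frac = 0.5, min_depth = 20,
                                  denominator = c("ag", "total"),
                                  replicate_id = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("transcript_id", "pos", "ref", "a_count", "g_count",
                  "other_count") %in% names(pileup)))
  pileup <- pileup[pileup$ref == "A", , drop = FALSE]
  total <- pileup$a_count + pileup$g_count +
    if (denominator == "total") pileup$other_count else 0L
  keep <- total > 0
  pileup <- pileup[keep, , drop = FALSE]
  total <- total[keep]
  persistence <- pileup$a_count / total
  out <- data.frame(
    transcript_id = pileup$transcript_id,
    pos = pileup$pos,
    ref = "A",
    a_count = pileup$a_count,
    total_count = total,
    persistence = persistence,
    called = total >= min_depth & persistence >= min_frac,
    replicate_id = if (!is.null(replicate_id)) replicate_id
      else if ("replicate_id" %in% names(pileup)) pileup$replicate_id
      else NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("etam_sites", "data.frame")
  out
}

#' @export
print.etam_sites <- function(x, ...) {
  cat("<etam_sites> ", sum(x$called), " called / ", nrow(x),
      " reference-A positions\n", sep = "")
  invisible(x)
}

#' Replicate consensus of persistent-A calls
#'
#' @param table1,table2 \code{etam_sites} tables from two biological
#'   replicates on the same reference.
#' @return List with \code{n1}, \code{n2} (called-site counts per replicate),
#'   \code{n_overlap}, and \code{overlap}, a data.frame of the
#'   (transcript_id, pos) pairs called in both.
#' @export
replicate_consensus <- function(table1, table2) {
  k1 <- table1[table1$called, c("transcript_id", "pos")]
  k2 <- table2[table2$called, c("transcript_id", "pos")]
  key1 <- paste(k1$transcript_id, k1$pos, sep = ":")
  key2 <- paste(k2$transcript_id, k2$pos, sep = ":")
  both <- k1[key1 %in% key2, , drop = FALSE]
  rownames(both) <- NULL
  list(n1 = nrow(k1), n2 = nrow(k2), n_overlap = nrow(both), overlap = both)
}

#' Check internal-control persistent sites
#'
#' Verifies that designated always-persistent positions (the synthetic
#' analogue of the two 23S rRNA m6A positions used as an internal control)
#' were called. Controls falling on a non-A reference row raise an error.
#'
#' @param table An \code{etam_sites} table.
#' @param controls data.frame with columns \code{transcript_id}, \code{pos};
#'   may have zero rows.
#' @param strict If \code{TRUE}, a missed control raises an error instead of
#'   a flagged report.
#' @param pileup Optional raw pileup used to verify the reference base at
#'   control positions.
#' @return List with \code{n_controls}, \code{n_detected}, \code{detected}
#'   (logical per control), \code{ok}.
#' @export
check_control_sites <- function(table, controls, strict = FALSE,
                                pileup = NULL) {
  if (is.null(controls) || nrow(controls) == 0) {
    return(list(n_controls = 0L, n_detected = 0L, detected = logical(0),
                ok = TRUE))
  }
  if (!"pos" %in% names(controls) && "position" %in% names(controls)) {
    controls$pos <- controls$position
  }
  if (!is.null(pileup)) {
    key_p <- paste(pileup$transcript_id, pileup$pos, sep = ":")
    key_c <- paste(controls$transcript_id, controls$pos, sep = ":")
    refs <- pileup$ref[match(key_c, key_p)]
    if (any(!is.na(refs) & refs != "A")) {
      stop("control position is not a reference A")
    }
  }
  called <- table[table$called, , drop = FALSE]
  key_t <- paste(called$transcript_id, called$pos, sep = ":")
  key_c <- paste(controls$transcript_id, controls$pos, sep = ":")
  detected <- key_c %in% key_t
  ok <- all(detected)
  if (!ok && strict) {
    stop("control site(s) not detected: ",
         paste(key_c[!detected], collapse = ", "))
  }
  list(n_controls = nrow(controls), n_detected = sum(detected),
       detected = detected, ok = ok)
}
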