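# Independent oracles, written as plain loops so they share no code path
# with the package implementation.

# Brute-force POM/POI peak caller for one transcript.
oracle_call_peaks <- function(dip, din, tx = "t", w = 50, step = 25,
                              min_cov = 10, min_pom = 3, min_poi = 3) {
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), poi = numeric(0),
                      stringsAsFactors = FALSE)
  len <- length(dip)
  if (len < step) return(empty)
  starts <- c()
  s <- 0
  while (TRUE) {
    starts <- c(starts, s)
    if (s + w >= len) break
    s <- s + step
  }
  med_ip <- median(dip)
  med_in <- median(din)
  if (med_ip == 0) return(empty)
  kept <- list()
  for (s in starts) {
    e <- min(s + w, len)
    if (e - s < 10) next
    mean_ip <- mean(dip[(s + 1):e])
    pom_ip <- mean_ip / med_ip
    if (!(mean_ip >= min_cov && pom_ip >= min_pom)) next   # candidate filter
    if (med_in > 0) {
      mean_in <- mean(din[(s + 1):e])
      pom_in <- mean_in / med_in
      if (mean_in >= min_cov && pom_in >= min_pom) next     # shared region
      if (pom_in == 0) next                                 # undefined POI
      poi <- pom_ip / pom_in
      if (poi > min_poi) kept[[length(kept) + 1]] <- c(s, e, poi)
    }
    # med_in == 0: input POM undefined -> candidate dropped
  }
  if (length(kept) == 0) return(empty)
  m <- do.call(rbind, kept)
  m <- m[order(m[, 1]), , drop = FALSE]
  peaks <- list()
  cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) {          # overlap or adjacency: coalesce
      cur[2] <- max(cur[2], m[i, 2])
      cur[3] <- max(cur[3], m[i, 3])
    } else {
      peaks[[length(peaks) + 1]] <- cur
      cur <- m[i, ]
    }
  }
  peaks[[length(peaks) + 1]] <- cur
  p <- do.call(rbind, peaks)
  data.frame(transcript_id = tx, start = as.integer(p[, 1]),
             end = as.integer(p[, 2]), poi = p[, 3],
             stringsAsFactors = FALSE)
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (valid without ties).
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Random coverage fixture with occasional spikes, so the oracle-equivalence
# test exercises both empty and non-empty peak outcomes.
random_track_pair <- function(len) {
  base <- sample(0:12, 1)
  dip <- rpois(len, base)
  din <- rpois(len, base)
  if (runif(1) < 0.5 && len >= 60) {
    s <- sample.int(len - 50, 1)
    dip[s:(s + 49)] <- dip[s:(s + 49)] + rpois(50, base * 8 + 5)
  }
  if (runif(1) < 0.15 && len >= 60) {    # shared spike in both samples
    s <- sample.int(len - 50, 1)
    sp <- rpois(50, base * 6 + 5)
    dip[s:(s + 49)] <- dip[s:(s + 49)] + sp
    din[s:(s + 49)] <- din[s:(s + 49)] + sp
  }
  list(ip = dip, input = din)
}
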