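test_that("POM windows enumerate on the 25-nt grid with a truncated terminus", {
  s <- compute_pom(rep(20, 200))
  expect_equal(s$start, seq(0, 150, by = 25))
  expect_equal(s$end, pmin(s$start + 50, 200))
  expect_true(all(s$pom == 1))           # constant track: mean == median

  s60 <- compute_pom(rep(5, 60))
  expect_equal(s60$start, c(0, 25))      # [0,50) and [25,60), no sliver
  expect_equal(s60$end, c(50, 60))

  spike <- c(rep(90, 50), rep(10, 150))
  expect_equal(compute_pom(spike)$pom[1], 9)   # mean 90 over median 10

  expect_equal(nrow(compute_pom(rep(0, 100))), 0)  # undefined POM dropped
  expect_equal(compute_pom(c(rep(0, 60), rep(8, 40)),
                           zero_median_policy = "pseudo")$median_cov[1], 8)
})

test_that("window filter keeps a window only when coverage and POM both pass", {
  sc <- data.frame(transcript_id = "t", start = 0L, end = 50L,
                   mean_cov = c(9, 100, 10, 10), median_cov = 1,
                   pom = c(10, 2.9, 3, 2.999))
  kept <- filter_windows(sc)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$mean_cov, 10)        # inclusive boundary retained
  expect_equal(kept$pom, 3)
})

test_that("call_peaks applies shared-region exclusion and the POI > 3 cutoff", {
  len <- 200
  mk <- function(v) coverage_set(list(t1 = v), "IP", "rep1")
  # IP spike POM 9, input mild bump POM 2 at the same window -> POI 4.5
  dip <- c(rep(90, 50), rep(10, 150))
  din <- c(rep(20, 50), rep(10, 150))
  pk <- call_peaks(mk(dip), coverage_set(list(t1 = din), "input", "rep1"))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$poi, 9 / 2)
  expect_equal(pk$replicates, "rep1")

  # same enrichment in input -> shared region, discarded
  pk2 <- call_peaks(mk(dip), coverage_set(list(t1 = dip), "input", "rep1"))
  expect_equal(nrow(pk2), 0)

  # identical arbitrary tracks -> never any peak
  set.seed(42)
  v <- rpois(200, 15)
  pk3 <- call_peaks(mk(v), coverage_set(list(t1 = v), "input", "rep1"))
  expect_equal(nrow(pk3), 0)

  # POI must exceed 3 strictly: IP POM 6 / input POM 2 = 3 -> rejected
  dip4 <- c(rep(60, 50), rep(10, 150))
  din4 <- c(rep(20, 50), rep(10, 150))
  # input bump has POM 2 so it is not shared, and POI = 6/2 = 3 exactly
  pk4 <- call_peaks(mk(dip4), coverage_set(list(t1 = din4), "input", "rep1"))
  expect_equal(nrow(pk4), 0)
})

test_that("adjacent retained windows coalesce into one max-scored peak", {
  # enrichment spanning [25,125) lights up overlapping windows
  dip <- rep(10, 300); dip[26:125] <- 90
  din <- rep(10, 300)
  pk <- call_peaks(coverage_set(list(t = dip), "IP", "r1"),
                   coverage_set(list(t = din), "input", "r1"))
  expect_equal(nrow(pk), 1)
  expect_lte(pk$start, 25)
  expect_gte(pk$end, 125)
  expect_equal(pk$poi, max(compute_pom(dip)$pom))
})

test_that("replicate merging is a coalescing union with provenance", {
  mk_pk <- function(tx, s, e, poi, rep) {
    d <- data.frame(transcript_id = tx, start = s, end = e, pom_ip = poi,
                    pom_input = 1, poi = poi, replicates = rep,
                    motifs = NA_character_, stringsAsFactors = FALSE)
    class(d) <- c("peak_set", "data.frame")
    d
  }
  a <- mk_pk("t1", 0L, 50L, 5, "rep1")
  b <- mk_pk("t1", 25L, 75L, 4, "rep2")
  m <- merge_replicates(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 75L)
  expect_equal(m$replicates, "rep1,rep2")
  expect_equal(m$poi, 5)

  # idempotence on identical sets
  m2 <- merge_replicates(list(a, a))
  expect_equal(m2$start, a$start)
  expect_equal(m2$end, a$end)

  # disjoint sets: plain union count
  c3 <- mk_pk(c("t1", "t2", "t3"), c(0L, 0L, 0L), c(50L, 50L, 50L), 5, "rep1")
  d4 <- mk_pk(c("t4", "t5", "t6", "t7"), rep(0L, 4), rep(50L, 4), 4, "rep2")
  expect_equal(nrow(merge_replicates(list(c3, d4))), 7)
})

test_that("motif scanning is exact, overlap-tolerant and alphabet-strict", {
  hits <- scan_motifs("UGCCAUGCCAU", "GCCAU")
  expect_equal(hits$offset, c(1L, 6L))
  expect_equal(nrow(scan_motifs("AAAA")), 0)
  expect_error(scan_motifs("ACGN"), "alphabet")
  # T input is transliterated
  expect_equal(scan_motifs("TGCCAT", "GCCAU")$offset, 1L)
})

test_that("the fbaA oligonucleotide carries one UGCCAG hit covering its modified A", {
  oligo <- "AACUUCGCACUGCCAGCAGUAAACUGCGUCGGUACUGACUCC"
  hits <- scan_motifs(oligo, "UGCCAG")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 10L)
  # the methylated A (offset 14) lies inside the motif [10, 16)
  expect_true(hits$offset <= 14 && 14 < hits$offset + 6)
  expect_equal(substr(oligo, 15, 15), "A")
})

test_that("motif restriction requires full containment within the peak", {
  seqs <- c(t1 = paste0(strrep("C", 20), "UGCCAG", strrep("C", 74)))
  mk <- function(s, e) {
    d <- data.frame(transcript_id = "t1", start = s, end = e, pom_ip = 9,
                    pom_input = 1, poi = 9, replicates = "rep1",
                    motifs = NA_character_, stringsAsFactors = FALSE)
    class(d) <- c("peak_set", "data.frame")
    d
  }
  expect_equal(nrow(filter_peaks_by_motif(mk(0L, 50L), seqs)), 1)   # contained
  expect_equal(nrow(filter_peaks_by_motif(mk(50L, 100L), seqs)), 0) # motif-free
  # motif starts 3 nt before the peak end: straddles the boundary -> dropped
  expect_equal(nrow(filter_peaks_by_motif(mk(0L, 23L), seqs)), 0)
  expect_equal(filter_peaks_by_motif(mk(0L, 26L), seqs)$motifs, "UGCCAG@20")
  expect_error(filter_peaks_by_motif(mk(0L, 50L), c(other = "ACGU")),
               "t1")
})

test_that("POM and POI are invariant under coverage rescaling", {
  set.seed(11)
  for (i in 1:20) {
    v <- rpois(150, 12)
    k <- sample(c(2, 5, 10), 1)
    p1 <- compute_pom(v)
    p2 <- compute_pom(v * k)
    expect_equal(p2$pom, p1$pom)
  }
  # scaling both IP and input leaves every call identical once the
  # mean-coverage floor is already cleared
  dip <- c(rep(90, 50), rep(10, 150)); din <- c(rep(20, 50), rep(10, 150))
  pk1 <- call_peaks(coverage_set(list(t = dip), "IP", "r"),
                    coverage_set(list(t = din), "input", "r"))
  pk3 <- call_peaks(coverage_set(list(t = dip * 3), "IP", "r"),
                    coverage_set(list(t = din * 3), "input", "r"))
  expect_equal(pk3$poi, pk1$poi)
  expect_equal(pk3$start, pk1$start)
})

test_that("peak calling is independent of transcript iteration order", {
  set.seed(13)
  depths_ip <- list(); depths_in <- list()
  for (tx in paste0("t", 1:6)) {
    pr <- random_track_pair(180)
    depths_ip[[tx]] <- pr$ip; depths_in[[tx]] <- pr$input
  }
  fwd <- call_peaks(coverage_set(depths_ip, "IP", "r"),
                    coverage_set(depths_in, "input", "r"))
  rev_ <- call_peaks(coverage_set(rev(depths_ip), "IP", "r"),
                     coverage_set(rev(depths_in), "input", "r"))
  expect_equal(as.data.frame(fwd), as.data.frame(rev_))
})
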