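test_that("transcript overlap reports symmetric percent shared over the union", {
  r <- transcript_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(r$n_shared, 2)
  expect_equal(r$n_union, 4)
  expect_equal(r$percent_shared, 50)
  expect_equal(transcript_overlap(c("a"), c("a"))$percent_shared, 100)
  expect_equal(transcript_overlap(c("a"), c("b"))$percent_shared, 0)
  expect_true(is.na(transcript_overlap(character(0),
                                       character(0))$percent_shared))
  # symmetry; and percent is 100 only for equal nonempty sets
  x <- c("a", "b"); y <- c("b", "c", "d")
  expect_equal(transcript_overlap(x, y)$percent_shared,
               transcript_overlap(y, x)$percent_shared)
  expect_lt(transcript_overlap(x, y)$percent_shared, 100)
  # asymmetric denominators remain available
  expect_equal(transcript_overlap(x, y, "first")$percent_shared, 50)
})

test_that("peaks-encompassing-sites counts use half-open containment", {
  pk <- data.frame(transcript_id = c("t1", "t2"), start = c(10L, 0L),
                   end = c(60L, 50L), pom_ip = 9, pom_input = 1, poi = 9,
                   replicates = "rep1", motifs = NA, stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  sites <- data.frame(transcript_id = c("t1", "t1", "t1", "t2", "t9"),
                      pos = c(10L, 30L, 59L, 50L, 5L))
  r <- peaks_encompassing_sites(pk, sites)
  expect_equal(r$n_peaks_with_site, 1)   # t2 site at pos 50 = end: outside
  expect_equal(r$n_sites_in_peaks, 3)    # one peak holding 3 sites
  expect_equal(peaks_encompassing_sites(pk, sites[0, ]),
               list(n_peaks_with_site = 0L, n_sites_in_peaks = 0L))
  # etam_sites input: only called rows count
  st <- data.frame(transcript_id = "t1", pos = 30L, called = FALSE)
  expect_equal(peaks_encompassing_sites(pk, st)$n_sites_in_peaks, 0)
})

transform_ann <- function(ann, len) {
  ann$end <- ann$start + len; ann$length <- len
  ann
}

test_that("metagene profile bins relative positions and ratios modified motifs", {
  # one transcript of length 100 with a motif at the start of each decile
  seq_parts <- vapply(0:9, function(b) {
    paste0("GCCAU", strrep("C", 5))
  }, character(1))
  seqs <- c(tx = paste(seq_parts, collapse = ""))
  ann <- data.frame(transcript_id = "tx", seqid = "c", start = 0L, end = 100L,
                    strand = "+", length = 100L, stringsAsFactors = FALSE)
  class(ann) <- c("tx_annotation", "data.frame")
  pk <- data.frame(transcript_id = "tx", start = 0L, end = 50L, pom_ip = 9,
                   pom_input = 1, poi = 9, replicates = "r", motifs = NA,
                   stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  prof <- metagene_profile(pk, seqs, ann)
  expect_equal(prof$n_total, rep(1, 10))
  expect_equal(prof$ratio, c(rep(1, 5), rep(0, 5)))   # peak covers bins 1-5
  # no peaks -> all-zero ratios where motifs exist
  empty_pk <- pk[0, ]
  expect_equal(metagene_profile(empty_pk, seqs, ann)$ratio, rep(0, 10))
  # numerator never exceeds denominator, and boundary positions bin correctly
  expect_true(all(prof$n_modified <= prof$n_total))
  mp <- metagene_profile(pk, c(tx = paste0(strrep("C", 99), "GCCAUCCCCC")),
                         transform_ann(ann, 109L))
  expect_equal(which(mp$n_total == 1), 10)  # rel pos 99/109 = 0.908 -> bin 10
})

test_that("metagene pooling is additive over transcripts", {
  seqs <- c(a = paste0("GCCAU", strrep("C", 95)),
            b = paste0(strrep("C", 50), "GCCAU", strrep("C", 45)))
  ann <- data.frame(transcript_id = c("a", "b"), seqid = "c",
                    start = c(0L, 0L), end = c(100L, 100L), strand = "+",
                    length = c(100L, 100L), stringsAsFactors = FALSE)
  class(ann) <- c("tx_annotation", "data.frame")
  pk <- data.frame(transcript_id = c("a", "b"), start = 0L, end = 100L,
                   pom_ip = 9, pom_input = 1, poi = 9, replicates = "r",
                   motifs = NA, stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  pooled <- metagene_profile(pk, seqs, ann)
  pa <- metagene_profile(pk[1, ], seqs["a"], ann[1, ])
  pb <- metagene_profile(pk[2, ], seqs["b"], ann[2, ])
  expect_equal(pooled$n_total, pa$n_total + pb$n_total)
  expect_equal(pooled$n_modified, pa$n_modified + pb$n_modified)
})

test_that("rank-sum comparison behaves at the extremes and warns on tiny samples", {
  set.seed(2)
  x <- runif(20)
  expect_equal(compare_profiles(x, x), 1, tolerance = 0.05)
  lo <- runif(20, 0, 0.1); hi <- runif(20, 0.9, 1)
  expect_lt(compare_profiles(lo, hi), 1e-6)
  expect_warning(p <- compare_profiles(numeric(1), x), "fewer than 2")
  expect_true(is.na(p))
})

test_that("RPKM follows the definition and zero library size errors", {
  r <- compute_rpkm(c(g1 = 10), c(g1 = 1000), 1e6)
  expect_equal(r$rpkm, 10)
  r2 <- compute_rpkm(c(g1 = 7, g2 = 0), c(g1 = 350, g2 = 500), 2e6)
  expect_equal(r2$rpkm, c(10, 0))
  expect_error(compute_rpkm(c(g1 = 1), c(g1 = 100), 0), "positive")
})

test_that("expression groups are deterministic equal thirds with remainder low", {
  v9 <- setNames(as.numeric(1:9), paste0("g", 1:9))
  g9 <- expression_groups(v9)
  expect_equal(unname(table(g9)[c("low", "mid", "high")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_true(all(g9[c("g1", "g2", "g3")] == "low"))
  expect_true(all(g9[c("g7", "g8", "g9")] == "high"))
  v10 <- setNames(as.numeric(1:10), paste0("g", sprintf("%02d", 1:10)))
  g10 <- expression_groups(v10)
  expect_equal(sum(g10 == "low"), 4)     # remainder goes to the lowest group
  # all-equal values: grouping still deterministic via id tie-break
  ve <- setNames(rep(1, 6), paste0("g", 6:1))
  ge <- expression_groups(ve)
  expect_equal(ge[order(names(ge))],
               setNames(c("low", "low", "mid", "mid", "high", "high"),
                        paste0("g", 1:6)))
  expect_error(expression_groups(v9[1:2]), "fewer genes")
})

test_that("expression comparison flags known fold changes and correlates", {
  genes <- paste0("g", 1:50)
  set.seed(9)
  base <- data.frame(gene = genes, count = 1, rpkm = runif(50, 5, 50),
                     log2_rpkm = NA, stringsAsFactors = FALSE)
  up4 <- base; up4$rpkm[1] <- base$rpkm[1] * 4
  cmp <- expression_comparison(base, up4, pseudocount = 0)
  expect_equal(cmp$table$log2fc[1], 2)
  expect_true(cmp$table$de_flag[1])
  expect_false(any(cmp$table$de_flag[-1]))
  same <- expression_comparison(base, base)
  expect_true(all(same$table$log2fc == 0))
  expect_equal(same$pearson_r, 1)
  # Pearson r on log2 RPKM is invariant under multiplicative rescaling
  scaled <- base; scaled$rpkm <- base$rpkm * 7
  expect_equal(expression_comparison(base, scaled, pseudocount = 0)$pearson_r,
               1)
  other <- base; other$gene <- paste0("h", 1:50)
  expect_error(expression_comparison(base, other), "shared")
})

test_that("methylation-by-expression counts and subset tracking are exact", {
  groups <- setNames(rep(c("low", "mid", "high"), each = 3), paste0("g", 1:9))
  pk <- data.frame(transcript_id = c("g7", "g8", "g1"), start = 0L, end = 50L,
                   pom_ip = 9, pom_input = 1, poi = 9, replicates = "r",
                   motifs = NA, stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  r <- methylation_by_expression(pk, groups,
                                 tracked = c("g7", "g8", "g9"))
  expect_equal(unname(r$methylated_by_group), c(1L, 0L, 2L))
  expect_equal(r$n_retained, 2)
  expect_equal(r$n_lost, 1)
  expect_equal(unname(r$retained_by_group), c(0L, 0L, 2L))
  # no methylation at all
  r0 <- methylation_by_expression(pk[0, ], groups)
  expect_true(all(r0$methylated_by_group == 0))
  # identical stress peakset -> nothing lost
  r1 <- methylation_by_expression(pk, groups, tracked = c("g7", "g8", "g1"))
  expect_equal(r1$n_lost, 0)
})

test_that("recovery metrics count 1-nt overlaps for peaks and identity for sites", {
  truth <- data.frame(transcript_id = paste0("t", 1:10), start = 100L,
                      end = 150L, stringsAsFactors = FALSE)
  called <- data.frame(transcript_id = c(paste0("t", 1:8), "t1", "t2"),
                       start = c(rep(149L, 8), 500L, 500L),
                       end = c(rep(200L, 8), 550L, 550L),
                       stringsAsFactors = FALSE)
  m <- recovery_metrics(called, truth)
  expect_equal(m$precision, 0.8)       # 8 of 10 calls touch truth (1-nt ok)
  expect_equal(m$recall, 0.8)
  perfect <- recovery_metrics(truth, truth)
  expect_equal(c(perfect$precision, perfect$recall), c(1, 1))
  none <- recovery_metrics(called[0, ], truth)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  # site matching is exact identity
  st_truth <- data.frame(transcript_id = "t1", position = c(5L, 9L))
  st_called <- data.frame(transcript_id = "t1", pos = c(5L, 7L),
                          called = TRUE)
  ms <- recovery_metrics(st_called, st_truth)
  expect_equal(ms$precision, 0.5)
  expect_equal(ms$recall, 0.5)
})
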