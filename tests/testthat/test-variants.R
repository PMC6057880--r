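# pileup of one column built from explicit base/quality observations
pileup_col <- function(bases, quals, chrom = "chr7", pos = 140453136L,
                       ref = "A") {
  data.frame(chrom = chrom, pos = pos, ref = ref, base = bases, qual = quals,
             stringsAsFactors = FALSE)
}

test_that("the caller applies all four inclusive thresholds", {
  # depth 1: below min-coverage, no call
  expect_equal(nrow(call_pileup(pileup_col("T", 30))), 0L)
  # everything at its minimum: depth 2, 2 alt reads, vaf 1, quals 20
  calls <- call_pileup(pileup_col(c("T", "T"), c(20, 20)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$vaf, 1)
  expect_equal(calls$avg_alt_quality, 20)
  expect_equal(calls$alt, "T")
  # vaf boundary inclusive: 2/200 = 0.01 is called
  big <- pileup_col(c(rep("A", 198), "T", "T"), c(rep(30, 198), 15, 15))
  expect_equal(nrow(call_pileup(big)), 1L)
  # just under the boundary: 2/201 < 0.01 is not
  bigger <- pileup_col(c(rep("A", 199), "T", "T"), c(rep(30, 199), 15, 15))
  expect_equal(nrow(call_pileup(bigger)), 0L)
  # quality floor: a sub-threshold observation supports nothing but
  # still deepens the column
  mixed <- pileup_col(c("A", "T", "T", "T"), c(30, 14, 20, 20))
  res <- call_pileup(mixed)
  expect_equal(res$depth, 4L)
  expect_equal(res$alt_reads, 2L)
  expect_equal(res$vaf, 0.5)
  expect_equal(res$avg_alt_quality, 20)
  expect_error(call_pileup(pileup_col("N", 30)), "invalid base")
})

test_that("degenerate thresholds emit exactly the non-reference base set", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    pu <- pileup_col(bases, rep(30, n), ref = "G")
    calls <- call_pileup(pu, min_coverage = 1, min_reads2 = 1,
                         min_var_freq = 0, min_avg_qual = 0)
    expect_setequal(calls$alt, setdiff(unique(bases), "G"))
  }
})

test_that("multi-column pileups keep columns independent", {
  pu <- rbind(
    pileup_col(c("T", "T", "A"), c(20, 25, 30), pos = 100L),
    pileup_col(c("C", "C"), c(18, 22), pos = 200L, ref = "G"),
    pileup_col("T", 40, pos = 300L)  # depth 1, never called
  )
  calls <- call_pileup(pu)
  expect_equal(calls$pos, c(100L, 200L))
  expect_equal(calls$alt, c("T", "C"))
  expect_equal(calls$vaf, c(2 / 3, 1))
  conflict <- rbind(pileup_col("T", 30, pos = 5L, ref = "A"),
                    pileup_col("T", 30, pos = 5L, ref = "C"))
  expect_error(call_pileup(conflict), "conflicting reference")
})

test_that("call-set merging unions on the key and keeps the deeper record", {
  per <- call_pileup(pileup_col(c("T", "T", "T", "A"), c(30, 30, 30, 30)),
                     sample_id = "S1")
  pooled <- call_pileup(pileup_col(c("T", "T", "T", "T", "T", "A"),
                                   rep(30, 6)),
                        sample_id = "S1", source = "pooled")
  merged <- merge_callsets(per, pooled)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$alt_reads, 5L)
  expect_equal(merged$source, "pooled")
  # disjoint sets concatenate
  other <- call_pileup(pileup_col(c("C", "C"), c(30, 30), pos = 999L,
                                  ref = "G"), sample_id = "S2")
  expect_equal(nrow(merge_callsets(per, other)), 2L)
  # identical duplicates collapse; per-sample wins the tie
  dup <- per; dup$source <- "pooled"
  m2 <- merge_callsets(per, dup)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$source, "per_sample")
  # idempotent and commutative
  expect_equal(merge_callsets(merged, merged[0, ]), merged)
  expect_equal(merge_callsets(pooled, per)[, names(merged)], merged)
  bad <- per; bad$ref <- "C"
  expect_error(merge_callsets(per, bad), "conflicting reference")
})

test_that("the cascade retains and discards per the annotation rules", {
  onc <- gen_variants(variant_sim_spec(0, 1, seed = 1))
  # oncogene at a COSMIC site, exonic missense, dbSNP absent: retained
  expect_true(all(filter_cascade(onc)$verdict == "retained"))
  v <- gen_variants(variant_sim_spec(1, 1, seed = 2))
  out <- filter_cascade(v)
  expect_equal(out$verdict, v$truth)
  # dbSNP nonflagged always discards
  expect_true("discarded:dbsnp_nonflagged" %in% out$verdict)
  # novel suppressor with clean context and absent from populations retained
  novel <- v[v$truth == "retained" & !v$in_cosmic, ]
  expect_true(nrow(novel) > 0)
  expect_error(filter_cascade(v[, setdiff(names(v), "region")]),
               "annotation column")
  miss <- v; miss$in_cosmic[1] <- NA
  expect_error(filter_cascade(miss), "missing annotation")
})

test_that("the cascade is a pure per-record function: order never matters", {
  v <- gen_variants(variant_sim_spec(3, 3, seed = 9))
  base <- filter_cascade(v)
  set.seed(4)
  for (i in 1:5) {
    perm <- sample(nrow(v))
    shuffled <- filter_cascade(v[perm, ])
    expect_equal(shuffled$verdict, base$verdict[perm])
  }
})

test_that("manual rescue bypasses the cascade and is marked low confidence", {
  v <- gen_variants(variant_sim_spec(1, 1, seed = 3))
  victim <- which(v$truth != "retained")[1]
  wl <- v[victim, c("sample_id", "chrom", "pos", "ref", "alt")]
  out <- filter_cascade(v, rescue = wl)
  expect_equal(out$verdict[victim], "retained")
  expect_equal(out$source[victim], "manual")
  expect_equal(flag_confidence(out$alt_reads[victim], out$source[victim]),
               "low")
})

test_that("confidence flags low support and manual additions", {
  expect_equal(flag_confidence(1), "low")
  expect_equal(flag_confidence(2), "low")
  expect_equal(flag_confidence(3), "high")
  expect_equal(flag_confidence(50), "high")
  expect_equal(flag_confidence(3, source = "manual"), "low")
  expect_equal(flag_confidence(c(1, 50), c("per_sample", "per_sample")),
               c("low", "high"))
  expect_error(flag_confidence(-1), "negative")
})

test_that("homopolymer adjacency follows the inclusive run definition", {
  expect_true(homopolymer_adjacent("ACGTAAAAAG", 4))   # 5' neighbour of run
  expect_true(homopolymer_adjacent("ACGTAAAAAG", 10))  # 3' neighbour
  expect_true(homopolymer_adjacent("ACGAAAAAAC", 6))   # inside a 6-run
  expect_false(homopolymer_adjacent("ACGTTTACGT", 5))  # max run 3
  expect_false(homopolymer_adjacent("AAAAACGTCGTCG", 8))  # 2 bp past the run
  expect_true(homopolymer_adjacent("ACGTAAAACG", 4, run_min = 4))
  expect_error(homopolymer_adjacent("ACG", 2), "too short")
  expect_error(homopolymer_adjacent("ACGTAAAAAG", 11), "outside")
})

test_that("oncoprint collapses cell states and orders samples by group", {
  samples <- c("S1", "S2", "S3", "S4")
  groups <- c(S1 = "suppression", S2 = "progression", S3 = "regression",
              S4 = "progression")
  vars <- data.frame(
    gene = c("BRAF", "BRAF", "NRAS", "BRAF"),
    sample_id = c("S2", "S2", "S1", "S3"),
    confidence = c("low", "high", "low", "high")
  )
  op <- oncoprint(vars, samples, c("BRAF", "NRAS"), groups)
  expect_equal(colnames(op$matrix), c("S2", "S4", "S1", "S3"))
  expect_equal(op$matrix["BRAF", "S2"], "mutated_high_conf")  # high wins
  expect_equal(op$matrix["NRAS", "S1"], "mutated_low_conf")
  expect_equal(op$matrix["NRAS", "S2"], "none")
  empty <- oncoprint(vars[0, ], samples, "BRAF", groups)
  expect_true(all(empty$matrix == "none"))
  expect_error(oncoprint(vars, c(samples, "S9"), "BRAF", groups),
               "without a response group")
  prev <- oncoprint_prevalence(op)
  expect_equal(prev$n_mutated[prev$gene == "BRAF"], 2L)
  expect_equal(prev$percent[prev$gene == "BRAF"], 50)
})

test_that("simulated cohort variants drive prevalence to the planted counts", {
  samples <- sprintf("S%02d", 1:31)
  vars <- gen_cohort_variants(samples, c(BRAF = 20, NRAS = 11), seed = 2)
  groups <- setNames(rep(c("progression", "suppression", "regression"),
                         c(10, 13, 8)), samples)
  op <- oncoprint(vars, samples, c("BRAF", "NRAS"), groups)
  prev <- oncoprint_prevalence(op)
  expect_equal(prev$n_mutated, c(20L, 11L))
  expect_identical(gen_cohort_variants(samples, c(BRAF = 20), seed = 2),
                   gen_cohort_variants(samples, c(BRAF = 20), seed = 2))
  expect_error(gen_cohort_variants(samples, c(BRAF = 40)), "between 0")
})

test_that("gene-role table covers the recurrent melanoma panel", {
  roles <- melanoma_gene_roles()
  expect_true(all(c("BRAF", "NRAS", "NF1", "KIT", "TP53", "CDKN2A",
                    "DDX3X") %in% roles$gene))
  expect_equal(roles$gene_role[roles$gene == "BRAF"], "oncogene")
  expect_equal(roles$gene_role[roles$gene == "NF1"], "tumor_suppressor")
  expect_true(all(roles$gene_role %in% c("oncogene", "tumor_suppressor")))
})

test_that("variant TSV and VCF round-trips preserve the annotated table", {
  v <- filter_cascade(gen_variants(variant_sim_spec(1, 1, seed = 6)))
  v$confidence <- flag_confidence(v$alt_reads, v$source)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(v, tsv)
  back <- read_variants_tsv(tsv)
  expect_equal(back$verdict, v$verdict)
  expect_equal(back$in_cosmic, v$in_cosmic)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, vcf)
  back2 <- read_variants_vcf(vcf)
  expect_equal(back2$pos, v$pos)
  expect_equal(back2$verdict, v$verdict)
  expect_equal(back2$gene_role, v$gene_role)
  expect_equal(back2$alt_reads, v$alt_reads)
})
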