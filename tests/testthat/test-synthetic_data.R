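test_that("generated motif sequences scan back to their requested class", {
  set.seed(3)
  specs <- expand.grid(cls = c("CANONICAL", "LONG_LOOP", "BULGE"),
                       stringsAsFactors = FALSE)
  for (r in 1:10) {
    for (cls in specs$cls) {
      s <- pqs_motif_seq(cls)
      h <- scan_pqs(s)
      expect_equal(h$motif_class, cls)
      expect_equal(c(h$start, h$end), c(0L, nchar(s)))
    }
    for (can in 0:3) {
      s <- pqs_motif_seq("TWO_QUARTET", can)
      h <- scan_pqs(s)
      expect_equal(h$motif_class, "TWO_QUARTET")
      expect_equal(h$canonicality, can)
    }
  }
})

test_that("same seed and config give bit-identical outputs", {
  cfg <- synthetic_config(seed = 42, n_genes = 8)
  tx1 <- make_transcriptome(cfg)
  tx2 <- make_transcriptome(cfg)
  expect_identical(tx1$genome, tx2$genome)
  expect_identical(tx1$truth, tx2$truth)
  expect_identical(tx1$annotation, tx2$annotation)
  nwk <- "((ref:1,sp1:1):1,(sp2:1,sp3:1):1);"
  a1 <- make_alignment(nwk, seed = 9, sub_rate = 0.1)
  a2 <- make_alignment(nwk, seed = 9, sub_rate = 0.1)
  expect_identical(a1$alignment, a2$alignment)
  # a different seed changes the draw
  expect_false(identical(tx1$genome,
                         make_transcriptome(synthetic_config(seed = 43,
                                                             n_genes = 8))$genome))
})

test_that("every planted PQS is recovered by re-scanning the emitted sequence", {
  cfg <- synthetic_config(seed = 7, n_genes = 12)
  tx <- make_transcriptome(cfg)
  pqs <- tx$truth[tx$truth$kind == "pqs", ]
  expect_gt(nrow(pqs), 15L)
  expect_true(any(pqs$region == "FIVE_UTR"), )
  for (i in seq_len(nrow(pqs))) {
    m <- tx$models[[pqs$transcript_id[i]]]
    h <- scan_pqs(substring(m$sequence, pqs$t_start[i] + 1L, pqs$t_end[i]))
    expect_equal(h$motif_class, pqs$motif_class[i])
    expect_equal(h$canonicality, pqs$canonicality[i])
    # region label agrees with the planted region
    expect_equal(assign_region(m, c(pqs$t_start[i], pqs$t_end[i])),
                 pqs$region[i])
    # guard zones: a full-transcript scan yields a hit at exactly this span
    full <- scan_pqs(m$sequence)
    at <- full[full$start == pqs$t_start[i], , drop = FALSE]
    expect_equal(nrow(at), 1L)
    expect_equal(at$end, pqs$t_end[i])
  }
  # CDS recipes decompose through their planted codons
  cds <- pqs[pqs$region == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    m <- tx$models[[cds$transcript_id[i]]]
    codons <- strsplit(cds$codons[i], ",")[[1]]
    expect_equal((cds$t_start[i] - m$cds_span[1]) %% 3L, 0L)
    got <- substring(cds_sequence(m),
                     cds$t_start[i] - m$cds_span[1] + 1L,
                     cds$t_end[i] - m$cds_span[1])
    expect_equal(got, paste(codons, collapse = ""))
  }
})

test_that("emitted files pass the package's own readers round-trip", {
  cfg <- synthetic_config(seed = 5, n_genes = 6)
  tx <- make_transcriptome(cfg)
  dir <- tempfile("synth")
  write_synthetic_transcriptome(tx, dir)
  expect_no_warning({
    models <- load_annotation(file.path(dir, "annotation.gtf"),
                              file.path(dir, "genome.fa"))
  })
  expect_setequal(names(models), names(tx$models))
  for (tid in names(models)) {
    expect_equal(models[[tid]]$sequence, tx$models[[tid]]$sequence)
    expect_equal(models[[tid]]$cds_span, tx$models[[tid]]$cds_span)
    expect_equal(models[[tid]]$strand, tx$models[[tid]]$strand)
  }
  calls <- read_tsv_table(file.path(dir, "rg4_calls.tsv"))
  expect_equal(nrow(calls), nrow(tx$rg4_calls))
  bed <- read_bed(file.path(dir, "rg4_calls.bed"))
  expect_equal(bed$start, tx$rg4_calls$start)
})

test_that("detection probability thins the call set as specified", {
  cfg0 <- synthetic_config(seed = 6, n_genes = 10, detection_prob = 0)
  expect_equal(nrow(make_transcriptome(cfg0)$rg4_calls), 0L)
  cfg1 <- synthetic_config(seed = 6, n_genes = 10, detection_prob = 1)
  tx1 <- make_transcriptome(cfg1)
  expect_equal(nrow(tx1$rg4_calls), nrow(tx1$truth))
  cfg5 <- synthetic_config(seed = 6, n_genes = 40, detection_prob = 0.5)
  tx5 <- make_transcriptome(cfg5)
  frac <- nrow(tx5$rg4_calls) / nrow(tx5$truth)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
})

test_that("zero-rate alignments are invariant and identities hit their truth", {
  nwk <- "((ref:1,sp1:1):1,(sp2:1.5,sp3:1.5):0.5);"
  al <- make_alignment(nwk, seed = 31, sub_rate = 0)
  expect_true(all(apply(al$alignment, 2, function(col)
    length(unique(col)) == 1L)))
  expect_equal(unname(al$truth$identity_vs_ref),
               rep(1, length(al$truth$identity_vs_ref)))
  # MAF coordinates are consistent: per-species sizes sum to src_size
  for (sp in rownames(al$alignment)) {
    sizes <- vapply(al$maf, function(b)
      b$size[b$src == paste0(sp, ".chr1")], integer(1))
    expect_equal(sum(sizes), sum(al$alignment[sp, ] != "-"))
  }
})

test_that("deletions never touch the motif when protected and MAF stays valid", {
  nwk <- "((ref:1,sp1:1):1,(sp2:1,sp3:1):1);"
  al <- make_alignment(nwk, seed = 13, sub_rate = 0, del_rate = 0.05,
                       n_blocks = 3)
  # reference row has no gaps in the emitted MAF
  for (b in al$maf) {
    expect_false(grepl("-", b$text[b$src == "ref.chr1"]))
  }
  # motif columns carry no deletions in any species
  w <- extract_windows(al$maf, al$rg4, "ref", flank = 0L)[[1]]
  expect_true(all(w$mat[, w$motif_cols] != "-"))
  recs <- conservation_records(w = list(w))
  expect_true(all(recs$has_pqs))
})

test_that("family generator ages follow the clade construction", {
  nwk <- "(((A:50,B:50):150,(C:120,D:120):80):300,(E:400,F:400):100);"
  clades <- list(Inner = c("A", "B"), Mid = c("A", "B", "C", "D"),
                 All = c("A", "B", "C", "D", "E", "F"))
  fm <- make_families(nwk, clades, n_families = 50, seed = 2)
  # a family spanning all leaves has the root age
  allfam <- fm$family_truth$family_id[fm$family_truth$clade_label == "All"][1]
  sp <- fm$families$species[fm$families$family_id == allfam]
  expect_equal(lca_age(fm$dtree, sp)$age_mya, 500)
  # reproducibility
  fm2 <- make_families(nwk, clades, n_families = 50, seed = 2)
  expect_identical(fm$families, fm2$families)
  expect_identical(fm$family_truth, fm2$family_truth)
})
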