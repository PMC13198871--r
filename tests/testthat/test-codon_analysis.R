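test_that("codon enrichment reproduces hand arithmetic on a toy gene", {
  # CDS: 20 codons, exactly 2 GGA inside the motif span and 2 elsewhere
  codons <- c("ATG", "ACT", "GGA", "TCT", "ACT", "GGA", "GGA", "GGT",
              rep("ACT", 11), "CAT")
  m <- toy_coding_model(paste(codons, collapse = ""))
  cs <- m$cds_span[1]
  hits <- data.frame(transcript_id = "toy", start = cs + 3L * 5L,
                     end = cs + 3L * 8L)  # codons GGA GGA GGT
  enr <- codon_enrichment(hits, list(toy = m))
  all_codons <- c(codons, "TAA")  # baseline = full CDS incl. stop
  f_base <- function(cod) sum(all_codons == cod) / length(all_codons)
  gga <- enr[enr$codon == "GGA", ]
  expect_equal(gga$count_in_rg4, 2L)
  expect_equal(gga$freq_in_rg4, 2 / 3)
  expect_equal(gga$freq_in_baseline, f_base("GGA"))
  expect_equal(gga$enrichment, (2 / 3) / f_base("GGA"))
  ggt <- enr[enr$codon == "GGT", ]
  expect_equal(ggt$freq_in_rg4, 1 / 3)
  # frequencies are proper distributions
  expect_equal(sum(enr$freq_in_rg4), 1)
  expect_equal(sum(enr$freq_in_baseline), 1)
  # codons absent from the motif have enrichment 0
  expect_true(all(enr$enrichment[enr$count_in_rg4 == 0] == 0))
  # sorted by decreasing enrichment, flag at >= 2
  expect_true(all(diff(enr$enrichment) <= 0))
  expect_equal(enr$enriched, enr$enrichment >= 2)
})

test_that("a codon is tallied only when >= 2 of its bases lie in the motif", {
  codons <- c("ATG", rep("ACT", 5), "GGA", "GGA", "GGA", rep("ACT", 10))
  m <- toy_coding_model(paste(codons, collapse = ""))
  cs <- m$cds_span[1]
  # motif covering codons 6..8 plus 1 base of codon 9 -> codon 9 not counted
  h1 <- data.frame(transcript_id = "toy", start = cs + 18L, end = cs + 28L)
  e1 <- codon_enrichment(h1, list(toy = m))
  expect_equal(sum(e1$count_in_rg4), 3L)
  # shifting to cover 2 bases of codon 9 adds it
  h2 <- data.frame(transcript_id = "toy", start = cs + 18L, end = cs + 29L)
  e2 <- codon_enrichment(h2, list(toy = m))
  expect_equal(sum(e2$count_in_rg4), 4L)
  # a hit starting 1 base before a codon boundary does not add that codon
  h3 <- data.frame(transcript_id = "toy", start = cs + 20L, end = cs + 27L)
  e3 <- codon_enrichment(h3, list(toy = m))
  expect_equal(sum(e3$count_in_rg4), 2L)
})

test_that("each harboring gene's canonical CDS enters the baseline once", {
  codons <- c("ATG", "GGA", "GGA", "GGT", rep("ACT", 10))
  m <- toy_coding_model(paste(codons, collapse = ""))
  cs <- m$cds_span[1]
  one <- data.frame(transcript_id = "toy", start = cs + 3L, end = cs + 12L)
  two <- rbind(one, one)  # two motifs in the same gene
  e1 <- codon_enrichment(one, list(toy = m))
  e2 <- codon_enrichment(two, list(toy = m))
  expect_equal(e1$count_in_baseline[e1$codon == "ACT"],
               e2$count_in_baseline[e2$codon == "ACT"])
})

test_that("tract decomposition matches frame arithmetic and the brute-force count", {
  # CDS "ATGGGA...": GGG at CDS offsets 2-4 spans codons 0 and 1
  m1 <- toy_coding_model(paste0("ATGGGA", strrep("ACT", 8)))
  d <- decompose_tract(m1, m1$cds_span[1] + 2L, 3L)
  expect_equal(d$tract_kind, "GGG")
  expect_equal(d$n_codons, 2L)
  expect_equal(d$residues, c("M", "G"))
  # CDS "GGGACC...": GGG at offsets 0-2 is one glycine codon
  m2 <- toy_coding_model(paste0("GGGACC", strrep("ACT", 8)))
  d <- decompose_tract(m2, m2$cds_span[1], 3L)
  expect_equal(d$n_codons, 1L)
  expect_equal(d$residues, "G")
  # CDS "AGGTTT...": GG at offsets 1-2 stays inside the arginine codon
  m3 <- toy_coding_model(paste0("AGGTTT", strrep("ACT", 8)))
  d <- decompose_tract(m3, m3$cds_span[1] + 1L, 2L)
  expect_equal(d$tract_kind, "GG")
  expect_equal(d$n_codons, 1L)
  expect_equal(d$residues, "R")
  # n_codons equals the brute-force distinct-codon count on random tracts
  set.seed(9)
  m4 <- toy_coding_model(paste(sample(rg4evo:::SENSE_CODONS, 40, TRUE),
                               collapse = ""))
  for (r in 1:20) {
    s <- m4$cds_span[1] + sample(0:100, 1)
    len <- sample(2:3, 1)
    want <- length(unique((seq.int(s, s + len - 1L) - m4$cds_span[1]) %/% 3L))
    expect_equal(decompose_tract(m4, s, len)$n_codons, want)
  }
  # tracts crossing the CDS end are excluded with a message
  expect_message(d <- decompose_tract(m1, m1$cds_span[2] - 1L, 3L), "excluded")
  expect_null(d)
})

test_that("amino-acid usage tallies every tract residue once per tract", {
  m <- toy_coding_model(paste0("GGGACCGGTGGA", strrep("ACT", 8)))
  cs <- m$cds_span[1]
  hits <- scan_pqs_set(setNames(m$sequence, "toy"))
  # build a synthetic hit frame with two known tracts
  fake <- data.frame(transcript_id = "toy", start = cs, end = cs + 12L,
                     tract_starts = I(list(c(cs, cs + 6L, cs + 9L, cs + 9L))),
                     tract_lens = I(list(c(3L, 2L, 2L, 2L))),
                     tract_bulge_offset = I(list(rep(NA_integer_, 4))),
                     loop_lens = I(list(c(1L, 1L, 1L))))
  usage <- tract_aa_usage(fake, list(toy = m))
  expect_equal(sort(unique(usage$aa)), c("G"))
  expect_equal(sum(usage$count), 4L)  # one glycine residue per tract here
  # empty input gives an empty table
  expect_equal(nrow(tract_aa_usage(fake[0, ], list(toy = m))), 0L)
  # subsetting restricts the residues
  expect_equal(nrow(tract_aa_usage(fake, list(toy = m), aa_subset = "E")), 0L)
})

test_that("a planted glycine-codon spike is recovered within sampling tolerance", {
  cfg <- synthetic_config(seed = 21, n_genes = 200,
                          embeddings = default_embeddings()[0, ],
                          spike = list(codon = "GGA", factor = 5,
                                       n_motifs = 200L, motif_codons = 12L),
                          cds_codons = c(550L, 650L))
  tx <- make_transcriptome(cfg)
  hits <- data.frame(transcript_id = tx$truth$transcript_id,
                     start = tx$truth$t_start, end = tx$truth$t_end)
  enr <- codon_enrichment(hits, tx$models)
  got <- enr$enrichment[enr$codon == "GGA"]
  expect_lt(abs(got - 5) / 5, 0.15)
  expect_true(enr$enriched[enr$codon == "GGA"])
})

test_that("without a spike almost no codon reaches 2x enrichment", {
  cfg <- synthetic_config(seed = 22, n_genes = 100,
                          embeddings = default_embeddings()[0, ],
                          spike = list(codon = "GGA", factor = 1,
                                       n_motifs = 100L, motif_codons = 12L),
                          cds_codons = c(550L, 650L))
  tx <- make_transcriptome(cfg)
  hits <- data.frame(transcript_id = tx$truth$transcript_id,
                     start = tx$truth$t_start, end = tx$truth$t_end)
  enr <- codon_enrichment(hits, tx$models)
  expect_lt(mean(enr$enrichment >= 2), 0.05)
})
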