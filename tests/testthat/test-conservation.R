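# Hand-written two-block, three-species MAF fixture. Reference rows:
#   block 1: "AAGG-CC" (ref positions 0..5, one insertion column)
#   block 2: "GGGG"    (ref positions 6..9)
maf_fixture <- function() {
  b1 <- data.frame(
    src = c("ref.chr1", "sp2.chr1", "sp3.chr1"),
    start = c(0L, 0L, 0L), size = c(6L, 7L, 5L), strand = "+",
    src_size = c(10L, 11L, 9L),
    text = c("AAGG-CC", "AAGGTCC", "--GGTCC"),
    stringsAsFactors = FALSE)
  b2 <- data.frame(
    src = c("ref.chr1", "sp2.chr1"),
    start = c(6L, 7L), size = c(4L, 3L), strand = "+",
    src_size = c(10L, 11L), text = c("GGGG", "GG-G"),
    stringsAsFactors = FALSE)
  list(b1, b2)
}

test_that("window extraction stitches blocks like the hand-computed matrix", {
  maf <- maf_fixture()
  rg4 <- data.frame(name = "r1", chrom = "chr1", start = 2L, end = 9L,
                    strand = "+", stringsAsFactors = FALSE)
  w <- extract_windows(maf, rg4, ref_species = "ref", flank = 1L)[[1]]
  # window [1, 10): block-1 columns 2..7 (incl. the insertion), block-2 1..4
  want <- rbind(
    ref = c("A", "G", "G", "-", "C", "C", "G", "G", "G", "G"),
    sp2 = c("A", "G", "G", "T", "C", "C", "G", "G", "-", "G"),
    sp3 = c("-", "G", "G", "T", "C", "C", "-", "-", "-", "-"))
  expect_equal(unname(w$mat), unname(want))
  expect_equal(rownames(w$mat), c("ref", "sp2", "sp3"))
  expect_equal(w$ref_col_pos, c(1L, 2L, 3L, NA, 4L, 5L, 6L, 7L, 8L, 9L))
  expect_equal(which(w$motif_cols), c(2L, 3L, 5L, 6L, 7L, 8L, 9L))
  # identities over the 7 motif reference bases "GG CC GGG"
  expect_equal(sequence_identity(w, "ref"), 1.0)
  expect_equal(sequence_identity(w, "sp2"), 6 / 7)  # gap at position 8
  expect_equal(sequence_identity(w, "sp3"), 4 / 7)  # absent from block 2
})

test_that("rG4s outside all blocks leave every species unaligned", {
  maf <- maf_fixture()
  rg4 <- data.frame(name = "r2", chrom = "chr9", start = 2L, end = 8L,
                    strand = "+", stringsAsFactors = FALSE)
  w <- extract_windows(maf, rg4, "ref", flank = 1L)
  recs <- conservation_records(w)
  expect_true(all(!recs$aligned))
  expect_true(all(!recs$has_pqs))
  expect_true(all(recs$identity == 0))
  ai <- average_identity(recs, "ref")
  expect_equal(ai$average_identity, 0)
  expect_equal(ai$n_aligned, 0L)
})

test_that("worked identity example: one substituted base in seven", {
  b <- list(data.frame(
    src = c("ref.chr1", "spX.chr1"), start = 0L, size = 7L, strand = "+",
    src_size = 7L, text = c("GGGAGGG", "GGGTGGG"), stringsAsFactors = FALSE))
  rg4 <- data.frame(name = "r", chrom = "chr1", start = 0L, end = 7L,
                    strand = "+", stringsAsFactors = FALSE)
  w <- extract_windows(b, rg4, "ref", flank = 0L)[[1]]
  expect_equal(sequence_identity(w, "spX"), 6 / 7)
  expect_equal(sequence_identity(w, "ref"), 1.0)
})

test_that("conservation records respect the has_pqs => aligned invariant", {
  set.seed(61)
  nwk <- "((ref:1,sp1:1):1,(sp2:1,sp3:1):1);"
  for (r in 1:5) {
    al <- make_alignment(nwk, seed = 100 + r, sub_rate = 0.15,
                         del_rate = 0.05)
    recs <- conservation_records(extract_windows(al$maf, al$rg4, "ref"))
    expect_true(all(!recs$has_pqs | recs$aligned))
    expect_true(all(recs$identity >= 0 & recs$identity <= 1))
    expect_equal(recs$identity[recs$species == "ref"], 1.0)
    # identity computed through the MAF path equals the simulator's truth
    expect_equal(setNames(recs$identity, recs$species)[names(al$truth$identity_vs_ref)],
                 al$truth$identity_vs_ref)
  }
})

test_that("simulated substitution probability is recovered as 1 - identity", {
  nwk <- "(ref:0,sp1:1,sp2:1,sp3:1,sp4:1);"
  for (p in c(0, 0.1)) {
    idents <- numeric(0)
    for (r in 1:50) {
      al <- make_alignment(nwk, seed = 3000 + r, sub_rate = p)
      recs <- conservation_records(extract_windows(al$maf, al$rg4, "ref"))
      idents <- c(idents, recs$identity[recs$species != "ref"])
    }
    if (p == 0) {
      expect_true(all(idents == 1))
    } else {
      mlen <- 15L
      se <- sqrt(p * (1 - p) / mlen) / sqrt(length(idents))
      expect_lt(abs(mean(idents) - (1 - p)), 3 * se + 1e-12)
    }
  }
})

test_that("clade summaries average correctly over rings and cumulative sets", {
  scheme <- clade_scheme(list(IN = c("a", "b"), OUT = c("a", "b", "c", "d")),
                         ages = c(IN = 10, OUT = 100))
  expect_equal(scheme$rings$OUT, c("c", "d"))
  recs <- data.frame(
    rg4_id = "r1", species = c("a", "b", "c", "d"),
    aligned = c(TRUE, TRUE, TRUE, FALSE),
    has_pqs = c(TRUE, TRUE, TRUE, FALSE),
    identity = c(1.0, 0.8, 0.5, 0), stringsAsFactors = FALSE)
  cs <- clade_summary(recs, scheme)
  inn <- cs[cs$clade == "IN", ]
  out <- cs[cs$clade == "OUT", ]
  expect_equal(inn$pqs_fraction, 1.0)
  expect_equal(inn$mean_identity, 0.9)     # mean over aligned species
  expect_equal(out$pqs_fraction, 0.5)      # ring: c TRUE, d FALSE
  expect_equal(out$mean_identity, 0.5)     # only c aligned in the ring
  cum <- clade_summary(recs, scheme, cumulative = TRUE)
  expect_equal(cum$n_species[cum$clade == "OUT"], 4L)
  expect_equal(cum$pqs_fraction[cum$clade == "OUT"], 3 / 4)
  # 4 species, 3 with PQS -> 0.75
  expect_equal(cum$n_with_pqs[cum$clade == "OUT"] /
                 cum$n_species[cum$clade == "OUT"], 0.75)
})

test_that("deep-branch-only mutations keep inner clades at least as conserved", {
  # substitutions only on the deep branch leading to the outer clade, so
  # the reference clade is untouched by construction
  nwk <- "((ref:1,sp1:1):1,(sp2:1,sp3:1):1);"
  tree <- ape::read.tree(text = nwk)
  outer_node <- ape::getMRCA(tree, c("sp2", "sp3"))
  probs <- ifelse(tree$edge[, 2] == outer_node, 0.5, 0)
  scheme <- clade_scheme(list(Inner = c("ref", "sp1"),
                              Outer = c("ref", "sp1", "sp2", "sp3")))
  frac <- matrix(NA_real_, 20, 2)
  for (r in 1:20) {
    al <- make_alignment(tree, seed = 500 + r, sub_probs = probs)
    recs <- conservation_records(extract_windows(al$maf, al$rg4, "ref"))
    cs <- clade_summary(recs, scheme)
    frac[r, ] <- cs$pqs_fraction[match(c("Inner", "Outer"), cs$clade)]
  }
  expect_true(all(frac[, 1] >= frac[, 2]))
  expect_true(all(frac[, 1] == 1))  # inner clade untouched by construction
})

test_that("CDS positional conservation matches hand enumeration on a toy family", {
  msa <- list(fam1 = c(
    hs = "GGGAGGGAGGGAGGG---ACT",
    mm = "GGGAGGGAGGGAGGG---ACT",
    dr = "---------------CCCACT"))
  rg4s <- data.frame(
    family = "fam1", species = c("hs", "mm"),
    start = c(0L, 0L), end = c(15L, 15L), stringsAsFactors = FALSE)
  pc <- positional_conservation_cds(msa, rg4s, flank_cols = 3L)
  d <- pc$detail
  expect_equal(d$status[d$species_a == "hs" & d$species_b == "mm"],
               "aligned_rg4")
  expect_equal(d$status[d$species_a == "hs" & d$species_b == "dr"],
               "no_alignment")  # dr is all-gap over the motif columns
  # partner PQS without an overlapping rG4
  rg4s2 <- rg4s[1, , drop = FALSE]
  pc2 <- positional_conservation_cds(msa, rg4s2, flank_cols = 3L)
  expect_equal(pc2$detail$status[pc2$detail$species_b == "mm"],
               "aligned_pqs_no_rg4")
  # species absent from the MSA
  rg4s3 <- data.frame(family = "fam1", species = "hs", start = 0L, end = 15L)
  msa2 <- list(fam1 = msa$fam1[c("hs", "dr")])
  pc3 <- positional_conservation_cds(msa2, rg4s3, flank_cols = 3L)
  expect_true(all(pc3$detail$status[pc3$detail$species_b == "dr"] ==
                    "no_alignment"))
})

test_that("UTR positional conservation uses half-open genomic overlap", {
  a <- data.frame(name = c("u1", "u2"), chrom = "chr1",
                  start = c(100L, 300L), end = c(120L, 320L),
                  stringsAsFactors = FALSE)
  b <- data.frame(chrom = "chr1", start = c(100L, 320L),
                  end = c(120L, 340L), stringsAsFactors = FALSE)
  res <- positional_conservation_utr(a, b)
  expect_equal(res$conserved, c(TRUE, FALSE))  # coincident; adjacent
  expect_equal(res$n_partners, c(1L, 0L))
})

test_that("random UTR placement matches the analytic collision probability", {
  set.seed(90)
  L <- 2000L; m <- 20L
  n <- 4000L
  sa <- sample(0:(L - m), n, replace = TRUE)
  sb <- sample(0:(L - m), n, replace = TRUE)
  a <- data.frame(name = paste0("a", seq_len(n)), chrom = "c",
                  start = sa, end = sa + m)
  b <- data.frame(chrom = "c", start = sb, end = sb + m)
  # one partner per rG4: overlap iff |sa - sb| < m
  res <- vapply(seq_len(n), function(i)
    positional_conservation_utr(a[i, ], b[i, ])$conserved, logical(1))
  npos <- L - m + 1L
  p_analytic <- (npos * (2 * m - 1) - m * (m - 1)) / npos^2
  se <- sqrt(p_analytic * (1 - p_analytic) / n)
  expect_lt(abs(mean(res) - p_analytic), 4 * se)
})

test_that("MAF reader and writer round-trip block structure", {
  maf <- maf_fixture()
  path <- tempfile(fileext = ".maf")
  write_maf(maf, path)
  back <- read_maf(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$src, maf[[1]]$src)
  expect_equal(back[[1]]$text, maf[[1]]$text)
  expect_equal(back[[2]]$start, maf[[2]]$start)
})
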