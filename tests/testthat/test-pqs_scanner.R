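test_that("worked motif examples are classified with their expected spans", {
  h <- scan_pqs("GGGAGGGAGGGAGGG")
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif_class, "CANONICAL")
  expect_equal(h$canonicality, 4L)
  expect_equal(h$loop_lens[[1]], c(1L, 1L, 1L))
  expect_equal(c(h$start, h$end), c(0L, 15L))

  h <- scan_pqs("GGAGGAGGAGG")
  expect_equal(h$motif_class, "TWO_QUARTET")
  expect_equal(h$canonicality, 0L)
  expect_equal(c(h$start, h$end), c(0L, 11L))

  expect_equal(nrow(scan_pqs("ATATATAT")), 0L)
  expect_equal(nrow(scan_pqs("")), 0L)

  # five tri-guanine tracts: one hit, canonicality capped at 4
  h <- scan_pqs("GGGAGGGAGGGAGGGAGGG")
  expect_equal(nrow(h), 1L)
  expect_equal(h$canonicality, 4L)
  expect_equal(c(h$start, h$end), c(0L, 19L))

  h <- scan_pqs("GGGAAAAAAAAGGGAGGGAGGG")
  expect_equal(h$motif_class, "LONG_LOOP")
  expect_equal(h$group, "G3")
  expect_equal(h$canonicality, 4L)

  h <- scan_pqs("GGGAGGGAGGGAGTGG")
  expect_equal(h$motif_class, "BULGE")
  expect_equal(h$group, "G2")
  expect_equal(h$canonicality, 3L)
})

test_that("canonicality counts tri-guanine tracts, capped and once per tract", {
  # mixture GGG,GG,GGG,GG -> 2
  h <- scan_pqs("GGGAGGAGGGAGG")
  expect_equal(h$motif_class, "TWO_QUARTET")
  expect_equal(h$canonicality, 2L)
  # a G>=4 tract counts once
  h <- scan_pqs("GGGGAGGGAGGGAGGG")
  expect_equal(h$canonicality, 4L)
  expect_equal(canonicality(h), 4L)
  # floor case: four GG tracts
  expect_equal(scan_pqs("GGAGGAGGAGG")$canonicality, 0L)
  # accessor recomputes from the tract decomposition
  h <- scan_pqs("GGGAGGGAGGGAGTGG")
  expect_equal(canonicality(h), h$canonicality)
})

test_that("classify_group maps classes to quartet-layer groups", {
  h <- rbind(scan_pqs("GGGAGGGAGGGAGGG"), scan_pqs("GGAGGAGGAGG"),
             scan_pqs("GGGAAAAAAAAGGGAGGGAGGG"))
  expect_equal(classify_group(h), c("G3", "G2", "G3"))
  expect_equal(h$group, classify_group(h))
})

test_that("scan output equals the brute-force enumeration oracle", {
  set.seed(101)
  for (r in 1:120) {
    s <- random_gseq(sample(60:200, 1), runif(1, 0.25, 0.6))
    got <- scan_pqs(s)[, c("start", "end", "motif_class", "canonicality")]
    want <- oracle_scan(s)
    expect_equal(got, want, ignore_attr = TRUE,
                 label = sprintf("greedy scan of %s", s))
  }
  for (r in 1:50) {
    s <- random_gseq(sample(60:150, 1), runif(1, 0.3, 0.6))
    got <- scan_pqs(s, scan_params(report_mode = "all"))
    want <- oracle_scan(s, mode = "all")
    expect_equal(got[, c("start", "end", "motif_class", "canonicality")],
                 want, ignore_attr = TRUE,
                 label = sprintf("all-mode scan of %s", s))
  }
})

test_that("hits satisfy the structural invariants of the motif grammars", {
  set.seed(77)
  n_checked <- 0L
  for (r in 1:60) {
    s <- random_gseq(200, runif(1, 0.35, 0.6))
    h <- scan_pqs(s)
    cs <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(h))) {
      ts <- h$tract_starts[[i]]; tl <- h$tract_lens[[i]]
      bo <- h$tract_bulge_offset[[i]]; ll <- h$loop_lens[[i]]
      expect_length(ts, 4L)
      # tracts and loops tile the span exactly
      expect_equal(ts[1], h$start[i])
      expect_equal(ts[4] + tl[4], h$end[i])
      expect_equal(ts[-1], (ts + tl)[-4] + ll)
      # tract contents: pure G runs, or exactly one single-base bulge
      for (k in 1:4) {
        tract <- cs[(ts[k] + 1L):(ts[k] + tl[k])]
        if (is.na(bo[k])) {
          expect_true(all(tract == "G"))
        } else {
          expect_true(tract[bo[k] + 1L] %in% c("A", "C", "T"))
          expect_true(all(tract[-(bo[k] + 1L)] == "G"))
          expect_gte(sum(tract == "G"), 3L)
        }
      }
      expect_equal(sum(!is.na(bo)), as.integer(h$motif_class[i] == "BULGE"))
      expect_true(h$canonicality[i] >= 0L && h$canonicality[i] <= 4L)
      if (h$motif_class[i] %in% c("CANONICAL", "LONG_LOOP")) {
        expect_equal(h$canonicality[i], 4L)
      }
      if (h$motif_class[i] == "LONG_LOOP") expect_gte(max(ll), 8L)
      n_checked <- n_checked + 1L
    }
    # greedy hits are sorted and non-overlapping
    if (nrow(h) > 1L) {
      expect_true(all(diff(h$start) > 0))
      expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("scan is a pure function and N disqualifies candidates", {
  set.seed(5)
  s <- random_gseq(150, 0.5)
  expect_identical(scan_pqs(s), scan_pqs(s))
  # an N inside the only possible loop kills the candidate
  expect_equal(nrow(scan_pqs("GGGNGGGAGGGAGGG")), 0L)
  # N in flanking sequence does not
  expect_equal(nrow(scan_pqs("NNGGGAGGGAGGGAGGGNN")), 1L)
  # the oracle agrees on N handling
  sN <- paste0(substr(s, 1, 70), "N", substr(s, 72, 150))
  expect_equal(scan_pqs(sN)[, c("start", "end", "motif_class", "canonicality")],
               oracle_scan(sN), ignore_attr = TRUE)
})

test_that("turning a loop base into G never lowers the top canonicality over that position", {
  set.seed(31)
  p_all <- scan_params(report_mode = "all")
  n_cases <- 0L
  for (r in 1:40) {
    s <- random_gseq(120, runif(1, 0.35, 0.55))
    h <- scan_pqs(s, p_all)
    if (nrow(h) == 0L) next
    i <- sample(nrow(h), 1)
    ts <- h$tract_starts[[i]]; tl <- h$tract_lens[[i]]
    loop_pos <- setdiff(seq.int(h$start[i], h$end[i] - 1L),
                        unlist(lapply(1:4, function(k)
                          seq.int(ts[k], ts[k] + tl[k] - 1L))))
    loop_pos <- loop_pos[substring(s, loop_pos + 1L, loop_pos + 1L) != "G"]
    if (!length(loop_pos)) next
    p <- sample(loop_pos, 1)
    covering_max <- function(hits, pos) {
      cov <- hits[hits$start <= pos & hits$end > pos, , drop = FALSE]
      if (nrow(cov)) max(cov$canonicality) else -1L
    }
    before <- covering_max(h, p)
    s2 <- paste0(substring(s, 1, p), "G", substring(s, p + 2L))
    after <- covering_max(scan_pqs(s2, p_all), p)
    expect_gte(after, before)
    n_cases <- n_cases + 1L
  }
  expect_gt(n_cases, 15L)
})

test_that("scan parameters are validated and configurable", {
  expect_error(scan_params(canonical_loop = c(0, 7)))
  expect_error(scan_params(long_loop_max = 3))
  # a tighter long-loop ceiling removes long-loop hits
  s <- "GGGAAAAAAAAAAAGGGAGGGAGGG"  # first loop 11 nt
  expect_equal(scan_pqs(s)$motif_class, "LONG_LOOP")
  h <- scan_pqs(s, scan_params(long_loop_max = 10L))
  expect_false(any(h$motif_class == "LONG_LOOP" & h$start == 0))
})
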