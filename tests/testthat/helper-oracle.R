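# Independent brute-force PQS oracle: enumerates every substring, tests
# grammar membership with backtracking regexes, assigns the
# highest-priority class, and applies the same reporting policies as the
# scanner. Shares no code with the G-run dynamic programme in R/.

oracle_patterns <- function(params) {
  L <- function(lo, hi) sprintf("[ACGT]{%d,%d}", lo, hi)
  L7 <- L(params$canonical_loop[1], params$canonical_loop[2])
  L12 <- L(1L, params$long_loop_max)
  Ltq <- L(params$two_quartet_loop[1], params$two_quartet_loop[2])
  B <- "(?:G[ACT]GG|GG[ACT]G|GG[ACT]GG)"
  T3 <- "G{3,}"
  list(
    can = paste0("^G{3,}(?:", L7, "G{3,}){3}$"),
    l12 = paste0("^G{3,}(?:", L12, "G{3,}){3}$"),
    bulge = paste0("^(?:",
                   B, L7, T3, L7, T3, L7, T3, "|",
                   T3, L7, B, L7, T3, L7, T3, "|",
                   T3, L7, T3, L7, B, L7, T3, "|",
                   T3, L7, T3, L7, T3, L7, B, ")$"),
    tq = paste0("^G{2,}(?:", Ltq, "G{2,}){3}$"),
    L7 = L7, Ltq = Ltq)
}

# Canonicality of a substring via subset regexes: largest c such that a
# tiling exists with >= c tracts of G{3,}.
oracle_canonicality <- function(sub, class, pat) {
  if (class %in% c("CANONICAL", "LONG_LOOP")) return(4L)
  if (class == "BULGE") return(3L)
  for (cc in 3:1) {
    subsets <- utils::combn(4, cc, simplify = FALSE)
    pats <- vapply(subsets, function(s) {
      tr <- rep("G{2,}", 4)
      tr[s] <- "G{3,}"
      paste0("^", tr[1], pat$Ltq, tr[2], pat$Ltq, tr[3], pat$Ltq, tr[4], "$")
    }, character(1))
    if (any(vapply(pats, function(p) grepl(p, sub, perl = TRUE), logical(1))))
      return(cc)
  }
  0L
}

oracle_scan <- function(seq, params = scan_params(),
                        mode = c("greedy", "all")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  cs <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(cs)
  empty <- data.frame(start = integer(0), end = integer(0),
                      motif_class = character(0), canonicality = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 11L) return(empty)
  gi <- which(cs == "G")
  si <- integer(0); sj <- integer(0)
  for (i in gi) {
    js <- gi[gi >= i + 10L]
    si <- c(si, rep(i, length(js)))
    sj <- c(sj, js)
  }
  if (!length(si)) return(empty)
  subs <- substring(seq, si, sj)
  pat <- oracle_patterns(params)
  can <- grepl(pat$can, subs, perl = TRUE)
  l12 <- grepl(pat$l12, subs, perl = TRUE)
  blg <- grepl(pat$bulge, subs, perl = TRUE)
  tq <- grepl(pat$tq, subs, perl = TRUE)
  class <- ifelse(can, "CANONICAL",
           ifelse(l12, "LONG_LOOP",
           ifelse(blg, "BULGE",
           ifelse(tq, "TWO_QUARTET", NA_character_))))
  keep <- !is.na(class)
  cand <- data.frame(start = si[keep] - 1L, end = sj[keep],
                     motif_class = class[keep], sub = subs[keep],
                     stringsAsFactors = FALSE)
  prio <- c(CANONICAL = 1L, LONG_LOOP = 2L, BULGE = 3L, TWO_QUARTET = 4L)
  pick_rows <- list()
  if (mode == "greedy") {
    p <- 0L
    repeat {
      avail <- cand[cand$start >= p, , drop = FALSE]
      if (!nrow(avail)) break
      s <- min(avail$start)
      at <- avail[avail$start == s, , drop = FALSE]
      cl <- names(prio)[min(prio[at$motif_class])]
      at <- at[at$motif_class == cl, , drop = FALSE]
      row <- at[which.max(at$end), , drop = FALSE]
      pick_rows[[length(pick_rows) + 1L]] <- row
      p <- row$end
    }
  } else {
    for (s in sort(unique(cand$start))) {
      at <- cand[cand$start == s, , drop = FALSE]
      for (cl in names(prio)) {
        atc <- at[at$motif_class == cl, , drop = FALSE]
        if (nrow(atc)) {
          pick_rows[[length(pick_rows) + 1L]] <-
            atc[which.max(atc$end), , drop = FALSE]
        }
      }
    }
  }
  if (!length(pick_rows)) return(empty)
  out <- do.call(rbind, pick_rows)
  out$canonicality <- vapply(seq_len(nrow(out)), function(i)
    oracle_canonicality(out$sub[i], out$motif_class[i], pat), integer(1))
  rownames(out) <- NULL
  out[, c("start", "end", "motif_class", "canonicality")]
}

# Random test sequence with controlled G content.
random_gseq <- function(len, g_frac) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - g_frac) / 3, (1 - g_frac) / 3, g_frac,
                        (1 - g_frac) / 3)), collapse = "")
}
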