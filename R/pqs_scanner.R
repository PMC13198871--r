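#' Scanner parameters for PQS detection
#'
#' Bundles the loop-length bounds of the four quadruplex motif grammars and
#' the overlap-reporting policy used by [scan_pqs()].
#'
#' The four grammars (in priority order) are:
#' \describe{
#'   \item{CANONICAL}{four G-tracts of >= 3 guanines, loops of
#'     `canonical_loop[1]`--`canonical_loop[2]` nt (default 1--7).}
#'   \item{LONG_LOOP}{four G-tracts of >= 3 guanines, loops of
#'     1--`long_loop_max` nt (default 12), not tilable with all loops within
#'     the canonical bounds (i.e. at least one loop longer than 7 nt).}
#'   \item{BULGE}{three pure G-tracts of >= 3 guanines plus exactly one
#'     bulged tract (one to two guanines, a single non-G base, then one to
#'     two guanines, with at least three guanines in total), loops 1--7 nt.}
#'   \item{TWO_QUARTET}{four G-tracts of >= 2 guanines, loops of
#'     `two_quartet_loop[1]`--`two_quartet_loop[2]` nt (default 1--7), not
#'     matching any higher grammar.}
#' }
#' A substring is assigned the highest-priority grammar it satisfies, so the
#' classes partition the candidate set.
#'
#' @param canonical_loop integer(2), min/max canonical loop length in nt.
#' @param long_loop_max integer(1), loop ceiling for the long-loop grammar.
#' @param two_quartet_loop integer(2), min/max two-quartet loop length.
#' @param report_mode `"greedy"` (leftmost-first maximal non-overlapping
#'   hits, the default used for conservation presence/absence questions) or
#'   `"all"` (one maximal hit per start position and motif class, used by
#'   enumeration oracles).
#' @return An object of class `"scan_params"`.
#' @examples
#' scan_params()
#' scan_params(long_loop_max = 10L)
#' @export
scan_params <- function(canonical_loop = c(1L, 7L), long_loop_max = 12L,
                        two_quartet_loop = c(1L, 7L),
                        report_mode = c("greedy", "all")) {
  report_mode <- match.arg(report_mode)
  canonical_loop <- as.integer(canonical_loop)
  two_quartet_loop <- as.integer(two_quartet_loop)
  long_loop_max <- as.integer(long_loop_max)
  stopifnot(length(canonical_loop) == 2L, length(two_quartet_loop) == 2L,
            canonical_loop[1] >= 1L, canonical_loop[2] >= canonical_loop[1],
            two_quartet_loop[1] >= 1L,
            two_quartet_loop[2] >= two_quartet_loop[1],
            long_loop_max >= canonical_loop[2])
  structure(list(canonical_loop = canonical_loop,
                 long_loop_max = long_loop_max,
                 two_quartet_loop = two_quartet_loop,
                 report_mode = report_mode),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat("PQS scan parameters\n")
  cat(sprintf("  canonical loops   : %d-%d nt\n", x$canonical_loop[1], x$canonical_loop[2]))
  cat(sprintf("  long-loop ceiling : %d nt\n", x$long_loop_max))
  cat(sprintf("  two-quartet loops : %d-%d nt\n", x$two_quartet_loop[1], x$two_quartet_loop[2]))
  cat(sprintf("  report mode       : %s\n", x$report_mode))
  invisible(x)
}

# Motif class levels in priority order (highest first).
PQS_CLASSES <- c("CANONICAL", "LONG_LOOP", "BULGE", "TWO_QUARTET")

empty_pqs_hits <- function() {
  data.frame(seq_id = character(0),
             start = integer(0), end = integer(0), width = integer(0),
             motif_class = character(0), group = character(0),
             canonicality = integer(0),
             tract_starts = I(list()), tract_lens = I(list()),
             tract_bulge_offset = I(list()), loop_lens = I(list()),
             stringsAsFactors = FALSE)
}

# Precompute per-base structure used by the G-run dynamic programme:
# grun[i] = number of consecutive G from position i (1-based), 0 if not G;
# badc[i] = cumulative count of non-ACGT bases up to i (prefix sums).
pqs_seq_context <- function(cs) {
  n <- length(cs)
  isg <- cs == "G"
  grun <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    j <- n - i + 1L
    run <- if (isg[j]) run + 1L else 0L
    grun[j] <- run
  }
  bad <- !(cs %in% c("A", "C", "G", "T"))
  list(n = n, cs = cs, grun = grun, badc = cumsum(as.integer(bad)))
}

# TRUE when every base of [a, b] (1-based inclusive) is in {A,C,G,T}.
span_clean <- function(ctx, a, b) {
  if (a > b) return(TRUE)
  lo <- if (a >= 2L) ctx$badc[a - 1L] else 0L
  ctx$badc[b] == lo
}

# Reachable-end dynamic programme for grammars whose four tracts are pure
# G-runs (canonical / long-loop superset / two-quartet). Returns a closure
# ends(pos) giving every exclusive end e such that [pos, e-1] tiles as
# T1 L1 T2 L2 T3 L3 T4 with tract length >= min_tract and loop length in
# [lmin, lmax]. Memoised over (pos, tract index), shared across starts.
make_endset_pure <- function(ctx, min_tract, lmin, lmax) {
  n <- ctx$n
  grun <- ctx$grun
  memo <- vector("list", 4L * n)
  rec <- function(pos, t) {
    if (pos > n) return(integer(0))
    key <- (t - 1L) * n + pos
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    g <- grun[pos]
    res <- integer(0)
    if (g >= min_tract) {
      if (t == 4L) {
        res <- pos + min_tract:g
      } else {
        for (l in min_tract:g) {
          for (lam in lmin:lmax) {
            np <- pos + l + lam
            if (np > n) break
            if (!span_clean(ctx, pos + l, np - 1L)) next
            res <- c(res, rec(np, t + 1L))
          }
        }
        res <- unique(res)
      }
    }
    memo[[key]] <<- res
    res
  }
  function(pos) rec(pos, 1L)
}

# Options for a bulged tract starting at pos: s1 guanines, one non-G
# (A/C/T), s2 guanines, s1+s2 >= 3 and s1,s2 in {1,2}. Returns tract
# lengths (s1 + 1 + s2) with attribute "s1".
bulge_tract_lens <- function(ctx, pos) {
  n <- ctx$n
  grun <- ctx$grun
  cs <- ctx$cs
  out <- integer(0)
  s1s <- integer(0)
  g <- grun[pos]
  if (g == 0L) return(out)
  for (s1 in 1:2) {
    if (g < s1) break
    mid <- pos + s1
    if (mid > n || !(cs[mid] %in% c("A", "C", "T"))) next
    g2 <- if (mid + 1L <= n) grun[mid + 1L] else 0L
    for (s2 in 1:2) {
      if (s1 + s2 < 3L || g2 < s2) next
      out <- c(out, s1 + 1L + s2)
      s1s <- c(s1s, s1)
    }
  }
  attr(out, "s1") <- s1s
  out
}

# Reachable-end DP for the bulge grammar: three pure G>=3 tracts plus
# exactly one bulged tract, loops in [lmin, lmax]. State adds a used-bulge
# flag.
make_endset_bulge <- function(ctx, lmin, lmax) {
  n <- ctx$n
  grun <- ctx$grun
  memo <- vector("list", 8L * n)
  rec <- function(pos, t, used) {
    if (pos > n) return(integer(0))
    key <- ((t - 1L) * 2L + used) * n + pos
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- integer(0)
    lens_pure <- if (grun[pos] >= 3L) 3L:grun[pos] else integer(0)
    lens_bulge <- if (used == 0L) bulge_tract_lens(ctx, pos) else integer(0)
    if (t == 4L) {
      # final tract: span ends exactly at tract end; a bulge here is only
      # legal when the other three tracts were pure, i.e. used == 0.
      res <- c(pos + lens_pure, pos + lens_bulge)
      # span must have used the bulge somewhere: enforced by caller taking
      # rec(pos, 1, 0) and subtracting the all-pure end set.
    } else {
      all_lens <- c(lens_pure, lens_bulge)
      all_used <- c(rep(used, length(lens_pure)),
                    rep(1L, length(lens_bulge)))
      for (k in seq_along(all_lens)) {
        l <- all_lens[k]
        for (lam in lmin:lmax) {
          np <- pos + l + lam
          if (np > n) break
          if (!span_clean(ctx, pos + l, np - 1L)) next
          res <- c(res, rec(np, t + 1L, all_used[k]))
        }
      }
    }
    res <- unique(res)
    memo[[key]] <<- res
    res
  }
  function(pos) rec(pos, 1L, 0L)
}

# Candidate class end-sets at one start. Returns list(CANONICAL=, LONG_LOOP=,
# BULGE=, TWO_QUARTET=) of exclusive ends after priority exclusion.
pqs_class_ends <- function(pos, dp) {
  e_can <- dp$can(pos)
  e_12 <- dp$sup(pos)
  e_bulge_all <- dp$bulge(pos)
  e_tq <- dp$tq(pos)
  # The bulge DP with used==0 also reaches all-pure tilings at the final
  # tract only through states that consumed the bulge; but a tiling that
  # never uses a bulged tract is exactly a canonical tiling, so subtracting
  # the canonical end-set removes it.
  list(CANONICAL = e_can,
       LONG_LOOP = setdiff(e_12, e_can),
       BULGE = setdiff(e_bulge_all, e_12),
       TWO_QUARTET = setdiff(e_tq, union(e_12, e_bulge_all)))
}

# Best tract/loop decomposition of the fixed span [s, e-1] under a grammar.
# Maximises canonicality (tracts containing a G-run >= 3), then earliest
# tract starts, then longest tracts. Returns list(starts, lens, bulge_off,
# loops, canonicality) with 1-based starts.
pqs_decompose <- function(ctx, s, e, min_tract, lmin, lmax, allow_bulge) {
  n <- ctx$n
  grun <- ctx$grun
  memo <- new.env(hash = TRUE, parent = emptyenv())
  # f(pos, t, used) = max canonicality achievable for tracts t..4 tiling
  # [pos, e-1]; -Inf when infeasible.
  f <- function(pos, t, used) {
    key <- paste0(pos, ".", t, ".", used)
    if (!is.null(v <- memo[[key]])) return(v)
    best <- -Inf
    opts <- tract_options(pos, used)
    if (t == 4L) {
      for (k in seq_len(nrow(opts))) {
        if (pos + opts$len[k] == e) best <- max(best, opts$canon[k])
      }
    } else {
      for (k in seq_len(nrow(opts))) {
        l <- opts$len[k]
        for (lam in lmin:lmax) {
          np <- pos + l + lam
          if (np >= e + 1L || np > n) break
          if (!span_clean(ctx, pos + l, np - 1L)) next
          sub <- f(np, t + 1L, opts$used[k])
          if (is.finite(sub)) best <- max(best, opts$canon[k] + sub)
        }
      }
    }
    memo[[key]] <- best
    best
  }
  tract_options <- function(pos, used) {
    len <- integer(0); canon <- integer(0); usd <- integer(0); boff <- integer(0)
    if (grun[pos] >= min_tract) {
      ls <- min_tract:grun[pos]
      len <- c(len, ls)
      canon <- c(canon, as.integer(ls >= 3L))
      usd <- c(usd, rep(used, length(ls)))
      boff <- c(boff, rep(NA_integer_, length(ls)))
    }
    if (allow_bulge && used == 0L) {
      bl <- bulge_tract_lens(ctx, pos)
      if (length(bl)) {
        len <- c(len, as.integer(bl))
        canon <- c(canon, rep(0L, length(bl)))  # sides <= 2 G, no GGG run
        usd <- c(usd, rep(1L, length(bl)))
        boff <- c(boff, attr(bl, "s1"))         # 0-based offset of non-G
      }
    }
    data.frame(len = len, canon = canon, used = usd, boff = boff)
  }
  total <- f(s, 1L, 0L)
  if (!is.finite(total)) return(NULL)
  # Reconstruct: among optimal transitions pick the smallest next tract
  # start, then the longest current tract.
  starts <- integer(4); lens <- integer(4); boffs <- integer(4); loops <- integer(3)
  pos <- s; used <- 0L
  for (t in 1:4) {
    opts <- tract_options(pos, used)
    remaining <- total - sum(as.integer(lens[seq_len(t - 1L)] >= 3L &
                                          is.na(boffs[seq_len(t - 1L)])))
    pick <- NULL
    if (t == 4L) {
      for (k in seq_len(nrow(opts))) {
        if (pos + opts$len[k] == e && opts$canon[k] == remaining) {
          if (is.null(pick) || opts$len[k] > pick$l) {
            pick <- list(l = opts$len[k], lam = NA_integer_,
                         used = opts$used[k], boff = opts$boff[k])
          }
        }
      }
    } else {
      for (k in seq_len(nrow(opts))) {
        l <- opts$len[k]
        for (lam in lmin:lmax) {
          np <- pos + l + lam
          if (np >= e + 1L || np > n) break
          if (!span_clean(ctx, pos + l, np - 1L)) next
          sub <- f(np, t + 1L, opts$used[k])
          if (is.finite(sub) && opts$canon[k] + sub == remaining) {
            better <- is.null(pick) || np < pick$np ||
              (np == pick$np && l > pick$l)
            if (better) pick <- list(l = l, lam = lam, np = np,
                                     used = opts$used[k], boff = opts$boff[k])
          }
        }
      }
    }
    stopifnot(!is.null(pick))
    starts[t] <- pos
    lens[t] <- pick$l
    boffs[t] <- pick$boff
    if (t < 4L) {
      loops[t] <- pick$lam
      pos <- pick$np
      used <- pick$used
    }
  }
  list(starts = starts, lens = lens, bulge_off = boffs, loops = loops,
       canonicality = min(4L, as.integer(total)))
}

decomp_grammar <- function(class, params) {
  switch(class,
         CANONICAL = list(min_tract = 3L, lmin = params$canonical_loop[1],
                          lmax = params$canonical_loop[2], bulge = FALSE),
         LONG_LOOP = list(min_tract = 3L, lmin = 1L,
                          lmax = params$long_loop_max, bulge = FALSE),
         BULGE = list(min_tract = 3L, lmin = params$canonical_loop[1],
                      lmax = params$canonical_loop[2], bulge = TRUE),
         TWO_QUARTET = list(min_tract = 2L, lmin = params$two_quartet_loop[1],
                            lmax = params$two_quartet_loop[2], bulge = FALSE))
}

#' Scan a nucleotide sequence for putative quadruplex sequences
#'
#' Detects PQSs of the four motif classes (canonical, long-loop, bulged,
#' two-quartet; see [scan_params()]) on the given sense-strand sequence and
#' reports each hit's tract/loop decomposition and canonicality (number of
#' G-tracts containing a run of >= 3 guanines, capped at 4).
#'
#' Under the default `"greedy"` report mode, hits form the leftmost-first
#' maximal non-overlapping set: scanning proceeds left to right, and at the
#' first position carrying any candidate the highest-priority class
#' (CANONICAL > LONG_LOOP > BULGE > TWO_QUARTET) is taken with its longest
#' feasible span, after which scanning resumes past the hit. `"all"` mode
#' reports, for every start position, the maximal candidate of every class
#' present there. A candidate substring is assigned the highest-priority
#' grammar it can tile; any base outside A/C/G/T disqualifies candidates
#' covering it.
#'
#' @param seq a single character string (or `DNAString`) over A/C/G/T/N.
#' @param params a [scan_params()] object.
#' @param seq_id identifier copied into the `seq_id` column.
#' @return A data frame with one row per hit: `seq_id`, 0-based half-open
#'   `start`/`end`, `width`, `motif_class`, `group` (`"G3"` for
#'   canonical/long-loop, `"G2"` otherwise), `canonicality`, plus list
#'   columns `tract_starts` (0-based), `tract_lens`, `tract_bulge_offset`
#'   (0-based offset of the bulged base within its tract, `NA` for pure
#'   tracts) and `loop_lens`.
#' @examples
#' scan_pqs("GGGAGGGAGGGAGGG")              # canonical, canonicality 4
#' scan_pqs("GGAGGAGGAGG")                  # two-quartet, canonicality 0
#' scan_pqs("ATATATAT")                     # no hits
#' @seealso [canonicality()], [classify_group()], [scan_pqs_set()]
#' @export
scan_pqs <- function(seq, params = scan_params(), seq_id = "seq") {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  if (is.na(seq) || nchar(seq) == 0L) return(empty_pqs_hits())
  cs <- strsplit(seq, "", fixed = TRUE)[[1]]
  ctx <- pqs_seq_context(cs)
  n <- ctx$n
  if (n < 11L) return(empty_pqs_hits())
  dp <- list(
    can = make_endset_pure(ctx, 3L, params$canonical_loop[1], params$canonical_loop[2]),
    sup = make_endset_pure(ctx, 3L, 1L, params$long_loop_max),
    bulge = make_endset_bulge(ctx, params$canonical_loop[1], params$canonical_loop[2]),
    tq = make_endset_pure(ctx, 2L, params$two_quartet_loop[1], params$two_quartet_loop[2])
  )
  rows <- list()
  emit <- function(s, e, class) {
    gr <- decomp_grammar(class, params)
    d <- pqs_decompose(ctx, s, e, gr$min_tract, gr$lmin, gr$lmax, gr$bulge)
    stopifnot(!is.null(d))
    data.frame(seq_id = seq_id,
               start = s - 1L, end = e - 1L, width = e - s,
               motif_class = class,
               group = if (class %in% c("CANONICAL", "LONG_LOOP")) "G3" else "G2",
               canonicality = d$canonicality,
               tract_starts = I(list(d$starts - 1L)),
               tract_lens = I(list(d$lens)),
               tract_bulge_offset = I(list(d$bulge_off)),
               loop_lens = I(list(d$loops)),
               stringsAsFactors = FALSE)
  }
  if (params$report_mode == "greedy") {
    pos <- 1L
    while (pos <= n - 10L) {
      if (ctx$grun[pos] == 0L) { pos <- pos + 1L; next }
      ends <- pqs_class_ends(pos, dp)
      hit <- FALSE
      for (cl in PQS_CLASSES) {
        if (length(ends[[cl]])) {
          e <- max(ends[[cl]])
          rows[[length(rows) + 1L]] <- emit(pos, e, cl)
          pos <- e
          hit <- TRUE
          break
        }
      }
      if (!hit) pos <- pos + 1L
    }
  } else {
    for (pos in seq_len(n - 10L)) {
      if (ctx$grun[pos] == 0L) next
      ends <- pqs_class_ends(pos, dp)
      for (cl in PQS_CLASSES) {
        if (length(ends[[cl]])) {
          rows[[length(rows) + 1L]] <- emit(pos, max(ends[[cl]]), cl)
        }
      }
    }
  }
  if (!length(rows)) return(empty_pqs_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a set of sequences for PQSs
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param params a [scan_params()] object.
#' @return Row-bound [scan_pqs()] results with `seq_id` from the names.
#' @export
scan_pqs_set <- function(seqs, params = scan_params()) {
  seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- lapply(names(seqs), function(id) scan_pqs(seqs[[id]], params, seq_id = id))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Canonicality of a PQS hit
#'
#' The number of G-tracts containing a guanine run of length >= 3, capped
#' at 4. A tract of four or more guanines still counts once; bulged tracts
#' (at most two guanines a side) never count. Canonical and long-loop hits
#' therefore always score 4, bulged hits 3, and two-quartet hits 0--3.
#'
#' @param hit one row of a [scan_pqs()] data frame (or the full frame, in
#'   which case a vector is returned).
#' @return integer vector of canonicality scores in 0..4.
#' @examples
#' canonicality(scan_pqs("GGGAGGGAGGGAGGGAGGG"))  # five GGG tracts -> 4
#' @export
canonicality <- function(hit) {
  stopifnot(is.data.frame(hit))
  vapply(seq_len(nrow(hit)), function(i) {
    lens <- hit$tract_lens[[i]]
    boff <- hit$tract_bulge_offset[[i]]
    min(4L, sum(lens >= 3L & is.na(boff)))
  }, integer(1))
}

#' Motif-class group of a PQS hit
#'
#' Canonical and long-loop motifs require tri-guanine tracts throughout and
#' form three stacked quartets (group `"G3"`); bulged and two-quartet motifs
#' form two quartets (group `"G2"`).
#'
#' @param hit one or more rows of a [scan_pqs()] data frame.
#' @return character vector, `"G3"` or `"G2"`.
#' @export
classify_group <- function(hit) {
  stopifnot(is.data.frame(hit))
  ifelse(hit$motif_class %in% c("CANONICAL", "LONG_LOOP"), "G3", "G2")
}
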