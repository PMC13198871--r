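#' @importFrom GenomicRanges GRanges findOverlaps pintersect
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Build a GRanges from a 0-based half-open data frame.
df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end),
                         strand = "*")
}

#' Overlap rG4s with genomic feature tracks
#'
#' Reports every (rG4, feature) pair sharing at least one genomic base.
#' Intervals are 0-based half-open, so touching intervals (end == start) do
#' not overlap.
#'
#' @param rg4s data frame with `chrom`, `start`, `end` and an id column
#'   `name` (a default id is derived from coordinates when absent).
#' @param features data frame with `chrom`, `start`, `end`, `kind` (e.g.
#'   `"RE"`), `label` (e.g. the repeat motif `"(TCC)n"`).
#' @return data frame with `rg4_id`, `kind`, `label`, `overlap_bases`.
#' @export
overlap_genomic <- function(rg4s, features) {
  stopifnot(all(c("chrom", "start", "end") %in% names(rg4s)),
            all(c("chrom", "start", "end") %in% names(features)))
  if (is.null(rg4s$name)) {
    rg4s$name <- sprintf("%s:%d-%d", rg4s$chrom, rg4s$start, rg4s$end)
  }
  shared <- intersect(unique(rg4s$chrom), unique(features$chrom))
  if (length(shared) == 0L && nrow(rg4s) && nrow(features)) {
    warning(sprintf("no shared chromosome names between rG4s (%s) and features (%s)",
                    paste(unique(rg4s$chrom), collapse = ","),
                    paste(unique(features$chrom), collapse = ",")))
  }
  if (nrow(rg4s) == 0L || nrow(features) == 0L) {
    return(data.frame(rg4_id = character(0), kind = character(0),
                      label = character(0), overlap_bases = integer(0),
                      stringsAsFactors = FALSE))
  }
  gr_r <- df_to_granges(rg4s)
  gr_f <- df_to_granges(features)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_f))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  ob <- suppressWarnings(
    IRanges::width(GenomicRanges::pintersect(gr_r[qi], gr_f[si])))
  data.frame(rg4_id = rg4s$name[qi],
             kind = if (!is.null(features$kind)) features$kind[si] else NA_character_,
             label = if (!is.null(features$label)) features$label[si] else NA_character_,
             overlap_bases = as.integer(ob),
             stringsAsFactors = FALSE)
}

#' Partition rG4s by repetitive-element and LCR overlap status
#'
#' The four-way partition underlying the motif/feature association summary:
#' every rG4 falls in exactly one of `LCR_only`, `RE_only`, `both`,
#' `neither`, so the counts sum to the input count.
#'
#' @param rg4_ids character vector of all rG4 ids under consideration.
#' @param re_hits,lcr_hits overlap reports (data frames with `rg4_id`).
#' @return named integer vector of the four partition counts.
#' @export
re_lcr_partition <- function(rg4_ids, re_hits, lcr_hits) {
  in_re <- rg4_ids %in% re_hits$rg4_id
  in_lcr <- rg4_ids %in% lcr_hits$rg4_id
  c(LCR_only = sum(in_lcr & !in_re),
    RE_only = sum(in_re & !in_lcr),
    both = sum(in_re & in_lcr),
    neither = sum(!in_re & !in_lcr))
}

#' Overlap CDS rG4s with peptide low-complexity regions
#'
#' Maps each CDS-located motif to peptide coordinates through its
#' transcript's reading frame and reports LCRs sharing at least one
#' residue. The LCR label is the sorted unique set of amino-acid letters
#' involved, comma-joined (e.g. `"D,E"`).
#'
#' @param rg4s data frame with `transcript_id`, `start`, `end` (transcript
#'   coordinates) and optionally `name`.
#' @param lcrs data frame with `protein_id`, `start`, `end` (0-based
#'   half-open residue intervals) and `aa_set` (comma-separated letters).
#' @param models named list of transcript models; `protein_id` values must
#'   equal transcript ids.
#' @return data frame `rg4_id`, `kind = "LCR"`, `label`,
#'   `overlap_bases` (shared residues).
#' @export
overlap_lcr <- function(rg4s, lcrs, models) {
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(rg4s))) {
    m <- models[[rg4s$transcript_id[i]]]
    id <- if (!is.null(rg4s$name)) rg4s$name[i]
          else sprintf("%s:%d-%d", rg4s$transcript_id[i], rg4s$start[i], rg4s$end[i])
    if (is.null(m) || is.null(m$cds_span) ||
        rg4s$start[i] < m$cds_span[1] || rg4s$end[i] > m$cds_span[2]) {
      n_skipped <- n_skipped + 1L
      next
    }
    p_lo <- (rg4s$start[i] - m$cds_span[1]) %/% 3L
    p_hi <- (rg4s$end[i] - 1L - m$cds_span[1]) %/% 3L + 1L  # half-open
    cand <- lcrs[lcrs$protein_id == rg4s$transcript_id[i], , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      ov <- min(p_hi, cand$end[j]) - max(p_lo, cand$start[j])
      if (ov >= 1L) {
        lab <- paste(sort(unique(strsplit(cand$aa_set[j], ",")[[1]])),
                     collapse = ",")
        out[[length(out) + 1L]] <-
          data.frame(rg4_id = id, kind = "LCR", label = lab,
                     overlap_bases = as.integer(ov), stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0L) {
    message(sprintf("overlap_lcr: %d rG4(s) not fully inside a CDS; skipped",
                    n_skipped))
  }
  if (!length(out)) {
    return(data.frame(rg4_id = character(0), kind = character(0),
                      label = character(0), overlap_bases = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Overlap 3' UTR rG4s with microRNA seed sites
#'
#' A seed site counts as overlapping when it intersects the rG4 footprint
#' widened by `window` nt on both sides, i.e. the seed lies within +/-
#' `window` nt of the motif (half-open on both ends). `window = 0` reduces
#' to plain intersection.
#'
#' @param rg4s data frame with genomic `chrom`, `start`, `end`, optional
#'   `name`.
#' @param seeds data frame with genomic `chrom`, `start`, `end` and a
#'   `label` (e.g. miRNA family).
#' @param window symmetric extension in nt (default 10).
#' @return data frame `rg4_id`, `kind = "MIR_SEED"`, `label`,
#'   `overlap_bases` (overlap with the widened footprint).
#' @export
overlap_mir_seed <- function(rg4s, seeds, window = 10L) {
  stopifnot(window >= 0L)
  wide <- rg4s
  wide$start <- pmax(0L, rg4s$start - as.integer(window))
  wide$end <- rg4s$end + as.integer(window)
  if (is.null(wide$name)) {
    wide$name <- sprintf("%s:%d-%d", rg4s$chrom, rg4s$start, rg4s$end)
  }
  seeds$kind <- "MIR_SEED"
  if (is.null(seeds$label)) seeds$label <- NA_character_
  overlap_genomic(wide, seeds)
}

#' Identify rG4s spanning splice junctions
#'
#' An rG4 (given in transcript coordinates) is reported when its interval
#' properly contains an exon-exon boundary of its transcript; a junction
#' at either interval end (half-open) does not count. Single-exon
#' transcripts are never reported.
#'
#' @param rg4s data frame with `transcript_id`, `start`, `end` (transcript
#'   coordinates), optional `name`.
#' @param models named list of transcript models.
#' @return data frame `rg4_id`, `kind = "SPLICE_JUNCTION"`,
#'   `label` (junction transcript position), `overlap_bases = 1`.
#' @export
overlap_splice_junction <- function(rg4s, models) {
  out <- list()
  for (i in seq_len(nrow(rg4s))) {
    m <- models[[rg4s$transcript_id[i]]]
    if (is.null(m) || nrow(m$exons) < 2L) next
    id <- if (!is.null(rg4s$name)) rg4s$name[i]
          else sprintf("%s:%d-%d", rg4s$transcript_id[i], rg4s$start[i], rg4s$end[i])
    junctions <- m$exons$t_end[-nrow(m$exons)]
    for (j in junctions) {
      if (j > rg4s$start[i] && j < rg4s$end[i]) {
        out[[length(out) + 1L]] <-
          data.frame(rg4_id = id, kind = "SPLICE_JUNCTION",
                     label = as.character(j), overlap_bases = 1L,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(rg4_id = character(0), kind = character(0),
                      label = character(0), overlap_bases = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
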