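#' The standard genetic code as a codon table
#'
#' @return named character vector mapping the 64 DNA codons to amino-acid
#'   letters (`"*"` for stops).
#' @export
codon_table <- function() {
  as.character(Biostrings::GENETIC_CODE)
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codon])
  out[is.na(out)] <- "X"  # codons containing N or other ambiguity
  out
}

# Codons of one CDS string, excluding any codon containing a non-ACGT base
# (count of exclusions attached as attribute "n_excluded").
cds_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(structure(character(0), n_excluded = 0L))
  cod <- substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  keep <- !grepl("[^ACGT]", cod)
  structure(cod[keep], n_excluded = sum(!keep))
}

#' Codon enrichment of CDS rG4 motifs against parent-gene CDS baselines
#'
#' Counts codons inside CDS-located rG4 motifs and compares their
#' frequencies with the codon frequencies of the concatenated CDSs of the
#' distinct rG4-harboring genes (each harboring gene's canonical-isoform
#' CDS counted exactly once, regardless of how many motifs it carries).
#' A codon is tallied for a motif when at least 2 of its 3 bases lie inside
#' the motif span, so flank codons touched by a single base are not
#' counted. Codons containing N are excluded from both tallies.
#'
#' @param hits data frame of CDS-located motifs with columns
#'   `transcript_id`, `start`, `end` (transcript coordinates, 0-based
#'   half-open).
#' @param models named list of [transcript_model()]s covering every
#'   `transcript_id` (all isoforms of the harboring genes; canonical
#'   isoforms are selected internally for the baseline).
#' @param min_overlap_bases minimum motif-overlap of a codon for it to be
#'   tallied (default 2).
#' @return data frame sorted by decreasing enrichment with columns `codon`,
#'   `aa`, `count_in_rg4`, `count_in_baseline`, `freq_in_rg4`,
#'   `freq_in_baseline`, `enrichment` (ratio of frequencies; `Inf` when the
#'   baseline count is zero but the motif count is not; 0 for codons absent
#'   from motifs) and logical `enriched` (`enrichment >= 2`).
#' @export
codon_enrichment <- function(hits, models, min_overlap_bases = 2L) {
  stopifnot(is.data.frame(hits),
            all(c("transcript_id", "start", "end") %in% names(hits)))
  rg4_codons <- character(0)
  harboring_genes <- character(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(hits))) {
    m <- models[[hits$transcript_id[i]]]
    if (is.null(m) || is.null(m$cds_span) || !m$cds_valid) {
      n_skipped <- n_skipped + 1L
      next
    }
    s <- hits$start[i]; e <- hits$end[i]
    if (s < m$cds_span[1] || e > m$cds_span[2]) {
      n_skipped <- n_skipped + 1L
      next
    }
    cds <- cds_sequence(m)
    cs <- m$cds_span[1]
    k_lo <- (s - cs) %/% 3L
    k_hi <- (e - 1L - cs) %/% 3L
    for (k in k_lo:k_hi) {
      c_start <- cs + 3L * k
      ov <- min(e, c_start + 3L) - max(s, c_start)
      if (ov >= min_overlap_bases) {
        cod <- substring(cds, 3L * k + 1L, 3L * k + 3L)
        if (!grepl("[^ACGT]", cod)) {
          rg4_codons <- c(rg4_codons, cod)
        }
      }
    }
    harboring_genes <- c(harboring_genes, m$gene_id)
  }
  if (n_skipped > 0L) {
    message(sprintf("codon_enrichment: %d hit(s) skipped (outside a valid CDS)",
                    n_skipped))
  }
  canonical <- select_canonical_isoforms(models)
  canonical_genes <- vapply(canonical, function(m) m$gene_id, character(1))
  base_codons <- character(0)
  for (g in unique(harboring_genes)) {
    m <- canonical[[which(canonical_genes == g)[1]]]
    if (is.null(m$cds_span) || !m$cds_valid) next
    base_codons <- c(base_codons, cds_codons(cds_sequence(m)))
  }
  all_codons <- sort(unique(c(rg4_codons, base_codons)))
  cnt_r <- table(factor(rg4_codons, levels = all_codons))
  cnt_b <- table(factor(base_codons, levels = all_codons))
  fr <- as.numeric(cnt_r) / max(1L, sum(cnt_r))
  fb <- as.numeric(cnt_b) / max(1L, sum(cnt_b))
  enr <- ifelse(fb > 0, fr / fb, ifelse(fr > 0, Inf, 0))
  out <- data.frame(codon = all_codons, aa = translate_codon(all_codons),
                    count_in_rg4 = as.integer(cnt_r),
                    count_in_baseline = as.integer(cnt_b),
                    freq_in_rg4 = fr, freq_in_baseline = fb,
                    enrichment = enr, enriched = enr >= 2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$enrichment, out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose a CDS-located G-tract into its codon span
#'
#' A di-guanine (GG) or tri-guanine (GGG) tract inside a CDS covers either
#' one codon or two consecutive codons; this reports which, together with
#' the translated residues. Runs longer than 3 nt are truncated to their
#' leading three bases and classed with the GGG tracts.
#'
#' @param t a coding [transcript_model()] with `cds_valid = TRUE`.
#' @param tract_start tract start in transcript coordinates (0-based).
#' @param tract_len tract length in nt (>= 2).
#' @return `list(tract_kind, n_codons, residues)` with `tract_kind` in
#'   `"GG"`/`"GGG"`, or `NULL` when the tract crosses the CDS boundary
#'   (excluded with a message).
#' @export
decompose_tract <- function(t, tract_start, tract_len) {
  stopifnot(inherits(t, "TranscriptModel"), !is.null(t$cds_span), t$cds_valid,
            tract_len >= 2L)
  if (tract_len > 3L) tract_len <- 3L
  kind <- if (tract_len == 2L) "GG" else "GGG"
  s <- tract_start; e <- tract_start + tract_len
  if (s < t$cds_span[1] || e > t$cds_span[2]) {
    message(sprintf("decompose_tract: tract [%d,%d) of %s crosses the CDS boundary; excluded",
                    s, e, t$transcript_id))
    return(NULL)
  }
  ks <- unique((seq.int(s, e - 1L) - t$cds_span[1]) %/% 3L)
  cds <- cds_sequence(t)
  codons <- substring(cds, 3L * ks + 1L, 3L * ks + 3L)
  list(tract_kind = kind, n_codons = length(ks),
       residues = translate_codon(codons))
}

# Iterate the pure G-tracts of scan hits located in CDSs, applying f to
# each decomposition. Bulged tracts are not pure G-runs and are skipped.
map_cds_tracts <- function(hits, models, f) {
  out <- list()
  for (i in seq_len(nrow(hits))) {
    m <- models[[hits$transcript_id[i]]]
    if (is.null(m) || is.null(m$cds_span) || !m$cds_valid) next
    starts <- hits$tract_starts[[i]]
    lens <- hits$tract_lens[[i]]
    boff <- hits$tract_bulge_offset[[i]]
    for (j in seq_along(starts)) {
      if (!is.na(boff[j])) next
      d <- decompose_tract(m, starts[j], lens[j])
      if (!is.null(d)) out[[length(out) + 1L]] <- f(d)
    }
  }
  out
}

#' Codon-span breakdown of CDS rG4 G-tracts
#'
#' Tabulates, for the pure GG and GGG tracts of CDS-located motifs, how
#' many span one codon versus two consecutive codons.
#'
#' @param hits [scan_pqs()]-style data frame with `transcript_id` and the
#'   tract list columns, in transcript coordinates.
#' @param models named list of transcript models.
#' @return data frame `tract_kind` x `n_codons` with counts.
#' @export
tract_codon_spans <- function(hits, models) {
  recs <- map_cds_tracts(hits, models, function(d)
    data.frame(tract_kind = d$tract_kind, n_codons = d$n_codons,
               stringsAsFactors = FALSE))
  if (!length(recs)) {
    return(data.frame(tract_kind = character(0), n_codons = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  recs <- do.call(rbind, recs)
  agg <- as.data.frame(table(recs$tract_kind, recs$n_codons),
                       stringsAsFactors = FALSE)
  names(agg) <- c("tract_kind", "n_codons", "count")
  agg$n_codons <- as.integer(agg$n_codons)
  agg
}

#' Amino-acid usage within CDS rG4 G-tracts
#'
#' Tallies every residue of every tract codon span once per tract
#' membership, optionally restricted to a residue subset (the analysis of
#' enriched residues restricts to the amino acids flagged by
#' [codon_enrichment()]).
#'
#' @param hits [scan_pqs()]-style data frame in transcript coordinates.
#' @param models named list of transcript models.
#' @param aa_subset optional character vector of residue letters to keep.
#' @return data frame `aa` x `tract_kind` with counts.
#' @export
tract_aa_usage <- function(hits, models, aa_subset = NULL) {
  recs <- map_cds_tracts(hits, models, function(d)
    data.frame(aa = d$residues, tract_kind = d$tract_kind,
               stringsAsFactors = FALSE))
  if (!length(recs)) {
    return(data.frame(aa = character(0), tract_kind = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  recs <- do.call(rbind, recs)
  if (!is.null(aa_subset)) recs <- recs[recs$aa %in% aa_subset, , drop = FALSE]
  if (nrow(recs) == 0L) {
    return(data.frame(aa = character(0), tract_kind = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  agg <- as.data.frame(table(recs$aa, recs$tract_kind),
                       stringsAsFactors = FALSE)
  names(agg) <- c("aa", "tract_kind", "count")
  agg[agg$count > 0, , drop = FALSE]
}
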