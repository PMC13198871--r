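#' Construct a transcript model
#'
#' A `TranscriptModel` is the coordinate hub of the package: it holds the
#' exon structure of one transcript and supports genomic <-> transcript <->
#' CDS/codon coordinate conversion and gene-region assignment. All
#' coordinates are 0-based half-open; transcript coordinates run 5' to 3'
#' in the sense orientation.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with genomic `start`, `end` columns (0-based
#'   half-open), in any order; stored sorted 5' to 3' in transcript
#'   orientation.
#' @param sequence spliced transcript sequence in sense orientation
#'   (reverse-complemented for `-` strand transcripts).
#' @param cds_span `c(start, end)` in transcript coordinates, or `NULL` for
#'   non-coding transcripts.
#' @return An object of class `"TranscriptModel"`: a list with the above
#'   fields plus `cds_valid` (`FALSE` when the CDS length is not a positive
#'   multiple of 3, in which case the transcript is excluded from codon
#'   analyses but retained for region assignment).
#' @examples
#' t <- transcript_model("t1", "g1", "chr1", "+",
#'                       data.frame(start = 0, end = 30),
#'                       sequence = strrep("A", 30))
#' assign_region(t, c(5, 15))
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             sequence, cds_span = NULL) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  stopifnot(all(exons$start < exons$end))
  if (nrow(exons) > 1L) {
    stopifnot(all(exons$start[-1] >= exons$end[-nrow(exons)]))
  }
  # transcript orientation: reverse genomic order on the minus strand
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  widths <- exons$end - exons$start
  tlen <- sum(widths)
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) == tlen)
  exons$t_start <- cumsum(c(0L, widths[-length(widths)]))
  exons$t_end <- exons$t_start + widths
  cds_valid <- FALSE
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    stopifnot(length(cds_span) == 2L, cds_span[1] >= 0L,
              cds_span[2] <= tlen, cds_span[1] < cds_span[2])
    cds_len <- cds_span[2] - cds_span[1]
    cds_valid <- (cds_len %% 3L) == 0L
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 sequence = sequence, cds_span = cds_span,
                 cds_valid = cds_valid, length = tlen),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s, %d exon(s), %d nt%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$length,
              if (is.null(x$cds_span)) ", non-coding"
              else sprintf(", CDS [%d,%d)%s", x$cds_span[1], x$cds_span[2],
                           if (x$cds_valid) "" else " (invalid frame)")))
  invisible(x)
}

#' Load transcript models from a GTF annotation and a genome FASTA
#'
#' Builds one [transcript_model()] per transcript: exons are spliced in
#' transcript orientation (reverse-complemented on the minus strand) and
#' CDS features are projected into transcript coordinates. Transcripts
#' whose CDS length is not a multiple of 3 (or whose CDS blocks are not
#' contiguous on the transcript) are flagged `cds_valid = FALSE` and
#' excluded from codon analyses, but retained for region assignment; a
#' message reports their count.
#'
#' @param annotation_file GTF path (exon and CDS features).
#' @param genome_file genome FASTA path, or a named character vector of
#'   chromosome sequences.
#' @return named list of `TranscriptModel` objects.
#' @export
load_annotation <- function(annotation_file, genome_file) {
  ann <- if (is.data.frame(annotation_file)) annotation_file else read_gtf(annotation_file)
  genome <- if (is.character(genome_file) && length(genome_file) > 1L ||
                !is.null(names(genome_file))) genome_file else read_fasta(genome_file)
  models <- list()
  n_bad_cds <- 0L
  for (tid in unique(ann$transcript_id)) {
    rows <- ann[ann$transcript_id == tid, , drop = FALSE]
    ex <- rows[rows$feature == "exon", , drop = FALSE]
    stopifnot(nrow(ex) > 0L)
    chrom <- ex$chrom[1]
    strand <- ex$strand[1]
    if (!chrom %in% names(genome)) {
      stop(sprintf("transcript %s: chromosome %s absent from genome FASTA",
                   tid, chrom))
    }
    cseq <- genome[[chrom]]
    if (max(ex$end) > nchar(cseq)) {
      stop(sprintf("transcript %s: exons extend beyond chromosome %s",
                   tid, chrom))
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    pieces <- substring(cseq, ex$start + 1L, ex$end)
    seq <- paste(pieces, collapse = "")
    if (strand == "-") seq <- revcomp(seq)
    m <- transcript_model(tid, ex$gene_id[1], chrom, strand,
                          ex[, c("start", "end")], seq)
    cds <- rows[rows$feature == "CDS", , drop = FALSE]
    if (nrow(cds) > 0L) {
      tiv <- lapply(seq_len(nrow(cds)), function(i)
        genomic_to_transcript(m, c(cds$start[i], cds$end[i])))
      if (any(vapply(tiv, is.null, logical(1)))) {
        stop(sprintf("transcript %s: CDS feature outside exons", tid))
      }
      tiv <- do.call(rbind, tiv)
      span <- c(min(tiv[, 1]), max(tiv[, 2]))
      contiguous <- sum(tiv[, 2] - tiv[, 1]) == span[2] - span[1]
      m <- transcript_model(tid, ex$gene_id[1], chrom, strand,
                            ex[, c("start", "end")], seq, cds_span = span)
      if (!contiguous) m$cds_valid <- FALSE
      if (!m$cds_valid) n_bad_cds <- n_bad_cds + 1L
    }
    models[[tid]] <- m
  }
  if (n_bad_cds > 0L) {
    message(sprintf("%d transcript(s) flagged cds_valid = FALSE (CDS not a multiple of 3 or not contiguous); excluded from codon analyses",
                    n_bad_cds))
  }
  models
}

# Map one genomic position (0-based) to a transcript position, or NA.
genomic_pos_to_transcript <- function(t, gpos) {
  ex <- t$exons
  k <- which(gpos >= ex$start & gpos < ex$end)
  if (length(k) != 1L) return(NA_integer_)
  if (t$strand == "+") {
    ex$t_start[k] + (gpos - ex$start[k])
  } else {
    ex$t_start[k] + (ex$end[k] - 1L - gpos)
  }
}

#' Project a genomic interval onto transcript coordinates
#'
#' @param t a `TranscriptModel`.
#' @param g genomic interval `c(start, end)` (0-based half-open) on
#'   `t$chrom`.
#' @return `c(start, end)` in transcript coordinates, or `NULL` when any
#'   base of `g` falls in an intron or outside the transcript.
#' @examples
#' t <- transcript_model("t1", "g1", "chr1", "+",
#'                       data.frame(start = 100, end = 130),
#'                       sequence = strrep("A", 30))
#' genomic_to_transcript(t, c(105, 115))  # [5, 15)
#' @export
genomic_to_transcript <- function(t, g) {
  stopifnot(inherits(t, "TranscriptModel"), length(g) == 2L, g[1] < g[2])
  tp <- vapply(seq.int(g[1], g[2] - 1L), function(p)
    genomic_pos_to_transcript(t, p), integer(1))
  if (anyNA(tp)) return(NULL)
  c(min(tp), max(tp) + 1L)
}

#' Project a transcript interval back to genomic blocks
#'
#' The inverse of [genomic_to_transcript()]: a transcript interval maps to
#' one or more genomic blocks (one per exon it touches).
#'
#' @param t a `TranscriptModel`.
#' @param iv transcript interval `c(start, end)`.
#' @return data frame of genomic blocks `chrom`, `start`, `end`, `strand`,
#'   ordered 5' to 3' along the transcript.
#' @export
transcript_to_genomic <- function(t, iv) {
  stopifnot(inherits(t, "TranscriptModel"), length(iv) == 2L,
            iv[1] >= 0L, iv[2] <= t$length, iv[1] < iv[2])
  ex <- t$exons
  blocks <- list()
  for (k in seq_len(nrow(ex))) {
    lo <- max(iv[1], ex$t_start[k])
    hi <- min(iv[2], ex$t_end[k])
    if (lo >= hi) next
    if (t$strand == "+") {
      gs <- ex$start[k] + (lo - ex$t_start[k])
      ge <- gs + (hi - lo)
    } else {
      ge <- ex$end[k] - (lo - ex$t_start[k])
      gs <- ge - (hi - lo)
    }
    blocks[[length(blocks) + 1L]] <-
      data.frame(chrom = t$chrom, start = gs, end = ge, strand = t$strand,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, blocks)
}

#' Gene-region labels
#'
#' @return character vector of the four region labels in display order.
#' @export
region_levels <- function() c("FIVE_UTR", "CDS", "THREE_UTR", "NONCODING")

#' Assign a gene region to a transcript interval
#'
#' Non-coding transcripts always yield `"NONCODING"`. For coding
#' transcripts the label is decided by the interval midpoint; a midpoint
#' falling exactly on a CDS boundary is assigned to the CDS, so
#' boundary-straddling motifs resolve deterministically.
#'
#' @param t a `TranscriptModel`.
#' @param iv transcript interval `c(start, end)`.
#' @return one of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"NONCODING"`.
#' @export
assign_region <- function(t, iv) {
  stopifnot(inherits(t, "TranscriptModel"), length(iv) == 2L,
            iv[1] >= 0, iv[2] <= t$length, iv[1] < iv[2])
  if (is.null(t$cds_span)) return("NONCODING")
  mid <- (iv[1] + iv[2]) / 2
  if (mid < t$cds_span[1]) "FIVE_UTR"
  else if (mid > t$cds_span[2]) "THREE_UTR"
  else "CDS"
}

#' Map a transcript position to its codon
#'
#' @param t a coding `TranscriptModel`.
#' @param pos transcript position (0-based).
#' @return `list(codon_index, offset)` with `codon_index = (pos -
#'   cds_start) %/% 3` and `offset = (pos - cds_start) %% 3`, or `NULL`
#'   when `pos` lies outside the CDS.
#' @examples
#' t <- transcript_model("t1", "g1", "chr1", "+",
#'                       data.frame(start = 0, end = 60),
#'                       sequence = strrep("A", 60), cds_span = c(50, 59))
#' transcript_to_codon(t, 57)  # codon 2, offset 1
#' @export
transcript_to_codon <- function(t, pos) {
  stopifnot(inherits(t, "TranscriptModel"), !is.null(t$cds_span))
  if (pos < t$cds_span[1] || pos >= t$cds_span[2]) return(NULL)
  off <- pos - t$cds_span[1]
  list(codon_index = off %/% 3L, offset = off %% 3L)
}

#' Extract the CDS sequence of a transcript
#'
#' @param t a coding `TranscriptModel`.
#' @return character string of the CDS (sense orientation).
#' @export
cds_sequence <- function(t) {
  stopifnot(inherits(t, "TranscriptModel"), !is.null(t$cds_span))
  substring(t$sequence, t$cds_span[1] + 1L, t$cds_span[2])
}

#' Select one canonical isoform per gene
#'
#' When several transcripts share a gene, region/codon analyses use a
#' single representative: the longest CDS, ties broken by the longest
#' transcript, then lexicographically smallest transcript id.
#'
#' @param models named list of `TranscriptModel`s.
#' @return named list restricted to one model per gene.
#' @export
select_canonical_isoforms <- function(models) {
  genes <- vapply(models, function(m) m$gene_id, character(1))
  keep <- character(0)
  for (g in unique(genes)) {
    ids <- names(models)[genes == g]
    cdslen <- vapply(ids, function(i) {
      m <- models[[i]]
      if (is.null(m$cds_span)) 0L else m$cds_span[2] - m$cds_span[1]
    }, integer(1))
    tlen <- vapply(ids, function(i) models[[i]]$length, integer(1))
    ord <- order(-cdslen, -tlen, ids)
    keep <- c(keep, ids[ord[1]])
  }
  models[keep]
}

#' Summarize transcript models as a table
#'
#' One row per transcript with its gene, strand and region lengths; the
#' join key for downstream tables.
#'
#' @param models named list of `TranscriptModel`s.
#' @return data frame with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `length`, `utr5_len`, `cds_len`, `utr3_len`, `cds_valid`.
#' @export
transcript_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    if (is.null(m$cds_span)) {
      u5 <- 0L; cl <- 0L; u3 <- 0L
    } else {
      u5 <- m$cds_span[1]
      cl <- m$cds_span[2] - m$cds_span[1]
      u3 <- m$length - m$cds_span[2]
    }
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               chrom = m$chrom, strand = m$strand, length = m$length,
               utr5_len = u5, cds_len = cl, utr3_len = u3,
               cds_valid = m$cds_valid, stringsAsFactors = FALSE)
  }))
}
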