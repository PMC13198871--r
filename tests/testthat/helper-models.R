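# Helpers building random annotations in memory, plus a per-base
# splice-and-complement oracle independent of TranscriptModel's exon
# arithmetic.

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Per-base oracle: walk the exon bases one by one in genomic order and
# assemble the sense-strand transcript sequence.
splice_oracle <- function(chrom_seq, exons, strand) {
  chars <- strsplit(chrom_seq, "", fixed = TRUE)[[1]]
  ex <- exons[order(exons$start), , drop = FALSE]
  out <- character(0)
  for (k in seq_len(nrow(ex))) {
    for (p in seq.int(ex$start[k], ex$end[k] - 1L)) {
      out <- c(out, chars[p + 1L])
    }
  }
  if (strand == "-") out <- rev(unname(comp_base[out]))
  paste(out, collapse = "")
}

# Per-base oracle mapping a genomic position to its transcript position.
pos_oracle <- function(exons, strand, gpos) {
  ex <- exons[order(exons$start), , drop = FALSE]
  gps <- unlist(lapply(seq_len(nrow(ex)), function(k)
    seq.int(ex$start[k], ex$end[k] - 1L)))
  if (strand == "-") gps <- rev(gps)
  m <- match(gpos, gps)
  if (is.na(m)) NA_integer_ else m - 1L
}

# Random multi-exon transcript on a random chromosome; returns the genome
# chunk, a GTF-style annotation data frame and the oracle sequence.
random_annotation <- function(n_exons = 3L, strand = "+", coding = TRUE,
                              chrom = "chrT", tid = "txT", gid = "geneT") {
  widths <- sample(30:80, n_exons, replace = TRUE)
  gaps <- sample(15:50, n_exons, replace = TRUE)
  starts <- 10L + cumsum(c(0L, head(widths + gaps, -1L)))
  exons <- data.frame(start = starts, end = starts + widths)
  chrom_len <- max(exons$end) + 20L
  chrom_seq <- random_gseq(chrom_len, 0.25)
  tlen <- sum(widths)
  ann <- data.frame(chrom = chrom, feature = "exon", start = exons$start,
                    end = exons$end, strand = strand, transcript_id = tid,
                    gene_id = gid, stringsAsFactors = FALSE)
  cds_span <- NULL
  if (coding && tlen >= 30L) {
    cds_len <- 3L * ((tlen - 20L) %/% 3L %/% 2L)
    cds_start <- 5L
    cds_span <- c(cds_start, cds_start + cds_len)
    # CDS genomic blocks via the per-base oracle (transcript -> genomic)
    ex <- exons[order(exons$start), , drop = FALSE]
    gps <- unlist(lapply(seq_len(nrow(ex)), function(k)
      seq.int(ex$start[k], ex$end[k] - 1L)))
    if (strand == "-") gps <- rev(gps)
    cds_g <- sort(gps[seq.int(cds_span[1] + 1L, cds_span[2])])
    brk <- c(0L, which(diff(cds_g) > 1L), length(cds_g))
    cds_rows <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(b) {
      seg <- cds_g[(brk[b] + 1L):brk[b + 1L]]
      data.frame(chrom = chrom, feature = "CDS", start = min(seg),
                 end = max(seg) + 1L, strand = strand, transcript_id = tid,
                 gene_id = gid, stringsAsFactors = FALSE)
    }))
    ann <- rbind(ann, cds_rows)
  }
  list(genome = setNames(chrom_seq, chrom), annotation = ann,
       exons = exons, strand = strand, cds_span = cds_span,
       oracle_seq = splice_oracle(chrom_seq, exons, strand))
}

# A small coding transcript built directly from a given CDS codon string.
toy_coding_model <- function(cds, utr5 = "TTTTTTTTTT", utr3 = "TTTTTTTTTT",
                             tid = "toy", gid = "toygene") {
  seqs <- paste0(utr5, cds, "TAA", utr3)
  transcript_model(tid, gid, "chrToy", "+",
                   data.frame(start = 0L, end = nchar(seqs)), seqs,
                   cds_span = c(nchar(utr5), nchar(utr5) + nchar(cds) + 3L))
}
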