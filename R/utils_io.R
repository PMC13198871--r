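#' @importFrom utils read.table write.table head tail
#' @importFrom stats setNames runif rbinom
NULL

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences over A/C/G/T/N (case preserved as
#'   upper case).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANTGCAN", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a (possibly wrapped) multi-record FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED-like file (3--6 columns)
#'
#' Coordinates stay in BED's native 0-based half-open convention, which is
#' also the package-internal convention.
#'
#' @param path BED file path.
#' @return data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(min(ncol(x), 6L))]
  x
}

#' Write a BED-like data frame
#'
#' @param df data frame with at least `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write tab-separated tables with headers
#'
#' Thin wrappers fixing the quoting and separator conventions used by every
#' table this package emits.
#'
#' @param path file path.
#' @return `read_tsv_table()` returns a data frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             comment.char = "", stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @param df data frame to write.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Extract one attribute value from GTF attribute strings of the form
# key "value"; key2 "value2"; ...
gtf_attr <- function(attrs, key) {
  pat <- paste0(key, " \"([^\"]*)\"")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(v) if (length(v) == 2L) v[2] else NA_character_,
         character(1))
}

#' Read transcript annotation from a GTF file
#'
#' Parses exon and CDS features only. GTF's 1-based closed coordinates are
#' converted to the package's 0-based half-open convention on read.
#'
#' @param path GTF file path.
#' @return data frame with columns `chrom`, `feature`, `start`, `end`
#'   (0-based half-open), `strand`, `transcript_id`, `gene_id`.
#' @export
read_gtf <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE,
                  col.names = c("chrom", "source", "feature", "start", "end",
                                "score", "strand", "frame", "attributes"))
  x <- x[x$feature %in% c("exon", "CDS"), , drop = FALSE]
  data.frame(chrom = x$chrom, feature = x$feature,
             start = x$start - 1L, end = x$end,
             strand = x$strand,
             transcript_id = gtf_attr(x$attributes, "transcript_id"),
             gene_id = gtf_attr(x$attributes, "gene_id"),
             stringsAsFactors = FALSE)
}

#' Write exon/CDS features to GTF
#'
#' @param df data frame as returned by [read_gtf()] (0-based half-open
#'   coordinates; converted to GTF 1-based closed on write).
#' @param path output path.
#' @export
write_gtf <- function(df, path) {
  lines <- sprintf(
    "%s\trg4evo\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    df$chrom, df$feature, df$start + 1L, df$end, df$strand,
    df$gene_id, df$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
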