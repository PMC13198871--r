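#' Read a multiple alignment format (MAF) file
#'
#' Parses alignment blocks (`a` paragraphs) keeping `s` lines only; `i`,
#' `e` and `q` lines are ignored. Coordinates follow the MAF convention
#' (0-based starts; `start` counted on the given strand).
#'
#' @param path MAF file path.
#' @return list of blocks, each a data frame with columns `src` (e.g.
#'   `"hs.chr1"`), `start`, `size`, `strand`, `src_size`, `text` (aligned
#'   row with gap characters).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur)) {
      blocks[[length(blocks) + 1L]] <<- do.call(rbind, cur)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      cur <- list()
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      cur[[length(cur) + 1L]] <- data.frame(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE)
    }
  }
  flush()
  blocks
}

#' Write alignment blocks to MAF
#'
#' @param blocks list of block data frames as returned by [read_maf()].
#' @param path output path.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$src, b$start, b$size,
                       b$strand, b$src_size, b$text), con)
    writeLines("", con)
  }
  invisible(path)
}

maf_species <- function(src) sub("\\..*$", "", src)
maf_chrom <- function(src) sub("^[^.]*\\.", "", src)

#' Nested clade scheme for conservation summaries
#'
#' Defines the ordered, nested taxonomic categories used to summarize
#' per-species conservation (by default the vertebrate series
#' Primates/Glires through Vertebrata is the intended usage). Each species
#' is assigned to its innermost clade ("ring" assignment), so rings are
#' disjoint; cumulative species sets are also derivable.
#'
#' @param clades named list, innermost first, mapping clade labels to their
#'   full (nested) species sets.
#' @param ages named numeric vector of per-clade divergence ages (MYA),
#'   same names as `clades`.
#' @return object of class `"clade_scheme"` with `order`, `clades`
#'   (cumulative sets), `rings` (disjoint innermost sets), `species_clade`
#'   (named map species -> innermost clade) and `ages`.
#' @export
clade_scheme <- function(clades, ages = NULL) {
  stopifnot(is.list(clades), !is.null(names(clades)))
  ord <- names(clades)
  for (k in seq_along(ord)[-1]) {
    stopifnot(all(clades[[k - 1L]] %in% clades[[k]]))  # nested
  }
  rings <- clades
  seen <- character(0)
  for (k in seq_along(ord)) {
    rings[[k]] <- setdiff(clades[[k]], seen)
    seen <- union(seen, clades[[k]])
  }
  sp_clade <- unlist(lapply(ord, function(l)
    setNames(rep(l, length(rings[[l]])), rings[[l]])))
  structure(list(order = ord, clades = clades, rings = rings,
                 species_clade = sp_clade, ages = ages),
            class = "clade_scheme")
}

#' Extract per-species alignment windows around rG4s
#'
#' For each rG4, collects the alignment columns of the motif plus `flank`
#' nt of reference sequence on each side, across all MAF blocks covering
#' the window. Columns are assembled per reference position; species
#' missing from a covering block contribute gap characters there. Insertion
#' columns (gap in the reference) interior to the window are retained so
#' PQS scanning sees the full species sequence, while identity is computed
#' over reference-base columns only.
#'
#' @param maf MAF path or [read_maf()] block list.
#' @param rg4s data frame with `name`, `chrom`, `start`, `end` (genomic,
#'   0-based half-open, on the reference assembly) and optional `strand`
#'   (`"-"` motifs are scanned on the reverse complement).
#' @param ref_species reference species prefix in the MAF `src` fields.
#' @param flank flank width in reference nt (default 30).
#' @return list of window objects: `rg4_id`, `chrom`, `start`, `end`,
#'   `strand`, `species`, `mat` (species x column character matrix, or
#'   `NULL` when no block covers the rG4), `ref_col_pos` (reference
#'   coordinate per column, `NA` for insertion columns) and `motif_cols`
#'   (logical mask of motif-span columns).
#' @export
extract_windows <- function(maf, rg4s, ref_species, flank = 30L) {
  blocks <- if (is.character(maf)) read_maf(maf) else maf
  all_species <- unique(unlist(lapply(blocks, function(b) maf_species(b$src))))
  ref_blocks <- lapply(blocks, function(b) {
    ridx <- which(maf_species(b$src) == ref_species)
    if (length(ridx) != 1L) return(NULL)
    stopifnot(b$strand[ridx] == "+")
    chars <- strsplit(b$text[ridx], "", fixed = TRUE)[[1]]
    nong <- chars != "-"
    refpos <- rep(NA_integer_, length(chars))
    refpos[nong] <- b$start[ridx] + seq_len(sum(nong)) - 1L
    list(b = b, chrom = maf_chrom(b$src[ridx]), refpos = refpos)
  })
  ref_blocks <- Filter(Negate(is.null), ref_blocks)
  out <- vector("list", nrow(rg4s))
  for (i in seq_len(nrow(rg4s))) {
    ws <- rg4s$start[i] - as.integer(flank)
    we <- rg4s$end[i] + as.integer(flank)
    strand <- if (!is.null(rg4s$strand)) rg4s$strand[i] else "+"
    cover <- Filter(function(rb) {
      rb$chrom == rg4s$chrom[i] &&
        any(!is.na(rb$refpos) & rb$refpos >= ws & rb$refpos < we)
    }, ref_blocks)
    if (!length(cover)) {
      out[[i]] <- list(rg4_id = rg4s$name[i], chrom = rg4s$chrom[i],
                       start = rg4s$start[i], end = rg4s$end[i],
                       strand = strand, species = all_species,
                       ref_species = ref_species,
                       mat = NULL, ref_col_pos = integer(0),
                       motif_cols = logical(0))
      next
    }
    # order covering blocks along the reference
    ord <- order(vapply(cover, function(rb) min(rb$refpos, na.rm = TRUE),
                        integer(1)))
    cover <- cover[ord]
    mats <- list()
    poss <- list()
    for (rb in cover) {
      inw <- !is.na(rb$refpos) & rb$refpos >= ws & rb$refpos < we
      keep <- which(inw)
      cols <- seq.int(min(keep), max(keep))  # interior insertions retained
      m <- matrix("-", nrow = length(all_species), ncol = length(cols),
                  dimnames = list(all_species, NULL))
      for (r in seq_len(nrow(rb$b))) {
        sp <- maf_species(rb$b$src[r])
        rowc <- strsplit(rb$b$text[r], "", fixed = TRUE)[[1]]
        m[sp, ] <- rowc[cols]
      }
      mats[[length(mats) + 1L]] <- m
      poss[[length(poss) + 1L]] <- rb$refpos[cols]
    }
    mat <- do.call(cbind, mats)
    ref_col_pos <- do.call(c, poss)
    motif_cols <- !is.na(ref_col_pos) & ref_col_pos >= rg4s$start[i] &
      ref_col_pos < rg4s$end[i]
    out[[i]] <- list(rg4_id = rg4s$name[i], chrom = rg4s$chrom[i],
                     start = rg4s$start[i], end = rg4s$end[i],
                     strand = strand, species = all_species,
                     ref_species = ref_species,
                     mat = mat, ref_col_pos = ref_col_pos,
                     motif_cols = motif_cols)
  }
  out
}

# Gap-free sequence of one species row over the window, in motif sense
# orientation.
window_species_seq <- function(w, sp) {
  if (is.null(w$mat)) return("")
  chars <- w$mat[sp, ]
  s <- paste(chars[chars != "-"], collapse = "")
  if (w$strand == "-") revcomp(s) else s
}

#' Sequence identity of an aligned species over a motif span
#'
#' The number of alignment columns (within the reference motif span) where
#' the species base matches the reference base, divided by the reference
#' motif length; gap and missing columns count as mismatches.
#'
#' @param w a window object from [extract_windows()].
#' @param sp species name.
#' @return identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(w, sp) {
  motif_len <- w$end - w$start
  if (is.null(w$mat) || !any(w$motif_cols)) return(0)
  ref <- toupper(w$mat[w$ref_species, w$motif_cols])
  other <- toupper(w$mat[sp, w$motif_cols])
  sum(other != "-" & other == ref) / motif_len
}

#' Per-species conservation records for a set of rG4 windows
#'
#' For each rG4 and each species aligned in the MAF: whether the species
#' has any aligned (non-gap) sequence over the window, whether its aligned
#' window sequence contains a PQS of any motif class, and its sequence
#' identity to the reference motif. PQS presence is never reported for
#' unaligned species.
#'
#' @param windows list from [extract_windows()].
#' @param params [scan_params()] used for the PQS search.
#' @return data frame with `rg4_id`, `species`, `aligned`, `has_pqs`,
#'   `identity`.
#' @export
conservation_records <- function(windows, params = scan_params()) {
  out <- list()
  for (w in windows) {
    for (sp in w$species) {
      aligned <- !is.null(w$mat) && any(w$mat[sp, ] != "-")
      has_pqs <- FALSE
      ident <- 0
      if (aligned) {
        seqs <- window_species_seq(w, sp)
        has_pqs <- nrow(scan_pqs(seqs, params)) > 0L
        ident <- sequence_identity(w, sp)
      }
      out[[length(out) + 1L]] <-
        data.frame(rg4_id = w$rg4_id, species = sp, aligned = aligned,
                   has_pqs = has_pqs, identity = ident,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average sequence identity per rG4
#'
#' The identity averaged over species with an alignment, excluding the
#' reference itself; rG4s aligned in no species are assigned 0.0.
#'
#' @param records data frame from [conservation_records()].
#' @param ref_species reference species to exclude from the average.
#' @return data frame `rg4_id`, `n_aligned`, `average_identity`.
#' @export
average_identity <- function(records, ref_species = NULL) {
  recs <- records
  if (!is.null(ref_species)) recs <- recs[recs$species != ref_species, , drop = FALSE]
  out <- lapply(split(recs, recs$rg4_id), function(d) {
    al <- d[d$aligned, , drop = FALSE]
    data.frame(rg4_id = d$rg4_id[1], n_aligned = nrow(al),
               average_identity = if (nrow(al)) mean(al$identity) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-clade conservation summaries
#'
#' Summarizes [conservation_records()] over the nested clades of a
#' [clade_scheme()]: per rG4 and clade, the number of member species, of
#' aligned species, of species with a conserved PQS, and the mean identity
#' over aligned species. Both disjoint "ring" and cumulative species sets
#' are supported.
#'
#' @param records data frame from [conservation_records()].
#' @param scheme a [clade_scheme()].
#' @param cumulative use cumulative (nested) species sets instead of
#'   disjoint rings.
#' @return data frame `rg4_id`, `clade`, `n_species`, `n_aligned`,
#'   `n_with_pqs`, `pqs_fraction`, `mean_identity` (`NA` when no species
#'   aligned).
#' @export
clade_summary <- function(records, scheme, cumulative = FALSE) {
  stopifnot(inherits(scheme, "clade_scheme"))
  sets <- if (cumulative) scheme$clades else scheme$rings
  out <- list()
  for (id in unique(records$rg4_id)) {
    d <- records[records$rg4_id == id, , drop = FALSE]
    for (cl in scheme$order) {
      dd <- d[d$species %in% sets[[cl]], , drop = FALSE]
      if (!nrow(dd)) next
      al <- dd[dd$aligned, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        rg4_id = id, clade = cl, n_species = nrow(dd),
        n_aligned = nrow(al), n_with_pqs = sum(dd$has_pqs),
        pqs_fraction = if (nrow(dd)) sum(dd$has_pqs) / nrow(dd) else NA_real_,
        mean_identity = if (nrow(al)) mean(al$identity) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort conservation distributions by region and canonicality
#'
#' Joins per-clade summaries with rG4 metadata and aggregates the
#' distribution of PQS conservation and identity per clade, gene region
#' and canonicality class.
#'
#' @param clade_df data frame from [clade_summary()].
#' @param rg4_meta data frame with `rg4_id`, `region`, `canonicality`.
#' @return aggregated data frame with one row per (clade, region,
#'   canonicality): `n_rg4s`, `mean_pqs_fraction`, `mean_identity`.
#' @export
conservation_cohort <- function(clade_df, rg4_meta) {
  m <- merge(clade_df, rg4_meta[, c("rg4_id", "region", "canonicality")],
             by = "rg4_id")
  key <- interaction(m$clade, m$region, m$canonicality, drop = TRUE)
  out <- lapply(split(m, key), function(d) {
    data.frame(clade = d$clade[1], region = d$region[1],
               canonicality = d$canonicality[1], n_rg4s = nrow(d),
               mean_pqs_fraction = mean(d$pqs_fraction, na.rm = TRUE),
               mean_identity = mean(d$mean_identity, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Map 0-based ungapped positions of an aligned row to column indices.
ungapped_to_cols <- function(row_chars) which(row_chars != "-")

#' Positional conservation of CDS rG4s through family alignments
#'
#' For every ordered species pair in a per-family codon-aware multiple
#' sequence alignment, classifies each rG4 of the first species by the
#' status of the second: `no_alignment` (either sequence absent from the
#' MSA, or the partner all-gap over the motif columns), `aligned_no_pqs`,
#' `aligned_pqs_no_rg4` (partner window holds a PQS but no overlapping
#' rG4), or `aligned_rg4` (an rG4 of the partner shares at least one
#' alignment column with the motif).
#'
#' @param msas named list (by family) of named character vectors: aligned
#'   CDS rows (gap `-`), names = species.
#' @param rg4s data frame with `family`, `species`, `start`, `end`
#'   (0-based half-open, in the ungapped row sequence of that species).
#' @param params [scan_params()] for the partner PQS search.
#' @param flank_cols alignment columns of context added around the motif
#'   for the PQS search (default 30).
#' @return list with `detail` (one row per rG4 x partner species) and
#'   `counts` (per ordered species pair x status).
#' @export
positional_conservation_cds <- function(msas, rg4s, params = scan_params(),
                                        flank_cols = 30L) {
  detail <- list()
  for (fam in unique(rg4s$family)) {
    msa <- msas[[fam]]
    fr <- rg4s[rg4s$family == fam, , drop = FALSE]
    rows <- lapply(msa, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    cols_of <- lapply(rows, ungapped_to_cols)
    species <- names(msa)
    for (i in seq_len(nrow(fr))) {
      sp_a <- fr$species[i]
      for (sp_b in setdiff(unique(c(species, fr$species)), sp_a)) {
        status <- "no_alignment"
        if (sp_a %in% species && sp_b %in% species) {
          acols <- cols_of[[sp_a]][seq.int(fr$start[i] + 1L, fr$end[i])]
          bchars <- rows[[sp_b]][acols]
          if (any(bchars != "-")) {
            status <- "aligned_no_pqs"
            lo <- max(1L, min(acols) - flank_cols)
            hi <- min(length(rows[[sp_b]]), max(acols) + flank_cols)
            bwin <- rows[[sp_b]][lo:hi]
            bseq <- paste(bwin[bwin != "-"], collapse = "")
            if (nrow(scan_pqs(bseq, params)) > 0L) status <- "aligned_pqs_no_rg4"
            brg4 <- rg4s[rg4s$family == fam & rg4s$species == sp_b, , drop = FALSE]
            for (j in seq_len(nrow(brg4))) {
              bcols <- cols_of[[sp_b]][seq.int(brg4$start[j] + 1L, brg4$end[j])]
              if (length(intersect(acols, bcols)) >= 1L) {
                status <- "aligned_rg4"
                break
              }
            }
          }
        }
        detail[[length(detail) + 1L]] <- data.frame(
          family = fam, species_a = sp_a, species_b = sp_b,
          start = fr$start[i], end = fr$end[i], status = status,
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(family = character(0), species_a = character(0),
               species_b = character(0), start = integer(0), end = integer(0),
               status = character(0), stringsAsFactors = FALSE)
  rownames(detail) <- NULL
  counts <- as.data.frame(table(species_a = detail$species_a,
                                species_b = detail$species_b,
                                status = detail$status),
                          stringsAsFactors = FALSE)
  names(counts)[4] <- "count"
  list(detail = detail, counts = counts[counts$count > 0, , drop = FALSE])
}

#' Positional conservation of UTR rG4s via pre-mapped partner coordinates
#'
#' A UTR rG4 counts as positionally conserved when its genomic coordinates
#' share at least one base with any partner rG4 pre-mapped (lifted over)
#' into the same genome. Optionally, a PQS-level status is derived by
#' scanning the rG4's own genomic window, mirroring the distinction between
#' structure-level and sequence-level conservation.
#'
#' @param rg4s_a data frame with `name`, `chrom`, `start`, `end` in genome
#'   A coordinates.
#' @param rg4s_b_mapped data frame of partner rG4s mapped into genome A
#'   (`chrom`, `start`, `end`).
#' @param genome optional named character vector of genome-A chromosome
#'   sequences, enabling the PQS status column.
#' @param params [scan_params()].
#' @param flank window flank for the PQS scan (default 30 nt).
#' @return data frame per rG4 of A: `rg4_id`, `conserved`, `n_partners`,
#'   `window_has_pqs` (`NA` without a genome).
#' @export
positional_conservation_utr <- function(rg4s_a, rg4s_b_mapped, genome = NULL,
                                        params = scan_params(), flank = 30L) {
  out <- lapply(seq_len(nrow(rg4s_a)), function(i) {
    same <- rg4s_b_mapped[rg4s_b_mapped$chrom == rg4s_a$chrom[i], , drop = FALSE]
    ov <- pmin(rg4s_a$end[i], same$end) - pmax(rg4s_a$start[i], same$start)
    n <- sum(ov >= 1L)
    haspqs <- NA
    if (!is.null(genome)) {
      cseq <- genome[[rg4s_a$chrom[i]]]
      lo <- max(0L, rg4s_a$start[i] - flank)
      hi <- min(nchar(cseq), rg4s_a$end[i] + flank)
      haspqs <- nrow(scan_pqs(substring(cseq, lo + 1L, hi), params)) > 0L
    }
    data.frame(rg4_id = rg4s_a$name[i], conserved = n >= 1L, n_partners = n,
               window_has_pqs = haspqs, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
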