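# Stable sub-seed derivation: one RNG stream per generated artifact,
# derived from the master seed by a label hash (kept below 2^31).
stable_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
# guard codons without guanine (cannot extend or seed a G-tract)
GUARD_CODONS <- c("ACA", "ACT", "ACC", "CAT", "CTA", "CTT", "TAC",
                  "TCA", "TCT", "TTA", "TTC", "CCA")

rand_seq <- function(n, probs = c(A = 0.3, C = 0.25, G = 0.2, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Build a PQS motif sequence of a requested class and canonicality
#'
#' Constructs a motif that the scanner provably assigns the requested
#' class and canonicality: canonical and long-loop motifs carry four GGG
#' tracts (canonicality 4), bulged motifs three GGG plus one bulged tract
#' (canonicality 3), and two-quartet motifs mix `canonicality` GGG tracts
#' with GG tracts (canonicality 0--3). Loop bases never contain G.
#'
#' @param motif_class one of `"CANONICAL"`, `"LONG_LOOP"`, `"BULGE"`,
#'   `"TWO_QUARTET"`.
#' @param canonicality requested canonicality (only used for two-quartet;
#'   forced to 4/4/3 for the other classes).
#' @param frame_mod3 when `TRUE`, loop lengths are adjusted so the motif
#'   length is a multiple of 3 and loops use only C (no in-frame stop can
#'   arise), for frame-consistent CDS embedding.
#' @return character motif sequence.
#' @export
pqs_motif_seq <- function(motif_class, canonicality = 4L, frame_mod3 = FALSE) {
  loop_alphabet <- if (frame_mod3) "C" else c("A", "C", "T")
  mkloop <- function(len) paste(sample(loop_alphabet, len, replace = TRUE),
                                collapse = "")
  tracts <- switch(motif_class,
    CANONICAL = rep("GGG", 4),
    LONG_LOOP = rep("GGG", 4),
    BULGE = {
      tr <- rep("GGG", 4)
      tr[sample.int(4, 1)] <- "GTGG"  # G [T] GG, three guanines total
      tr
    },
    TWO_QUARTET = {
      stopifnot(canonicality >= 0L, canonicality <= 3L)
      sample(c(rep("GGG", canonicality), rep("GG", 4L - canonicality)))
    },
    stop("unknown motif class: ", motif_class))
  base_loops <- if (motif_class == "LONG_LOOP") c(8L, 1L, 1L) else c(1L, 1L, 1L)
  for (extra in 0:2) {
    loops <- base_loops
    loops[2] <- loops[2] + extra
    total <- sum(nchar(tracts)) + sum(loops)
    if (!frame_mod3 || total %% 3L == 0L) break
  }
  paste0(tracts[1], mkloop(loops[1]), tracts[2], mkloop(loops[2]),
         tracts[3], mkloop(loops[3]), tracts[4])
}

expected_canonicality <- function(motif_class, requested) {
  switch(motif_class, CANONICAL = 4L, LONG_LOOP = 4L, BULGE = 3L,
         TWO_QUARTET = as.integer(requested))
}

# Replace guanines by A in [from, to) (1-based inclusive bounds given as
# 0-based half-open interval) of a character vector sequence.
degquard <- function(chars, from, to) {
  idx <- seq.int(max(1L, from + 1L), min(length(chars), to))
  chars[idx][chars[idx] == "G"] <- "A"
  chars
}

#' Synthetic transcriptome configuration
#'
#' Defaults define the study conditions emulated by [make_transcriptome()]:
#' mRNAs with 5'UTR/CDS/3'UTR structure, PQSs of controlled class and
#' canonicality embedded with G-free guard zones (so re-scanning recovers
#' exactly the planted motif), optional codon-spike intervals for
#' enrichment calibration, and truth-subsampled rG4 calls.
#'
#' @param seed master RNG seed; all outputs are bit-reproducible given the
#'   seed.
#' @param n_genes number of genes (one transcript each, own chromosome).
#' @param utr5_len,utr3_len length ranges in nt.
#' @param cds_codons CDS length range in codons (incl. start/stop).
#' @param n_exons_range exon count range per transcript.
#' @param base_probs background base composition.
#' @param embeddings data frame (`region`, `motif_class`, `canonicality`,
#'   `n`) of PQS embeddings to plant, assigned to genes cyclically.
#' @param spike list describing codon-spike intervals:
#'   `codon`, `factor` (sampling multiple of the uniform 1/61 codon
#'   frequency), `n_motifs`, `motif_codons`; `n_motifs = 0` disables
#'   spiking. At most one spike interval is placed per gene so the
#'   parent-CDS baseline stays representative.
#' @param detection_prob probability that a planted motif appears in the
#'   emitted rG4 call set.
#' @param frac_minus fraction of genes placed on the minus strand.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 30L,
                             utr5_len = c(80L, 160L),
                             cds_codons = c(120L, 220L),
                             utr3_len = c(100L, 220L),
                             n_exons_range = c(1L, 3L),
                             base_probs = c(A = 0.3, C = 0.25, G = 0.2, T = 0.25),
                             embeddings = default_embeddings(),
                             spike = list(codon = "GGA", factor = 1,
                                          n_motifs = 0L, motif_codons = 12L),
                             detection_prob = 1,
                             frac_minus = 0.5) {
  stopifnot(detection_prob >= 0, detection_prob <= 1,
            frac_minus >= 0, frac_minus <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 utr5_len = utr5_len, cds_codons = cds_codons,
                 utr3_len = utr3_len, n_exons_range = n_exons_range,
                 base_probs = base_probs, embeddings = embeddings,
                 spike = spike, detection_prob = detection_prob,
                 frac_minus = frac_minus),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_embeddings <- function() {
  data.frame(
    region = c("FIVE_UTR", "CDS", "CDS", "THREE_UTR", "THREE_UTR", "CDS"),
    motif_class = c("CANONICAL", "TWO_QUARTET", "CANONICAL", "TWO_QUARTET",
                    "LONG_LOOP", "BULGE"),
    canonicality = c(4L, 0L, 4L, 2L, 4L, 3L),
    n = c(4L, 6L, 4L, 5L, 3L, 4L),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic transcriptome with embedded PQS truth
#'
#' Emits a genome, transcript annotation, rG4 call set and ground-truth
#' ledger consistent with each other: re-scanning the emitted sequence at
#' a planted locus recovers the planted motif class and canonicality
#' (15-nt G-free guard zones flank every embedding, so no candidate can
#' bridge into background sequence). CDS embeddings are placed on codon
#' boundaries through explicit codon recipes; codon-spike intervals sample
#' their codons at `factor` times the uniform baseline frequency.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `genome` (named chromosome sequences), `annotation`
#'   (GTF-style data frame), `models` (transcript models), `rg4_calls`
#'   (calls surviving detection subsampling), `truth` (all planted
#'   intervals incl. codon recipes) and `cfg`.
#' @export
make_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stable_seed(cfg$seed, "transcriptome"))
  emb <- cfg$embeddings[rep(seq_len(nrow(cfg$embeddings)), cfg$embeddings$n), ,
                        drop = FALSE]
  n_spike <- if (cfg$spike$n_motifs > 0L) cfg$spike$n_motifs else 0L
  plant_gene <- c(
    if (nrow(emb)) ((seq_len(nrow(emb)) - 1L) %% cfg$n_genes) + 1L,
    if (n_spike) ((seq_len(n_spike) - 1L) %% cfg$n_genes) + 1L)
  genome <- character(0)
  models <- list()
  ann <- list()
  truth <- list()
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%03d", g)
    tid <- sprintf("tx%03d", g)
    chrom <- sprintf("chr%03d", g)
    u5 <- sample(cfg$utr5_len[1]:cfg$utr5_len[2], 1)
    nc <- sample(cfg$cds_codons[1]:cfg$cds_codons[2], 1)
    u3 <- sample(cfg$utr3_len[1]:cfg$utr3_len[2], 1)
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, nc - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    chars <- strsplit(paste0(rand_seq(u5, cfg$base_probs), cds,
                             rand_seq(u3, cfg$base_probs)),
                      "", fixed = TRUE)[[1]]
    tlen <- length(chars)
    cds_span <- c(u5, u5 + 3L * nc)
    # ---- plant embeddings assigned to this gene ----
    gene_truth <- list()
    used <- matrix(numeric(0), ncol = 2)  # occupied [start,end) spans
    free_slot <- function(s, e) {
      s >= 0 && e <= tlen &&
        (nrow(used) == 0 || all(e + 18L <= used[, 1] | s - 18L >= used[, 2]))
    }
    which_emb <- which(plant_gene[seq_len(nrow(emb))] == g)
    for (k in which_emb) {
      region <- emb$region[k]
      cls <- emb$motif_class[k]
      can <- expected_canonicality(cls, emb$canonicality[k])
      if (region == "CDS") {
        motif <- pqs_motif_seq(cls, emb$canonicality[k], frame_mod3 = TRUE)
        mlen <- nchar(motif)
        ncod <- mlen %/% 3L
        ok <- FALSE
        for (try in 1:50) {
          ci <- sample(7:(nc - ncod - 7L), 1)
          s <- cds_span[1] + 3L * ci
          if (free_slot(s - 15L, s + mlen + 15L)) { ok <- TRUE; break }
        }
        if (!ok) next
        e <- s + mlen
        # guard codons (G-free) around the recipe
        gl <- sample(GUARD_CODONS, 5, replace = TRUE)
        gr <- sample(GUARD_CODONS, 5, replace = TRUE)
        chars[(s - 14L):s] <- strsplit(paste(gl, collapse = ""), "")[[1]]
        chars[(s + 1L):e] <- strsplit(motif, "")[[1]]
        chars[(e + 1L):(e + 15L)] <- strsplit(paste(gr, collapse = ""), "")[[1]]
        codons <- substring(motif, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
        recipe <- paste(codons, collapse = ",")
      } else {
        motif <- pqs_motif_seq(cls, emb$canonicality[k])
        mlen <- nchar(motif)
        rng <- if (region == "FIVE_UTR") c(0L, cds_span[1])
               else c(cds_span[2], tlen)
        if (rng[2] - rng[1] < mlen + 36L) next
        ok <- FALSE
        for (try in 1:50) {
          s <- sample((rng[1] + 16L):(rng[2] - mlen - 16L), 1)
          if (free_slot(s - 15L, s + mlen + 15L)) { ok <- TRUE; break }
        }
        if (!ok) next
        e <- s + mlen
        chars <- degquard(chars, s - 15L, s)
        chars[(s + 1L):e] <- strsplit(motif, "")[[1]]
        chars <- degquard(chars, e, e + 15L)
        recipe <- NA_character_
      }
      used <- rbind(used, c(s, e))
      gene_truth[[length(gene_truth) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, region = region,
        t_start = s, t_end = e, motif_class = cls, canonicality = can,
        kind = "pqs", codons = recipe, stringsAsFactors = FALSE)
    }
    # ---- codon-spike interval (at most one per gene) ----
    spike_idx <- which(plant_gene[nrow(emb) + seq_len(n_spike)] == g)
    if (length(spike_idx) >= 1L) {
      mcod <- cfg$spike$motif_codons
      p_target <- min(1, cfg$spike$factor / length(SENSE_CODONS))
      others <- setdiff(SENSE_CODONS, cfg$spike$codon)
      draw <- function() {
        if (runif(1) < p_target) cfg$spike$codon else sample(others, 1)
      }
      for (try in 1:50) {
        ci <- sample(7:(nc - mcod - 7L), 1)
        s <- cds_span[1] + 3L * ci
        if (free_slot(s, s + 3L * mcod)) break
      }
      e <- s + 3L * mcod
      codons <- replicate(mcod, draw())
      chars[(s + 1L):e] <- strsplit(paste(codons, collapse = ""), "")[[1]]
      used <- rbind(used, c(s, e))
      gene_truth[[length(gene_truth) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, region = "CDS",
        t_start = s, t_end = e, motif_class = "SPIKE",
        canonicality = NA_integer_, kind = "codon_spike",
        codons = paste(codons, collapse = ","), stringsAsFactors = FALSE)
    }
    # ---- exon structure (cuts avoid planted spans) ----
    n_ex <- sample(cfg$n_exons_range[1]:cfg$n_exons_range[2], 1)
    cuts <- integer(0)
    if (n_ex > 1L) {
      forb <- used
      cand <- setdiff(30:(tlen - 30L), unlist(lapply(seq_len(nrow(forb)),
        function(i) seq.int(forb[i, 1] - 1L, forb[i, 2] + 1L))))
      cand <- cand[c(TRUE, diff(cand) > 0)]
      if (length(cand) >= n_ex - 1L) {
        cuts <- sort(sample(cand, n_ex - 1L))
        cuts <- cuts[c(TRUE, diff(cuts) >= 25L)]
      }
    }
    strand <- if (runif(1) < cfg$frac_minus) "-" else "+"
    bounds <- c(0L, cuts, tlen)
    widths <- diff(bounds)
    introns <- if (length(widths) > 1L)
      sample(40:120, length(widths) - 1L, replace = TRUE) else integer(0)
    pad <- 50L
    tx_seq <- paste(chars, collapse = "")
    pieces <- substring(tx_seq, bounds[-length(bounds)] + 1L, bounds[-1])
    if (strand == "-") pieces_g <- rev(revcomp(pieces)) else pieces_g <- pieces
    gseq_parts <- character(0)
    exon_g <- data.frame(start = integer(0), end = integer(0))
    pos <- pad
    for (x in seq_along(pieces_g)) {
      exon_g <- rbind(exon_g,
                      data.frame(start = pos, end = pos + nchar(pieces_g[x])))
      gseq_parts <- c(gseq_parts, pieces_g[x])
      pos <- pos + nchar(pieces_g[x])
      if (x < length(pieces_g)) {
        il <- introns[x]
        gseq_parts <- c(gseq_parts, rand_seq(il, cfg$base_probs))
        pos <- pos + il
      }
    }
    gseq <- paste0(rand_seq(pad, cfg$base_probs),
                   paste(gseq_parts, collapse = ""),
                   rand_seq(pad, cfg$base_probs))
    genome[chrom] <- gseq
    m <- transcript_model(tid, gid, chrom, strand, exon_g, tx_seq,
                          cds_span = cds_span)
    models[[tid]] <- m
    ex_rows <- data.frame(chrom = chrom, feature = "exon",
                          start = m$exons$start[order(m$exons$start)],
                          end = m$exons$end[order(m$exons$start)],
                          strand = strand, transcript_id = tid, gene_id = gid,
                          stringsAsFactors = FALSE)
    cds_blocks <- transcript_to_genomic(m, cds_span)
    cds_rows <- data.frame(chrom = chrom, feature = "CDS",
                           start = cds_blocks$start, end = cds_blocks$end,
                           strand = strand, transcript_id = tid, gene_id = gid,
                           stringsAsFactors = FALSE)
    ann[[length(ann) + 1L]] <- rbind(ex_rows, cds_rows)
    if (length(gene_truth)) truth[[length(truth) + 1L]] <-
      do.call(rbind, gene_truth)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               region = character(0), t_start = integer(0),
               t_end = integer(0), motif_class = character(0),
               canonicality = integer(0), kind = character(0),
               codons = character(0), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  if (nrow(truth)) truth$name <- sprintf("rg4_%04d", seq_len(nrow(truth)))
  # genomic footprint of each planted interval
  calls <- truth
  if (nrow(calls)) {
    gcoord <- lapply(seq_len(nrow(calls)), function(i) {
      b <- transcript_to_genomic(models[[calls$transcript_id[i]]],
                                 c(calls$t_start[i], calls$t_end[i]))
      data.frame(chrom = b$chrom[1], start = min(b$start), end = max(b$end),
                 strand = b$strand[1], stringsAsFactors = FALSE)
    })
    calls <- cbind(calls, do.call(rbind, gcoord))
    keep <- runif(nrow(calls)) < cfg$detection_prob
    calls <- calls[keep, , drop = FALSE]
  }
  rownames(calls) <- NULL
  list(genome = genome, annotation = do.call(rbind, ann), models = models,
       rg4_calls = calls, truth = truth, cfg = cfg)
}

#' Write a synthetic transcriptome bundle to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `rg4_calls.bed` (name = motif
#' class, score = canonicality), `rg4_calls.tsv` (full call table) and
#' `truth.tsv`.
#'
#' @param tx result of [make_transcriptome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_transcriptome <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(tx$genome, file.path(dir, "genome.fa"))
  write_gtf(tx$annotation, file.path(dir, "annotation.gtf"))
  calls <- tx$rg4_calls
  if (nrow(calls)) {
    bed <- data.frame(chrom = calls$chrom, start = calls$start,
                      end = calls$end, name = calls$motif_class,
                      score = ifelse(is.na(calls$canonicality), 0L,
                                     calls$canonicality),
                      strand = calls$strand)
    write_bed(bed, file.path(dir, "rg4_calls.bed"))
  }
  write_tsv_table(calls, file.path(dir, "rg4_calls.tsv"))
  write_tsv_table(tx$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Simulate a multiple alignment of an rG4 window along a tree
#'
#' Evolves a root window (background sequence with a planted PQS at the
#' center) down a phylogeny by per-site independent substitutions (uniform
#' choice among the three alternative bases, so expected identity across
#' one branch of probability `p` is exactly `1 - p`) and optional
#' single-base deletions (never inside the planted motif by default). The
#' first tip is the reference species; alignment columns whose reference
#' state was deleted are dropped so the emitted MAF reference row is
#' gap-free.
#'
#' @param newick tree with branch lengths (time units).
#' @param seed RNG seed.
#' @param window_len total root window length (motif centered).
#' @param motif_class,canonicality planted motif spec.
#' @param sub_rate per-site substitution probability per unit branch
#'   length (branch probability = `min(1, sub_rate * length)`).
#' @param sub_probs optional explicit per-branch substitution
#'   probabilities (ordered as `tree$edge` rows), overriding `sub_rate`.
#' @param del_rate per-site single-base deletion probability per unit
#'   branch length (applied outside the motif unless
#'   `protect_motif = FALSE`).
#' @param protect_motif keep the planted motif free of deletions.
#' @param n_blocks number of MAF blocks to split the window into.
#' @param chrom chromosome name used in MAF `src` fields.
#' @return list with `maf` (block list), `tree` (`phylo`), `alignment`
#'   (species x column matrix incl. the root), `rg4` (reference
#'   coordinates of the planted motif, BED-style data frame) and `truth`
#'   (root sequence, per-species motif identity, per-branch probabilities).
#' @export
make_alignment <- function(newick, seed = 1L, window_len = 101L,
                           motif_class = "CANONICAL", canonicality = 4L,
                           sub_rate = 0, sub_probs = NULL, del_rate = 0,
                           protect_motif = TRUE, n_blocks = 1L,
                           chrom = "chr1") {
  set.seed(stable_seed(seed, "alignment"))
  tree <- if (inherits(newick, "phylo")) newick else
    ape::read.tree(text = newick)
  stopifnot(!is.null(tree$edge.length))
  motif <- pqs_motif_seq(motif_class, canonicality)
  mlen <- nchar(motif)
  stopifnot(window_len >= mlen + 2L)
  flank <- (window_len - mlen) %/% 2L
  root_chars <- strsplit(paste0(rand_seq(flank), motif,
                                rand_seq(window_len - mlen - flank)),
                         "", fixed = TRUE)[[1]]
  root_chars <- degquard(root_chars, 0L, flank)
  root_chars <- degquard(root_chars, flank + mlen, window_len)
  motif_cols <- seq.int(flank + 1L, flank + mlen)
  n_tip <- length(tree$tip.label)
  if (is.null(sub_probs)) {
    sub_probs <- pmin(1, sub_rate * tree$edge.length)
  }
  stopifnot(length(sub_probs) == nrow(tree$edge))
  del_probs <- pmin(1, del_rate * tree$edge.length)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- root_chars
  bases <- c("A", "C", "G", "T")
  # parents precede children in tree$edge after cladewise reorder
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  ord <- match(paste(edge[, 1], edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (r in seq_len(nrow(edge))) {
    par <- edge[r, 1]; child <- edge[r, 2]
    p <- sub_probs[ord[r]]
    pd <- del_probs[ord[r]]
    s <- seqs[[par]]
    live <- which(s != "-")
    mut <- live[runif(length(live)) < p]
    for (i in mut) s[i] <- sample(setdiff(bases, s[i]), 1)
    if (pd > 0) {
      cand <- live
      if (protect_motif) cand <- setdiff(cand, motif_cols)
      del <- cand[runif(length(cand)) < pd]
      s[del] <- "-"
    }
    seqs[[child]] <- s
  }
  aln <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(aln) <- tree$tip.label
  ref <- tree$tip.label[1]
  keep_cols <- which(aln[ref, ] != "-")
  aln <- aln[, keep_cols, drop = FALSE]
  root_kept <- root_chars[keep_cols]
  motif_cols_kept <- which(keep_cols %in% motif_cols)
  # reference coordinates: column j is reference position j-1
  m_start <- min(motif_cols_kept) - 1L
  m_end <- max(motif_cols_kept)
  # split into MAF blocks
  ncols <- ncol(aln)
  brk <- unique(round(seq(0, ncols, length.out = n_blocks + 1L)))
  blocks <- list()
  offsets <- setNames(rep(0L, n_tip), tree$tip.label)
  for (b in seq_len(length(brk) - 1L)) {
    cols <- seq.int(brk[b] + 1L, brk[b + 1L])
    rows <- list()
    for (sp in tree$tip.label) {
      txt <- paste(aln[sp, cols], collapse = "")
      size <- sum(aln[sp, cols] != "-")
      rows[[length(rows) + 1L]] <- data.frame(
        src = paste0(sp, ".", chrom), start = offsets[[sp]], size = size,
        strand = "+", src_size = sum(aln[sp, ] != "-"), text = txt,
        stringsAsFactors = FALSE)
      offsets[[sp]] <- offsets[[sp]] + size
    }
    blocks[[b]] <- do.call(rbind, rows)
  }
  identity_truth <- vapply(tree$tip.label, function(sp) {
    sum(aln[sp, motif_cols_kept] == root_chars[keep_cols][motif_cols_kept] &
          aln[sp, motif_cols_kept] != "-") / mlen
  }, numeric(1))
  ref_identity <- vapply(tree$tip.label, function(sp) {
    sum(aln[sp, motif_cols_kept] == aln[ref, motif_cols_kept] &
          aln[sp, motif_cols_kept] != "-") / mlen
  }, numeric(1))
  rg4 <- data.frame(name = "rg4_1", chrom = chrom, start = m_start,
                    end = m_end, strand = "+", stringsAsFactors = FALSE)
  list(maf = blocks, tree = tree, alignment = aln, rg4 = rg4,
       truth = list(root_seq = paste(root_kept, collapse = ""),
                    motif = motif, motif_class = motif_class,
                    canonicality = expected_canonicality(motif_class,
                                                         canonicality),
                    identity_vs_root = identity_truth,
                    identity_vs_ref = ref_identity,
                    sub_probs = sub_probs, ref = ref))
}

#' Write a synthetic alignment bundle to disk
#'
#' @param al result of [make_alignment()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_alignment <- function(al, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(al$maf, file.path(dir, "alignment.maf"))
  ape::write.tree(al$tree, file.path(dir, "tree.nwk"))
  write_bed(al$rg4, file.path(dir, "rg4.bed"))
  write_tsv_table(data.frame(species = names(al$truth$identity_vs_ref),
                             identity_vs_ref = al$truth$identity_vs_ref),
                  file.path(dir, "identity_truth.tsv"))
  invisible(dir)
}

#' Generate synthetic gene families over a dated tree
#'
#' Families are assigned whole clades as species sets (so their LCA age is
#' the clade node age by construction) and planted with an age-dependent
#' rG4-harboring probability; a configurable fraction of families carry
#' ohnolog genes with a boosted harboring rate.
#'
#' @param newick dated ultrametric tree.
#' @param clade_config named list (innermost clade first) mapping labels to
#'   species sets; families are drawn uniformly over these clades.
#' @param n_families number of families.
#' @param harbor_prob named numeric vector (by clade label) of harboring
#'   probabilities.
#' @param ohnolog_frac fraction of families whose genes are ohnologs.
#' @param ohnolog_boost multiplicative harboring boost for ohnolog
#'   families (capped at probability 1).
#' @param seed RNG seed.
#' @return list with `families` (long data frame), `family_truth`,
#'   `rg4_genes` (character vector), `ohnolog_genes`, `dtree`,
#'   `clade_config`.
#' @export
make_families <- function(newick, clade_config, n_families = 100L,
                          harbor_prob = NULL, ohnolog_frac = 0.2,
                          ohnolog_boost = 2, seed = 1L) {
  set.seed(stable_seed(seed, "families"))
  dtree <- read_dated_tree(if (inherits(newick, "phylo")) newick else
    ape::read.tree(text = newick))
  labels <- names(clade_config)
  if (is.null(harbor_prob)) {
    harbor_prob <- setNames(seq(0.2, 0.8, length.out = length(labels)), labels)
  }
  fams <- list(); truth <- list()
  rg4_genes <- character(0); ohno_genes <- character(0)
  for (f in seq_len(n_families)) {
    fid <- sprintf("fam%04d", f)
    lab <- sample(labels, 1)
    sp <- clade_config[[lab]]
    genes <- sprintf("%s_%s", fid, sp)
    is_ohno <- runif(1) < ohnolog_frac
    p <- harbor_prob[[lab]]
    if (is_ohno) p <- min(1, p * ohnolog_boost)
    harb <- runif(1) < p
    if (harb) rg4_genes <- c(rg4_genes, sample(genes, 1))
    if (is_ohno) ohno_genes <- c(ohno_genes, genes[1])
    fams[[f]] <- data.frame(family_id = fid, species = sp, gene_id = genes,
                            stringsAsFactors = FALSE)
    truth[[f]] <- data.frame(family_id = fid, clade_label = lab,
                             harboring = harb, ohnolog = is_ohno,
                             harbor_prob = p, stringsAsFactors = FALSE)
  }
  list(families = do.call(rbind, fams),
       family_truth = do.call(rbind, truth),
       rg4_genes = rg4_genes, ohnolog_genes = ohno_genes,
       dtree = dtree, clade_config = clade_config)
}

#' Write a synthetic gene-family bundle to disk
#'
#' @param fm result of [make_families()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_families <- function(fm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(fm$families, file.path(dir, "families.tsv"))
  write_tsv_table(data.frame(gene_id = fm$ohnolog_genes),
                  file.path(dir, "ohnologs.tsv"))
  ape::write.tree(fm$dtree$tree, file.path(dir, "species_tree.nwk"))
  write_tsv_table(fm$family_truth, file.path(dir, "family_truth.tsv"))
  write_tsv_table(data.frame(gene_id = fm$rg4_genes),
                  file.path(dir, "rg4_genes.tsv"))
  invisible(dir)
}

#' Generate feature tracks with planted overlaps for a synthetic transcriptome
#'
#' Plants repetitive-element intervals and peptide LCRs over a sample of
#' the CDS calls, and microRNA seed sites at controlled distances from the
#' 3' UTR calls, recording for every planted feature whether it should be
#' reported by the corresponding overlap operator.
#'
#' @param tx result of [make_transcriptome()].
#' @param re_prob,lcr_prob per-call planting probabilities.
#' @param mir_offsets gaps (nt) between each 3' UTR call's genomic end and
#'   a planted seed start; offsets < 10 fall inside the +/- 10 nt window,
#'   larger ones outside.
#' @param seed RNG seed.
#' @return list with `re` (BED-style data frame, `name` = repeat label),
#'   `lcr` (`protein_id`, `start`, `end`, `aa_set`), `mir` (BED-style) and
#'   `truth` (planted pairs with the expected overlap verdict).
#' @export
make_feature_tracks <- function(tx, re_prob = 0.6, lcr_prob = 0.6,
                                mir_offsets = c(4L, 15L), seed = 1L) {
  set.seed(stable_seed(seed, "features"))
  re <- list(); lcr <- list(); mir <- list(); truth <- list()
  calls <- tx$rg4_calls[tx$rg4_calls$kind == "pqs", , drop = FALSE]
  re_labels <- c("(TCC)n", "(GGA)n", "GA-rich", "(CCG)n")
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    m <- tx$models[[cl$transcript_id]]
    if (cl$region == "CDS") {
      if (runif(1) < re_prob) {
        s <- cl$start + 2L
        re[[length(re) + 1L]] <- data.frame(
          chrom = cl$chrom, start = s, end = s + 9L,
          name = sample(re_labels, 1), stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          rg4_id = cl$name, kind = "RE", expected = TRUE)
      }
      if (runif(1) < lcr_prob) {
        p_lo <- (cl$t_start - m$cds_span[1]) %/% 3L
        p_hi <- (cl$t_end - 1L - m$cds_span[1]) %/% 3L + 1L
        ks <- seq.int(p_lo, p_hi - 1L)
        res <- translate_codon(substring(cds_sequence(m), 3L * ks + 1L,
                                         3L * ks + 3L))
        lcr[[length(lcr) + 1L]] <- data.frame(
          protein_id = cl$transcript_id, start = p_lo, end = p_hi,
          aa_set = paste(sort(unique(res)), collapse = ","),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          rg4_id = cl$name, kind = "LCR", expected = TRUE)
      }
    }
    if (cl$region == "THREE_UTR") {
      for (off in mir_offsets) {
        mir[[length(mir) + 1L]] <- data.frame(
          chrom = cl$chrom, start = cl$end + off, end = cl$end + off + 7L,
          name = sprintf("miR_%s_%d", cl$name, off), stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          rg4_id = cl$name, kind = "MIR_SEED", expected = off < 10L)
      }
    }
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(re = bind(re, data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), name = character(0))),
       lcr = bind(lcr, data.frame(protein_id = character(0),
                                  start = integer(0), end = integer(0),
                                  aa_set = character(0))),
       mir = bind(mir, data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0), name = character(0))),
       truth = bind(truth, data.frame(rg4_id = character(0),
                                      kind = character(0),
                                      expected = logical(0))))
}
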