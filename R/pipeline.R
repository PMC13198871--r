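#' Tabulate rG4 counts by gene region and canonicality
#'
#' The region x canonicality count matrix (regions as rows, canonicality
#' classes 0--4 as columns) that summarizes an rG4 call set; every record
#' is counted exactly once, so the margins equal the input count.
#'
#' @param rg4s data frame with `region` (in [region_levels()]) and
#'   `canonicality` (0--4).
#' @return 4 x 5 integer matrix.
#' @examples
#' tabulate_canonicality(data.frame(region = c("FIVE_UTR", "CDS", "CDS"),
#'                                  canonicality = c(4, 0, 0)))
#' @export
tabulate_canonicality <- function(rg4s) {
  stopifnot(all(rg4s$region %in% region_levels()),
            all(rg4s$canonicality %in% 0:4))
  tab <- table(factor(rg4s$region, levels = region_levels()),
               factor(rg4s$canonicality, levels = 0:4))
  m <- matrix(as.integer(tab), nrow = 4L,
              dimnames = list(region = region_levels(),
                              canonicality = as.character(0:4)))
  m
}

#' Merge per-sample rG4 call sets with a replicate-consensus filter
#'
#' Calls from multiple detection sets are clustered by genomic overlap;
#' each cluster keeps the union span, and only clusters supported by at
#' least `min_sets` distinct detection sets are retained (the
#' replicate-consensus rule that separates genuine rG4s from single-set
#' detections).
#'
#' @param call_sets list of data frames (`chrom`, `start`, `end`, 0-based
#'   half-open), one per detection set.
#' @param min_sets minimum number of supporting sets (default 2).
#' @return data frame of merged calls: `chrom`, `start`, `end`, `n_sets`.
#' @export
merge_rg4_calls <- function(call_sets, min_sets = 2L) {
  stopifnot(length(call_sets) >= 1L)
  all_df <- do.call(rbind, lapply(seq_along(call_sets), function(i) {
    d <- call_sets[[i]][, c("chrom", "start", "end")]
    d$set <- i
    d
  }))
  gr <- GenomicRanges::GRanges(all_df$chrom,
                               IRanges::IRanges(all_df$start + 1L, all_df$end))
  merged <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(merged, gr)
  nsets <- vapply(seq_along(merged), function(i) {
    length(unique(all_df$set[S4Vectors::subjectHits(ov)[
      S4Vectors::queryHits(ov) == i]]))
  }, integer(1))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged),
                    n_sets = nsets, stringsAsFactors = FALSE)
  out[out$n_sets >= min_sets, , drop = FALSE]
}

#' Pipeline configuration
#'
#' Validates input paths before any computation starts; a missing path is
#' a configuration error, not a mid-run failure.
#'
#' @param annotation,genome,rg4_calls required input paths (GTF, FASTA, and
#'   a call table: a `.tsv` with `transcript_id`, `t_start`, `t_end` or a
#'   genomic `.bed`).
#' @param out_dir output directory (created at run time).
#' @param params a [scan_params()].
#' @param re_bed,lcr_tsv,mir_bed optional feature tracks.
#' @param maf,tree optional whole-genome alignment and dated tree for
#'   conservation/ancestral stages; `ref_species` names the MAF reference.
#' @param families,ohnologs optional gene-family inputs.
#' @param clades optional named list of clade species sets (innermost
#'   first) shared by the conservation and family stages.
#' @param clade_ages optional named numeric vector of clade ages (MYA).
#' @param drift_nodes named list of clade species sets at which ancestral
#'   reconstruction is run (e.g. `list(Mammalia = ...)`).
#' @param seed seed recorded in the manifest.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(annotation, genome, rg4_calls, out_dir,
                            params = scan_params(), re_bed = NULL,
                            lcr_tsv = NULL, mir_bed = NULL, maf = NULL,
                            tree = NULL, families = NULL, ohnologs = NULL,
                            clades = NULL, clade_ages = NULL,
                            drift_nodes = NULL, ref_species = NULL,
                            seed = 1L) {
  paths <- c(annotation = annotation, genome = genome, rg4_calls = rg4_calls,
             re_bed = re_bed, lcr_tsv = lcr_tsv, mir_bed = mir_bed,
             maf = maf, tree = tree, families = families,
             ohnologs = ohnologs)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("pipeline config error, missing input file(s): ",
         paste(sprintf("%s (%s)", names(missing), missing), collapse = ", "))
  }
  structure(list(annotation = annotation, genome = genome,
                 rg4_calls = rg4_calls, out_dir = out_dir, params = params,
                 re_bed = re_bed, lcr_tsv = lcr_tsv, mir_bed = mir_bed,
                 maf = maf, tree = tree, families = families,
                 ohnologs = ohnologs, clades = clades,
                 clade_ages = clade_ages, drift_nodes = drift_nodes,
                 ref_species = ref_species, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Characterize one call interval by scanning its transcript subsequence.
characterize_call <- function(m, t_start, t_end, params) {
  sub <- substring(m$sequence, t_start + 1L, t_end)
  hits <- scan_pqs(sub, params)
  if (nrow(hits) == 0L) return(NULL)
  h <- hits[1L, , drop = FALSE]
  h$start <- h$start + t_start
  h$end <- h$end + t_start
  h$tract_starts[[1]] <- h$tract_starts[[1]] + t_start
  h
}

#' Run the full rG4 evolutionary analysis pipeline
#'
#' Orchestrates all stages available from the configured inputs: loading
#' the annotation, characterizing calls (motif class, canonicality,
#' region), the region x canonicality tabulation, codon analyses, feature
#' overlaps, gene-family aging, whole-genome-alignment conservation and
#' ancestral canonicality drift. Writes one TSV per table to `out_dir`
#' plus a machine-readable `manifest.json` (package version, parameters,
#' input/output MD5 hashes): identical inputs and configuration produce
#' identical outputs and hashes.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list of all result tables (also written to
#'   `cfg$out_dir`).
#' @export
run_rg4_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- "annotation"
  tryCatch({
    models <- load_annotation(cfg$annotation, cfg$genome)
    res$transcripts <- transcript_table(models)

    stage <- "rg4_calls"
    calls <- if (grepl("\\.bed$", cfg$rg4_calls)) {
      bed <- read_bed(cfg$rg4_calls)
      mapped <- lapply(seq_len(nrow(bed)), function(i) {
        for (m in models) {
          if (m$chrom != bed$chrom[i]) next
          tiv <- genomic_to_transcript(m, c(bed$start[i], bed$end[i]))
          if (!is.null(tiv)) {
            return(data.frame(transcript_id = m$transcript_id,
                              t_start = tiv[1], t_end = tiv[2],
                              name = if (!is.null(bed$name)) bed$name[i]
                                     else sprintf("rg4_%04d", i),
                              stringsAsFactors = FALSE))
          }
        }
        NULL
      })
      do.call(rbind, Filter(Negate(is.null), mapped))
    } else {
      read_tsv_table(cfg$rg4_calls)
    }
    if (is.null(calls$name)) calls$name <- sprintf("rg4_%04d", seq_len(nrow(calls)))

    stage <- "characterization"
    chr_rows <- list()
    for (i in seq_len(nrow(calls))) {
      m <- models[[calls$transcript_id[i]]]
      if (is.null(m)) next
      h <- characterize_call(m, calls$t_start[i], calls$t_end[i], cfg$params)
      region <- assign_region(m, c(calls$t_start[i], calls$t_end[i]))
      chr_rows[[length(chr_rows) + 1L]] <- data.frame(
        rg4_id = calls$name[i], transcript_id = calls$transcript_id[i],
        gene_id = m$gene_id, t_start = calls$t_start[i],
        t_end = calls$t_end[i], region = region,
        motif_class = if (is.null(h)) NA_character_ else h$motif_class,
        canonicality = if (is.null(h)) NA_integer_ else h$canonicality,
        group = if (is.null(h)) NA_character_ else h$group,
        stringsAsFactors = FALSE)
    }
    rg4s <- do.call(rbind, chr_rows)
    res$rg4s <- rg4s

    stage <- "tabulation"
    scanned <- rg4s[!is.na(rg4s$canonicality), , drop = FALSE]
    res$canonicality_matrix <- tabulate_canonicality(scanned)
    res$class_distribution <- as.data.frame(
      table(motif_class = scanned$motif_class, region = scanned$region),
      stringsAsFactors = FALSE)
    res$group_distribution <- as.data.frame(
      table(group = scanned$group, region = scanned$region),
      stringsAsFactors = FALSE)

    stage <- "codon_analysis"
    cds_calls <- scanned[scanned$region == "CDS", , drop = FALSE]
    if (nrow(cds_calls)) {
      chits <- list()
      for (i in seq_len(nrow(cds_calls))) {
        m <- models[[cds_calls$transcript_id[i]]]
        h <- characterize_call(m, cds_calls$t_start[i], cds_calls$t_end[i],
                               cfg$params)
        if (!is.null(h)) {
          h$transcript_id <- cds_calls$transcript_id[i]
          chits[[length(chits) + 1L]] <- h
        }
      }
      if (length(chits)) {
        chits <- do.call(rbind, chits)
        enr_hits <- data.frame(transcript_id = chits$transcript_id,
                               start = chits$start, end = chits$end)
        res$codon_enrichment <- codon_enrichment(enr_hits, models)
        res$tract_spans <- tract_codon_spans(chits, models)
        res$tract_aa <- tract_aa_usage(chits, models)
      }
    }

    stage <- "feature_overlap"
    genomic_calls <- NULL
    if (!is.null(cfg$re_bed) || !is.null(cfg$mir_bed)) {
      gc <- lapply(seq_len(nrow(rg4s)), function(i) {
        m <- models[[rg4s$transcript_id[i]]]
        b <- transcript_to_genomic(m, c(rg4s$t_start[i], rg4s$t_end[i]))
        data.frame(name = rg4s$rg4_id[i], chrom = b$chrom[1],
                   start = min(b$start), end = max(b$end),
                   region = rg4s$region[i], stringsAsFactors = FALSE)
      })
      genomic_calls <- do.call(rbind, gc)
    }
    if (!is.null(cfg$re_bed)) {
      re <- read_bed(cfg$re_bed)
      re$kind <- "RE"
      re$label <- if (!is.null(re$name)) re$name else NA_character_
      res$re_overlap <- overlap_genomic(genomic_calls, re)
    }
    if (!is.null(cfg$lcr_tsv)) {
      lcrs <- read_tsv_table(cfg$lcr_tsv)
      lhits <- data.frame(transcript_id = rg4s$transcript_id,
                          start = rg4s$t_start, end = rg4s$t_end,
                          name = rg4s$rg4_id)
      lhits <- lhits[rg4s$region == "CDS", , drop = FALSE]
      res$lcr_overlap <- suppressMessages(overlap_lcr(lhits, lcrs, models))
      if (!is.null(res$re_overlap)) {
        cds_ids <- rg4s$rg4_id[rg4s$region == "CDS"]
        res$re_lcr_partition <- as.data.frame(as.list(
          re_lcr_partition(cds_ids, res$re_overlap, res$lcr_overlap)))
      }
    }
    if (!is.null(cfg$mir_bed)) {
      seeds <- read_bed(cfg$mir_bed)
      seeds$label <- if (!is.null(seeds$name)) seeds$name else NA_character_
      utr3 <- genomic_calls[genomic_calls$region == "THREE_UTR", , drop = FALSE]
      res$mir_overlap <- overlap_mir_seed(utr3, seeds)
    }
    res$splice_overlap <- overlap_splice_junction(
      data.frame(transcript_id = rg4s$transcript_id, start = rg4s$t_start,
                 end = rg4s$t_end, name = rg4s$rg4_id), models)

    stage <- "gene_family_age"
    if (!is.null(cfg$families) && !is.null(cfg$tree) && !is.null(cfg$clades)) {
      fams <- read_gene_families(cfg$families)
      dtree <- read_dated_tree(cfg$tree)
      fa <- assign_family_ages(fams, dtree, cfg$clades)
      res$family_ages <- fa
      rg4_genes <- data.frame(gene_id = rg4s$gene_id, region = rg4s$region)
      res$harboring <- harboring_fraction(fams, fa, rg4_genes)
      if (!is.null(cfg$ohnologs)) {
        res$ohnolog_contrast <- ohnolog_contrast(fams, rg4_genes,
                                                 read_ohnologs(cfg$ohnologs))
      }
    }

    stage <- "conservation"
    if (!is.null(cfg$maf) && !is.null(cfg$ref_species)) {
      gcalls <- genomic_calls
      if (is.null(gcalls)) {
        gc <- lapply(seq_len(nrow(rg4s)), function(i) {
          m <- models[[rg4s$transcript_id[i]]]
          b <- transcript_to_genomic(m, c(rg4s$t_start[i], rg4s$t_end[i]))
          data.frame(name = rg4s$rg4_id[i], chrom = b$chrom[1],
                     start = min(b$start), end = max(b$end),
                     strand = b$strand[1], region = rg4s$region[i],
                     stringsAsFactors = FALSE)
        })
        gcalls <- do.call(rbind, gc)
      }
      windows <- extract_windows(cfg$maf, gcalls, cfg$ref_species)
      records <- conservation_records(windows, cfg$params)
      res$conservation_records <- records
      res$average_identity <- average_identity(records, cfg$ref_species)
      if (!is.null(cfg$clades)) {
        scheme <- clade_scheme(cfg$clades, cfg$clade_ages)
        res$clade_summary <- clade_summary(records, scheme)
      }
      stage <- "ancestral"
      if (!is.null(cfg$drift_nodes) && !is.null(cfg$tree)) {
        dtree <- read_dated_tree(cfg$tree)
        meta <- data.frame(rg4_id = rg4s$rg4_id, region = rg4s$region,
                           canonicality = rg4s$canonicality)
        meta <- meta[!is.na(meta$canonicality), , drop = FALSE]
        wuse <- Filter(function(w) w$rg4_id %in% meta$rg4_id, windows)
        drifts <- lapply(names(cfg$drift_nodes), function(lab)
          drift_analysis(wuse, meta, dtree, cfg$drift_nodes[[lab]], lab,
                         cfg$params))
        res$drift <- do.call(rbind, drifts)
      }
    }
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  # ---- write outputs + manifest ----
  written <- character(0)
  for (nm in names(res)) {
    obj <- res[[nm]]
    path <- file.path(cfg$out_dir, paste0(nm, ".tsv"))
    if (is.matrix(obj)) {
      df <- as.data.frame(obj)
      df <- cbind(region = rownames(obj), df)
      write_tsv_table(df, path)
    } else if (is.data.frame(obj)) {
      flat <- obj[, !vapply(obj, is.list, logical(1)), drop = FALSE]
      write_tsv_table(flat, path)
    } else next
    written <- c(written, path)
  }
  inputs <- Filter(Negate(is.null),
                   cfg[c("annotation", "genome", "rg4_calls", "re_bed",
                         "lcr_tsv", "mir_bed", "maf", "tree", "families",
                         "ohnologs")])
  manifest <- list(
    package = "rg4evo",
    version = as.character(utils::packageVersion("rg4evo")),
    seed = cfg$seed,
    params = cfg$params[c("canonical_loop", "long_loop_max",
                          "two_quartet_loop", "report_mode")],
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
    outputs = setNames(as.list(unname(tools::md5sum(written))),
                       basename(written)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
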