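# Fitch small-parsimony over the 5-letter alphabet {A,C,G,T,-}, encoded as
# bitmasks. Any other character (N, ambiguity) is treated as a gap.
FITCH_STATES <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 16L)

fitch_encode <- function(chars) {
  m <- FITCH_STATES[toupper(chars)]
  m[is.na(m)] <- FITCH_STATES[["-"]]
  unname(m)
}

# Bottom-up Fitch pass returning the root state SET (bitmask) for one
# column of tip states (named by tip label). `kids` may be supplied
# precomputed (split(tree$edge[,2], tree$edge[,1])) to avoid rebuilding it
# per column.
fitch_root_set <- function(tree, tip_masks, kids = NULL) {
  n_tip <- length(tree$tip.label)
  if (is.null(kids)) kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- integer(n_tip + tree$Nnode)
  sets[seq_len(n_tip)] <- tip_masks[tree$tip.label]
  rec <- function(node) {
    if (node <= n_tip) return(sets[node])
    cs <- vapply(kids[[as.character(node)]], rec, integer(1))
    inter <- Reduce(bitwAnd, cs)
    v <- if (inter != 0L) inter else Reduce(bitwOr, cs)
    sets[node] <<- v
    v
  }
  rec(n_tip + 1L)
}

# Deterministic tie-break: the reference base when in the set, else the
# first state in the fixed order A < C < G < T < -.
fitch_pick_state <- function(set_mask, ref_char = NA) {
  states <- names(FITCH_STATES)
  if (!is.na(ref_char)) {
    rm <- FITCH_STATES[toupper(ref_char)]
    if (!is.na(rm) && bitwAnd(set_mask, rm) != 0L) return(toupper(ref_char))
  }
  for (s in states) {
    if (bitwAnd(set_mask, FITCH_STATES[[s]]) != 0L) return(s)
  }
  "-"
}

#' Fitch parsimony reconstruction of an alignment's root sequence
#'
#' Per-column small parsimony over the alphabet \{A, C, G, T, gap\}: tip
#' state sets are intersected (or united when disjoint) bottom-up, and the
#' root set is resolved to a single state by preferring the reference base
#' when it is in the set, then the fixed order A < C < G < T < gap. Gaps
#' are a fifth character state during reconstruction and are removed from
#' the returned sequence.
#'
#' @param mat character matrix (rows = species incl. gaps `-`, columns =
#'   alignment columns).
#' @param tree rooted `phylo` whose tip labels are (a subset of) the row
#'   names of `mat`.
#' @param ref_chars optional character vector (one per column) used for
#'   tie-breaking, typically the reference row.
#' @return list with `states` (root state per column, incl. `-`), `seq`
#'   (gap-free root sequence) and `cols` (column index of each base of
#'   `seq`).
#' @export
fitch_reconstruct <- function(mat, tree, ref_chars = NULL) {
  stopifnot(all(tree$tip.label %in% rownames(mat)))
  ncols <- ncol(mat)
  if (is.null(ref_chars)) ref_chars <- rep(NA_character_, ncols)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  states <- character(ncols)
  for (j in seq_len(ncols)) {
    masks <- fitch_encode(mat[tree$tip.label, j])
    names(masks) <- tree$tip.label
    states[j] <- fitch_pick_state(fitch_root_set(tree, masks, kids),
                                  ref_chars[j])
  }
  keep <- which(states != "-")
  list(states = states, seq = paste(states[keep], collapse = ""), cols = keep)
}

#' Reconstruct the ancestral window of an rG4 at a named clade
#'
#' Restricts the species tree to the clade's species that are aligned in
#' the window, then runs [fitch_reconstruct()] on the window columns. At
#' least two aligned clade species are required; otherwise no
#' reconstruction is produced and the window is flagged.
#'
#' @param w a window object from [extract_windows()].
#' @param dtree a [read_dated_tree()] object (tip labels = species).
#' @param clade_species species belonging to the target clade.
#' @param node_label label stored on the result (e.g. `"Mammalia"`).
#' @return list of class `"AncestralWindow"` with `rg4_id`, `node_label`,
#'   `seq` (gap-free ancestral sequence), `cols` (window column of each
#'   base), `n_species`; or `NULL` when fewer than two clade species are
#'   aligned.
#' @export
reconstruct_ancestral_window <- function(w, dtree, clade_species, node_label) {
  if (is.null(w$mat)) return(NULL)
  aligned_sp <- rownames(w$mat)[apply(w$mat != "-", 1, any)]
  use <- intersect(intersect(clade_species, aligned_sp), dtree$tree$tip.label)
  if (length(use) < 2L) return(NULL)
  sub <- ape::keep.tip(dtree$tree, use)
  ref_chars <- w$mat[w$ref_species, ]
  fr <- fitch_reconstruct(w$mat[use, , drop = FALSE], sub, ref_chars)
  structure(list(rg4_id = w$rg4_id, node_label = node_label,
                 seq = fr$seq, cols = fr$cols, n_species = length(use),
                 strand = w$strand, motif_cols = which(w$motif_cols)),
            class = "AncestralWindow")
}

#' PQS on an ancestral window, matched to the modern motif
#'
#' Scans the reconstructed ancestral sequence and selects, among the hits,
#' the one whose alignment columns overlap the modern motif's columns the
#' most; ties go to the higher canonicality, then the leftmost hit.
#'
#' @param aw an `AncestralWindow` from [reconstruct_ancestral_window()].
#' @param params [scan_params()].
#' @param modern_cols window column indices of the modern motif (defaults
#'   to `aw$motif_cols`).
#' @return one [scan_pqs()] row with an added `overlap_cols` column, or
#'   `NULL` when the ancestral window holds no PQS.
#' @export
ancestral_pqs <- function(aw, params = scan_params(), modern_cols = NULL) {
  stopifnot(inherits(aw, "AncestralWindow"))
  if (is.null(modern_cols)) modern_cols <- aw$motif_cols
  seqs <- if (aw$strand == "-") revcomp(aw$seq) else aw$seq
  hits <- scan_pqs(seqs, params)
  if (nrow(hits) == 0L) return(NULL)
  L <- nchar(aw$seq)
  ov <- vapply(seq_len(nrow(hits)), function(i) {
    # positions of the hit in the gap-free ancestral sequence, mapped back
    # to window columns (reverse orientation for minus-strand motifs)
    pos <- seq.int(hits$start[i] + 1L, hits$end[i])
    if (aw$strand == "-") pos <- L + 1L - pos
    length(intersect(aw$cols[pos], modern_cols))
  }, integer(1))
  best <- order(-ov, -hits$canonicality, hits$start)[1]
  out <- hits[best, , drop = FALSE]
  out$overlap_cols <- ov[best]
  rownames(out) <- NULL
  out
}

#' Classify canonicality drift between a modern rG4 and its ancestral PQS
#'
#' @param modern_canonicality integer 0--4 of the modern rG4.
#' @param ancestral_canonicality integer 0--4 of the matched ancestral PQS,
#'   or `NA` when the ancestral window lacks a PQS.
#' @return data frame with `modern_canonicality`, `ancestral_canonicality`
#'   and `drift` in `GAIN` (modern higher), `LOSS` (modern lower),
#'   `UNCHANGED`, `NO_ANCESTRAL_PQS`.
#' @examples
#' classify_drift(4, 2)$drift  # "GAIN"
#' classify_drift(0, 2)$drift  # "LOSS"
#' @export
classify_drift <- function(modern_canonicality, ancestral_canonicality) {
  stopifnot(length(modern_canonicality) == length(ancestral_canonicality))
  drift <- ifelse(is.na(ancestral_canonicality), "NO_ANCESTRAL_PQS",
           ifelse(modern_canonicality > ancestral_canonicality, "GAIN",
           ifelse(modern_canonicality < ancestral_canonicality, "LOSS",
                  "UNCHANGED")))
  data.frame(modern_canonicality = modern_canonicality,
             ancestral_canonicality = ancestral_canonicality,
             drift = drift, stringsAsFactors = FALSE)
}

#' Canonicality-drift analysis of a window set at a named clade
#'
#' Runs reconstruction, ancestral PQS matching and drift classification for
#' every window, producing the per-rG4 drift table summarized by region in
#' cohort views.
#'
#' @param windows list from [extract_windows()].
#' @param rg4_meta data frame with `rg4_id`, `region`, `canonicality`
#'   (modern values).
#' @param dtree a [read_dated_tree()] object.
#' @param clade_species species of the target clade.
#' @param node_label clade label (e.g. `"Tetrapoda"`).
#' @param params [scan_params()].
#' @param ancestral_seqs optional named character vector (by `rg4_id`) of
#'   externally reconstructed ancestral window sequences; when provided,
#'   these bypass the parsimony reconstruction (the external-ancestor input
#'   path) and hit-to-motif matching is by best-overlap on the plain
#'   sequence positions.
#' @return data frame per rG4: `rg4_id`, `node_label`, `region`,
#'   `modern_canonicality`, `ancestral_canonicality`, `drift`
#'   (`NO_RECONSTRUCTION` when fewer than two clade species align).
#' @export
drift_analysis <- function(windows, rg4_meta, dtree, clade_species,
                           node_label, params = scan_params(),
                           ancestral_seqs = NULL) {
  out <- list()
  for (w in windows) {
    meta <- rg4_meta[rg4_meta$rg4_id == w$rg4_id, , drop = FALSE]
    stopifnot(nrow(meta) == 1L)
    anc_can <- NA_integer_
    status <- NULL
    if (!is.null(ancestral_seqs)) {
      if (!w$rg4_id %in% names(ancestral_seqs)) {
        status <- "NO_RECONSTRUCTION"
      } else {
        hits <- scan_pqs(ancestral_seqs[[w$rg4_id]], params)
        if (nrow(hits)) anc_can <- hits$canonicality[order(-hits$width)][1]
      }
    } else {
      aw <- reconstruct_ancestral_window(w, dtree, clade_species, node_label)
      if (is.null(aw)) {
        status <- "NO_RECONSTRUCTION"
      } else {
        hit <- ancestral_pqs(aw, params)
        if (!is.null(hit)) anc_can <- hit$canonicality
      }
    }
    drift <- if (!is.null(status)) status else
      classify_drift(meta$canonicality, anc_can)$drift
    out[[length(out) + 1L]] <- data.frame(
      rg4_id = w$rg4_id, node_label = node_label, region = meta$region,
      modern_canonicality = meta$canonicality,
      ancestral_canonicality = anc_can, drift = drift,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
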