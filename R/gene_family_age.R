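#' Read a dated (ultrametric) species tree
#'
#' Node ages in MYA are taken from the branch lengths of an ultrametric
#' Newick tree (leaf age 0, parent age >= child age).
#'
#' @param path Newick file path, or an `ape::phylo` object.
#' @return list with `tree` (`phylo`), `ages` (named numeric, internal node
#'   ages indexed by node number) and `leaves` (tip labels).
#' @export
read_dated_tree <- function(path) {
  tree <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  stopifnot(!is.null(tree$edge.length))
  ages <- ape::branching.times(tree)
  list(tree = tree, ages = ages, leaves = tree$tip.label)
}

# Species-name reconciliation: exact match after lowercasing and
# underscore/space normalization.
normalize_species <- function(x) {
  gsub("[ _]+", "_", tolower(trimws(x)))
}

#' Age of the last common ancestor of a species set
#'
#' @param dtree a [read_dated_tree()] object.
#' @param species character vector of species names; names not resolvable
#'   against the tree leaves (after case/underscore normalization) are
#'   dropped with a warning.
#' @return list with `node` (node number; a tip for single-species sets)
#'   and `age_mya` (0 for single-species families).
#' @examples
#' dt <- read_dated_tree(ape::read.tree(text = "((A:10,B:10):90,C:100);"))
#' lca_age(dt, c("A", "B"))$age_mya  # 10
#' lca_age(dt, c("A", "C"))$age_mya  # 100
#' @export
lca_age <- function(dtree, species) {
  leaves_norm <- normalize_species(dtree$leaves)
  sp_norm <- unique(normalize_species(species))
  idx <- match(sp_norm, leaves_norm)
  if (anyNA(idx)) {
    warning(sprintf("%d species name(s) not resolvable against the tree; dropped",
                    sum(is.na(idx))))
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0L) stop("no resolvable species in the set")
  if (length(idx) == 1L) return(list(node = idx, age_mya = 0))
  node <- ape::getMRCA(dtree$tree, dtree$leaves[idx])
  list(node = node, age_mya = unname(dtree$ages[as.character(node)]))
}

#' Read gene-family membership and ohnolog tables
#'
#' The family table is long-format TSV with columns `family_id`, `species`,
#' `gene_id`; the ohnolog table has a `gene_id` column.
#'
#' @param path TSV file path.
#' @return data frame (`read_gene_families`) or character vector of gene
#'   ids (`read_ohnologs`).
#' @export
read_gene_families <- function(path) {
  df <- read_tsv_table(path)
  stopifnot(all(c("family_id", "species", "gene_id") %in% names(df)))
  df
}

#' @rdname read_gene_families
#' @export
read_ohnologs <- function(path) {
  df <- read_tsv_table(path)
  stopifnot("gene_id" %in% names(df))
  unique(df$gene_id)
}

#' Assign LCA ages and clade labels to gene families
#'
#' Each family's age is the age of the minimal tree node ancestral to all
#' its (resolvable) species. The clade label is the innermost configured
#' clade whose species set contains the family's species; families covered
#' by no configured clade get `NA`.
#'
#' @param families long-format data frame (`family_id`, `species`,
#'   `gene_id`).
#' @param dtree a [read_dated_tree()] object.
#' @param clade_config named list mapping clade labels to their member
#'   species (leaf sets); evaluated innermost (smallest) first.
#' @return data frame with one row per family: `family_id`, `age_mya`,
#'   `clade_label`, `n_species`.
#' @export
assign_family_ages <- function(families, dtree, clade_config) {
  cfg_norm <- lapply(clade_config, normalize_species)
  ord <- order(vapply(cfg_norm, length, integer(1)))
  leaves_norm <- normalize_species(dtree$leaves)
  out <- lapply(split(families, families$family_id), function(fam) {
    sp <- unique(fam$species)
    la <- suppressWarnings(lca_age(dtree, sp))
    sp_norm <- intersect(normalize_species(sp), leaves_norm)
    label <- NA_character_
    for (k in ord) {
      if (all(sp_norm %in% cfg_norm[[k]])) {
        label <- names(cfg_norm)[k]
        break
      }
    }
    data.frame(family_id = fam$family_id[1], age_mya = la$age_mya,
               clade_label = label, n_species = length(sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Genes carrying an rG4 passing the region filter. rg4_genes is either a
# character vector (any region) or a data frame with gene_id and region.
harboring_gene_set <- function(rg4_genes, region_filter) {
  if (is.character(rg4_genes)) return(unique(rg4_genes))
  stopifnot(all(c("gene_id", "region") %in% names(rg4_genes)))
  if (identical(region_filter, "ALL")) return(unique(rg4_genes$gene_id))
  unique(rg4_genes$gene_id[rg4_genes$region == region_filter])
}

#' Fraction of gene families harboring rG4s, by age clade
#'
#' @param families long-format membership data frame (`family_id`,
#'   `species`, `gene_id`).
#' @param family_ages data frame from [assign_family_ages()].
#' @param rg4_genes character vector of rG4-harboring gene ids, or a data
#'   frame with `gene_id` and `region` for region-filtered views.
#' @param region_filter `"ALL"` or one of [region_levels()].
#' @return data frame per clade: `clade_label`, `n_families`,
#'   `n_harboring`, `fraction`; clades with no families are omitted.
#' @export
harboring_fraction <- function(families, family_ages, rg4_genes,
                               region_filter = "ALL") {
  genes <- harboring_gene_set(rg4_genes, region_filter)
  harb <- vapply(split(families$gene_id, families$family_id),
                 function(g) any(g %in% genes), logical(1))
  fa <- family_ages
  fa$harboring <- unname(harb[fa$family_id])
  fa <- fa[!is.na(fa$clade_label), , drop = FALSE]
  out <- lapply(split(fa, fa$clade_label), function(d) {
    data.frame(clade_label = d$clade_label[1], n_families = nrow(d),
               n_harboring = sum(d$harboring),
               fraction = sum(d$harboring) / nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$clade_label), , drop = FALSE]
}

#' Contrast rG4 harboring between all families and ohnolog families
#'
#' Compares the rG4-harboring fraction of all gene families against the
#' subset containing at least one gene retained from the vertebrate
#' whole-genome duplications (ohnologs).
#'
#' @inheritParams harboring_fraction
#' @param ohnolog_genes character vector of ohnolog gene ids.
#' @return two-row data frame (`group` in `"all"`/`"ohnolog"`) with
#'   `n_families`, `n_harboring`, `fraction` (NA fraction when the ohnolog
#'   subset is empty, with a warning).
#' @export
ohnolog_contrast <- function(families, rg4_genes, ohnolog_genes,
                             region_filter = "ALL") {
  genes <- harboring_gene_set(rg4_genes, region_filter)
  by_fam <- split(families$gene_id, families$family_id)
  harb <- vapply(by_fam, function(g) any(g %in% genes), logical(1))
  is_ohno <- vapply(by_fam, function(g) any(g %in% ohnolog_genes), logical(1))
  if (!any(is_ohno)) {
    warning("no gene family contains an ohnolog gene; ohnolog fraction is NA")
  }
  mkrow <- function(group, sel) {
    n <- sum(sel)
    data.frame(group = group, n_families = n, n_harboring = sum(harb[sel]),
               fraction = if (n > 0) sum(harb[sel]) / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(mkrow("all", rep(TRUE, length(harb))), mkrow("ohnolog", is_ohno))
}
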