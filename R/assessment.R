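#' Resolution of a rooted tree
#'
#' Percentage of the maximum possible number of internal nodes that are
#' present: `100 * (internal nodes excluding the root) / (n - 2)` for `n`
#' leaves. 100 exactly for a fully binary tree, 0 for a star. The
#' root-inclusive convention `100 * internal / (n - 1)` is available because
#' published resolution figures do not always state their denominator.
#'
#' @param tree A `phylo` with at least 3 leaves.
#' @param convention `"exclusive"` (default, root excluded) or `"inclusive"`.
#' @return A percentage in `[0, 100]`.
#' @export
resolution <- function(tree, convention = c("exclusive", "inclusive")) {
  convention <- match.arg(convention)
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop("resolution requires at least 3 leaves")
  if (convention == "exclusive") 100 * (tree$Nnode - 1L) / (n - 2L)
  else 100 * tree$Nnode / (n - 1L)
}

# does record r support cluster C? S = C restricted to r's leaves must have
# >= 2 taxa, not swallow the whole record, and match a cluster of r exactly
# (or merely be compatible with r's clusters, under the relaxed reading)
record_supports <- function(cluster, record, compatible = FALSE) {
  leaves <- record$tree$tip.label
  S <- intersect(cluster, leaves)
  if (length(S) < 2L || length(setdiff(leaves, cluster)) == 0L) return(FALSE)
  cl <- clusters(record$tree)
  key <- cluster_key(S)
  if (!compatible) {
    return(any(vapply(cl, cluster_key, "") == key))
  }
  all(vapply(cl, function(D) {
    i <- length(intersect(S, D))
    i == 0L || i == length(S) || i == length(D)
  }, TRUE))
}

#' Source support for one clade
#'
#' A source record supports a cluster when the cluster's restriction to the
#' record's taxa (at least two of them, and not the record's whole leaf set)
#' is exactly one of the record's clusters. A clade with no supporting record
#' is *novel*.
#'
#' @param cluster Character vector of leaf names (at least 2).
#' @param records List of [source_record] objects.
#' @param compatible Count compatible-but-unresolved records as support?
#' @return A one-row tibble: `cluster`, `size`, `n_support`,
#'   `supporting_ids` (list column), `status`.
#' @export
clade_support <- function(cluster, records, compatible = FALSE) {
  stopifnot(length(cluster) >= 2L)
  records <- as_record_list(records)
  supp <- record_ids(records)[vapply(records, function(r)
    record_supports(cluster, r, compatible), TRUE)]
  tibble::tibble(cluster = cluster_key(cluster), size = length(cluster),
                 n_support = length(supp), supporting_ids = list(supp),
                 status = ifelse(length(supp), "supported", "novel"))
}

#' Novel clades of a supertree
#'
#' Computes [clade_support()] for every non-trivial cluster of the supertree
#' and, per taxon, whether its smallest containing non-trivial cluster is
#' novel (a taxon "placed in a novel clade").
#'
#' @param supertree A `phylo` on the union of the records' taxa.
#' @param records List of [source_record] objects.
#' @param compatible Passed to [clade_support()].
#' @return A `clade_support_report`: `clades` tibble, `taxa` tibble, and the
#'   novel-clade and novel-taxon percentages.
#' @export
novel_clades <- function(supertree, records, compatible = FALSE) {
  supertree <- validate_tree(supertree)
  records <- as_record_list(records)
  cl <- clusters(supertree)
  clades <- dplyr::bind_rows(lapply(cl, clade_support, records = records,
                                    compatible = compatible))
  # smallest containing non-trivial cluster, per taxon
  status_of <- stats::setNames(clades$status, clades$cluster)
  taxa <- sort(supertree$tip.label)
  smallest <- vapply(taxa, function(t) {
    containing <- cl[vapply(cl, function(c) t %in% c, TRUE)]
    if (!length(containing)) return(NA_character_)
    cluster_key(containing[[which.min(lengths(containing))]])
  }, "")
  taxa_tbl <- tibble::tibble(
    taxon = taxa, smallest_cluster = unname(smallest),
    in_novel_clade = !is.na(smallest) & status_of[smallest] == "novel")
  structure(list(
    clades = clades, taxa = taxa_tbl,
    pct_novel_clades = if (nrow(clades)) 100 * mean(clades$status == "novel") else 0,
    pct_taxa_in_novel_clades = 100 * mean(taxa_tbl$in_novel_clade, na.rm = TRUE)),
    class = "clade_support_report")
}

#' @export
print.clade_support_report <- function(x, ...) {
  cat(sprintf("clade support: %d clusters, %.2f%% novel; %.2f%% of taxa in novel clades\n",
              nrow(x$clades), x$pct_novel_clades, x$pct_taxa_in_novel_clades))
  invisible(x)
}

#' Rogue-taxon diagnostics for one taxon
#'
#' Summarises the four warning signs for unstable supertree placement: few
#' source-tree occurrences, variable position (distinct sibling sets relative
#' to a reference taxon sample), frequent placement inside polytomies, and
#' frequent appearance only as an outgroup.
#'
#' @param taxon Taxon name.
#' @param records List of [source_record] objects.
#' @param reference_taxa Taxon sample against which positions are compared;
#'   defaults to the 10 most frequent taxa across the records.
#' @return A one-row tibble: `taxon`, `occurrence_count`, `distinct_positions`,
#'   `polytomy_fraction`, `outgroup_fraction`.
#' @export
rogue_report <- function(taxon, records, reference_taxa = NULL) {
  records <- as_record_list(records)
  if (is.null(reference_taxa)) {
    freq <- sort(table(unlist(lapply(records, function(r) r$tree$tip.label))),
                 decreasing = TRUE)
    reference_taxa <- setdiff(names(freq), taxon)[1:min(10L, length(freq))]
    reference_taxa <- reference_taxa[!is.na(reference_taxa)]
  }
  occ <- Filter(function(r) taxon %in% r$tree$tip.label, records)
  if (!length(occ)) {
    return(tibble::tibble(taxon = taxon, occurrence_count = 0L,
                          distinct_positions = 0L, polytomy_fraction = 0,
                          outgroup_fraction = 0))
  }
  positions <- character(length(occ))
  in_poly <- logical(length(occ))
  as_out <- logical(length(occ))
  for (i in seq_along(occ)) {
    r <- occ[[i]]
    phy <- r$tree
    tip <- match(taxon, phy$tip.label)
    parent <- phy$edge[phy$edge[, 2] == tip, 1]
    kids <- phy$edge[phy$edge[, 1] == parent, 2]
    in_poly[i] <- length(kids) > 2L
    sets <- node_tipsets(phy)
    sibs <- setdiff(unlist(sets[kids]), taxon)
    positions[i] <- cluster_key(intersect(sibs, reference_taxa))
    as_out[i] <- taxon %in% r$outgroup_taxa
  }
  tibble::tibble(taxon = taxon, occurrence_count = length(occ),
                 distinct_positions = length(unique(positions)),
                 polytomy_fraction = mean(in_poly),
                 outgroup_fraction = mean(as_out))
}

#' Rogue-taxon diagnostics for many taxa
#'
#' @param records List of [source_record] objects.
#' @param taxa Taxa to report on; defaults to every taxon in the dataset.
#' @param reference_taxa See [rogue_report()].
#' @return A tibble with one row per taxon.
#' @export
rogue_table <- function(records, taxa = NULL, reference_taxa = NULL) {
  records <- as_record_list(records)
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(records, function(r) r$tree$tip.label))))
  }
  dplyr::bind_rows(lapply(taxa, rogue_report, records = records,
                          reference_taxa = reference_taxa))
}

#' Data-availability matrix
#'
#' Presence/absence of each taxon in each source tree, with rows (taxa) and
#' columns (trees) both ordered by descending frequency (ties lexicographic),
#' plus marginal counts.
#'
#' @param records List of [source_record] objects.
#' @return An `mrp_availability`: binary `matrix` (taxa x trees),
#'   `taxon_counts` and `tree_counts` tibbles.
#' @export
availability_matrix <- function(records) {
  records <- as_record_list(records)
  ids <- record_ids(records)
  taxa <- sort(unique(unlist(lapply(records, function(r) r$tree$tip.label))))
  mat <- matrix(0L, nrow = length(taxa), ncol = length(ids),
                dimnames = list(taxa, ids))
  for (j in seq_along(records)) mat[records[[j]]$tree$tip.label, j] <- 1L
  row_ord <- order(-rowSums(mat), rownames(mat))
  col_ord <- order(-colSums(mat), colnames(mat))
  mat <- mat[row_ord, col_ord, drop = FALSE]
  structure(list(
    matrix = mat,
    taxon_counts = tibble::tibble(taxon = rownames(mat),
                                  n_trees = as.integer(rowSums(mat))),
    tree_counts = tibble::tibble(id = colnames(mat),
                                 n_taxa = as.integer(colSums(mat)))),
    class = "mrp_availability")
}

#' @export
print.mrp_availability <- function(x, ...) {
  cat(sprintf("data availability: %d taxa x %d source trees; fill %.1f%%\n",
              nrow(x$matrix), ncol(x$matrix), 100 * mean(x$matrix)))
  invisible(x)
}

#' Plot a data-availability matrix
#'
#' Dot plot of taxon presence per source tree, both axes sorted by frequency.
#'
#' @param object An `mrp_availability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrp_availability <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(object$matrix,
                                              stringsAsFactors = FALSE))
  names(df) <- c("taxon", "tree", "present")
  df <- dplyr::filter(df, .data$present > 0)
  df$taxon <- factor(df$taxon, levels = rev(rownames(object$matrix)))
  df$tree <- factor(df$tree, levels = colnames(object$matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tree, y = .data$taxon)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "source trees (by frequency)", y = "taxa (by frequency)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Write an availability matrix as sparse triplets
#'
#' MTX-style plain-text triplet file plus the row/column orderings.
#'
#' @param x An `mrp_availability`.
#' @param path Output path for the triplet file; orderings are written next to
#'   it with suffixes `.taxa` and `.trees`.
#' @return `path`, invisibly.
#' @export
write_availability <- function(x, path) {
  stopifnot(inherits(x, "mrp_availability"))
  idx <- which(x$matrix == 1L, arr.ind = TRUE)
  con <- file(path, "w")
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(x$matrix), ncol(x$matrix), nrow(idx)), con)
  writeLines(sprintf("%d %d 1", idx[, 1], idx[, 2]), con)
  close(con)
  writeLines(rownames(x$matrix), paste0(path, ".taxa"))
  writeLines(colnames(x$matrix), paste0(path, ".trees"))
  invisible(path)
}
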