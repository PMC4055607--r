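#' Search configuration
#'
#' Settings for the heuristic parsimony search: number of random-addition
#' starts, the rearrangement move set, a cap on hill-climbing rounds, and the
#' width of the equal-length plateau explored when collecting all optimal
#' trees.
#'
#' @param seed Integer seed; all randomness in the search derives from it.
#' @param n_random_starts Number of random stepwise-addition starting trees.
#' @param moves Subset of `c("NNI", "SPR")`.
#' @param max_rounds Safety cap on hill-climbing rounds per start.
#' @param plateau_max Maximum number of equal-length trees explored per
#'   plateau when collecting most-parsimonious trees.
#' @param keep_all_optimal Collect the full (plateau-limited) set of optimal
#'   trees rather than a single best tree?
#' @return A `search_config` list.
#' @export
search_config <- function(seed = 1L, n_random_starts = 3L,
                          moves = c("NNI", "SPR"), max_rounds = 200L,
                          plateau_max = 64L, keep_all_optimal = TRUE) {
  moves <- match.arg(moves, c("NNI", "SPR"), several.ok = TRUE)
  stopifnot(n_random_starts >= 1L, max_rounds >= 1L, plateau_max >= 1L)
  structure(list(seed = as.integer(seed),
                 n_random_starts = as.integer(n_random_starts),
                 moves = moves, max_rounds = as.integer(max_rounds),
                 plateau_max = as.integer(plateau_max),
                 keep_all_optimal = isTRUE(keep_all_optimal)),
            class = "search_config")
}

#' Parsimony length of a tree on an MRP matrix
#'
#' Minimum number of state changes summed over all matrix columns, computed by
#' the two-state Sankoff dynamic programme (Fitch on bifurcations, exact on
#' multifurcations). Missing entries `"?"` are treated as the free state set
#' `{0, 1}`.
#'
#' @param tree A `phylo` whose leaves are exactly the matrix taxa (including
#'   the hypothetical outgroup). Polytomies are allowed.
#' @param matrix An [mrp_matrix].
#' @param per_column Return the per-column vector instead of the total?
#' @return Integer tree length (or per-column integer vector).
#' @export
tree_length <- function(tree, matrix, per_column = FALSE) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  tree <- validate_tree(tree)
  if (!setequal(tree$tip.label, matrix$taxa)) {
    missing <- setdiff(matrix$taxa, tree$tip.label)
    extra <- setdiff(tree$tip.label, matrix$taxa)
    stop("tree leaves and matrix taxa differ",
         if (length(missing)) paste0("; missing from tree: ",
                                     paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; absent from matrix: ",
                                   paste(utils::head(extra, 5), collapse = ", ")))
  }
  tt <- tt_from_phylo(tree, matrix$taxa)
  lens <- sankoff_lengths_cpp(tt_par0(tt$par), tt_tax0(tt$taxon), states_int(matrix))
  if (per_column) lens else sum(lens)
}

# initial tree for a search: outgroup basal, first two ingroup taxa as a cherry
tt_init <- function(n_taxa, outgroup_row, first_two) {
  m <- 2L * n_taxa - 1L
  par <- rep(NA_integer_, m)
  taxon <- rep(NA_integer_, m)
  taxon[seq_len(n_taxa)] <- seq_len(n_taxa)
  root <- n_taxa + 1L
  cherry <- n_taxa + 2L
  par[root] <- 0L
  par[outgroup_row] <- root
  par[cherry] <- root
  par[first_two] <- cherry
  list(par = par, taxon = taxon)
}

#' Random-addition starting tree
#'
#' Builds a binary tree by adding taxa in a seeded random order, each at the
#' insertion point that minimises parsimony length; the hypothetical outgroup
#' stays basal throughout.
#'
#' @param matrix An [mrp_matrix].
#' @param seed Integer seed controlling the addition order.
#' @return A binary rooted `phylo` containing every matrix taxon.
#' @export
stepwise_addition <- function(matrix, seed = 1L) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa (including the outgroup)")
  sti <- states_int(matrix)
  out_row <- match(mrp_outgroup_name(), taxa)
  ingroup <- setdiff(seq_len(n), out_row)
  ord <- with_seed(seed, sample(ingroup))
  tt <- tt_init(n, out_row, ord[1:2])
  insertable <- c(ord[1], ord[2], n + 2L) # any ingroup node incl. ingroup root
  if (length(ord) > 2L) {
    for (k in 3:length(ord)) {
      t_new <- ord[k]
      u <- n + k
      cands <- lapply(insertable, function(v) {
        q <- tt$par
        q[u] <- q[v]
        q[v] <- u
        q[t_new] <- u
        list(par = q, taxon = tt$taxon)
      })
      lens <- tt_score_many(cands, tt$taxon, sti)
      tt <- cands[[which.min(lens)]]
      insertable <- c(insertable, t_new, u)
    }
  }
  tt_to_phylo(tt, taxa)
}

climb_and_plateau <- function(tt, sti, taxa, outnode, config) {
  len <- tt_score(tt, sti)
  n_moves <- 0L
  repeat {
    improved <- FALSE
    for (round in seq_len(config$max_rounds)) {
      nb <- tt_neighbors(tt, outnode, config$moves)
      if (!length(nb)) break
      lens <- tt_score_many(nb, tt$taxon, sti)
      best <- min(lens)
      if (best < len) {
        tt <- nb[[which.min(lens)]]
        len <- best
        n_moves <- n_moves + 1L
        improved <- TRUE
      } else break
    }
    # plateau exploration: breadth-limited walk over equal-length neighbours
    pool <- list(tt)
    names(pool) <- tt_key(tt, taxa)
    if (config$keep_all_optimal) {
      queue <- pool
      shorter <- NULL
      while (length(queue) && length(pool) < config$plateau_max) {
        cur <- queue[[1]]
        queue <- queue[-1]
        nb <- tt_neighbors(cur, outnode, config$moves)
        lens <- tt_score_many(nb, cur$taxon, sti)
        if (any(lens < len)) {
          shorter <- nb[[which.min(lens)]]
          len <- min(lens)
          break
        }
        for (i in which(lens == len)) {
          k <- tt_key(nb[[i]], taxa)
          if (is.null(pool[[k]]) && length(pool) < config$plateau_max) {
            pool[[k]] <- nb[[i]]
            queue[[k]] <- nb[[i]]
          }
        }
      }
      if (!is.null(shorter)) {
        tt <- shorter
        n_moves <- n_moves + 1L
        next
      }
    }
    return(list(trees = pool, length = len, n_moves = n_moves))
  }
}

#' Heuristic parsimony search
#'
#' Multiple random-addition starts, each refined by NNI/SPR hill climbing;
#' equal-length neighbours of each local optimum are explored breadth-first
#' (up to `plateau_max`) to collect most-parsimonious trees. Deterministic for
#' a fixed configuration.
#'
#' @param matrix An [mrp_matrix].
#' @param config A [search_config].
#' @return An `mrp_search` object: `best_length`, `mpts` (distinct optimal
#'   trees, rooted, outgroup included), and a per-start `trace` tibble.
#' @export
heuristic_search <- function(matrix, config = search_config()) {
  stopifnot(inherits(matrix, "mrp_matrix"), inherits(config, "search_config"))
  taxa <- matrix$taxa
  if (length(taxa) < 4L) stop("need at least 4 taxa")
  sti <- states_int(matrix)
  outnode <- match(mrp_outgroup_name(), taxa)
  best_len <- Inf
  pool <- list()
  trace <- vector("list", config$n_random_starts)
  for (s in seq_len(config$n_random_starts)) {
    start_seed <- config$seed + 7919L * (s - 1L)
    start_phy <- stepwise_addition(matrix, seed = start_seed)
    tt <- tt_from_phylo(start_phy, taxa)
    start_len <- tt_score(tt, sti)
    res <- climb_and_plateau(tt, sti, taxa, outnode, config)
    trace[[s]] <- tibble::tibble(start = s, seed = start_seed,
                                 start_length = start_len,
                                 final_length = res$length,
                                 n_improving_moves = res$n_moves,
                                 n_plateau_trees = length(res$trees))
    if (res$length < best_len) {
      best_len <- res$length
      pool <- res$trees
    } else if (res$length == best_len) {
      for (k in names(res$trees)) if (is.null(pool[[k]])) pool[[k]] <- res$trees[[k]]
    }
  }
  mpts <- lapply(pool[order(names(pool))], tt_to_phylo, taxa = taxa)
  names(mpts) <- NULL
  structure(list(best_length = as.integer(best_len), mpts = mpts,
                 trace = dplyr::bind_rows(trace), config = config,
                 n_taxa = length(taxa), n_columns = ncol(matrix$states),
                 method = "heuristic"),
            class = "mrp_search")
}

#' Exhaustive parsimony search (small-problem oracle)
#'
#' Enumerates every rooted binary topology on the ingroup taxa (outgroup held
#' basal) and returns the exact global optimum. Intended as a testing oracle;
#' limited to 9 ingroup taxa.
#'
#' @param matrix An [mrp_matrix].
#' @param max_keep Cap on the number of optimal trees retained.
#' @return An `mrp_search` object with exact `best_length` and all optimal
#'   trees (up to `max_keep`).
#' @export
exhaustive_search <- function(matrix, max_keep = 10000L) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  taxa <- matrix$taxa
  out_row <- match(mrp_outgroup_name(), taxa)
  ingroup <- setdiff(seq_along(taxa), out_row)
  if (length(ingroup) > 9L) stop("exhaustive search is limited to 9 ingroup taxa")
  if (length(ingroup) < 2L) stop("need at least 2 ingroup taxa")
  res <- exhaustive_cpp(states_int(matrix), ingroup - 1L, out_row - 1L,
                        as.integer(max_keep))
  taxon <- res$taxon + 1L
  taxon[taxon == 0L] <- NA_integer_
  mpts <- lapply(res$trees, function(pv) {
    par <- pv + 1L
    par[pv == -1L] <- 0L
    par[pv == -2L] <- NA_integer_
    tt_to_phylo(list(par = par, taxon = taxon), taxa)
  })
  keys <- vapply(mpts, write_newick, "")
  mpts <- mpts[order(keys)]
  trace <- tibble::tibble(start = 1L, seed = NA_integer_,
                          start_length = NA_integer_,
                          final_length = as.integer(res$best_length),
                          n_improving_moves = NA_integer_,
                          n_plateau_trees = length(mpts))
  structure(list(best_length = as.integer(res$best_length), mpts = mpts,
                 trace = trace, config = NULL, n_taxa = length(taxa),
                 n_columns = ncol(matrix$states),
                 n_trees_scored = res$n_scored, truncated = res$truncated,
                 method = "exhaustive"),
            class = "mrp_search")
}

#' @export
print.mrp_search <- function(x, ...) {
  cat(sprintf("MRP parsimony search (%s)\n", x$method))
  cat(sprintf("  taxa: %d  columns: %d\n", x$n_taxa, x$n_columns))
  cat(sprintf("  best length: %d steps\n", x$best_length))
  cat(sprintf("  optimal trees retained: %d\n", length(x$mpts)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-tree summary of a parsimony search
#'
#' @param x An `mrp_search` object.
#' @param ... Unused.
#' @return A tibble with one row per optimal tree.
#' @export
tidy.mrp_search <- function(x, ...) {
  tibble::tibble(tree = seq_along(x$mpts),
                 length = x$best_length,
                 n_leaves = vapply(x$mpts, ape::Ntip, 0L),
                 resolution = vapply(x$mpts, resolution, 0),
                 newick = vapply(x$mpts, write_newick, ""))
}

#' One-row summary of a parsimony search
#'
#' @param x An `mrp_search` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mrp_search <- function(x, ...) {
  tibble::tibble(method = x$method, best_length = x$best_length,
                 n_mpts = length(x$mpts), n_taxa = x$n_taxa,
                 n_columns = x$n_columns)
}

#' Plot the search trace
#'
#' Start versus final tree length for each random-addition start.
#'
#' @param object An `mrp_search` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrp_search <- function(object, ...) {
  tr <- object$trace
  tr_long <- tidyr::pivot_longer(tr, c("start_length", "final_length"),
                                 names_to = "stage", values_to = "length")
  ggplot2::ggplot(tr_long, ggplot2::aes(x = factor(.data$start), y = .data$length,
                                        group = .data$start)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stage)) +
    ggplot2::geom_hline(yintercept = object$best_length, linetype = 2) +
    ggplot2::labs(x = "random-addition start", y = "tree length (steps)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Strict consensus of a set of trees
#'
#' The tree whose cluster set is exactly the intersection of the input
#' trees' cluster sets.
#'
#' @param trees List of `phylo` objects sharing one leaf set.
#' @return A `phylo` object.
#' @export
strict_consensus <- function(trees) {
  stopifnot(length(trees) >= 1L)
  trees <- lapply(trees, validate_tree)
  leaves <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), leaves)) stop("trees have differing leaf sets")
  }
  if (length(trees) == 1L) return(trees[[1]])
  common <- Reduce(function(acc, t) {
    keys <- vapply(clusters(t), cluster_key, "")
    acc[names(acc) %in% keys]
  }, trees[-1], {
    cl <- clusters(trees[[1]])
    stats::setNames(cl, vapply(cl, cluster_key, ""))
  })
  tree_from_clusters(leaves, unname(common))
}

# build a rooted tree from a pairwise-compatible cluster set
tree_from_clusters <- function(leaves, clusterlist) {
  rec <- function(set, cls) {
    inside <- Filter(function(c) length(c) < length(set) && all(c %in% set), cls)
    maximal <- Filter(function(c) {
      !any(vapply(inside, function(d) length(d) > length(c) && all(c %in% d), TRUE))
    }, inside)
    covered <- unlist(maximal)
    parts <- c(lapply(maximal, function(c) rec(c, inside)),
               as.list(sort(setdiff(set, covered))))
    if (length(parts) == 1L) return(parts[[1]])
    paste0("(", paste(sort(unlist(parts)), collapse = ","), ")")
  }
  parse_newick(paste0(rec(sort(leaves), clusterlist), ";"))
}

# rooted triplet shapes for all leaf triples: 0 = star, otherwise the index
# (within the sorted triple) of the leaf outside the cherry
triplet_codes <- function(phy, taxa) {
  idx <- match(taxa, phy$tip.label)
  if (anyNA(idx)) stop("taxon missing from tree")
  mr <- ape::mrca(phy)[idx, idx, drop = FALSE]
  dep <- node_depths(phy)
  n <- length(taxa)
  trips <- utils::combn(n, 3)
  codes <- integer(ncol(trips))
  for (q in seq_len(ncol(trips))) {
    i <- trips[1, q]; j <- trips[2, q]; k <- trips[3, q]
    d <- c(dep[mr[i, j]], dep[mr[i, k]], dep[mr[j, k]])
    mx <- max(d)
    deepest <- which(d == mx)
    codes[q] <- if (length(deepest) > 1L) 0L else c(3L, 2L, 1L)[deepest]
  }
  list(trips = trips, codes = codes)
}

#' Greedy agreement subtree
#'
#' Finds a taxon subset on which all input trees induce identical restrictions
#' by repeatedly deleting the taxon involved in the largest number of
#' conflicting rooted triplets. The result is verified against the definition
#' (identical restricted cluster sets) before returning; it is not guaranteed
#' to be the maximum agreement subtree.
#'
#' @param trees List of two or more `phylo` objects on one shared leaf set.
#' @param occurrence Optional named numeric vector of per-taxon source-tree
#'   occurrence counts used to break ties (lowest count removed first).
#' @return A `phylo` restriction common to all inputs, with attribute
#'   `"taxa"` giving the retained taxon set.
#' @export
agreement_subtree <- function(trees, occurrence = NULL) {
  stopifnot(length(trees) >= 2L)
  trees <- lapply(trees, validate_tree)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), taxa)) stop("trees have differing leaf sets")
  }
  S <- taxa
  repeat {
    if (length(S) <= 2L) break
    tc <- lapply(trees, triplet_codes, taxa = S)
    codes <- vapply(tc, `[[`, tc[[1]]$codes, "codes")
    codes <- matrix(codes, ncol = length(trees))
    conflict <- apply(codes, 1, function(r) length(unique(r)) > 1L)
    if (!any(conflict)) break
    trips <- tc[[1]]$trips[, conflict, drop = FALSE]
    counts <- tabulate(as.vector(trips), nbins = length(S))
    worst <- which(counts == max(counts))
    if (length(worst) > 1L && !is.null(occurrence)) {
      occ <- occurrence[S[worst]]
      occ[is.na(occ)] <- 0
      worst <- worst[order(occ, S[worst])]
    }
    S <- S[-worst[1]]
  }
  out <- prune_to_taxa(trees[[1]], S)
  keys <- vapply(trees, function(t) write_newick(prune_to_taxa(t, S)), "")
  if (length(unique(keys)) != 1L) {
    stop("internal error: agreement check failed on the returned taxon set")
  }
  attr(out, "taxa") <- S
  out
}

#' Exact maximum agreement subtree (small-problem oracle)
#'
#' Maximum-cardinality taxon subset on which all trees induce identical
#' restrictions, by enumeration over subsets. Limited to 12 shared leaves.
#'
#' @param trees List of two or more `phylo` objects on one shared leaf set.
#' @return The agreement restriction as a `phylo`, with attribute `"taxa"`.
#' @export
mast_exact <- function(trees) {
  stopifnot(length(trees) >= 2L)
  trees <- lapply(trees, validate_tree)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), taxa)) stop("trees have differing leaf sets")
  }
  n <- length(taxa)
  if (n > 12L) stop("exact MAST is limited to 12 shared leaves")
  tc <- lapply(trees, triplet_codes, taxa = taxa)
  codes <- matrix(vapply(tc, `[[`, tc[[1]]$codes, "codes"), ncol = length(trees))
  conflict <- apply(codes, 1, function(r) length(unique(r)) > 1L)
  conflict_masks <- if (any(conflict)) {
    apply(tc[[1]]$trips[, conflict, drop = FALSE], 2,
          function(t) sum(bitwShiftL(1L, t - 1L)))
  } else integer(0)
  for (size in n:2) {
    combos <- utils::combn(n, size)
    for (q in seq_len(ncol(combos))) {
      mask <- sum(bitwShiftL(1L, combos[, q] - 1L))
      if (!length(conflict_masks) ||
          all(bitwAnd(mask, conflict_masks) != conflict_masks)) {
        S <- taxa[combos[, q]]
        out <- prune_to_taxa(trees[[1]], S)
        attr(out, "taxa") <- S
        return(out)
      }
    }
  }
  stop("no agreement subset of size >= 2 found") # unreachable: pairs always agree
}

#' Root on the hypothetical outgroup and extract the ingroup tree
#'
#' Re-roots the tree so the named outgroup is sister to all other taxa, then
#' (by default) removes the outgroup leaf for reporting.
#'
#' @param tree A `phylo` containing the outgroup leaf.
#' @param outgroup_name Outgroup leaf label (default the reserved MRP name).
#' @param drop Remove the outgroup leaf after rooting?
#' @return A `phylo` object.
#' @export
root_on_outgroup <- function(tree, outgroup_name = mrp_outgroup_name(),
                             drop = TRUE) {
  tree <- validate_tree(tree)
  if (!outgroup_name %in% tree$tip.label) {
    stop("outgroup leaf not present: ", outgroup_name)
  }
  root <- tree_root(tree)
  out_tip <- match(outgroup_name, tree$tip.label)
  basal <- any(tree$edge[, 1] == root & tree$edge[, 2] == out_tip)
  rooted <- if (basal) tree else {
    validate_tree(ape::root(ape::unroot(tree), outgroup = outgroup_name,
                            resolve.root = TRUE))
  }
  if (!drop) return(rooted)
  if (ape::Ntip(rooted) < 3L) stop("dropping the outgroup would leave fewer than 2 leaves")
  validate_tree(ape::drop.tip(rooted, outgroup_name))
}
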