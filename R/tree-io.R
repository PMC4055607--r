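#' @useDynLib mrptree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang .data
NULL

# Trees are ape "phylo" objects throughout: rooted, leaf-labelled, polytomies
# allowed, branch lengths ignored. Leaf labels are "Genus_species" strings.

#' Parse a single rooted Newick statement
#'
#' Reads one Newick statement into a rooted `phylo` tree. Quoted labels are
#' unquoted, whitespace inside labels becomes a single underscore, and branch
#' lengths are discarded (the pipeline is topology-only).
#'
#' @param text A single Newick string ending in `";"`.
#' @return A rooted `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!grepl(";\\s*$", text)) stop("Newick statement must end with ';'")
  bal <- check_balance(text)
  if (bal$ok == FALSE) {
    stop(sprintf("unbalanced parentheses in Newick string at position %d", bal$pos))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree read")
  validate_tree(phy)
}

check_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(list(ok = FALSE, pos = i))
    }
  }
  if (depth != 0L) return(list(ok = FALSE, pos = nchar(text)))
  list(ok = TRUE, pos = NA_integer_)
}

normalise_label <- function(x) {
  x <- gsub("'", "", x, fixed = TRUE)
  x <- gsub("[ \t]+", "_", x)
  x <- gsub("_+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Validate (and normalise) a rooted tree
#'
#' Checks the tree invariants: exactly one root, unique non-empty leaf labels,
#' no unlabelled leaves. Labels are normalised to single-underscore form and
#' branch lengths dropped.
#'
#' @param phy A `phylo` object.
#' @return The validated `phylo` object.
#' @export
validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy$tip.label <- normalise_label(phy$tip.label)
  if (any(!nzchar(phy$tip.label)) || anyNA(phy$tip.label)) {
    stop("tree has unlabelled leaves")
  }
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  roots <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(roots) != 1L) stop("tree does not have exactly one root")
  phy
}

tree_root <- function(phy) setdiff(phy$edge[, 1], phy$edge[, 2])

# children lists indexed by node id
node_children <- function(phy) {
  m <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", m)
  sp <- split(phy$edge[, 2], phy$edge[, 1])
  ch[as.integer(names(sp))] <- sp
  ch
}

# list over all nodes: tip labels subtended by each node
node_tipsets <- function(phy) {
  nt <- ape::Ntip(phy)
  m <- nt + phy$Nnode
  sets <- vector("list", m)
  sets[seq_len(nt)] <- as.list(phy$tip.label)
  ord <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]
    v <- ord$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

# number of edges from the root, per node
node_depths <- function(phy) {
  nt <- ape::Ntip(phy)
  m <- nt + phy$Nnode
  depth <- integer(m)
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + 1L
  }
  depth
}

cluster_key <- function(x) paste(sort(x), collapse = "|")

#' Clusters (clades) of a rooted tree
#'
#' Returns the leaf set subtended by each internal node, excluding the root.
#' Trivial single-leaf clusters are excluded unless requested.
#'
#' @param tree A `phylo` object.
#' @param include_trivial Also return the single-leaf clusters?
#' @return A list of character vectors (leaf-name sets), sorted canonically.
#' @export
clusters <- function(tree, include_trivial = FALSE) {
  tree <- validate_tree(tree)
  nt <- ape::Ntip(tree)
  root <- tree_root(tree)
  internal <- setdiff(seq_len(nt + tree$Nnode)[-seq_len(nt)], root)
  sets <- node_tipsets(tree)
  out <- lapply(internal, function(i) sort(sets[[i]]))
  if (include_trivial) out <- c(out, as.list(sort(tree$tip.label)))
  keys <- vapply(out, cluster_key, "")
  out[order(keys)]
}

#' Write a tree as a canonical Newick string
#'
#' Children are emitted in lexicographic order of their smallest descendant
#' label, so equal trees always serialise identically (stable diffs/tests).
#'
#' @param tree A `phylo` object.
#' @return A single Newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  tree <- validate_tree(tree)
  nt <- ape::Ntip(tree)
  ch <- node_children(tree)
  rec <- function(nd) {
    if (nd <= nt) {
      lab <- tree$tip.label[nd]
      return(list(str = lab, min = lab))
    }
    subs <- lapply(ch[[nd]], rec)
    mins <- vapply(subs, `[[`, "", "min")
    o <- order(mins)
    list(str = paste0("(", paste(vapply(subs, `[[`, "", "str")[o], collapse = ","), ")"),
         min = mins[o[1]])
  }
  paste0(rec(tree_root(tree))$str, ";")
}

canonical_newick <- function(tree) write_newick(tree)

# equality of rooted topologies up to node rotation
same_topology <- function(a, b) {
  identical(write_newick(a), write_newick(b))
}

#' Restrict a tree to a taxon subset
#'
#' Induced restriction: drops all leaves outside `keep` and suppresses the
#' resulting degree-one internal nodes, so the cluster set of the result is
#' exactly the non-trivial restriction of the original cluster set.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain (at least 2 present).
#' @return The restricted `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- validate_tree(tree)
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 2L) stop("fewer than 2 leaves would survive the restriction")
  if (length(keep) == length(tree$tip.label)) return(tree)
  validate_tree(ape::keep.tip(tree, keep))
}

#' Read a collection of named trees
#'
#' Reads either a file of one-Newick-per-line statements or a NEXUS file with
#' a `TREES` block (`TRANSLATE` tables are honoured).
#'
#' @param path File path.
#' @param format `"newick-list"` or `"nexus"`.
#' @return A named list of `phylo` objects.
#' @export
read_tree_collection <- function(path, format = c("newick-list", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "newick-list") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    trees <- lapply(lines, parse_newick)
    names(trees) <- sprintf("tree_%d", seq_along(trees))
    return(trees)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("begin\\s+trees", txt, ignore.case = TRUE)) {
    stop("NEXUS file has no TREES block: ", path)
  }
  read_nexus_trees(txt, path)
}

# TREES-block parser: TRANSLATE tables honoured per tree (trees may cover
# different taxon subsets, which shared-translation readers often reject);
# rooting comments [&R]/[&U] are recorded but not otherwise interpreted
read_nexus_trees <- function(txt, path = "<text>") {
  txt <- gsub("\\[%[^]]*\\]", "", txt) # non-rooting comments are dropped below
  block <- sub("(?is).*?begin\\s+trees\\s*;", "", txt, perl = TRUE)
  block <- sub("(?is)[\r\n[:space:]]end[[:space:]]*;.*", "", block, perl = TRUE)
  statements <- strsplit(block, ";", fixed = TRUE)[[1]]
  statements <- trimws(gsub("[\r\n\t]+", " ", statements))
  statements <- statements[nzchar(statements)]
  translate <- character(0)
  trees <- list()
  for (st in statements) {
    if (grepl("(?i)^translate([[:space:]]|$)", st, perl = TRUE)) {
      body <- sub("(?i)^translate\\s+", "", st, perl = TRUE)
      pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
      translate <- stats::setNames(
        vapply(pairs, function(p) gsub("'", "", p[2]), ""),
        vapply(pairs, `[`, "", 1))
    } else if (grepl("(?i)^u?tree[[:space:]]", st, perl = TRUE)) {
      name <- sub("(?i)^u?tree\\s+\\*?\\s*([^=\\s]+)\\s*=.*$", "\\1", st, perl = TRUE)
      nwk <- sub("^[^=]*=\\s*", "", st)
      rooted_tag <- if (grepl("\\[&R\\]", nwk)) "R" else
        if (grepl("\\[&U\\]", nwk)) "U" else NA_character_
      nwk <- trimws(gsub("\\[[^]]*\\]", "", nwk))
      if (length(translate)) {
        toks <- regmatches(nwk, gregexpr("[^(),:;\\s]+", nwk))[[1]]
        nums <- toks[grepl("^\\d+$", toks)]
        bad <- setdiff(unique(nums), names(translate))
        if (length(bad)) {
          stop(sprintf("tree '%s' in %s: token(s) %s missing from TRANSLATE",
                       name, path, paste(bad, collapse = ", ")))
        }
        for (k in names(translate)) {
          nwk <- gsub(paste0("(?<=[(,])", k, "(?=[,):])"), translate[[k]],
                      nwk, perl = TRUE)
        }
      }
      nwk <- gsub(":[0-9.eE+-]+", "", nwk) # branch lengths are topology-noise
      tr <- parse_newick(paste0(nwk, ";"))
      attr(tr, "rooting") <- rooted_tag
      trees[[name]] <- tr
    }
  }
  if (!length(trees)) stop("no TREE statements found in ", path)
  trees
}

#' Write a collection of named trees
#'
#' @param trees Named list of `phylo` objects.
#' @param path Output file path.
#' @param format `"newick-list"` or `"nexus"` (TREES block with TRANSLATE).
#' @param translate Write a TRANSLATE table in NEXUS output?
#' @return `path`, invisibly.
#' @export
write_tree_collection <- function(trees, path, format = c("newick-list", "nexus"),
                                  translate = TRUE) {
  format <- match.arg(format)
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    names(trees) <- sprintf("tree_%d", seq_along(trees))
  }
  nwk <- vapply(trees, write_newick, "")
  if (format == "newick-list") {
    writeLines(nwk, path)
    return(invisible(path))
  }
  taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN TREES;", con)
  if (translate) {
    idx <- stats::setNames(seq_along(taxa), taxa)
    tab <- sprintf("\t\t%d %s%s", idx, taxa,
                   c(rep(",", length(taxa) - 1L), ";"))
    writeLines("\tTRANSLATE", con)
    writeLines(tab, con)
    nwk <- vapply(nwk, function(s) {
      for (t in rev(taxa)) { # longest-name-safe via boundary regex
        s <- gsub(paste0("(?<=[(,])", t, "(?=[,)])"), idx[[t]], s, perl = TRUE)
      }
      s
    }, "")
  }
  writeLines(sprintf("\tTREE %s = [&R] %s", names(trees), nwk), con)
  writeLines("END;", con)
  invisible(path)
}
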