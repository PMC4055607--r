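#' Configuration for the synthetic source-tree generator
#'
#' Defines the study conditions emulated by the generator: a known true tree,
#' many partially overlapping source trees, controlled topological conflict,
#' and the curation problems seen in literature-mined data (synonyms,
#' higher-taxon labels, genus-level paraphyly, duplicate studies, a poorly
#' resolved seed taxonomy tree).
#'
#' @param n_taxa Number of species in the true tree (>= 4).
#' @param n_source_trees Number of sampled source trees (seed tree extra).
#' @param size_distribution `c(min, max)` leaves per source tree; defaults to
#'   `c(8, 16)` clipped to `n_taxa`.
#' @param conflict_nni_per_tree Random NNI perturbations applied per tree.
#' @param p_synonym Fraction of leaf occurrences renamed to a registered
#'   synonym.
#' @param p_higher_taxon Per-record probability of collapsing one unstructured
#'   clade to a higher-taxon label.
#' @param p_paraphyly_injection Per-record probability of planting a
#'   genus-level leaf alongside a congeneric species.
#' @param include_seed_tree Add a poorly resolved all-taxon taxonomy tree?
#' @param seed_tree_resolution Fraction of internal nodes retained in it.
#' @param duplicate_study_count Number of cloned (non-independent) records.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_taxa = 32L, n_source_trees = 20L,
                             size_distribution = NULL,
                             conflict_nni_per_tree = 0L,
                             p_synonym = 0, p_higher_taxon = 0,
                             p_paraphyly_injection = 0,
                             include_seed_tree = TRUE,
                             seed_tree_resolution = 0.3,
                             duplicate_study_count = 0L, seed = 1L) {
  if (is.null(size_distribution)) {
    size_distribution <- c(max(4L, min(8L, n_taxa)), min(16L, n_taxa))
  }
  stopifnot(n_taxa >= 4L, length(size_distribution) == 2L,
            size_distribution[1] >= 4L,
            size_distribution[1] <= size_distribution[2],
            size_distribution[2] <= n_taxa,
            p_synonym >= 0, p_synonym <= 1,
            p_higher_taxon >= 0, p_higher_taxon <= 1,
            p_paraphyly_injection >= 0, p_paraphyly_injection <= 1)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_source_trees = as.integer(n_source_trees),
                 size_distribution = as.integer(size_distribution),
                 conflict_nni_per_tree = as.integer(conflict_nni_per_tree),
                 p_synonym = p_synonym, p_higher_taxon = p_higher_taxon,
                 p_paraphyly_injection = p_paraphyly_injection,
                 include_seed_tree = isTRUE(include_seed_tree),
                 seed_tree_resolution = seed_tree_resolution,
                 duplicate_study_count = as.integer(duplicate_study_count),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a random true tree
#'
#' Rooted binary tree by seeded random sequential joining (each new leaf
#' attached on a uniformly chosen edge). Leaves are named
#' `Genus##_species##`, with genus sizes drawn geometrically so that genus
#' expansion and paraphyly handling can be exercised.
#'
#' @param n Number of leaves (>= 4).
#' @param seed Integer seed.
#' @param mean_genus_size Expected species per genus.
#' @return A binary rooted `phylo`.
#' @export
generate_true_tree <- function(n, seed = 1L, mean_genus_size = 2.5) {
  stopifnot(n >= 4L)
  with_seed(seed, {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, 1L + stats::rgeom(1, 1 / mean_genus_size))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0L]
    # two-level random sequential joining: a genus-level topology whose
    # leaves are replaced by random species subtrees, so genera are clades
    genus_names <- sprintf("Genus%02d", seq_along(sizes))
    if (length(sizes) == 1L) {
      spp <- sprintf("%s_species%02d", genus_names[1], seq_len(sizes[1]))
      return(parse_newick(paste0(random_joining_newick(spp), ";")))
    }
    genus_nwk <- random_joining_newick(genus_names)
    for (g in seq_along(sizes)) {
      spp <- sprintf("%s_species%02d", genus_names[g], seq_len(sizes[g]))
      sub <- if (length(spp) == 1L) spp else random_joining_newick(spp)
      genus_nwk <- gsub(paste0("(?<=[(,])", genus_names[g], "(?=[,)])"),
                        sub, genus_nwk, perl = TRUE)
    }
    parse_newick(paste0(genus_nwk, ";"))
  })
}

# random binary topology over labels by sequential joining; bare newick string
random_joining_newick <- function(labels) {
  stopifnot(length(labels) >= 2L)
  subtrees <- as.list(labels[1:2])
  # represent the growing tree as nested two-element lists; attach each new
  # leaf on a uniformly chosen edge (i.e. next to a uniformly chosen node)
  tree <- list(labels[1], labels[2])
  count_nodes <- function(x) if (is.character(x)) 1L else
    1L + count_nodes(x[[1]]) + count_nodes(x[[2]])
  attach_at <- function(x, k, leaf) {
    # k indexes nodes in preorder; returns list(node = updated subtree, used)
    if (k == 1L) return(list(node = list(x, leaf), used = TRUE))
    if (is.character(x)) return(list(node = x, used = FALSE))
    k <- k - 1L
    n1 <- count_nodes(x[[1]])
    if (k <= n1) {
      r <- attach_at(x[[1]], k, leaf)
      list(node = list(r$node, x[[2]]), used = r$used)
    } else {
      r <- attach_at(x[[2]], k - n1, leaf)
      list(node = list(x[[1]], r$node), used = r$used)
    }
  }
  if (length(labels) > 2L) {
    for (i in 3:length(labels)) {
      k <- sample.int(count_nodes(tree), 1L)
      tree <- attach_at(tree, k, labels[i])$node
    }
  }
  to_nwk <- function(x) if (is.character(x)) x else
    paste0("(", to_nwk(x[[1]]), ",", to_nwk(x[[2]]), ")")
  to_nwk(tree)
}

# one random rooted NNI move, in place; returns the tree unchanged when no
# eligible internal edge exists
random_nni <- function(phy) {
  tt <- tt_from_phylo(phy, sort(phy$tip.label))
  ch <- tt_children(tt)
  root <- tt_root(tt)
  cands <- which(!is.na(tt$par) & is.na(tt$taxon) & tt$par != 0L)
  cands <- cands[vapply(cands, function(v) {
    length(setdiff(ch[[tt$par[v]]], v)) == 1L && length(ch[[v]]) == 2L
  }, TRUE)]
  if (!length(cands)) return(phy)
  v <- cands[sample.int(length(cands), 1L)]
  p <- tt$par[v]
  sib <- setdiff(ch[[p]], v)
  cc <- ch[[v]][sample.int(2L, 1L)]
  q <- tt$par
  q[cc] <- p
  q[sib] <- v
  tt_to_phylo(list(par = q, taxon = tt$taxon), sort(phy$tip.label))
}

#' Sample overlapping source trees from a true tree
#'
#' Each record restricts the true tree to a random leaf subset within the
#' configured size range; subsets are chained (every subset shares at least
#' two taxa with the previous one) so the dataset is connected by
#' construction. Optional conflict is injected as random NNI moves, and an
#' optional seed taxonomy tree covers all taxa at low resolution.
#'
#' @param true_tree The reference `phylo`.
#' @param config A [synthetic_config].
#' @return A list of [source_record] objects (plus attribute `"nni_log"`).
#' @export
sample_source_trees <- function(true_tree, config) {
  stopifnot(inherits(config, "synthetic_config"))
  taxa <- sort(true_tree$tip.label)
  n <- length(taxa)
  tag_pool <- c("cytb", "nd2", "nd3", "rag1", "rag2", "12s", "16s", "coi",
                "myoglobin", "fib5", "morphology", "behaviour", "osteology",
                "dna-dna", "allozymes", "syrinx")
  with_seed(config$seed + 1L, {
    records <- vector("list", config$n_source_trees)
    nni_log <- vector("list", config$n_source_trees)
    prev <- NULL
    for (i in seq_len(config$n_source_trees)) {
      size <- sample(config$size_distribution[1]:config$size_distribution[2], 1L)
      size <- min(size, n)
      if (is.null(prev)) {
        subset <- sample(taxa, size)
      } else {
        anchors <- sample(prev, 2L)
        subset <- c(anchors, sample(setdiff(taxa, anchors), size - 2L))
      }
      prev <- subset
      tr <- prune_to_taxa(true_tree, subset)
      moves <- 0L
      if (config$conflict_nni_per_tree > 0L) {
        for (m in seq_len(config$conflict_nni_per_tree)) {
          tr <- random_nni(tr)
          moves <- moves + 1L
        }
      }
      tags <- c(tag_pool[1L + (i - 1L) %% length(tag_pool)],
                sprintf("locus%03d", i)) # unique set: no accidental redundancy
      records[[i]] <- source_record(
        id = sprintf("t%03d", i), tree = tr,
        year = sample(1976:2008, 1L, prob = (1:33)^2),
        character_tags = tags,
        method_tag = sample(c("parsimony", "likelihood", "bayesian", "nj"), 1L),
        outgroup_taxa = sort(tr$tip.label)[1])
      nni_log[[i]] <- tibble::tibble(id = records[[i]]$id, n_nni = moves)
    }
    if (config$include_seed_tree) {
      seed_tree <- collapse_to_resolution(true_tree, config$seed_tree_resolution)
      records[[length(records) + 1L]] <- source_record(
        id = "seed_taxonomy", tree = seed_tree, year = 2008L,
        character_tags = "taxonomy", method_tag = "taxonomy")
    }
    structure(records, nni_log = dplyr::bind_rows(nni_log))
  })
}

# keep roughly `fraction` of the non-root internal nodes, collapsing the rest
collapse_to_resolution <- function(phy, fraction) {
  cl <- clusters(phy)
  if (!length(cl)) return(phy)
  k <- max(1L, round(fraction * length(cl)))
  keep <- sample(seq_along(cl), k)
  tree_from_clusters(sort(phy$tip.label), cl[keep])
}

#' Inject curation noise into clean records
#'
#' With seeded randomness: renames leaf occurrences to registered synonyms,
#' collapses unstructured clades (cherries) to higher-taxon labels, plants
#' bare genus-level leaves next to congeners (apparent paraphyly), and clones
#' records with pruned taxon sets (planted non-independent studies). Every
#' perturbation is recorded with the rule that reverses it.
#'
#' @param records Clean [source_record] list (from [sample_source_trees()]).
#' @param config A [synthetic_config].
#' @return A list: `records` (noisy), `ground_truth` (rules tibble, name map,
#'   duplicate pairs).
#' @export
apply_name_noise <- function(records, config) {
  stopifnot(inherits(config, "synthetic_config"))
  records <- as_record_list(records)
  all_taxa <- sort(unique(unlist(lapply(records, function(r) r$tree$tip.label))))
  syn_of <- stats::setNames(sub("species", "cognatus", all_taxa), all_taxa)
  used_syn <- character(0)
  higher_rules <- list()
  name_map <- list()
  dup_pairs <- list()
  with_seed(config$seed + 2L, {
    noisy <- records
    for (i in seq_along(noisy)) {
      r <- noisy[[i]]
      if (identical(r$character_tags, "taxonomy")) next # seed tree stays clean
      touched <- character(0)
      # presence elsewhere, so substitutions can never be filtered away
      elsewhere <- unique(unlist(lapply(records[-i], function(x) x$tree$tip.label)))
      # 1. synonyms
      if (config$p_synonym > 0) {
        hit <- r$tree$tip.label[stats::runif(ape::Ntip(r$tree)) < config$p_synonym]
        for (t in hit) {
          r$tree$tip.label[r$tree$tip.label == t] <- syn_of[[t]]
          used_syn <- union(used_syn, t)
          touched <- c(touched, t, syn_of[[t]])
          name_map[[length(name_map) + 1L]] <- tibble::tibble(
            record = r$id, kind = "synonym", from = t, to = syn_of[[t]])
        }
      }
      # 2. higher-taxon collapse of one unstructured clade (cherry)
      if (stats::runif(1) < config$p_higher_taxon) {
        cl <- clusters(r$tree)
        cherries <- Filter(function(c) length(c) == 2L &&
                             !any(c %in% touched) && all(c %in% elsewhere), cl)
        if (length(cherries)) {
          ch <- cherries[[sample.int(length(cherries), 1L)]]
          lab <- sprintf("CladeH%02d", length(higher_rules) + 1L)
          pr <- drop_tips_checked(r, ch[2], "higher-taxon collapse")
          if (pr$valid) {
            r <- pr
            r$tree$tip.label[r$tree$tip.label == ch[1]] <- lab
            r$tree <- validate_tree(r$tree)
            higher_rules[[lab]] <- ch
            touched <- c(touched, ch, lab)
            name_map[[length(name_map) + 1L]] <- tibble::tibble(
              record = r$id, kind = "higher_taxon", from = cluster_key(ch), to = lab)
          }
        }
      }
      # 3. apparent paraphyly: genus cherry -> bare genus leaf + congener
      if (stats::runif(1) < config$p_paraphyly_injection) {
        cl <- clusters(r$tree)
        genus_of <- function(x) sub("_.*$", "", x)
        eligible <- Filter(function(c) {
          length(c) == 2L && !any(c %in% touched) && all(grepl("_", c)) &&
            genus_of(c[1]) == genus_of(c[2]) && all(c %in% elsewhere) &&
            # the genus must contain exactly this pair dataset-wide, so that
            # genus expansion after curation restores the cherry verbatim
            setequal(all_taxa[startsWith(all_taxa, paste0(genus_of(c[1]), "_"))], c)
        }, cl)
        if (length(eligible)) {
          ch <- eligible[[sample.int(length(eligible), 1L)]]
          g <- genus_of(ch[1])
          r$tree$tip.label[r$tree$tip.label == ch[1]] <- g
          r$tree <- validate_tree(r$tree)
          touched <- c(touched, ch, g)
          name_map[[length(name_map) + 1L]] <- tibble::tibble(
            record = r$id, kind = "paraphyly", from = ch[1], to = g)
        }
      }
      noisy[[i]] <- r
    }
    # 4. planted duplicate (non-independent) studies
    if (config$duplicate_study_count > 0L) {
      eligible <- which(vapply(noisy, function(r)
        ape::Ntip(r$tree) >= 6L && !identical(r$character_tags, "taxonomy"), TRUE))
      picks <- sample(eligible, min(config$duplicate_study_count, length(eligible)))
      for (j in picks) {
        orig <- noisy[[j]]
        keep <- sort(sample(orig$tree$tip.label,
                            max(4L, floor(0.7 * ape::Ntip(orig$tree)))))
        clone <- orig
        clone$id <- paste0(orig$id, "_dup")
        clone$tree <- prune_to_taxa(orig$tree, keep)
        noisy[[length(noisy) + 1L]] <- clone
        dup_pairs[[length(dup_pairs) + 1L]] <- tibble::tibble(
          original = orig$id, clone = clone$id)
      }
    }
    rules <- substitution_rules(
      c(syn_of[used_syn], names(higher_rules)),
      c(lapply(used_syn, function(t) t), unname(higher_rules)))
    list(records = noisy,
         ground_truth = list(
           rules = rules,
           name_map = if (length(name_map)) dplyr::bind_rows(name_map) else
             tibble::tibble(record = character(), kind = character(),
                            from = character(), to = character()),
           duplicate_pairs = if (length(dup_pairs)) dplyr::bind_rows(dup_pairs) else
             tibble::tibble(original = character(), clone = character())))
  })
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_true_tree()], [sample_source_trees()] and
#' [apply_name_noise()]; optionally writes the dataset in the pipeline's
#' input layout (NEXUS tree file, metadata blocks, substitution rules,
#' ground truth).
#'
#' @param config A [synthetic_config].
#' @param dir Optional output directory (created if needed).
#' @return A list: `records`, `true_tree`, `ground_truth`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  true_tree <- generate_true_tree(config$n_taxa, seed = config$seed)
  clean <- sample_source_trees(true_tree, config)
  noised <- apply_name_noise(clean, config)
  out <- list(records = noised$records, true_tree = true_tree,
              clean_records = clean,
              ground_truth = c(noised$ground_truth,
                               list(nni_log = attr(clean, "nni_log"))),
              config = config)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' Write a dataset directory
#'
#' Layout: `trees.nex` (all source trees, names = record ids),
#' `metadata.txt` (flat key-value blocks), `substitutions.txt` (rename and
#' expand rules), `true_tree.nwk` and `name_map.tsv` when ground truth is
#' present.
#'
#' @param dataset A list with at least `records`; see [generate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- as_record_list(dataset$records)
  trees <- stats::setNames(lapply(records, `[[`, "tree"), record_ids(records))
  write_tree_collection(trees, file.path(dir, "trees.nex"), format = "nexus")
  con <- file(file.path(dir, "metadata.txt"), "w")
  for (r in records) {
    writeLines(c("[record]",
                 paste0("id = ", r$id),
                 paste0("year = ", r$year),
                 paste0("characters = ", paste(r$character_tags, collapse = ", ")),
                 paste0("method = ", r$method_tag),
                 paste0("outgroup = ", paste(r$outgroup_taxa, collapse = ", ")),
                 ""), con)
  }
  close(con)
  rules <- dataset$ground_truth$rules
  if (is.null(rules)) rules <- substitution_rules(character(0), list())
  write_substitutions(rules, file.path(dir, "substitutions.txt"))
  if (!is.null(dataset$true_tree)) {
    writeLines(write_newick(dataset$true_tree), file.path(dir, "true_tree.nwk"))
  }
  if (!is.null(dataset$ground_truth$name_map)) {
    utils::write.table(dataset$ground_truth$name_map,
                       file.path(dir, "name_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset directory
#'
#' Reads the layout written by [write_dataset()] and cross-checks tree names
#' against metadata ids (mismatches are reported as issues, not errors).
#'
#' @param dir Dataset directory.
#' @return A list: `records`, `rules`, `issues` tibble.
#' @export
read_dataset <- function(dir) {
  tree_path <- file.path(dir, "trees.nex")
  meta_path <- file.path(dir, "metadata.txt")
  if (!file.exists(tree_path)) stop("missing trees.nex in ", dir)
  if (!file.exists(meta_path)) stop("missing metadata.txt in ", dir)
  trees <- read_tree_collection(tree_path, format = "nexus")
  lines <- trimws(readLines(meta_path, warn = FALSE))
  blocks <- split(lines, cumsum(lines == "[record]"))
  blocks <- blocks[vapply(blocks, function(b) any(b == "[record]"), TRUE)]
  meta <- lapply(blocks, function(b) {
    kv <- b[grepl("=", b, fixed = TRUE)]
    keys <- trimws(sub("=.*$", "", kv))
    vals <- trimws(sub("^[^=]*=", "", kv))
    stats::setNames(as.list(vals), keys)
  })
  issues <- list()
  records <- list()
  meta_ids <- vapply(meta, function(m) m$id %||% "", "")
  for (m in meta) {
    if (is.null(m$id) || !m$id %in% names(trees)) {
      issues[[length(issues) + 1L]] <- tibble::tibble(
        type = "id_mismatch", item = m$id %||% "<missing>",
        detail = "metadata record has no matching tree")
      next
    }
    splitcsv <- function(x) if (is.null(x) || !nzchar(x)) character(0) else
      trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    records[[length(records) + 1L]] <- source_record(
      id = m$id, tree = trees[[m$id]],
      year = suppressWarnings(as.integer(m$year %||% NA)),
      character_tags = if (length(splitcsv(m$characters))) splitcsv(m$characters)
      else "unspecified",
      method_tag = m$method %||% "unspecified",
      outgroup_taxa = splitcsv(m$outgroup))
  }
  for (nm in setdiff(names(trees), meta_ids)) {
    issues[[length(issues) + 1L]] <- tibble::tibble(
      type = "id_mismatch", item = nm, detail = "tree has no metadata record")
  }
  rules_path <- file.path(dir, "substitutions.txt")
  rules <- if (file.exists(rules_path)) read_substitutions(rules_path) else
    substitution_rules(character(0), list())
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(type = character(), item = character(), detail = character())
  list(records = records, rules = rules, issues = issues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
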