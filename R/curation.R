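#' Create a source-tree record
#'
#' One unit of curation: a rooted tree plus its study metadata.
#'
#' @param id Unique record identifier.
#' @param tree A `phylo` object.
#' @param year Publication year.
#' @param character_tags Character vector of data types used by the study
#'   (e.g. `"cytb"`, `"morphology"`); non-empty, normalised to lower case.
#' @param method_tag Tree-building method label (free text; `"taxonomy"`
#'   marks the seed/backbone tree).
#' @param outgroup_taxa Taxa used as outgroups in the original study.
#' @return A `source_record` object.
#' @export
source_record <- function(id, tree, year = NA_integer_,
                          character_tags = "unspecified",
                          method_tag = "unspecified",
                          outgroup_taxa = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  tree <- validate_tree(tree)
  character_tags <- sort(unique(tolower(trimws(character_tags))))
  if (!length(character_tags) || any(!nzchar(character_tags))) {
    stop("character_tags must be non-empty")
  }
  structure(list(id = id, tree = tree, year = as.integer(year),
                 character_tags = character_tags, method_tag = method_tag,
                 outgroup_taxa = as.character(outgroup_taxa),
                 valid = TRUE, flags = character()),
            class = "source_record")
}

#' @export
print.source_record <- function(x, ...) {
  cat(sprintf("source record '%s' (%s): %d leaves; characters: %s\n",
              x$id, ifelse(is.na(x$year), "year n/a", x$year),
              ape::Ntip(x$tree), paste(x$character_tags, collapse = ", ")))
  invisible(x)
}

as_record_list <- function(records) {
  if (inherits(records, "source_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, TRUE, "source_record")))
  records
}

record_ids <- function(records) vapply(as_record_list(records), `[[`, "", "id")

#' Summarise records as a tibble
#'
#' @param x A list of [source_record] objects.
#' @param ... Unused.
#' @return One row per record: id, year, leaf count, tags.
#' @export
records_summary <- function(x, ...) {
  x <- as_record_list(x)
  tibble::tibble(id = record_ids(x),
                 year = vapply(x, `[[`, 1L, "year"),
                 n_leaves = vapply(x, function(r) ape::Ntip(r$tree), 0L),
                 character_tags = vapply(x, function(r)
                   paste(r$character_tags, collapse = ","), ""),
                 method_tag = vapply(x, `[[`, "", "method_tag"),
                 valid = vapply(x, `[[`, TRUE, "valid"))
}

# ---- substitution rules -----------------------------------------------------

#' Build a substitution-rule table
#'
#' @param old_label Labels to match.
#' @param replacements List of character vectors: empty = delete the leaf,
#'   length one = rename, longer = expand into a polytomy.
#' @return A tibble with columns `old_label`, `action`, `replacements`.
#' @export
substitution_rules <- function(old_label, replacements) {
  stopifnot(length(old_label) == length(replacements))
  if (anyDuplicated(old_label)) stop("rules must be keyed uniquely by old_label")
  action <- vapply(replacements, function(r) {
    if (length(r) == 0L) "delete" else if (length(r) == 1L) "rename" else "expand"
  }, "")
  tibble::tibble(old_label = as.character(old_label), action = action,
                 replacements = lapply(replacements, as.character))
}

#' Read a substitution file
#'
#' Plain text, one rule per line: `old_label = new1, new2, ...`. An empty
#' right-hand side deletes the leaf; a single name renames it; several names
#' expand it into a polytomy. Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return A rule tibble (see [substitution_rules()]).
#' @export
read_substitutions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(substitution_rules(character(0), list()))
  }
  if (!all(grepl("=", lines, fixed = TRUE))) {
    stop("malformed substitution line (no '='): ",
         lines[!grepl("=", lines, fixed = TRUE)][1])
  }
  old <- trimws(sub("=.*$", "", lines))
  rhs <- trimws(sub("^[^=]*=", "", lines))
  reps <- lapply(rhs, function(r) {
    if (!nzchar(r)) character(0) else trimws(strsplit(r, ",", fixed = TRUE)[[1]])
  })
  substitution_rules(old, reps)
}

#' Write a substitution file
#'
#' @param rules A rule tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitutions <- function(rules, path) {
  lines <- sprintf("%s = %s", rules$old_label,
                   vapply(rules$replacements, paste, "", collapse = ", "))
  writeLines(lines, path)
  invisible(path)
}

# depth of each tip, used for the keep-nearest-root duplicate policy
tip_depths <- function(phy) node_depths(phy)[seq_len(ape::Ntip(phy))]

drop_tips_checked <- function(record, tips, reason) {
  tree <- record$tree
  keep <- setdiff(tree$tip.label, tips)
  if (length(keep) < 2L) {
    record$valid <- FALSE
    record$flags <- c(record$flags,
                      sprintf("invalid: %s leaves fewer than 2 taxa", reason))
    return(record)
  }
  record$tree <- validate_tree(ape::keep.tip(tree, keep))
  record
}

#' Standardise leaf names in a record
#'
#' Applies rename and delete rules (synonyms, misspellings, exclusions). If a
#' rename creates duplicate leaves, the copy closest to the root is kept and
#' the others pruned, with a warning. A record reduced below two leaves is
#' flagged invalid rather than erroring.
#'
#' @param record A [source_record].
#' @param rules Rule tibble containing only rename/delete actions.
#' @return The updated record.
#' @export
standardize_names <- function(record, rules) {
  stopifnot(inherits(record, "source_record"))
  if (any(rules$action == "expand")) {
    stop("standardize_names accepts only rename/delete rules")
  }
  tree <- record$tree
  del <- rules$old_label[rules$action == "delete"]
  hit_del <- intersect(tree$tip.label, del)
  if (length(hit_del)) {
    record <- drop_tips_checked(record, hit_del, "deletion")
    if (!record$valid) return(record)
    tree <- record$tree
  }
  ren <- rules[rules$action == "rename", ]
  idx <- match(tree$tip.label, ren$old_label)
  if (any(!is.na(idx))) {
    tree$tip.label[!is.na(idx)] <-
      vapply(ren$replacements[idx[!is.na(idx)]], `[`, "", 1)
    dup_names <- unique(tree$tip.label[duplicated(tree$tip.label)])
    if (length(dup_names)) {
      warning(sprintf("record %s: synonym collapse created duplicate leaves (%s); keeping the copy closest to the root",
                      record$id, paste(dup_names, collapse = ", ")))
      depths <- tip_depths(tree)
      drop_idx <- unlist(lapply(dup_names, function(nm) {
        hits <- which(tree$tip.label == nm)
        hits[-which.min(depths[hits])]
      }))
      # prune by index: temporarily disambiguate labels
      tmp <- tree
      tmp$tip.label <- sprintf("@@%d", seq_along(tmp$tip.label))
      tmp <- ape::keep.tip(tmp, setdiff(tmp$tip.label, sprintf("@@%d", drop_idx)))
      tmp$tip.label <- tree$tip.label[as.integer(sub("@@", "", tmp$tip.label))]
      tree <- tmp
    }
    record$tree <- validate_tree(tree)
    if (ape::Ntip(record$tree) < 2L) {
      record$valid <- FALSE
      record$flags <- c(record$flags, "invalid: fewer than 2 taxa after renaming")
    }
  }
  record
}

# replace one leaf by a polytomy of `members` through canonical-Newick surgery
replace_leaf_with_polytomy <- function(tree, leaf, members) {
  members <- sort(unique(members))
  stopifnot(length(members) >= 2L, leaf %in% tree$tip.label)
  nwk <- write_newick(tree)
  poly <- paste0("(", paste(members, collapse = ","), ")")
  out <- gsub(paste0("(?<=[(,])", leaf, "(?=[,)])"), poly, nwk, perl = TRUE)
  parse_newick(out)
}

#' Substitute a higher-taxon (or vernacular) leaf
#'
#' Replaces the matching leaf by a polytomy of the rule's constituent taxa,
#' restricted to taxa already present in the dataset so the substitution
#' cannot inflate the taxon set. A singleton intersection renames the leaf; an
#' empty one prunes it with a warning.
#'
#' @param record A [source_record].
#' @param rule A single expand rule (one row of a rule tibble).
#' @param dataset_taxa Character vector of taxa present in the dataset.
#' @return The updated record.
#' @export
substitute_higher_taxon <- function(record, rule, dataset_taxa) {
  stopifnot(inherits(record, "source_record"))
  if (nrow(rule) != 1L || rule$action == "delete") {
    stop("rule must be a single expand (or rename) rule")
  }
  leaf <- rule$old_label
  if (!leaf %in% record$tree$tip.label) return(record)
  members <- rule$replacements[[1]]
  kept <- intersect(members, setdiff(dataset_taxa, record$tree$tip.label))
  filtered <- setdiff(members, kept)
  if (length(filtered)) {
    record$flags <- c(record$flags,
                      sprintf("substitution %s: filtered absent/duplicate taxa: %s",
                              leaf, paste(filtered, collapse = ", ")))
  }
  if (length(kept) == 0L) {
    warning(sprintf("record %s: no constituent of '%s' present in the dataset; leaf pruned",
                    record$id, leaf))
    return(drop_tips_checked(record, leaf, sprintf("pruning '%s'", leaf)))
  }
  if (length(kept) == 1L) {
    record$tree$tip.label[record$tree$tip.label == leaf] <- kept
    record$tree <- validate_tree(record$tree)
    return(record)
  }
  record$tree <- replace_leaf_with_polytomy(record$tree, leaf, kept)
  record
}

#' Derive genus membership from a taxon list
#'
#' @param dataset_taxa Character vector of `Genus_species` names.
#' @return Named list mapping genus to its species present in the list.
#' @export
genus_membership_from_taxa <- function(dataset_taxa) {
  sp <- dataset_taxa[grepl("_", dataset_taxa)]
  split(sp, sub("_.*$", "", sp))
}

#' Expand genus-level leaves to species polytomies
#'
#' Leaf labels without an underscore-separated epithet are treated as
#' genus-level and replaced by a polytomy of the genus members already present
#' in the dataset (singleton: rename; none/unknown genus: record flagged for a
#' manual rule).
#'
#' @param record A [source_record].
#' @param genus_membership Named list genus -> species vector; defaults to
#'   membership derived from `dataset_taxa`.
#' @param dataset_taxa Character vector of taxa present in the dataset.
#' @return The updated record.
#' @export
expand_genera <- function(record, genus_membership = NULL, dataset_taxa) {
  stopifnot(inherits(record, "source_record"))
  if (is.null(genus_membership)) {
    genus_membership <- genus_membership_from_taxa(dataset_taxa)
  }
  genus_leaves <- record$tree$tip.label[!grepl("_", record$tree$tip.label)]
  for (g in genus_leaves) {
    members <- genus_membership[[g]]
    if (is.null(members)) {
      record$flags <- c(record$flags,
                        sprintf("unknown genus '%s': needs a manual rule", g))
      next
    }
    rule <- substitution_rules(g, list(members))
    record <- substitute_higher_taxon(record, rule, dataset_taxa)
    if (!record$valid) break
  }
  record
}

#' All placements of a paraphyletic group
#'
#' For a named group occurring at several positions in a tree, returns the
#' distinct trees obtained by keeping one occurrence (relabelled to the
#' placeholder) and pruning the rest. A monophyletic group collapses directly
#' to a single placeholder leaf.
#'
#' @param tree A `phylo` object.
#' @param group Character vector of the group's leaf labels in the tree.
#' @param placeholder Label for the retained occurrence.
#' @return A list of `phylo` trees (duplicates removed).
#' @export
permute_paraphyletic <- function(tree, group, placeholder) {
  tree <- validate_tree(tree)
  occ <- intersect(tree$tip.label, group)
  if (!length(occ)) stop("group has no leaves in the tree")
  if (placeholder %in% setdiff(tree$tip.label, occ)) {
    stop("placeholder collides with an existing leaf")
  }
  mono <- length(occ) == 1L || {
    sets <- node_tipsets(tree)
    anc <- vapply(sets, function(s) all(occ %in% s), TRUE)
    smallest <- which(anc)[which.min(lengths(sets)[anc])]
    setequal(sets[[smallest]], occ)
  }
  make_one <- function(keep_leaf) {
    t2 <- if (length(occ) > 1L) {
      pruned <- drop_tips_checked(
        structure(list(id = "tmp", tree = tree, valid = TRUE, flags = character()),
                  class = "source_record"),
        setdiff(occ, keep_leaf), "paraphyly pruning")
      if (!pruned$valid) return(NULL)
      pruned$tree
    } else tree
    t2$tip.label[t2$tip.label == keep_leaf] <- placeholder
    validate_tree(t2)
  }
  if (mono) {
    out <- make_one(occ[1])
    if (is.null(out)) stop("collapsing the group leaves fewer than 2 taxa")
    return(list(out))
  }
  perms <- Filter(Negate(is.null), lapply(sort(occ), make_one))
  if (!length(perms)) stop("all permutations leave fewer than 2 taxa")
  keys <- vapply(perms, write_newick, "")
  perms[!duplicated(keys)]
}

#' Mini-supertree of a set of permutation trees
#'
#' Encodes the trees as an MRP matrix and returns the strict consensus of all
#' most-parsimonious trees (exhaustive search up to 9 ingroup taxa, heuristic
#' above). Used to resolve paraphyletic-taxon placements and to combine
#' non-independent studies.
#'
#' @param trees List of `phylo` objects sharing one leaf set.
#' @param config Optional [search_config] for the heuristic fallback.
#' @return A `phylo` object.
#' @export
build_mini_supertree <- function(trees, config = search_config()) {
  stopifnot(length(trees) >= 1L)
  trees <- lapply(trees, validate_tree)
  if (length(trees) == 1L) return(trees[[1]])
  keys <- vapply(trees, write_newick, "")
  if (length(unique(keys)) == 1L) return(trees[[1]])
  leaves <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), leaves)) {
      stop("mini-supertree inputs must share one leaf set")
    }
  }
  recs <- lapply(seq_along(trees), function(i) {
    source_record(sprintf("perm_%d", i), trees[[i]], character_tags = "permutation")
  })
  mat <- build_matrix(recs)
  if (ncol(mat$states) == 0L) {
    return(tree_from_clusters(leaves, list())) # star: no signal at all
  }
  res <- if (length(leaves) <= 9L) exhaustive_search(mat) else
    heuristic_search(mat, config)
  ingroup <- lapply(res$mpts, root_on_outgroup)
  strict_consensus(ingroup)
}

#' Detect non-independent studies
#'
#' Two records are non-independent when they carry identical character-tag
#' sets and identical taxa (flagged for manual combination) or one taxon set
#' is a proper subset of the other (the less comprehensive record is marked
#' dropped).
#'
#' @param records List of [source_record] objects.
#' @return A tibble with columns `id_a`, `id_b`, `relation`
#'   (`"identical"`/`"subset"`) and `drop` (id of the record to remove, `NA`
#'   for identical pairs, which need manual combination).
#' @export
detect_nonindependence <- function(records) {
  records <- as_record_list(records)
  tags <- vapply(records, function(r) paste(r$character_tags, collapse = ";"), "")
  leafsets <- lapply(records, function(r) sort(r$tree$tip.label))
  ids <- record_ids(records)
  out <- list()
  for (grp in split(seq_along(records), tags)) {
    if (length(grp) < 2L) next
    for (a in grp) for (b in grp) {
      if (a >= b) next
      la <- leafsets[[a]]; lb <- leafsets[[b]]
      if (identical(la, lb)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          id_a = ids[a], id_b = ids[b], relation = "identical", drop = NA_character_)
      } else if (all(la %in% lb)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          id_a = ids[a], id_b = ids[b], relation = "subset", drop = ids[a])
      } else if (all(lb %in% la)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          id_a = ids[a], id_b = ids[b], relation = "subset", drop = ids[b])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          relation = character(), drop = character()))
  }
  dplyr::bind_rows(out)
}

#' Check pairwise taxonomic overlap of a dataset
#'
#' Builds the overlap graph (edge when two records share at least two taxa)
#' and reports its connected components; a dataset is usable for supertree
#' construction only when there is exactly one component.
#'
#' @param records List of [source_record] objects.
#' @return An `overlap_report`: `components` (list of id sets), `edges`
#'   tibble (`id_a`, `id_b`, `shared`), and `passes`.
#' @export
check_connectivity <- function(records) {
  records <- as_record_list(records)
  ids <- record_ids(records)
  leafsets <- lapply(records, function(r) r$tree$tip.label)
  edges <- list()
  n <- length(records)
  if (n > 1L) {
    for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
      shared <- length(intersect(leafsets[[a]], leafsets[[b]]))
      if (shared >= 2L) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          id_a = ids[a], id_b = ids[b], shared = shared)
      }
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(id_a = character(), id_b = character(), shared = integer())
  g <- igraph::graph_from_data_frame(edges[, c("id_a", "id_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  components <- unname(split(ids, comp$membership[ids]))
  structure(list(components = components, edges = edges,
                 passes = comp$no == 1L),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("taxonomic overlap: %d component(s); %s\n", length(x$components),
              if (x$passes) "dataset is connected" else "dataset is NOT connected"))
  if (!x$passes) {
    for (i in seq_along(x$components)) {
      cat(sprintf("  component %d: %s\n", i, paste(x$components[[i]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Cross-check a dataset against its metadata and rules
#'
#' Report-only validation: leaves absent from the canonical name list,
#' substitution rules referencing taxa absent from the dataset ("problem
#' taxa"), duplicate record ids, and records flagged invalid upstream.
#'
#' @param records List of [source_record] objects.
#' @param rules Optional rule tibble to check against the dataset.
#' @param canonical Optional character vector of canonical taxon names.
#' @return A tibble of issues (`type`, `item`, `detail`); zero rows when clean.
#' @export
validate_dataset <- function(records, rules = NULL, canonical = NULL) {
  records <- as_record_list(records)
  ids <- record_ids(records)
  issues <- list()
  add <- function(type, item, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(type = type, item = item,
                                                     detail = detail)
  }
  dups <- unique(ids[duplicated(ids)])
  for (d in dups) add("duplicate_id", d, "record id occurs more than once")
  dataset_taxa <- sort(unique(unlist(lapply(records, function(r) r$tree$tip.label))))
  if (!is.null(canonical)) {
    for (t in setdiff(dataset_taxa, canonical)) {
      add("unknown_taxon", t, "leaf label not in the canonical name list")
    }
  }
  if (!is.null(rules)) {
    for (i in seq_len(nrow(rules))) {
      missing <- setdiff(rules$replacements[[i]], dataset_taxa)
      if (length(missing)) {
        add("problem_taxon", rules$old_label[i],
            paste("replacement taxa absent from the dataset:",
                  paste(missing, collapse = ", ")))
      }
    }
  }
  for (r in records) {
    if (!isTRUE(r$valid)) add("invalid_record", r$id, paste(r$flags, collapse = "; "))
  }
  if (!length(issues)) {
    return(tibble::tibble(type = character(), item = character(),
                          detail = character()))
  }
  dplyr::bind_rows(issues)
}

# fix paraphyletic genus-level occurrences in one record: a bare-genus leaf
# co-occurring with congeneric species (or several bare occurrences) is
# permuted, summarised by a mini-supertree, and left as a single placeholder
resolve_paraphyly <- function(record, dataset_taxa, config = search_config()) {
  stopifnot(inherits(record, "source_record"))
  repeat {
    labs <- record$tree$tip.label
    bare <- labs[!grepl("_", labs)]
    target <- NULL
    for (g in sort(unique(bare))) {
      members <- labs[labs == g | startsWith(labs, paste0(g, "_"))]
      if (length(members) > 1L) { target <- list(genus = g, members = members); break }
    }
    if (is.null(target)) return(record)
    perms <- permute_paraphyletic(record$tree, target$members, target$genus)
    record$tree <- if (length(perms) == 1L) perms[[1]] else
      build_mini_supertree(perms, config)
    record$flags <- c(record$flags,
                      sprintf("paraphyletic occurrences of '%s' reduced via %d permutation(s)",
                              target$genus, length(perms)))
  }
}

#' Run the full curation protocol on a dataset
#'
#' Applies, in order: name standardisation (rename/delete rules), paraphyly
#' resolution (permutation + mini-supertree), higher-taxon substitution
#' (expand rules), genus expansion, non-independence filtering (subset records
#' dropped), connectivity checking, and final validation.
#'
#' @param records List of [source_record] objects.
#' @param rules Rule tibble (rename/delete and expand rules together).
#' @param canonical Optional canonical name list for validation.
#' @param config [search_config] for mini-supertrees.
#' @return A list: `records` (curated, invalid/dropped removed), `dropped`
#'   tibble, `nonindependence` tibble, `overlap` report, `issues` tibble.
#' @export
curate_dataset <- function(records, rules = NULL, canonical = NULL,
                           config = search_config()) {
  records <- as_record_list(records)
  if (is.null(rules)) rules <- substitution_rules(character(0), list())
  nonexp <- rules[rules$action != "expand", ]
  exp_rules <- rules[rules$action == "expand", ]
  records <- lapply(records, standardize_names, rules = nonexp)
  dropped <- list()
  keep <- vapply(records, `[[`, TRUE, "valid")
  for (r in records[!keep]) {
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      id = r$id, reason = paste(r$flags, collapse = "; "))
  }
  records <- records[keep]
  # dataset taxa: species-level names present after standardisation
  dataset_taxa <- sort(unique(unlist(lapply(records, function(r)
    r$tree$tip.label[grepl("_", r$tree$tip.label)]))))
  records <- lapply(records, resolve_paraphyly, dataset_taxa = dataset_taxa,
                    config = config)
  if (nrow(exp_rules)) {
    records <- lapply(records, function(r) {
      for (i in seq_len(nrow(exp_rules))) {
        r <- substitute_higher_taxon(r, exp_rules[i, ], dataset_taxa)
        if (!r$valid) break
      }
      r
    })
  }
  records <- lapply(records, expand_genera, dataset_taxa = dataset_taxa)
  keep <- vapply(records, `[[`, TRUE, "valid")
  for (r in records[!keep]) {
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      id = r$id, reason = paste(r$flags, collapse = "; "))
  }
  records <- records[keep]
  nonind <- detect_nonindependence(records)
  to_drop <- unique(stats::na.omit(nonind$drop))
  for (d in to_drop) {
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      id = d, reason = "non-independent subset of a more comprehensive study")
  }
  records <- records[!record_ids(records) %in% to_drop]
  overlap <- check_connectivity(records)
  issues <- validate_dataset(records, rules = rules, canonical = canonical)
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(id = character(), reason = character())
  list(records = records, dropped = dropped, nonindependence = nonind,
       overlap = overlap, issues = issues)
}
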