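test_that("the true-tree generator is deterministic with the promised shape", {
  t1 <- generate_true_tree(24, seed = 3)
  t2 <- generate_true_tree(24, seed = 3)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_identical(ape::Ntip(t1), 24L)
  expect_true(ape::is.binary(t1))
  expect_identical(length(clusters(generate_true_tree(64, seed = 4))), 62L)
  expect_identical(length(clusters(generate_true_tree(4, seed = 5))), 2L)
  # genus labels with epithets, genera forming clades
  expect_true(all(grepl("^Genus\\d+_species\\d+$", t1$tip.label)))
  genera <- unique(sub("_.*$", "", t1$tip.label))
  sets <- lapply(clusters(t1, include_trivial = TRUE), identity)
  for (g in genera) {
    members <- sort(t1$tip.label[startsWith(t1$tip.label, paste0(g, "_"))])
    expect_true(any(vapply(sets, function(s) identical(sort(s), members), TRUE)))
  }
})

test_that("sampled source trees restrict the true tree and stay connected", {
  cfg <- synthetic_config(n_taxa = 24, n_source_trees = 12, seed = 8)
  true_tree <- generate_true_tree(cfg$n_taxa, seed = cfg$seed)
  records <- sample_source_trees(true_tree, cfg)
  expect_length(records, 13)  # + seed taxonomy tree
  expect_true(check_connectivity(records)$passes)
  for (r in records[1:12]) {
    restricted <- prune_to_taxa(true_tree, r$tree$tip.label)
    expect_identical(cluster_keys(r$tree), cluster_keys(restricted))
    expect_true(ape::Ntip(r$tree) >= cfg$size_distribution[1])
    expect_true(ape::Ntip(r$tree) <= cfg$size_distribution[2])
  }
  seedrec <- records[[13]]
  expect_identical(seedrec$character_tags, "taxonomy")
  expect_identical(sort(seedrec$tree$tip.label), sort(true_tree$tip.label))
  expect_lt(resolution(seedrec$tree), 50)
})

test_that("one NNI perturbation changes at most two clusters", {
  cfg <- synthetic_config(n_taxa = 16, n_source_trees = 8,
                          size_distribution = c(10, 12),
                          conflict_nni_per_tree = 1, seed = 9)
  true_tree <- generate_true_tree(cfg$n_taxa, seed = cfg$seed)
  records <- sample_source_trees(true_tree, cfg)
  for (r in records[1:8]) {
    restricted <- prune_to_taxa(true_tree, r$tree$tip.label)
    diff <- length(setdiff(cluster_keys(r$tree), cluster_keys(restricted)))
    expect_lte(diff, 2L)
  }
})

test_that("name noise at zero proportions is the identity", {
  cfg <- synthetic_config(n_taxa = 16, n_source_trees = 8, seed = 10)
  true_tree <- generate_true_tree(cfg$n_taxa, seed = cfg$seed)
  records <- sample_source_trees(true_tree, cfg)
  noised <- apply_name_noise(records, cfg)
  expect_identical(nrow(noised$ground_truth$name_map), 0L)
  for (i in seq_along(records)) {
    expect_identical(write_newick(noised$records[[i]]$tree),
                     write_newick(records[[i]]$tree))
  }
})

test_that("full synonym noise renames every eligible leaf and inverts exactly", {
  cfg <- synthetic_config(n_taxa = 16, n_source_trees = 8, p_synonym = 1,
                          seed = 11)
  ds <- generate_dataset(cfg)
  for (r in ds$records) {
    if (identical(r$character_tags, "taxonomy")) next
    expect_true(all(grepl("cognatus", r$tree$tip.label)))
  }
  cur <- curate_dataset(ds$records, rules = ds$ground_truth$rules)
  ids <- record_ids(cur$records)
  for (r0 in ds$clean_records) {
    expect_identical(cluster_keys(cur$records[[match(r0$id, ids)]]$tree),
                     cluster_keys(r0$tree))
  }
})

test_that("planted duplicate studies are detected exactly", {
  cfg <- synthetic_config(n_taxa = 20, n_source_trees = 10,
                          duplicate_study_count = 3, seed = 12)
  ds <- generate_dataset(cfg)
  expect_identical(nrow(ds$ground_truth$duplicate_pairs), 3L)
  flagged <- detect_nonindependence(ds$records)
  expect_identical(nrow(flagged), 3L)
  expect_setequal(flagged$drop, ds$ground_truth$duplicate_pairs$clone)
})

test_that("dataset generation is byte-identical for a fixed seed", {
  cfg <- synthetic_config(n_taxa = 12, n_source_trees = 6, p_synonym = 0.2,
                          p_higher_taxon = 0.3, seed = 13)
  d1 <- file.path(tempdir(), "ds_rep1")
  d2 <- file.path(tempdir(), "ds_rep2")
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 3)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("dataset directories round-trip through read_dataset", {
  cfg <- synthetic_config(n_taxa = 12, n_source_trees = 6, seed = 14)
  dir <- file.path(tempdir(), "ds_io")
  ds <- generate_dataset(cfg, dir = dir)
  back <- read_dataset(dir)
  expect_identical(nrow(back$issues), 0L)
  expect_identical(record_ids(back$records), record_ids(ds$records))
  for (i in seq_along(ds$records)) {
    expect_identical(write_newick(back$records[[i]]$tree),
                     write_newick(ds$records[[i]]$tree))
    expect_identical(back$records[[i]]$character_tags,
                     ds$records[[i]]$character_tags)
  }
  # a tree without metadata (and vice versa) is reported
  writeLines(c(readLines(file.path(dir, "metadata.txt")),
               "[record]", "id = ghost"), file.path(dir, "metadata.txt"))
  back2 <- read_dataset(dir)
  expect_true("id_mismatch" %in% back2$issues$type)
})
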