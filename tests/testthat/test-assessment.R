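rec2 <- function(id, nwk, tags = "cytb", ...) {
  source_record(id, parse_newick(nwk), character_tags = tags, ...)
}

test_that("resolution follows the internal-node formula in both conventions", {
  expect_equal(resolution(parse_newick("((A,B),(C,D));")), 100)
  expect_equal(resolution(parse_newick("(A,B,C,D,E);")), 0)
  expect_equal(resolution(parse_newick("((A,B),C,D,E);")), 100 / 3)
  expect_equal(resolution(parse_newick("(A,B,C);"), convention = "inclusive"), 50)
  expect_error(resolution(parse_newick("(A,B);")), "at least 3")
  set.seed(41)
  for (i in 1:10) {
    t0 <- random_tree(sample(4:15, 1), p_polytomy = 0.4)
    r <- resolution(t0)
    expect_identical(r == 100, ape::is.binary(t0))
    expect_identical(r == 0, t0$Nnode == 1L)
  }
})

test_that("clade support uses the exact restricted-cluster rule", {
  records <- list(rec2("r1", "((A,B),C);"))
  expect_identical(clade_support(c("A", "B"), records)$status, "supported")
  expect_identical(clade_support(c("A", "D"), records)$status, "novel")
  # restriction rule: {A,B,E} restricts to {A,B}, a cluster of r1
  got <- clade_support(c("A", "B", "E"), records)
  expect_identical(got$status, "supported")
  expect_identical(got$supporting_ids[[1]], "r1")
  # the record's whole leaf set never counts as support
  expect_identical(clade_support(c("A", "B", "C"), records)$status, "novel")
  # compatibility-based support is more permissive
  expect_identical(clade_support(c("A", "C"), records)$status, "novel")
  expect_identical(clade_support(c("A", "C"), records, compatible = TRUE)$status,
                   "novel")  # {A,C} conflicts with cluster {A,B}
  expect_identical(
    clade_support(c("B", "C"), list(rec2("r1", "(A,B,C,D);")),
                  compatible = TRUE)$status, "supported")
})

test_that("clade support is invariant under consistent relabelling", {
  records <- list(rec2("r1", "(((A,B),C),D);"), rec2("r2", "((B,C),(D,E));",
                                                     tags = "nd2"))
  map <- c(A = "W1", B = "W2", C = "W3", D = "W4", E = "W5")
  relab <- lapply(records, function(r) {
    r$tree$tip.label <- unname(map[r$tree$tip.label])
    r
  })
  for (cl in list(c("A", "B"), c("B", "C", "D"), c("A", "E"))) {
    expect_identical(clade_support(cl, records)$status,
                     clade_support(unname(map[cl]), relab)$status)
  }
})

test_that("novel_clades flags unsupported clades and affected taxa", {
  src <- rec2("r1", "(((A,B),C),(D,E));")
  none <- novel_clades(src$tree, list(src))
  expect_identical(sum(none$clades$status == "novel"), 0L)
  expect_equal(none$pct_taxa_in_novel_clades, 0)
  # a taxon grafted where no source places it yields a novel parent clade
  supertree <- parse_newick("(((A,(B,X)),C),(D,E));")
  nov <- novel_clades(supertree, list(src))
  expect_true("B|X" %in% nov$clades$cluster[nov$clades$status == "novel"])
  expect_true(nov$taxa$in_novel_clade[nov$taxa$taxon == "X"])
  # removing a record can only shrink or preserve support lists
  records <- list(src, rec2("r2", "((A,B),(C,D));", tags = "nd2"))
  full <- novel_clades(supertree, records)
  less <- novel_clades(supertree, list(src))
  for (i in seq_len(nrow(full$clades))) {
    expect_true(all(less$clades$supporting_ids[[i]] %in%
                      full$clades$supporting_ids[[i]]))
  }
})

test_that("rogue reports quantify the four warning signs", {
  r1 <- rec2("r1", "((A,B,X),(C,D));")
  out <- rogue_report("X", list(r1))
  expect_identical(out$occurrence_count, 1L)
  expect_identical(out$distinct_positions, 1L)
  expect_equal(out$polytomy_fraction, 1)
  expect_equal(out$outgroup_fraction, 0)
  absent <- rogue_report("Zz", list(r1))
  expect_identical(unname(unlist(absent[, -1])), c(0, 0, 0, 0))
  # variable position across records, and outgroup usage
  r2 <- rec2("r2", "((A,B),(C,X));", tags = "nd2", outgroup_taxa = "X")
  r3 <- rec2("r3", "((A,X),(C,D));", tags = "rag1")
  multi <- rogue_report("X", list(r1, r2, r3), reference_taxa = c("A", "B", "C", "D"))
  expect_identical(multi$occurrence_count, 3L)
  expect_identical(multi$distinct_positions, 3L)
  expect_equal(multi$polytomy_fraction, 1 / 3)
  expect_equal(multi$outgroup_fraction, 1 / 3)
  tbl <- rogue_table(list(r1, r2, r3))
  expect_identical(nrow(tbl), 5L)
})

test_that("availability matrix orders by frequency and conserves counts", {
  r1 <- rec2("r1", "((A_a,B_b),C_c);")
  r2 <- rec2("r2", "(B_b,C_c);", tags = "nd2")
  av <- availability_matrix(list(r1, r2))
  expect_identical(rownames(av$matrix), c("B_b", "C_c", "A_a"))
  expect_identical(av$taxon_counts$n_trees, c(2L, 2L, 1L))
  expect_identical(sum(av$matrix), 5L)  # = total leaf count over records
  expect_identical(av$tree_counts$n_taxa[match(c("r1", "r2"), av$tree_counts$id)],
                   vapply(list(r1, r2), function(r) ape::Ntip(r$tree), 0L))
  single <- availability_matrix(list(r1))
  expect_true(all(single$taxon_counts$n_trees == 1L))
  expect_s3_class(autoplot(av), "ggplot")
  f <- tempfile(fileext = ".mtx")
  write_availability(av, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".taxa")))
  trip <- utils::read.table(f, skip = 2)
  expect_identical(nrow(trip), 5L)
})
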