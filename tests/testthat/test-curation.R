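rec <- function(id, nwk, tags = "cytb", ...) {
  source_record(id, parse_newick(nwk), character_tags = tags, ...)
}

test_that("standardize_names renames, deletes, and collapses synonym duplicates", {
  r <- rec("x", "((Corvus_corone_cornix,Pica_pica),Gallus_gallus);")
  rules <- substitution_rules("Corvus_corone_cornix", list("Corvus_cornix"))
  expect_identical(
    write_newick(standardize_names(r, rules)$tree),
    "((Corvus_cornix,Pica_pica),Gallus_gallus);")
  # no matching rules: unchanged
  expect_identical(write_newick(standardize_names(r,
    substitution_rules("Zzz_zzz", list("Yyy_yyy")))$tree), write_newick(r$tree))
  # two leaves becoming one synonym: single copy kept (closest to root), warning
  r2 <- rec("y", "(((A_a,B_b),C_c),D_d);")
  rules2 <- substitution_rules(c("A_a", "C_c"), list("Syn_syn", "Syn_syn"))
  expect_warning(out <- standardize_names(r2, rules2), "duplicate")
  expect_identical(sum(out$tree$tip.label == "Syn_syn"), 1L)
  expect_identical(write_newick(out$tree), "((B_b,Syn_syn),D_d);")
  # deletion below two leaves flags the record invalid
  r3 <- rec("z", "(A_a,B_b);")
  out3 <- standardize_names(r3, substitution_rules("A_a", list(character(0))))
  expect_false(out3$valid)
  # expand rules are rejected here
  expect_error(standardize_names(r, substitution_rules("F", list(c("a", "b")))),
               "rename/delete")
})

test_that("substitute_higher_taxon expands to in-dataset constituents only", {
  r <- rec("x", "((Corvidae,(X_x,Y_y)),Z_z);")
  rule <- substitution_rules("Corvidae", list(c("Corvus_corax", "Pica_pica")))
  dataset <- c("Corvus_corax", "Pica_pica", "X_x", "Y_y", "Z_z")
  expect_identical(write_newick(substitute_higher_taxon(r, rule, dataset)$tree),
                   "(((Corvus_corax,Pica_pica),(X_x,Y_y)),Z_z);")
  # singleton intersection renames
  out <- substitute_higher_taxon(r, rule, c("Corvus_corax", "X_x", "Y_y", "Z_z"))
  expect_true("Corvus_corax" %in% out$tree$tip.label)
  expect_false("Corvidae" %in% out$tree$tip.label)
  # empty intersection prunes with a warning, and the filtering is logged
  expect_warning(out2 <- substitute_higher_taxon(r, rule, c("X_x", "Y_y", "Z_z")),
                 "pruned")
  expect_false("Corvidae" %in% out2$tree$tip.label)
  expect_match(paste(out2$flags, collapse = " "), "filtered")
})

test_that("expand_genera handles known, singleton, and unknown genera", {
  dataset <- c("Gallus_gallus", "Gallus_varius", "Pica_pica", "Corvus_corax")
  r <- rec("x", "((Gallus,Pica_pica),Corvus_corax);")
  out <- expand_genera(r, dataset_taxa = dataset)
  expect_identical(write_newick(out$tree),
                   "(Corvus_corax,((Gallus_gallus,Gallus_varius),Pica_pica));")
  r2 <- rec("y", "((Pica,Gallus_gallus),Corvus_corax);")
  out2 <- expand_genera(r2, dataset_taxa = dataset)
  expect_true("Pica_pica" %in% out2$tree$tip.label)
  r3 <- rec("z", "((Xyzus,Gallus_gallus),Corvus_corax);")
  out3 <- expand_genera(r3, dataset_taxa = dataset)
  expect_match(paste(out3$flags, collapse = " "), "unknown genus 'Xyzus'")
})

test_that("permute_paraphyletic enumerates, dedupes, and collapses monophyly", {
  pp <- permute_paraphyletic(parse_newick("((A1,B),(A2,C));"), c("A1", "A2"), "A")
  expect_setequal(vapply(pp, write_newick, ""),
                  c("((A,B),C);", "((A,C),B);"))
  mono <- permute_paraphyletic(parse_newick("((A1,A2),B);"), c("A1", "A2"), "A")
  expect_identical(vapply(mono, write_newick, ""), "(A,B);")
  # symmetric positions collapse to fewer permutations than occurrences
  sym <- permute_paraphyletic(parse_newick("((A1,(A2,B)),C);"),
                              c("A1", "A2"), "A")
  expect_identical(vapply(sym, write_newick, ""), "((A,B),C);")
  expect_error(permute_paraphyletic(parse_newick("(A,(B,C));"), "Z", "P"),
               "no leaves")
  for (t in pp) expect_setequal(t$tip.label, c("A", "B", "C"))
})

test_that("mini-supertrees summarise permutations and pass identity cases", {
  perms <- list(parse_newick("((A,B),C);"), parse_newick("((A,C),B);"))
  expect_identical(write_newick(build_mini_supertree(perms)), "(A,B,C);")
  one <- parse_newick("((A,B),C);")
  expect_identical(write_newick(build_mini_supertree(list(one))),
                   write_newick(one))
  expect_identical(write_newick(build_mini_supertree(list(one, one))),
                   write_newick(one))
})

test_that("non-independence detection follows the subset/identical verdicts", {
  r1 <- rec("r1", "((A_a,B_b),C_c);", tags = "cytb")
  r2 <- rec("r2", "(A_a,B_b);", tags = "cytb")
  out <- detect_nonindependence(list(r1, r2))
  expect_identical(out$relation, "subset")
  expect_identical(out$drop, "r2")
  # symmetric in record order
  out_rev <- detect_nonindependence(list(r2, r1))
  expect_identical(out_rev$drop, "r2")
  r3 <- rec("r3", "((A_a,B_b),C_c);", tags = "cytb")
  ident <- detect_nonindependence(list(r1, r3))
  expect_identical(ident$relation, "identical")
  expect_true(is.na(ident$drop))
  # different characters: no flag
  r4 <- rec("r4", "((A_a,B_b),C_c);", tags = "morphology")
  expect_identical(nrow(detect_nonindependence(list(r1, r4))), 0L)
})

test_that("connectivity reporting partitions records by >= 2 shared taxa", {
  t1 <- rec("T1", "((A_a,B_b),C_c);")
  t2 <- rec("T2", "((B_b,C_c),D_d);", tags = "nd2")
  t3 <- rec("T3", "(E_e,F_f);", tags = "rag1")
  bad <- check_connectivity(list(t1, t2, t3))
  expect_false(bad$passes)
  expect_length(bad$components, 2)
  t3b <- rec("T3", "((C_c,D_d),E_e);", tags = "rag1")
  good <- check_connectivity(list(t1, t2, t3b))
  expect_true(good$passes)
  expect_identical(nrow(good$edges), 2L)
  expect_true(check_connectivity(list(t1))$passes)
})

test_that("validate_dataset reports problem taxa, id clashes, and unknown names", {
  r1 <- rec("r1", "((A_a,B_b),C_c);")
  rules <- substitution_rules("Fam", list(c("A_a", "Zz_zz")))
  rep1 <- validate_dataset(list(r1), rules = rules)
  expect_identical(rep1$type, "problem_taxon")
  expect_match(rep1$detail, "Zz_zz")
  expect_identical(nrow(validate_dataset(list(r1))), 0L)
  rep2 <- validate_dataset(list(r1, r1))
  expect_true("duplicate_id" %in% rep2$type)
  rep3 <- validate_dataset(list(r1), canonical = c("A_a", "B_b"))
  expect_true("unknown_taxon" %in% rep3$type)
  expect_true("C_c" %in% rep3$item)
})

test_that("the full curation pipeline is a no-op on a clean dataset", {
  ds <- generate_dataset(synthetic_config(n_taxa = 16, n_source_trees = 8,
                                          seed = 90))
  cur <- curate_dataset(ds$records)
  expect_identical(nrow(cur$dropped), 0L)
  expect_identical(nrow(cur$issues), 0L)
  expect_true(cur$overlap$passes)
  ids <- record_ids(cur$records)
  for (r0 in ds$records) {
    expect_identical(write_newick(cur$records[[match(r0$id, ids)]]$tree),
                     write_newick(r0$tree))
  }
})
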