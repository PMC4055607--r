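quartet_matrix <- function(cells) {
  taxa <- c(mrp_outgroup_name(), "A", "B", "C", "D")
  manual_matrix(matrix(cells, ncol = 1, dimnames = list(taxa, NULL)))
}

test_that("tree_length matches brute-force enumeration on worked cases", {
  tr <- parse_newick("(MRP_Outgroup,((A,B),(C,D)));")
  m1 <- quartet_matrix(c("0", "1", "1", "0", "0"))
  states <- c(MRP_Outgroup = 0L, A = 1L, B = 1L, C = 0L, D = 0L)
  expect_identical(tree_length(tr, m1), oracle_column_length(tr, states))
  expect_identical(tree_length(tr, m1), 1L)
  m2 <- quartet_matrix(c("0", "1", "?", "0", "0"))
  states2 <- c(MRP_Outgroup = 0L, A = 1L, B = NA, C = 0L, D = 0L)
  expect_identical(tree_length(tr, m2), oracle_column_length(tr, states2))
  expect_identical(tree_length(tr, m2), 1L)
  m3 <- quartet_matrix(c("0", "0", "0", "0", "0"))
  expect_identical(tree_length(tr, m3), 0L)
  expect_error(tree_length(parse_newick("(A,(B,C));"), m1), "differ")
})

test_that("tree_length equals the enumeration oracle on random cases", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    taxa <- c(mrp_outgroup_name(), sort(sprintf("T%02d", seq_len(n - 1))))
    tr <- random_tree_on(taxa, p_polytomy = ifelse(i %% 2 == 0, 0.3, 0))
    col <- random_column(taxa)
    m <- manual_matrix(col)
    states <- col_states(col)
    expect_identical(tree_length(tr, m), oracle_column_length(tr, states))
  }
})

test_that("tree_length respects the informative-column bounds", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    taxa <- c(mrp_outgroup_name(), sort(sprintf("T%02d", seq_len(n - 1))))
    st <- do.call(cbind, replicate(6, random_column(taxa), simplify = FALSE))
    m <- manual_matrix(st)
    tr <- random_tree_on(taxa)
    ones <- colSums(st == "1")
    zeros <- colSums(st == "0")
    lower <- sum(ones >= 1 & zeros >= 1)
    upper <- sum(pmin(ones, zeros + 1))
    len <- tree_length(tr, m)
    expect_gte(len, lower)
    expect_lte(len, upper)
  }
})

test_that("tree_length agrees with phangorn's Fitch score on binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    taxa <- c(mrp_outgroup_name(), sort(sprintf("T%02d", seq_len(n - 1))))
    st <- do.call(cbind, replicate(8, random_column(taxa), simplify = FALSE))
    m <- manual_matrix(st)
    tr <- random_tree_on(taxa)
    pd <- phangorn::phyDat(m$states, type = "USER", levels = c("0", "1"),
                           ambiguity = "?")
    expect_identical(tree_length(tr, m),
                     as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("stepwise addition is deterministic and optimal on compatible data", {
  src <- parse_newick("(((A,B),(C,D)),((E,F),G));")
  rec <- source_record("s", src, character_tags = "cytb")
  m <- build_matrix(list(rec))
  t1 <- stepwise_addition(m, seed = 9)
  t2 <- stepwise_addition(m, seed = 9)
  expect_identical(write_newick(t1), write_newick(t2))
  # compatible matrix: greedy addition attains the perfect-fit length
  expect_identical(tree_length(t1, m), ncol(m$states))
})

test_that("exhaustive search enumerates all rooted shapes and bounds the heuristic", {
  r1 <- source_record("r1", parse_newick("((A,B),(C,E));"), character_tags = "a")
  r2 <- source_record("r2", parse_newick("((B,D),(C,E));"), character_tags = "b")
  m <- build_matrix(list(r1, r2))  # 5 ingroup taxa
  ex <- exhaustive_search(m)
  expect_identical(ex$n_trees_scored, 105)  # (2n-3)!! for n = 5
  hs <- heuristic_search(m, search_config(seed = 3, n_random_starts = 2))
  expect_lte(ex$best_length, hs$best_length)
  # compatible single-source matrix: optimum equals the column count
  m1 <- build_matrix(list(r1))
  expect_identical(exhaustive_search(m1)$best_length, ncol(m1$states))
  expect_error(exhaustive_search(build_matrix(list(source_record(
    "big", parse_newick(paste0("(", paste(LETTERS[1:12], collapse = ","), ",(X,Y));")),
    character_tags = "x")))), "limited to 9")
})

test_that("heuristic search recovers a single binary source tree exactly", {
  src <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  m <- build_matrix(list(source_record("s", src, character_tags = "cytb")))
  res <- heuristic_search(m, search_config(seed = 4, n_random_starts = 2))
  expect_identical(res$best_length, ncol(m$states))
  with_og <- parse_newick(paste0("(MRP_Outgroup,", sub(";$", ");", write_newick(src))))
  expect_true(write_newick(with_og) %in% vapply(res$mpts, write_newick, ""))
})

test_that("two conflicting quartet characters give length 3 and both resolutions", {
  r1 <- source_record("r1", parse_newick("((A,B),C,D);"), character_tags = "a")
  r2 <- source_record("r2", parse_newick("((A,C),B,D);"), character_tags = "b")
  m <- build_matrix(list(r1, r2))
  expect_identical(ncol(m$states), 2L)
  ex <- exhaustive_search(m)
  expect_identical(ex$best_length, 3L)
  mpt_keys <- vapply(lapply(ex$mpts, root_on_outgroup), cluster_keys,
                     character(2))
  expect_true(any(apply(mpt_keys, 2, function(k) "A|B" %in% k)))
  expect_true(any(apply(mpt_keys, 2, function(k) "A|C" %in% k)))
  hs <- heuristic_search(m, search_config(seed = 1, n_random_starts = 3))
  expect_identical(hs$best_length, 3L)
})

test_that("search results are deterministic for a fixed configuration", {
  set.seed(34)
  ds <- generate_dataset(synthetic_config(n_taxa = 10, n_source_trees = 6,
                                          size_distribution = c(5, 8),
                                          conflict_nni_per_tree = 1,
                                          include_seed_tree = FALSE, seed = 77))
  m <- build_matrix(ds$records)
  cfg <- search_config(seed = 5, n_random_starts = 2)
  a <- heuristic_search(m, cfg)
  b <- heuristic_search(m, cfg)
  expect_identical(a$best_length, b$best_length)
  expect_identical(vapply(a$mpts, write_newick, ""),
                   vapply(b$mpts, write_newick, ""))
  expect_identical(a$trace, b$trace)
})

test_that("strict consensus intersects cluster sets (and matches ape)", {
  expect_identical(write_newick(strict_consensus(list(
    parse_newick("((A,B),(C,D));"), parse_newick("((A,B),C,D);")))),
    "((A,B),C,D);")
  expect_identical(write_newick(strict_consensus(list(
    parse_newick("((A,B),(C,D));"), parse_newick("((A,C),(B,D));")))),
    "(A,B,C,D);")
  one <- parse_newick("((A,B),C);")
  expect_identical(write_newick(strict_consensus(list(one))), write_newick(one))
  expect_error(strict_consensus(list(one, parse_newick("((A,B),D);"))),
               "differing leaf sets")
  set.seed(35)
  for (i in 1:10) {
    taxa <- sprintf("T%02d", 1:8)
    ts <- lapply(1:3, function(j) random_tree_on(taxa))
    mine <- strict_consensus(ts)
    theirs <- ape::consensus(ts, p = 1, rooted = TRUE)
    expect_identical(sort(cluster_keys(mine)), sort(cluster_keys(theirs)))
  }
})

test_that("agreement subtree is a true agreement set bounded by the exact MAST", {
  a <- parse_newick("((A,B),(C,D));")
  b <- parse_newick("((A,C),(B,D));")
  ag <- agreement_subtree(list(a, b))
  expect_identical(length(attr(ag, "taxa")), 2L)  # frozen from subset enumeration
  mx <- mast_exact(list(a, b))
  expect_identical(ape::Ntip(mx), 2L)
  t0 <- parse_newick("(((A,B),C),(D,E));")
  expect_identical(write_newick(agreement_subtree(list(t0, t0))),
                   write_newick(t0))
  expect_identical(ape::Ntip(mast_exact(list(t0, t0))), 5L)
  # star vs binary: restrictions only agree on pairs
  star <- parse_newick("(A,B,C,D,E);")
  expect_identical(ape::Ntip(mast_exact(list(star, t0))), 2L)
  set.seed(36)
  for (i in 1:20) {
    taxa <- sprintf("T%02d", 1:8)
    ts <- list(random_tree_on(taxa), random_tree_on(taxa))
    ag <- agreement_subtree(list(validate_tree(ts[[1]]), validate_tree(ts[[2]])))
    mx <- mast_exact(ts)
    expect_lte(ape::Ntip(ag), ape::Ntip(mx))
    S <- attr(ag, "taxa")
    expect_identical(write_newick(prune_to_taxa(ts[[1]], S)),
                     write_newick(prune_to_taxa(ts[[2]], S)))
  }
})

test_that("root_on_outgroup extracts the ingroup and is idempotent", {
  expect_identical(write_newick(root_on_outgroup(
    parse_newick("((OUT,A),(B,C));"), "OUT")), "(A,(B,C));")
  expect_identical(write_newick(root_on_outgroup(
    parse_newick("(OUT,(A,(B,C)));"), "OUT")), "(A,(B,C));")
  expect_error(root_on_outgroup(parse_newick("(A,(B,C));"), "OUT"),
               "not present")
  set.seed(37)
  for (i in 1:15) {
    taxa <- c("OUT", sprintf("T%02d", 1:6))
    tr <- random_tree_on(taxa)
    once <- root_on_outgroup(tr, "OUT", drop = FALSE)
    twice <- root_on_outgroup(once, "OUT", drop = FALSE)
    expect_identical(write_newick(twice), write_newick(once))
  }
})

test_that("compatible overlapping sources put every source cluster in the consensus", {
  set.seed(38)
  for (i in 1:5) {
    ds <- generate_dataset(synthetic_config(n_taxa = 8, n_source_trees = 5,
                                            size_distribution = c(4, 7),
                                            include_seed_tree = TRUE,
                                            seed = 400 + i))
    m <- build_matrix(ds$records)
    ex <- exhaustive_search(m, max_keep = 20000)
    expect_identical(ex$best_length, ncol(m$states))  # perfect fit
    mpts <- lapply(utils::head(ex$mpts, 25), root_on_outgroup)
    for (t in mpts) {
      for (r in ds$records) {
        restricted <- cluster_keys(prune_to_taxa(t, r$tree$tip.label))
        for (k in cluster_keys(r$tree)) expect_true(k %in% restricted)
      }
    }
  }
})

test_that("tidy and glance summarise search results", {
  m <- build_matrix(list(
    source_record("r1", parse_newick("((A,B),(C,D));"), character_tags = "a")))
  res <- heuristic_search(m, search_config(seed = 1, n_random_starts = 1))
  td <- tidy(res)
  expect_true(all(c("tree", "length", "n_leaves", "newick") %in% names(td)))
  expect_true(all(td$length == res$best_length))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$best_length, res$best_length)
  expect_s3_class(autoplot(res), "ggplot")
})
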