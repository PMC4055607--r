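# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force and independent of the package's
# own algorithms: enumeration over explicit state assignments, direct cluster
# intersections, and ape's tree simulators.

# random rooted tree via ape, optionally with polytomies, no branch lengths
random_tree <- function(n, p_polytomy = 0) {
  phy <- ape::rtree(n)
  if (p_polytomy > 0 && phy$Nnode > 1) {
    internal <- which(phy$edge[, 2] > n)
    phy$edge.length[] <- 1
    hit <- internal[stats::runif(length(internal)) < p_polytomy]
    phy$edge.length[hit] <- 0
    phy <- ape::di2multi(phy, tol = 1e-8)
  }
  phy$edge.length <- NULL
  phy
}

# minimum state changes for one binary column by enumeration over all
# assignments to internal nodes and missing-state leaves
oracle_column_length <- function(phy, states) {
  nt <- ape::Ntip(phy)
  m <- nt + phy$Nnode
  fixed <- states[phy$tip.label]
  free <- c(which(is.na(fixed)), (nt + 1L):m)
  k <- length(free)
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    assign <- integer(m)
    assign[seq_len(nt)] <- fixed
    assign[free] <- as.integer(intToBits(mask))[seq_len(k)]
    best <- min(best, sum(assign[phy$edge[, 1]] != assign[phy$edge[, 2]]))
  }
  as.integer(best)
}

# brute-force restriction of a cluster set to a taxon subset
oracle_restricted_clusters <- function(tree, keep) {
  cl <- clusters(tree)
  res <- lapply(cl, function(c) sort(intersect(c, keep)))
  res <- Filter(function(c) length(c) >= 2 && length(c) < length(keep), res)
  sort(unique(vapply(res, paste, "", collapse = "|")))
}

cluster_keys <- function(tree) {
  vapply(clusters(tree), paste, "", collapse = "|")
}

# an mrp_matrix built directly from explicit cells (bypasses encode_tree)
manual_matrix <- function(states) {
  taxa <- rownames(states)
  prov <- tibble::tibble(source_id = character(0), node = integer(0),
                         cluster = character(0), column = integer(0))
  mrptree:::new_mrp_matrix(taxa, states, prov)
}

# random column over given taxa: outgroup 0, others 0/1/?
random_column <- function(taxa) {
  s <- sample(c("0", "1", "?"), length(taxa), replace = TRUE)
  s[taxa == mrp_outgroup_name()] <- "0"
  matrix(s, ncol = 1, dimnames = list(taxa, NULL))
}

# random tree whose leaves are the given taxa (outgroup placement arbitrary)
random_tree_on <- function(taxa, p_polytomy = 0) {
  phy <- random_tree(length(taxa), p_polytomy)
  phy$tip.label <- sample(taxa)
  phy
}

# named 0/1/NA state vector from a one-column character matrix
col_states <- function(col) {
  s <- col[, 1]
  out <- rep(NA_integer_, length(s))
  out[s != "?"] <- as.integer(s[s != "?"])
  names(out) <- rownames(col)
  out
}

expect_same_clusters <- function(a, b) {
  expect_identical(cluster_keys(a), cluster_keys(b))
}
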