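# Internal search-tree representation: list(par, taxon)
#  - par:   integer parent vector over node ids (0 = root, NA = unused slot)
#  - taxon: integer row index into the matrix taxon list (NA = internal node)
# Leaves are nodes 1..T (node i carries taxon row i), internal nodes T+1..2T-1.
# All randomness is drawn inside with_seed() so the session RNG is untouched.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

tt_par0 <- function(par) {
  p <- par - 1L
  p[is.na(par)] <- -2L
  p[!is.na(par) & par == 0L] <- -1L
  p
}

tt_tax0 <- function(taxon) {
  t0 <- taxon - 1L
  t0[is.na(t0)] <- -1L
  t0
}

tt_score <- function(tt, sti) {
  sankoff_total_cpp(tt_par0(tt$par), tt_tax0(tt$taxon), sti)
}

tt_score_many <- function(tts, taxon, sti) {
  sankoff_many_cpp(lapply(tts, function(t) tt_par0(t$par)), tt_tax0(taxon), sti)
}

tt_root <- function(tt) which(!is.na(tt$par) & tt$par == 0L)

tt_children <- function(tt) {
  m <- length(tt$par)
  ch <- vector("list", m)
  ok <- which(!is.na(tt$par) & tt$par > 0L)
  sp <- split(ok, tt$par[ok])
  ch[as.integer(names(sp))] <- sp
  ch
}

tt_descendants <- function(tt, v) {
  ch <- tt_children(tt)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, x)
    stack <- c(stack, ch[[x]])
  }
  out
}

tt_from_phylo <- function(phy, taxa) {
  nt <- ape::Ntip(phy)
  m <- nt + phy$Nnode
  par <- rep(NA_integer_, m)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par[tree_root(phy)] <- 0L
  taxon <- rep(NA_integer_, m)
  taxon[seq_len(nt)] <- match(phy$tip.label, taxa)
  if (anyNA(taxon[seq_len(nt)])) stop("tree leaf not present in taxon list")
  list(par = par, taxon = taxon)
}

tt_to_phylo <- function(tt, taxa) {
  used <- which(!is.na(tt$par))
  tips <- used[!is.na(tt$taxon[used])]
  ints <- used[is.na(tt$taxon[used])]
  root <- tt_root(tt)
  ints <- c(root, setdiff(ints, root))
  nt <- length(tips)
  map <- integer(length(tt$par))
  map[tips] <- seq_len(nt)
  map[ints] <- nt + seq_along(ints)
  kids <- used[tt$par[used] > 0L]
  edge <- cbind(map[tt$par[kids]], map[kids])
  phy <- structure(list(edge = edge,
                        tip.label = taxa[tt$taxon[tips]],
                        Nnode = length(ints)),
                   class = "phylo")
  validate_tree(ape::reorder.phylo(phy, "cladewise"))
}

# canonical serialisation used for deduplication of search trees
tt_key <- function(tt, taxa) {
  ch <- tt_children(tt)
  rec <- function(nd) {
    if (!is.na(tt$taxon[nd])) {
      lab <- taxa[tt$taxon[nd]]
      return(c(lab, lab))
    }
    subs <- lapply(ch[[nd]], rec)
    mins <- vapply(subs, `[`, "", 2)
    o <- order(mins)
    c(paste0("(", paste(vapply(subs, `[`, "", 1)[o], collapse = ","), ")"),
      mins[o[1]])
  }
  rec(tt_root(tt))[1]
}

# rooted NNI: for each internal edge (p, v) exchange v's sibling with one of
# v's children; the outgroup never moves (its sibling edge is skipped)
tt_nni_neighbors <- function(tt, outnode) {
  ch <- tt_children(tt)
  res <- list()
  for (v in which(!is.na(tt$par) & is.na(tt$taxon))) {
    p <- tt$par[v]
    if (is.na(p) || p == 0L) next
    sib <- setdiff(ch[[p]], v)
    if (length(sib) != 1L || sib == outnode) next
    for (cc in ch[[v]]) {
      q <- tt$par
      q[cc] <- p
      q[sib] <- v
      res[[length(res) + 1L]] <- list(par = q, taxon = tt$taxon)
    }
  }
  res
}

# rooted SPR with the outgroup held basal: prune any node below the root's
# children, regraft on any edge outside the pruned subtree
tt_spr_neighbors <- function(tt, outnode) {
  ch <- tt_children(tt)
  root <- tt_root(tt)
  used <- which(!is.na(tt$par))
  res <- list()
  for (v in used) {
    p <- tt$par[v]
    if (p == 0L || p == root) next
    g <- tt$par[p]
    sib <- setdiff(ch[[p]], v)
    if (length(sib) != 1L) next
    sub <- tt_descendants(tt, v)
    forbidden <- c(sub, root, outnode, sib, p)
    for (w in setdiff(used, forbidden)) {
      q <- tt$par
      q[sib] <- g
      q[p] <- q[w]
      q[w] <- p
      res[[length(res) + 1L]] <- list(par = q, taxon = tt$taxon)
    }
  }
  res
}

tt_neighbors <- function(tt, outnode, moves) {
  out <- list()
  if ("NNI" %in% moves) out <- c(out, tt_nni_neighbors(tt, outnode))
  if ("SPR" %in% moves) out <- c(out, tt_spr_neighbors(tt, outnode))
  out
}
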