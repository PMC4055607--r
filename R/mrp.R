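#' Reserved name of the hypothetical all-zero outgroup
#'
#' The Baum-Ragan matrix is rooted with an artificial outgroup scored 0 for
#' every column; this name is reserved and may not occur as a real taxon.
#'
#' @return The reserved taxon name.
#' @export
mrp_outgroup_name <- function() "MRP_Outgroup"

#' Baum-Ragan encoding of one source tree
#'
#' One binary pseudo-character per non-trivial cluster (the root, an all-ones
#' uninformative column, is excluded): taxa subtended by the node are scored
#' 1, the tree's other taxa 0, taxa absent from the tree `?`, and the
#' hypothetical outgroup 0.
#'
#' @param tree A `phylo` object.
#' @param universe Character vector of all taxa in the dataset (the tree's
#'   leaves must be a subset).
#' @return A character matrix with one row per `universe` taxon plus the
#'   outgroup (first row) and one column per cluster; attribute `"clusters"`
#'   holds the encoded clusters. Zero columns if the tree has no internal
#'   structure.
#' @export
encode_tree <- function(tree, universe) {
  tree <- validate_tree(tree)
  universe <- sort(unique(universe))
  if (mrp_outgroup_name() %in% universe) {
    stop("the reserved outgroup name collides with a real taxon")
  }
  if (!all(tree$tip.label %in% universe)) {
    stop("tree leaves outside the taxon universe: ",
         paste(setdiff(tree$tip.label, universe), collapse = ", "))
  }
  taxa <- c(mrp_outgroup_name(), universe)
  cl <- if (ape::Ntip(tree) >= 3L) clusters(tree) else list()
  mat <- matrix(character(0), nrow = length(taxa), ncol = length(cl),
                dimnames = list(taxa, NULL))
  if (length(cl)) {
    mat[] <- "?"
    mat[tree$tip.label, ] <- "0"
    for (j in seq_along(cl)) mat[cl[[j]], j] <- "1"
    mat[mrp_outgroup_name(), ] <- "0"
  } else {
    message("tree contributes no informative columns (no non-trivial clusters)")
  }
  attr(mat, "clusters") <- cl
  mat
}

#' Build the MRP matrix for a curated dataset
#'
#' Concatenates the Baum-Ragan columns of every record's tree over the union
#' of all leaf sets. Taxa are ordered lexicographically with the hypothetical
#' outgroup first; per-column provenance (source record and node) is kept.
#'
#' @param records List of [source_record] objects (curated: canonical names).
#' @return An `mrp_matrix`: `taxa`, `states` (character matrix in
#'   `{"0","1","?"}`), and a `provenance` tibble.
#' @export
build_matrix <- function(records) {
  records <- as_record_list(records)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  universe <- sort(unique(unlist(lapply(records, function(r) r$tree$tip.label))))
  taxa <- c(mrp_outgroup_name(), universe)
  cols <- list()
  prov <- list()
  for (r in records) {
    enc <- encode_tree(r$tree, universe)
    if (ncol(enc)) {
      cols[[length(cols) + 1L]] <- enc[taxa, , drop = FALSE]
      prov[[length(prov) + 1L]] <- tibble::tibble(
        source_id = r$id, node = seq_len(ncol(enc)),
        cluster = vapply(attr(enc, "clusters"), cluster_key, ""))
    }
  }
  states <- if (length(cols)) do.call(cbind, cols) else
    matrix(character(0), nrow = length(taxa), dimnames = list(taxa, NULL))
  provenance <- if (length(prov)) dplyr::bind_rows(prov) else
    tibble::tibble(source_id = character(), node = integer(), cluster = character())
  provenance$column <- seq_len(nrow(provenance))
  new_mrp_matrix(taxa, states, provenance)
}

new_mrp_matrix <- function(taxa, states, provenance) {
  dimnames(states) <- list(taxa, NULL)
  x <- structure(list(taxa = taxa, states = states, provenance = provenance),
                 class = "mrp_matrix")
  validate_mrp_matrix(x)
}

validate_mrp_matrix <- function(x) {
  st <- x$states
  if (!all(st %in% c("0", "1", "?"))) stop("matrix cells must be 0, 1 or ?")
  og <- match(mrp_outgroup_name(), x$taxa)
  if (is.na(og)) stop("matrix lacks the hypothetical outgroup row")
  if (ncol(st) && !all(st[og, ] == "0")) stop("outgroup row must be all zero")
  x
}

states_int <- function(matrix) {
  sti <- matrix(2L, nrow = nrow(matrix$states), ncol = ncol(matrix$states))
  sti[matrix$states == "0"] <- 0L
  sti[matrix$states == "1"] <- 1L
  sti
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat(sprintf("MRP matrix: %d taxa (incl. outgroup) x %d binary columns\n",
              length(x$taxa), ncol(x$states)))
  cat(sprintf("  from %d source trees\n", length(unique(x$provenance$source_id))))
  qs <- if (length(x$states)) mean(x$states == "?") else NA_real_
  cat(sprintf("  missingness: %.1f%%\n", 100 * qs))
  invisible(x)
}

#' Write an MRP matrix to TNT or NEXUS format
#'
#' TNT output uses the `xread` dialect (non-interleaved); NEXUS output uses a
#' `DATA` block with `DATATYPE=STANDARD`, `SYMBOLS="0 1"`, `MISSING=?`.
#'
#' @param matrix An `mrp_matrix`.
#' @param path Output file path.
#' @param format `"tnt"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("tnt", "nexus")) {
  format <- match.arg(format)
  validate_mrp_matrix(matrix)
  taxa <- gsub("[ \t]+", "_", matrix$taxa)
  rows <- apply(matrix$states, 1, paste, collapse = "")
  if (!length(rows)) rows <- rep("", length(taxa))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tnt") {
    writeLines("xread", con)
    writeLines(sprintf("%d %d", ncol(matrix$states), length(taxa)), con)
    writeLines(paste(taxa, rows), con)
    writeLines(";", con)
    writeLines("proc /;", con)
  } else {
    writeLines("#NEXUS", con)
    writeLines("BEGIN DATA;", con)
    writeLines(sprintf("\tDIMENSIONS NTAX=%d NCHAR=%d;",
                       length(taxa), ncol(matrix$states)), con)
    writeLines("\tFORMAT DATATYPE=STANDARD SYMBOLS=\"0 1\" MISSING=?;", con)
    writeLines("\tMATRIX", con)
    writeLines(sprintf("\t%s %s", taxa, rows), con)
    writeLines("\t;", con)
    writeLines("END;", con)
  }
  invisible(path)
}

#' Read an MRP matrix from TNT or NEXUS format
#'
#' The TNT reader tolerates interleaved blocks (repeated taxon rows are
#' concatenated; `&` interleave markers are skipped). The gap symbol `-` is
#' read as `?`. Provenance is not recoverable from these formats and is left
#' empty.
#'
#' @param path Input file path.
#' @param format `"tnt"` or `"nexus"`.
#' @return An `mrp_matrix` (taxon order as in the file).
#' @export
read_matrix <- function(path, format = c("tnt", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "tnt") {
    start <- grep("^\\s*xread([[:space:]]|$)", lines)
    if (!length(start)) stop("no xread statement found in ", path)
    body <- lines[(start[1] + 1L):length(lines)]
    body <- sub("'.*?'", "", body) # xread title comments
    dims <- NULL
    taxa <- character(0)
    rows <- list()
    for (ln in body) {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      if (grepl("^;", ln) || grepl("^proc([[:space:]]|$)", ln)) break
      if (grepl("^&", ln)) next # interleave marker
      toks <- strsplit(ln, "[ \t]+")[[1]]
      if (is.null(dims)) {
        if (length(toks) != 2L || anyNA(suppressWarnings(as.integer(toks)))) {
          stop("expected 'nchar ntax' dimensions after xread in ", path)
        }
        dims <- as.integer(toks)
        next
      }
      if (length(toks) != 2L) stop("malformed matrix row: ", ln)
      nm <- toks[1]
      if (nm %in% taxa) {
        rows[[nm]] <- paste0(rows[[nm]], toks[2])
      } else {
        taxa <- c(taxa, nm)
        rows[[nm]] <- toks[2]
      }
    }
    if (length(taxa) != dims[2]) {
      stop(sprintf("expected %d taxa but read %d in %s", dims[2], length(taxa), path))
    }
    cells <- parse_state_rows(unlist(rows[taxa]), dims[1], taxa)
  } else {
    txt <- toupper(paste(lines, collapse = "\n"))
    if (!grepl("BEGIN DATA", txt)) stop("no DATA block found in ", path)
    mstart <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
    if (!length(mstart)) stop("no MATRIX statement found in ", path)
    dim_line <- grep("DIMENSIONS", lines, ignore.case = TRUE, value = TRUE)[1]
    nchar_m <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dim_line,
                              ignore.case = TRUE))
    taxa <- character(0)
    rows <- list()
    for (ln in lines[(mstart[1] + 1L):length(lines)]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      if (grepl("^;", ln) || grepl("^END", ln, ignore.case = TRUE)) break
      toks <- strsplit(ln, "[ \t]+")[[1]]
      if (length(toks) != 2L) stop("malformed matrix row: ", ln)
      nm <- toks[1]
      if (nm %in% taxa) rows[[nm]] <- paste0(rows[[nm]], toks[2])
      else { taxa <- c(taxa, nm); rows[[nm]] <- toks[2] }
    }
    cells <- parse_state_rows(unlist(rows[taxa]), nchar_m, taxa)
  }
  prov <- tibble::tibble(source_id = character(), node = integer(),
                         cluster = character(), column = integer())
  x <- structure(list(taxa = taxa, states = cells, provenance = prov),
                 class = "mrp_matrix")
  og <- match(mrp_outgroup_name(), taxa)
  if (!is.na(og) && ncol(cells) && !all(cells[og, ] == "0")) {
    stop("outgroup row in ", path, " is not all zero")
  }
  x
}

parse_state_rows <- function(rowstrings, nchar_expected, taxa) {
  if (nchar_expected == 0L) {
    return(matrix(character(0), nrow = length(taxa), dimnames = list(taxa, NULL)))
  }
  lens <- nchar(rowstrings)
  if (any(lens != nchar_expected)) {
    bad <- taxa[lens != nchar_expected][1]
    stop(sprintf("ragged matrix: taxon %s has %d characters, expected %d",
                 bad, lens[match(bad, taxa)], nchar_expected))
  }
  cells <- do.call(rbind, strsplit(rowstrings, "", fixed = TRUE))
  cells[cells == "-"] <- "?"
  bad <- setdiff(unique(as.vector(cells)), c("0", "1", "?"))
  if (length(bad)) stop("unexpected matrix symbol(s): ", paste(bad, collapse = " "))
  dimnames(cells) <- list(taxa, NULL)
  cells
}
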