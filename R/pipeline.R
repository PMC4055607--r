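#' Run one stage of the supertree pipeline
#'
#' Stages communicate through files only, so any stage can be re-run or fed
#' external inputs (for example a published matrix). Every stage writes its
#' artifacts plus a plain-text `log_<stage>.txt` recording the seed and the
#' key counts.
#'
#' @param stage One of `"simulate"`, `"curate"`, `"matrix"`, `"search"`,
#'   `"summarize"`, `"assess"`, `"verify"`.
#' @param input Input directory (or file, for `matrix`/`search` inputs).
#' @param output Output directory (created if needed).
#' @param synthetic [synthetic_config] for `simulate`.
#' @param search [search_config] for `search` (and mini-supertrees).
#' @param verify_files Named list of local file paths for `verify`:
#'   `source_trees` (NEXUS), `matrix` (TNT), `mpts` (NEXUS). Missing entries
#'   are skipped with a notice.
#' @return The stage's main result, invisibly; `verify` returns its
#'   recomputed numbers (or a skip notice).
#' @export
run_pipeline <- function(stage = c("simulate", "curate", "matrix", "search",
                                   "summarize", "assess", "verify"),
                         input = NULL, output = NULL,
                         synthetic = synthetic_config(),
                         search = search_config(),
                         verify_files = list()) {
  stage <- match.arg(stage)
  switch(stage,
         simulate = stage_simulate(output, synthetic),
         curate = stage_curate(input, output, search),
         matrix = stage_matrix(input, output),
         search = stage_search(input, output, search),
         summarize = stage_summarize(input, output),
         assess = stage_assess(input, output),
         verify = stage_verify(verify_files, output))
}

stage_log <- function(dir, stage, lines) {
  writeLines(c(sprintf("stage: %s", stage), lines),
             file.path(dir, sprintf("log_%s.txt", stage)))
}

need <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing ", what, ": ", if (is.null(path)) "<not given>" else path,
         call. = FALSE)
  }
  path
}

stage_simulate <- function(output, synthetic) {
  stopifnot(!is.null(output))
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(synthetic, dir = output)
  stage_log(output, "simulate",
            c(sprintf("seed: %d", synthetic$seed),
              sprintf("taxa: %d", synthetic$n_taxa),
              sprintf("records: %d", length(ds$records))))
  invisible(ds)
}

stage_curate <- function(input, output, search = search_config()) {
  need(file.path(input, "trees.nex"), "source-tree file (trees.nex)")
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  ds <- read_dataset(input)
  cur <- curate_dataset(ds$records, rules = ds$rules, config = search)
  if (!cur$overlap$passes) {
    stop("dataset fails the taxonomic-overlap check: ",
         length(cur$overlap$components), " components: ",
         paste(vapply(cur$overlap$components, paste, "", collapse = "+"),
               collapse = " | "), call. = FALSE)
  }
  write_dataset(list(records = cur$records), output)
  utils::write.table(cur$dropped, file.path(output, "dropped.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cur$issues, file.path(output, "issues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cur$nonindependence[, c("id_a", "id_b", "relation", "drop")],
                     file.path(output, "nonindependence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  taxa <- unique(unlist(lapply(cur$records, function(r) r$tree$tip.label)))
  stage_log(output, "curate",
            c(sprintf("records in: %d", length(ds$records)),
              sprintf("records out: %d", length(cur$records)),
              sprintf("dropped: %d", nrow(cur$dropped)),
              sprintf("taxa: %d", length(taxa)),
              sprintf("issues: %d", nrow(cur$issues))))
  invisible(cur)
}

stage_matrix <- function(input, output) {
  need(file.path(input, "trees.nex"), "curated tree file (trees.nex)")
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  ds <- read_dataset(input)
  mat <- build_matrix(ds$records)
  write_matrix(mat, file.path(output, "matrix.tnt"), format = "tnt")
  write_matrix(mat, file.path(output, "matrix.nex"), format = "nexus")
  utils::write.table(mat$provenance, file.path(output, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(output, "matrix",
            c(sprintf("taxa: %d", length(mat$taxa)),
              sprintf("columns: %d", ncol(mat$states))))
  invisible(mat)
}

stage_search <- function(input, output, search = search_config()) {
  path <- need(file.path(input, "matrix.tnt"), "MRP matrix (matrix.tnt)")
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  mat <- read_matrix(path, format = "tnt")
  res <- heuristic_search(mat, search)
  write_tree_collection(stats::setNames(res$mpts,
                                        sprintf("mpt_%d", seq_along(res$mpts))),
                        file.path(output, "mpts.nex"), format = "nexus")
  utils::write.table(res$trace, file.path(output, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(output, "search",
            c(sprintf("seed: %d", search$seed),
              sprintf("taxa: %d", res$n_taxa),
              sprintf("columns: %d", res$n_columns),
              sprintf("best length: %d", res$best_length),
              sprintf("mpts: %d", length(res$mpts))))
  invisible(res)
}

stage_summarize <- function(input, output) {
  path <- need(file.path(input, "mpts.nex"), "MPT file (mpts.nex)")
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  mpts <- read_tree_collection(path, format = "nexus")
  ingroup <- lapply(mpts, root_on_outgroup)
  cons <- strict_consensus(ingroup)
  writeLines(write_newick(cons), file.path(output, "consensus.nwk"))
  agr <- if (length(ingroup) >= 2L) agreement_subtree(ingroup) else ingroup[[1]]
  writeLines(write_newick(agr), file.path(output, "agreement.nwk"))
  stage_log(output, "summarize",
            c(sprintf("mpts: %d", length(mpts)),
              sprintf("consensus resolution: %.2f%%", resolution(cons)),
              sprintf("agreement leaves: %d", ape::Ntip(agr))))
  invisible(list(consensus = cons, agreement = agr))
}

stage_assess <- function(input, output) {
  # input: directory holding both the curated dataset and the summary trees
  need(file.path(input, "trees.nex"), "curated tree file (trees.nex)")
  cons_path <- need(file.path(input, "consensus.nwk"), "supertree (consensus.nwk)")
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  ds <- read_dataset(input)
  supertree <- parse_newick(readLines(cons_path, warn = FALSE)[1])
  nov <- novel_clades(supertree, ds$records)
  clades_flat <- dplyr::mutate(nov$clades, supporting_ids = vapply(
    .data$supporting_ids, paste, "", collapse = ","))
  utils::write.table(clades_flat, file.path(output, "clade_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nov$taxa, file.path(output, "taxa_placement.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rog <- rogue_table(ds$records)
  utils::write.table(rog, file.path(output, "rogue_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  avail <- availability_matrix(ds$records)
  write_availability(avail, file.path(output, "availability.mtx"))
  stage_log(output, "assess",
            c(sprintf("supertree leaves: %d", ape::Ntip(supertree)),
              sprintf("resolution (root-exclusive): %.2f%%", resolution(supertree)),
              sprintf("novel clades: %d of %d (%.2f%%)",
                      sum(nov$clades$status == "novel"), nrow(nov$clades),
                      nov$pct_novel_clades),
              sprintf("taxa in novel clades: %.2f%%", nov$pct_taxa_in_novel_clades)))
  invisible(list(novel = nov, rogue = rog, availability = avail))
}

stage_verify <- function(verify_files, output = NULL) {
  have <- function(k) !is.null(verify_files[[k]]) && file.exists(verify_files[[k]])
  if (!any(vapply(c("source_trees", "matrix", "mpts"), have, TRUE))) {
    message("verify: no published files supplied; nothing to recompute")
    return(invisible(list(skipped = TRUE)))
  }
  out <- list(skipped = FALSE)
  if (have("source_trees")) {
    trees <- read_tree_collection(verify_files$source_trees, format = "nexus")
    out$n_source_trees <- length(trees)
    out$n_source_taxa <- length(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  }
  if (have("matrix")) {
    mat <- read_matrix(verify_files$matrix, format = "tnt")
    out$matrix_taxa <- length(mat$taxa)
    out$matrix_columns <- ncol(mat$states)
    if (have("mpts")) {
      mpts <- read_tree_collection(verify_files$mpts, format = "nexus")
      mpts <- lapply(mpts, function(t) {
        if (!mrp_outgroup_name() %in% t$tip.label) {
          # published MPTs may omit the artificial outgroup: attach it basally
          parse_newick(sub("^\\(", sprintf("(%s,(", mrp_outgroup_name()),
                           sub(";$", ");", write_newick(t))))
        } else t
      })
      out$mpt_lengths <- vapply(mpts, tree_length, 0L, matrix = mat)
    }
  }
  if (have("mpts") && !have("matrix")) {
    mpts <- read_tree_collection(verify_files$mpts, format = "nexus")
  }
  if (exists("mpts", inherits = FALSE)) {
    ingroup <- lapply(mpts, function(t) {
      if (mrp_outgroup_name() %in% t$tip.label) root_on_outgroup(t) else t
    })
    out$mpt_resolution_exclusive <- vapply(ingroup, resolution, 0)
    out$mpt_resolution_inclusive <-
      vapply(ingroup, resolution, 0, convention = "inclusive")
    if (length(ingroup) >= 2L) {
      agr <- agreement_subtree(ingroup)
      out$agreement_leaves <- ape::Ntip(agr)
    }
  }
  if (!is.null(output)) {
    dir.create(output, recursive = TRUE, showWarnings = FALSE)
    flat <- unlist(out)
    writeLines(sprintf("%s: %s", names(flat), as.character(flat)),
               file.path(output, "verify.txt"))
  }
  invisible(out)
}
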