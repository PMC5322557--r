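# End-to-end orchestration: simulate (or load) -> align -> cluster ->
# classify -> reconstruct -> compare -> report, deterministic under a
# fixed seed, with a manifest of all written artifacts.

#' Run the full analysis pipeline
#'
#' Stages: all-vs-all alignment, best-hit transitive-closure clustering,
#' annotation triage, state matrix, ancestral-content calls, lineage
#' events and the loss-count comparison between the first two ingroup
#' lineages. Identical inputs and seed give an identical bundle.
#'
#' @param gs A [genome_set()] (e.g. from [simulate_evolution()] or
#'   [read_simulation()]).
#' @param scoring An [alignment_config()].
#' @param clade_presence Passed to [call_ancestral()].
#' @param outdir Optional output directory; when given, all stage outputs
#'   plus a `MANIFEST` (path, md5) and a JSON summary are written.
#' @param contigs Optional contig sequences enabling the 5' rescue.
#' @param seed Optional integer recorded in the summary (provenance; the
#'   pipeline itself is deterministic given its inputs).
#' @return An `ancgene_run` with components `hits`, `partition`,
#'   `statuses`, `status_calls`, `state_matrix`, `ancestral_calls`,
#'   `lineage_events`, `loss_comparison`, `summary`.
#' @export
run_pipeline <- function(gs, scoring = alignment_config(),
                         clade_presence = "any", outdir = NULL,
                         contigs = NULL, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  hits <- stage("align", all_vs_all_align(gs, scoring))
  genes <- gs$genes
  has_hit <- setNames(genes$gene_id %in% c(hits$query_id, hits$subject_id),
                      genes$gene_id)
  art <- stage("artifact_filter", flag_artifacts(genes, has_hit))
  genes$status <- art$new_status[match(genes$gene_id, art$gene_id)]
  non_art <- genes$gene_id[genes$status != "artifact"]
  edges <- stage("best_hits", best_hit_edges(
    hits[hits$query_id %in% non_art & hits$subject_id %in% non_art, ,
         drop = FALSE], genes))
  partition <- stage("cluster", cluster_families(edges, non_art))
  gs2 <- gs; gs2$genes <- genes
  cls <- stage("classify", classify_gene_status(gs2, partition, hits,
                                                contigs))
  genes$status <- unname(cls$statuses[genes$gene_id])
  sm <- stage("state_matrix",
              build_state_matrix(partition, genes,
                                 genome_ids = names(gs$roles)))
  fam_mob <- family_mobile_category(partition, genes)
  calls <- stage("ancestor", call_ancestral(sm, gs$roles, gs$clades,
                                            family_mobile = fam_mob,
                                            clade_presence = clade_presence))
  events <- stage("lineage_events",
                  assign_lineage_events(calls, sm, gs$roles, gs$clades))
  lins <- names(events$lineages)
  cmp <- if (length(lins) >= 2)
    stage("loss_comparison", compare_loss_counts(events, lins[1], lins[2]))
  else NULL
  summary <- list(
    genomes = length(gs$roles), genes = nrow(gs$genes),
    artifacts = sum(genes$status == "artifact"),
    hits = nrow(hits), families = length(partition$families),
    pseudogenes = sum(genes$status == "pseudogene"),
    ancestral = sum(calls$ancestral),
    ancestrally_inactivated = sum(calls$ancestrally_inactivated),
    excluded_mobile = sum(calls$excluded_mobile),
    non_ancestral = sum(!calls$ancestral & !calls$excluded_mobile))
  if (!is.null(seed)) summary$seed <- as.integer(seed)
  run <- structure(list(genomes = gs, hits = hits, partition = partition,
                        statuses = cls$statuses, status_calls = cls$calls,
                        state_matrix = sm, ancestral_calls = calls,
                        lineage_events = events, loss_comparison = cmp,
                        family_mobile = fam_mob, summary = summary),
                   class = "ancgene_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.ancgene_run <- function(x, ...) {
  s <- x$summary
  cat("ancgene_run:\n")
  cat(sprintf("  %d genomes, %d gene records (%d artifacts, %d pseudogenes)\n",
              s$genomes, s$genes, s$artifacts, s$pseudogenes))
  cat(sprintf("  %d hits -> %d families\n", s$hits, s$families))
  cat(sprintf("  ancestral content: %d families (+%d ancestrally inactivated, %d mobile excluded)\n",
              s$ancestral, s$ancestrally_inactivated, s$excluded_mobile))
  if (!is.null(x$loss_comparison) && x$loss_comparison$valid)
    cat(sprintf("  loss comparison: chi2 = %.3f, p = %.3g\n",
                x$loss_comparison$chi2, x$loss_comparison$p_value))
  invisible(x)
}

#' @export
summary.ancgene_run <- function(object, ...) {
  print(object)
  print(object$lineage_events)
  invisible(object$summary)
}

#' Write an analysis bundle to disk
#'
#' @param run An `ancgene_run`.
#' @param outdir Output directory.
#' @return The directory, invisibly; a `MANIFEST` lists every artifact
#'   with its md5 checksum.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_hits(run$hits, file.path(outdir, "hits.tsv"))
  write_partition(run$partition, file.path(outdir, "families.tsv"))
  write_state_report(run$state_matrix, file.path(outdir, "state_matrix.tsv"))
  write.table(run$status_calls, file.path(outdir, "status_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_ancestral_outputs(run$ancestral_calls, run$lineage_events,
                          run$loss_comparison, outdir)
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(outdir, full.names = TRUE),
                   file.path(outdir, "MANIFEST"))
  md5 <- tools::md5sum(files)
  writeLines(paste(md5, basename(names(md5)), sep = "  "),
             file.path(outdir, "MANIFEST"))
  invisible(outdir)
}
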