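# All-vs-all cross-genome protein search and best-hit transitive-closure
# clustering into ortholog families, plus the family x genome state matrix.

.blosum62 <- function() {
  if (is.null(.ancgene_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ancgene_cache$blosum62 <- e$BLOSUM62
  }
  .ancgene_cache$blosum62
}

#' Alignment/search configuration
#'
#' Defaults: BLOSUM62, affine gaps (open 11, extend 1), exact 4-mer seeds,
#' report hits with bitscore >= 50 and e-value <= 1e-5 under a
#' Karlin-Altschul approximation (gapped BLOSUM62 lambda = 0.267,
#' K = 0.041; search space = query length x total letters in the other
#' genomes). `screen_min` is the raw-score floor of the ungapped X-drop
#' extension that gates the banded Smith-Waterman.
#'
#' @param min_bitscore,max_evalue Reporting thresholds.
#' @param k Seed word length.
#' @param screen_min Raw ungapped score needed to trigger full alignment.
#' @param xdrop X-drop for the ungapped extension (raw score units).
#' @param band Half-width of the Smith-Waterman band around the seed
#'   diagonal.
#' @param gap_open,gap_ext Affine gap penalties (gap of length L costs
#'   `gap_open + gap_ext * L`).
#' @param lambda,K Karlin-Altschul parameters.
#' @param max_seeds Seeds retained per candidate pair.
#' @return List of class `alignment_config`.
#' @export
alignment_config <- function(min_bitscore = 50, max_evalue = 1e-5, k = 4,
                             screen_min = 45, xdrop = 20, band = 24,
                             gap_open = 11, gap_ext = 1,
                             lambda = 0.267, K = 0.041, max_seeds = 8) {
  structure(list(min_bitscore = min_bitscore, max_evalue = max_evalue,
                 k = as.integer(k), screen_min = as.integer(screen_min),
                 xdrop = as.integer(xdrop), band = as.integer(band),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext), lambda = lambda, K = K,
                 max_seeds = as.integer(max_seeds)),
            class = "alignment_config")
}

#' All-vs-all cross-genome protein alignment
#'
#' Finds local similarities between proteins of different genomes: exact
#' k-mer seeding, ungapped X-drop screening, then banded affine
#' Smith-Waterman around the best seed diagonal. Hits are reported in both
#' directions with deterministic order (query id, then descending bitscore,
#' then subject id).
#'
#' @param gs A [genome_set()] with `aa_seq` present for all non-artifact
#'   genes.
#' @param scoring An [alignment_config()].
#' @return Hit data.frame in BLAST outfmt-6 column layout (see
#'   [read_hits()]).
#' @export
all_vs_all_align <- function(gs, scoring = alignment_config()) {
  genes <- gs$genes[gs$genes$status != "artifact", , drop = FALSE]
  if (nrow(genes) == 0) return(.empty_hits())
  if (any(is.na(genes$aa_seq)))
    stop("aa_seq missing for gene(s): ",
         paste(head(genes$gene_id[is.na(genes$aa_seq)], 5), collapse = ", "))
  sm <- .blosum62()
  alpha <- rownames(sm)
  enc <- lapply(strsplit(genes$aa_seq, ""), function(ch) {
    i <- match(ch, alpha)
    i[is.na(i)] <- match("X", alpha)
    i - 1L
  })
  gidx <- match(genes$genome_id, sort(unique(genes$genome_id)))
  raw <- .align_all_cpp(enc, gidx, sm, scoring$k, scoring$screen_min,
                        scoring$xdrop, scoring$band, scoring$gap_open,
                        scoring$gap_ext, scoring$max_seeds)
  if (nrow(raw) == 0) return(.empty_hits())
  lens <- nchar(genes$aa_seq)
  tot_by_genome <- tapply(lens, genes$genome_id, sum)
  total <- sum(lens)
  bits <- (scoring$lambda * raw$raw_score - log(scoring$K)) / log(2)
  mk <- function(qi, si, qs, qe, ss, se) {
    n_other <- total - tot_by_genome[genes$genome_id[qi]]
    ev <- as.numeric(lens[qi]) * as.numeric(n_other) * 2^(-bits)
    data.frame(query_id = genes$gene_id[qi], subject_id = genes$gene_id[si],
               identity_pct = 100 * raw$ident / raw$aln_len,
               aln_len = raw$aln_len, mismatches = raw$mismatches,
               gapopens = raw$gapopens, qstart = qs, qend = qe,
               sstart = ss, send = se, evalue = unname(ev),
               bitscore = bits, stringsAsFactors = FALSE)
  }
  hits <- rbind(mk(raw$qi, raw$si, raw$qstart, raw$qend, raw$sstart, raw$send),
                mk(raw$si, raw$qi, raw$sstart, raw$send, raw$qstart, raw$qend))
  hits <- hits[hits$bitscore >= scoring$min_bitscore &
               hits$evalue <= scoring$max_evalue, , drop = FALSE]
  hits <- hits[order(hits$query_id, -hits$bitscore, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             identity_pct = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gapopens = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Best-hit edges
#'
#' For each query gene and each other genome, one undirected edge to the
#' subject with the highest bitscore in that genome (ties broken by lower
#' e-value, then higher percent identity, then lexicographically smallest
#' subject id).
#'
#' @param hits Hit data.frame ([all_vs_all_align()] or [read_hits()]).
#' @param genes Gene table resolving ids to genomes.
#' @return data.frame with columns `a`, `b` (unique unordered pairs).
#' @export
best_hit_edges <- function(hits, genes) {
  if (nrow(hits) == 0)
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  gmap <- setNames(genes$genome_id, genes$gene_id)
  sgenome <- gmap[hits$subject_id]
  o <- order(hits$query_id, sgenome, -hits$bitscore, hits$evalue,
             -hits$identity_pct, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  keep <- !duplicated(paste(h$query_id, sgenome[o], sep = "\r"))
  h <- h[keep, , drop = FALSE]
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  e <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  e[order(e$a, e$b), , drop = FALSE]
}

#' Cluster genes into families by transitive closure
#'
#' Families are the connected components of the best-hit graph: if A
#' clusters with B and with C, then B and C share a family. Genes with no
#' edge form singleton families; two genes of one genome may share a family
#' (fragments, recent duplicates, paralogs).
#'
#' @param edges Edge data.frame from [best_hit_edges()].
#' @param gene_ids All gene ids to be covered (non-artifact genes).
#' @return A `family_partition`: list with `families` (named list
#'   `family_id -> gene ids`) and `membership` (named vector
#'   `gene_id -> family_id`).
#' @export
cluster_families <- function(edges, gene_ids) {
  gene_ids <- sort(unique(gene_ids))
  bad <- setdiff(unique(c(edges$a, edges$b)), gene_ids)
  if (length(bad)) stop("edges reference unknown gene(s): ",
                        paste(head(bad, 5), collapse = ", "))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = gene_ids)
  comp <- igraph::components(g)$membership
  comp <- comp[gene_ids]
  # deterministic family ids ordered by smallest member gene id
  first <- tapply(names(comp), comp, min)
  ord <- order(first)
  relabel <- setNames(seq_along(ord), names(first)[ord])
  fam_num <- relabel[as.character(comp)]
  fam_id <- sprintf("FAM%05d", fam_num)
  membership <- setNames(fam_id, names(comp))
  families <- split(names(membership), membership)
  structure(list(families = families, membership = membership),
            class = "family_partition")
}

#' @export
print.family_partition <- function(x, ...) {
  sizes <- lengths(x$families)
  cat("family_partition:", length(x$families), "families over",
      length(x$membership), "genes (", sum(sizes == 1), "singletons, max size",
      max(sizes), ")\n")
  invisible(x)
}

#' Build the family x genome state matrix
#'
#' Cell state is `intact` if the family has at least one intact member in
#' that genome, else `pseudogene` if at least one pseudogene member, else
#' `absent`. Artifacts are never counted; `unclassified` members count as
#' intact (classification is assumed final, and an unclassified survivor of
#' all rules is an intact call).
#'
#' @param partition A `family_partition`.
#' @param genes Gene table with final `status`.
#' @param genome_ids Genomes to include as columns (default: all in
#'   `genes`).
#' @return A `state_matrix`: list with character matrix `states` and
#'   integer matrix `counts` (family x genome member counts).
#' @export
build_state_matrix <- function(partition, genes, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(genes$genome_id))
  fams <- names(partition$families)
  keep <- genes$status != "artifact" & genes$gene_id %in% names(partition$membership)
  g <- genes[keep, , drop = FALSE]
  fam_of <- partition$membership[g$gene_id]
  states <- matrix("absent", length(fams), length(genome_ids),
                   dimnames = list(fams, genome_ids))
  counts <- matrix(0L, length(fams), length(genome_ids),
                   dimnames = list(fams, genome_ids))
  if (nrow(g)) {
    eff <- ifelse(g$status == "pseudogene", "pseudogene", "intact")
    key <- paste(fam_of, g$genome_id, sep = "\r")
    cnt <- table(key)
    any_int <- tapply(eff == "intact", key, any)
    ks <- strsplit(names(cnt), "\r", fixed = TRUE)
    fi <- match(vapply(ks, `[`, "", 1L), fams)
    gi <- match(vapply(ks, `[`, "", 2L), genome_ids)
    ok <- !is.na(fi) & !is.na(gi)
    counts[cbind(fi[ok], gi[ok])] <- as.integer(cnt)[ok]
    states[cbind(fi[ok], gi[ok])] <-
      ifelse(unname(any_int)[ok], "intact", "pseudogene")
  }
  structure(list(states = states, counts = counts), class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  tab <- apply(x$states, 2, function(col) table(factor(col,
    levels = c("intact", "pseudogene", "absent"))))
  cat("state_matrix:", nrow(x$states), "families x", ncol(x$states),
      "genomes\n")
  print(tab)
  invisible(x)
}

#' Write a state-matrix report
#'
#' One genome per column using the tokens `Intact`/`Pseudogene`/`Absent`;
#' cells backed by more than one member carry a `(Fg)` fragmented/duplicated
#' annotation.
#'
#' @param sm A `state_matrix`.
#' @param path Output TSV path.
#' @export
write_state_report <- function(sm, path) {
  tok <- c(intact = "Intact", pseudogene = "Pseudogene", absent = "Absent")
  m <- matrix(tok[sm$states], nrow(sm$states), ncol(sm$states),
              dimnames = dimnames(sm$states))
  m[sm$counts > 1] <- paste0(m[sm$counts > 1], " (Fg)")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(paste(c("family_id", colnames(m)), collapse = "\t"), con, sep = "\n")
  if (nrow(m))
    writeLines(paste(rownames(m), apply(m, 1, paste, collapse = "\t"),
                     sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Write a family partition TSV
#'
#' @param partition A `family_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines("family_id\tgene_id", con, sep = "\n")
  m <- partition$membership[order(unname(partition$membership),
                                  names(partition$membership))]
  if (length(m))
    writeLines(paste(unname(m), names(m), sep = "\t"), con, sep = "\n")
  invisible(path)
}
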