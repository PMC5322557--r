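# Annotation triage: artifact filtering, the relative-length pseudogene
# rule with its domain exception, the 5'-truncation start-codon rescue, and
# the contig-edge override. Applied in that fixed order; each rule emits
# StatusCall rows recording what fired and why.

.status_call <- function(gene_id, old, new, rule, ref_len = NA_real_,
                         ratio = NA_real_) {
  data.frame(gene_id = gene_id, old_status = old, new_status = new,
             rule_fired = rule, reference_length = ref_len,
             length_ratio = ratio, stringsAsFactors = FALSE)
}

.empty_calls <- function() .status_call(character(0), character(0),
                                        character(0), character(0),
                                        numeric(0), numeric(0))

#' Flag annotation artifacts
#'
#' A gene is an artifact iff its protein is shorter than 100 amino acids
#' (strictly), it has no significant similarity hit, and it carries no
#' annotated domain. All other genes are unchanged.
#'
#' @param genes Gene table with `aa_seq` present.
#' @param has_hit Named logical vector `gene_id -> has a significant hit`
#'   (genes absent from the vector count as having none).
#' @return StatusCall data.frame (one row per gene).
#' @export
flag_artifacts <- function(genes, has_hit) {
  if (any(is.na(genes$aa_seq)))
    stop("aa_seq missing for gene(s): ",
         paste(head(genes$gene_id[is.na(genes$aa_seq)], 5), collapse = ", "))
  hh <- rep(FALSE, nrow(genes))
  idx <- match(genes$gene_id, names(has_hit))
  hh[!is.na(idx)] <- as.logical(has_hit[idx[!is.na(idx)]])
  ndom <- vapply(genes$domains, nrow, 1L)
  is_art <- nchar(genes$aa_seq) < 100L & !hh & ndom == 0L
  .status_call(genes$gene_id, genes$status,
               ifelse(is_art, "artifact", genes$status),
               ifelse(is_art, "artifact_short_no_evidence", "no_change"))
}

#' Classify pseudogenes by relative length
#'
#' Within each family, a member whose protein is shorter than 80% (strict)
#' of the median length of its cross-genome reference members is called a
#' pseudogene -- unless it preserves every ancestral domain (domain ids
#' shared by all reference members; the exception needs at least one such
#' domain). The reference pool for a member is taken from the other
#' genomes' members: those pre-labelled intact when any exist, otherwise
#' every member not pre-labelled pseudogene; in both cases only members
#' within 80% of the longest pool member serve as references (a truncated
#' member must not drag the reference median down). Members with no
#' cross-genome reference are left unchanged; members that pass the rule
#' with a reference become intact calls.
#'
#' @param genes Gene table with `aa_seq`.
#' @param partition A `family_partition` covering the genes.
#' @return StatusCall data.frame for every non-artifact clustered gene.
#' @export
classify_pseudogenes <- function(genes, partition) {
  g <- genes[genes$status != "artifact" &
             genes$gene_id %in% names(partition$membership), , drop = FALSE]
  if (nrow(g) == 0) return(.empty_calls())
  if (any(is.na(g$aa_seq)))
    stop("aa_seq missing for gene(s): ",
         paste(head(g$gene_id[is.na(g$aa_seq)], 5), collapse = ", "))
  len <- nchar(g$aa_seq)
  genome <- g$genome_id
  status <- g$status
  dom_ids <- lapply(g$domains, function(d) unique(d$domain_id))
  fam_of <- partition$membership[g$gene_id]
  res <- rep("no_change", nrow(g))
  new_status <- g$status
  ref_len_out <- rep(NA_real_, nrow(g))
  ratio_out <- rep(NA_real_, nrow(g))
  for (members in split(seq_len(nrow(g)), fam_of)) {
    for (m in members[status[members] %in% c("intact", "unclassified")]) {
      others <- members[genome[members] != genome[m]]
      pool <- if (any(status[others] == "intact"))
        others[status[others] == "intact"]
      else others[status[others] != "pseudogene"]
      if (length(pool) == 0) next
      refs <- pool[len[pool] >= 0.8 * max(len[pool])]
      rl <- median(len[refs])
      ratio <- len[m] / rl
      ref_len_out[m] <- rl; ratio_out[m] <- ratio
      if (ratio < 0.8) {
        anc_dom <- Reduce(intersect, dom_ids[refs])
        if (length(anc_dom) > 0 && all(anc_dom %in% dom_ids[[m]])) {
          res[m] <- "domain_exception"
          new_status[m] <- "intact"
        } else {
          res[m] <- "length_lt_80"
          new_status[m] <- "pseudogene"
        }
      } else if (status[m] == "unclassified") {
        new_status[m] <- "intact"
      }
    }
  }
  .status_call(g$gene_id, g$status, new_status, res, ref_len_out, ratio_out)
}

#' Rescue a 5'-truncated pseudogene by an upstream start codon
#'
#' Applies only when the truncation is on the 5' side: scans upstream
#' in-frame on the coding strand until the nearest in-frame stop; if an
#' alternative bacterial start (ATG/GTG/TTG) gives an implied ORF reaching
#' at least 80% of the reference length with no internal stop, the gene is
#' reclassified intact with a corrected start coordinate.
#'
#' @param gene One-row gene table (current status pseudogene).
#' @param contig_seq Contig nucleotide sequence (forward strand). When
#'   missing the rescue is skipped with a warning.
#' @param reference_length Reference protein length (amino acids).
#' @param truncation_side `"5prime"`, `"3prime"` or `"unknown"` (only
#'   `"5prime"` is acted on).
#' @return A one-row StatusCall; the corrected start is in attribute
#'   `corrected_start` when the rescue fires.
#' @export
rescue_five_prime <- function(gene, contig_seq, reference_length,
                              truncation_side = "5prime") {
  old <- gene$status
  no <- .status_call(gene$gene_id, old, old, "no_change",
                     reference_length,
                     nchar(gene$aa_seq) / reference_length)
  if (!identical(old, "pseudogene") || truncation_side != "5prime")
    return(no)
  if (missing(contig_seq) || is.null(contig_seq) || is.na(contig_seq)) {
    warning("contig sequence unavailable; 5' rescue skipped for ",
            gene$gene_id)
    return(no)
  }
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")
  glen <- gene$end - gene$start + 1L
  codon_at <- function(pos5) {
    # codon at 5'-offset `pos5` (bp upstream of the gene start, multiple of 3)
    if (gene$strand == "+") {
      a <- gene$start - pos5
      if (a < 1) return(NULL)
      substr(contig_seq, a, a + 2L)
    } else {
      b <- gene$end + pos5
      if (b > nchar(contig_seq)) return(NULL)
      .revcomp(substr(contig_seq, b - 2L, b))
    }
  }
  pos5 <- 3L
  repeat {
    cod <- codon_at(pos5)
    if (is.null(cod)) break
    if (cod %in% stops) break
    if (cod %in% starts) {
      orf_aa <- (glen + pos5) / 3
      if (orf_aa / reference_length >= 0.8) {
        out <- .status_call(gene$gene_id, old, "intact",
                            "five_prime_rescue", reference_length,
                            orf_aa / reference_length)
        attr(out, "corrected_start") <- if (gene$strand == "+")
          gene$start - pos5 else gene$start
        attr(out, "corrected_end") <- if (gene$strand == "+")
          gene$end else gene$end + pos5
        return(out)
      }
    }
    pos5 <- pos5 + 3L
  }
  no
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Contig-edge override
#'
#' A gene broken by a contig edge with no apparent stop mutation is
#' considered active regardless of its length ratio: if the (possibly
#' incomplete) CDS contains no internal in-frame stop codon, status becomes
#' intact. A trailing partial codon is ignored; a terminal stop codon is
#' not counted as internal.
#'
#' @param gene One-row gene table.
#' @return A one-row StatusCall.
#' @export
apply_contig_edge_rule <- function(gene) {
  old <- gene$status
  if (!isTRUE(gene$contig_edge))
    return(.status_call(gene$gene_id, old, old, "no_change"))
  if (is.na(gene$nt_seq))
    stop("nt_seq required for the contig-edge rule: ", gene$gene_id)
  nt <- gene$nt_seq
  ncod <- nchar(nt) %/% 3L
  if (ncod == 0)
    return(.status_call(gene$gene_id, old, old, "no_change"))
  cods <- substring(nt, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  internal <- cods[-length(cods)]
  has_stop <- any(internal %in% c("TAA", "TAG", "TGA"))
  if (!has_stop)
    .status_call(gene$gene_id, old, "intact", "contig_edge_active")
  else
    .status_call(gene$gene_id, old, old, "no_change")
}

#' Run the full annotation triage in its fixed order
#'
#' Artifact filter, then the family-relative pseudogene rule, then the 5'
#' rescue (skipped unless contig sequences are supplied), then the
#' contig-edge override. The result is deterministic and idempotent.
#'
#' @param gs A [genome_set()].
#' @param partition A `family_partition` over the non-artifact genes.
#' @param hits Hit data.frame used for the artifact rule's
#'   has-a-significant-match flag.
#' @param contigs Optional named character vector `contig_id -> sequence`
#'   enabling the 5' rescue.
#' @return List with `statuses` (named vector `gene_id -> final status`)
#'   and `calls` (all StatusCall rows, in application order).
#' @export
classify_gene_status <- function(gs, partition, hits, contigs = NULL) {
  genes <- gs$genes
  has_hit <- setNames(genes$gene_id %in% c(hits$query_id, hits$subject_id),
                      genes$gene_id)
  calls1 <- flag_artifacts(genes, has_hit)
  genes$status <- calls1$new_status[match(genes$gene_id, calls1$gene_id)]
  calls2 <- classify_pseudogenes(genes, partition)
  genes$status[match(calls2$gene_id, genes$gene_id)] <- calls2$new_status
  calls3 <- .empty_calls()
  if (!is.null(contigs)) {
    ref_len <- setNames(calls2$reference_length, calls2$gene_id)
    for (i in which(genes$status == "pseudogene")) {
      rl <- ref_len[genes$gene_id[i]]
      if (is.na(rl)) next
      side <- .truncation_side(genes[i, ], hits)
      cl <- rescue_five_prime(genes[i, ], contigs[[genes$contig_id[i]]],
                              rl, side)
      calls3 <- rbind(calls3, cl)
      genes$status[i] <- cl$new_status
    }
  }
  calls4 <- .empty_calls()
  for (i in which(genes$contig_edge & genes$status == "pseudogene")) {
    cl <- apply_contig_edge_rule(genes[i, ])
    calls4 <- rbind(calls4, cl)
    genes$status[i] <- cl$new_status
  }
  # survivors of all rules are final intact calls
  genes$status[genes$status == "unclassified"] <- "intact"
  list(statuses = setNames(genes$status, genes$gene_id),
       calls = rbind(calls1, calls2, calls3, calls4))
}

# which side is truncated, judged from the best hit against a longer
# family member: alignment covering the subject's 3' end but not its 5'
# end means the missing sequence is 5'
.truncation_side <- function(gene, hits) {
  h <- hits[hits$query_id == gene$gene_id, , drop = FALSE]
  if (nrow(h) == 0) return("unknown")
  h <- h[which.max(h$bitscore), ]
  send_near_end <- !is.na(h$send) && h$send >= h$sstart &&
    (h$qend >= nchar(gene$aa_seq) - 2L)
  sstart_far <- h$sstart > 5L
  if (sstart_far && (h$qstart <= 3L)) return("5prime")
  if (send_near_end && !sstart_far) return("3prime")
  "unknown"
}
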