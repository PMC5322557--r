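# Reading and writing the external representations: FASTA, the gene table
# TSV, BLAST outfmt-6 hits, Newick trees, GFF3 export.

.AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWYX"
.NT_LETTERS <- "ACGTN"

.MOBILE_CATEGORIES <- c("none", "phage", "plasmid", "transposase",
                        "toxin_antitoxin", "APSE", "pHD5AT")
.STATUS_LEVELS <- c("intact", "pseudogene", "artifact", "unclassified")

#' Read a FASTA file into a named character vector
#'
#' Headers are truncated at the first whitespace; sequences are uppercased
#' and validated against the amino-acid (20 letters plus `X`) or nucleotide
#' (`ACGTN`) alphabet.
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  names(seqs) <- ids
  legal <- if (kind == "protein") .AA_LETTERS else .NT_LETTERS
  bad <- regexpr(sprintf("[^%s]", legal), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                 kind, substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "wb")  # binary mode keeps LF endings on every platform
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    chunks <- substring(s, seq(1L, max(nchar(s), 1L), width),
                        pmin(seq(1L, max(nchar(s), 1L), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

.parse_domains <- function(txt) {
  # "dom1:1-50;dom2:60-120" -> data.frame(domain_id, aa_start, aa_end)
  if (is.na(txt) || !nzchar(txt))
    return(data.frame(domain_id = character(0), aa_start = integer(0),
                      aa_end = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed domain triple: '", parts[which(bad)[1]], "'")
  data.frame(domain_id = vapply(m, `[`, "", 2L),
             aa_start = as.integer(vapply(m, `[`, "", 3L)),
             aa_end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

.format_domains <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("")
  paste(sprintf("%s:%d-%d", df$domain_id, df$aa_start, df$aa_end),
        collapse = ";")
}

#' Read a gene annotation table
#'
#' Tab-separated with one header line; columns `gene_id`, `contig_id`,
#' `start`, `end`, `strand`, `status`, `contig_edge`, `mobile_category`,
#' `domains` (semicolon-separated `id:aa_start-aa_end`; empty allowed).
#' Unknown status tokens are mapped to `"unclassified"` with a warning.
#'
#' @param path Path to the TSV.
#' @param genome_id Genome identifier attached to every record.
#' @return A gene table `data.frame` (one row per gene record, `domains`
#'   as a list column).
#' @export
read_gene_table <- function(path, genome_id) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("gene_id", "contig_id", "start", "end", "strand", "status",
            "contig_edge", "mobile_category", "domains")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  start <- as.integer(raw$start); end <- as.integer(raw$end)
  if (any(start > end)) {
    i <- which(start > end)[1]
    stop(sprintf("gene '%s': start (%d) > end (%d)", raw$gene_id[i],
                 start[i], end[i]))
  }
  status <- raw$status
  unknown <- !(status %in% .STATUS_LEVELS)
  if (any(unknown)) {
    warning("unknown status value(s) mapped to 'unclassified': ",
            paste(unique(status[unknown]), collapse = ", "))
    status[unknown] <- "unclassified"
  }
  gene_table(gene_id = raw$gene_id, genome_id = genome_id,
             contig_id = raw$contig_id, start = start, end = end,
             strand = raw$strand, status = status,
             contig_edge = tolower(raw$contig_edge) %in% c("true", "t", "1"),
             mobile_category = raw$mobile_category,
             domains = lapply(raw$domains, .parse_domains))
}

#' Construct a gene table
#'
#' The in-memory carrier for annotated gene records: one row per gene, with
#' 1-based inclusive coordinates on the forward strand of the contig and
#' amino-acid domain intervals as a list column.
#'
#' @param gene_id,genome_id,contig_id,start,end,strand,status,contig_edge,mobile_category
#'   Per-record fields (recycled where length 1).
#' @param nt_seq,aa_seq Optional sequences (`NA` where absent).
#' @param domains List of data.frames (`domain_id`, `aa_start`, `aa_end`).
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, genome_id, contig_id = "c1", start = 1L,
                       end = 3L, strand = "+", status = "unclassified",
                       contig_edge = FALSE, mobile_category = "none",
                       nt_seq = NA_character_, aa_seq = NA_character_,
                       domains = NULL) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id, genome_id = rep_len(genome_id, n),
                   contig_id = rep_len(contig_id, n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(strand, n),
                   status = rep_len(status, n),
                   contig_edge = rep_len(contig_edge, n),
                   mobile_category = rep_len(mobile_category, n),
                   nt_seq = rep_len(nt_seq, n), aa_seq = rep_len(aa_seq, n),
                   stringsAsFactors = FALSE)
  if (is.null(domains)) domains <- rep(list(.parse_domains("")), n)
  df$domains <- domains
  validate_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

#' @rdname gene_table
#' @param x A gene table.
#' @export
validate_gene_table <- function(x) {
  stopifnot(all(x$start <= x$end))
  if (anyDuplicated(x$gene_id))
    stop("duplicate gene_id: ", x$gene_id[duplicated(x$gene_id)][1])
  bad_status <- setdiff(unique(x$status), .STATUS_LEVELS)
  if (length(bad_status)) stop("invalid status: ", bad_status[1])
  bad_mob <- setdiff(unique(x$mobile_category), .MOBILE_CATEGORIES)
  if (length(bad_mob)) stop("invalid mobile_category: ", bad_mob[1])
  has_both <- !is.na(x$nt_seq) & !is.na(x$aa_seq) & x$status == "intact"
  if (any(has_both)) {
    ok <- nchar(x$nt_seq[has_both]) == 3L * (nchar(x$aa_seq[has_both]) + 1L)
    if (!all(ok))
      stop("intact gene '", x$gene_id[has_both][!ok][1],
           "': nt length must be 3*(aa length + 1) counting the stop codon")
  }
  for (i in seq_len(nrow(x))) {
    d <- x$domains[[i]]
    if (!is.na(x$aa_seq[i]) && nrow(d) &&
        (any(d$aa_start < 1L) || any(d$aa_end > nchar(x$aa_seq[i]))))
      stop("gene '", x$gene_id[i], "': domain interval outside the protein")
  }
  invisible(x)
}

#' Write a gene table TSV
#'
#' @param genes Gene table.
#' @param path Output path.
#' @param statuses Optional status column override (the simulator writes
#'   `unclassified` so that classification stays the pipeline's job).
#' @export
write_gene_table <- function(genes, path, statuses = NULL) {
  out <- data.frame(gene_id = genes$gene_id, contig_id = genes$contig_id,
                    start = genes$start, end = genes$end,
                    strand = genes$strand,
                    status = if (is.null(statuses)) genes$status else statuses,
                    contig_edge = ifelse(genes$contig_edge, "true", "false"),
                    mobile_category = genes$mobile_category,
                    domains = vapply(genes$domains, .format_domains, ""),
                    stringsAsFactors = FALSE)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Export a gene table as GFF3
#'
#' Status, mobile category and domain intervals are carried as column-9
#' attributes.
#'
#' @param genes Gene table.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  if (nrow(genes)) {
    attrs <- sprintf("ID=%s;status=%s;mobile_category=%s;domains=%s",
                     genes$gene_id, genes$status, genes$mobile_category,
                     vapply(genes$domains, .format_domains, ""))
    writeLines(paste(genes$contig_id, "ancgene", "CDS", genes$start,
                     genes$end, ".", genes$strand, "0", attrs, sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Assemble a genome set
#'
#' Bundles the gene tables of several genomes with their ingroup/outgroup
#' roles and named ingroup clades.
#'
#' @param genes A single gene table covering all genomes (or a list of
#'   per-genome tables, which are concatenated).
#' @param roles Named character vector `genome_id -> "ingroup"|"outgroup"`.
#' @param clades Named list `clade_name -> character vector of genome_ids`;
#'   every clade must be a subset of the ingroup.
#' @param tree Optional `phylo` species tree whose tip labels are the
#'   genome ids.
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(genes, roles, clades = list(), tree = NULL) {
  if (is.list(genes) && !is.data.frame(genes))
    genes <- do.call(rbind, genes)
  validate_gene_table(genes)
  class(genes) <- c("gene_table", "data.frame")
  gids <- sort(unique(genes$genome_id))
  # a genome may legitimately be empty (e.g. total loss in a simulation),
  # but every gene must belong to a genome with a declared role
  if (length(setdiff(gids, names(roles))))
    stop("gene table contains genomes with no declared role: ",
         paste(setdiff(gids, names(roles)), collapse = ", "))
  if (!all(roles %in% c("ingroup", "outgroup"))) stop("bad role value")
  ing <- names(roles)[roles == "ingroup"]
  for (cl in names(clades))
    if (!all(clades[[cl]] %in% ing))
      stop("clade '", cl, "' contains non-ingroup genomes")
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
    if (!setequal(tree$tip.label, names(roles)))
      stop("tree tip labels do not match the declared genomes")
  }
  structure(list(genes = genes, roles = roles, clades = clades, tree = tree),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$roles), "genomes,", nrow(x$genes),
      "gene records\n")
  for (g in names(x$roles))
    cat(sprintf("  %s (%s): %d genes\n", g, x$roles[[g]],
                sum(x$genes$genome_id == g)))
  if (length(x$clades))
    cat("  clades:", paste(sprintf("%s={%s}", names(x$clades),
        vapply(x$clades, paste, "", collapse = ",")), collapse = " "), "\n")
  invisible(x)
}

#' Read a Newick species tree
#'
#' @param path Newick file.
#' @param genome_ids Optional character vector; when given, tip labels must
#'   coincide with it.
#' @return An `ape` `phylo` tree.
#' @export
read_tree <- function(path, genome_ids = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick tree: ", path)
  if (!is.null(genome_ids) && !setequal(tr$tip.label, genome_ids))
    stop("tree labels {", paste(sort(tr$tip.label), collapse = ","),
         "} do not match genomes {", paste(sort(genome_ids), collapse = ","),
         "}")
  tr
}

#' @rdname read_tree
#' @param tree A `phylo` tree.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read tabular similarity hits (BLAST outfmt 6)
#'
#' Self-hits and hits between genes of the same genome are discarded (the
#' search is cross-genome by construction); ids must resolve to loaded gene
#' records.
#'
#' @param path 12-column tab-separated hit file.
#' @param genes Gene table used to resolve ids to genomes.
#' @return data.frame of hits (`query_id`, `subject_id`, `identity_pct`,
#'   `aln_len`, `mismatches`, `gapopens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
read_hits <- function(path, genes) {
  cols <- c("query_id", "subject_id", "identity_pct", "aln_len",
            "mismatches", "gapopens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  h <- read.delim(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (nrow(h) == 0) {
    h <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    return(h)
  }
  if (ncol(h) != 12) stop("expected 12 tab-separated columns, got ", ncol(h))
  names(h) <- cols
  for (nm in c("identity_pct", "evalue", "bitscore")) h[[nm]] <- as.numeric(h[[nm]])
  for (nm in c("aln_len", "mismatches", "gapopens", "qstart", "qend",
               "sstart", "send")) h[[nm]] <- as.integer(h[[nm]])
  gmap <- setNames(genes$genome_id, genes$gene_id)
  unknown <- setdiff(unique(c(h$query_id, h$subject_id)), names(gmap))
  if (length(unknown))
    stop("hit ids not present in the gene table: ",
         paste(head(unknown, 10), collapse = ", "))
  self <- h$query_id == h$subject_id
  within <- gmap[h$query_id] == gmap[h$subject_id]
  dropped <- sum(!self & within)
  if (dropped > 0)
    message(dropped, " within-genome hit(s) discarded (cross-genome search only)")
  h[!self & !within, , drop = FALSE]
}

#' Write hits in BLAST outfmt 6
#'
#' @param hits Hit data.frame as returned by [all_vs_all_align()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  con <- file(path, "wb"); on.exit(close(con))
  if (nrow(hits))
    writeLines(paste(hits$query_id, hits$subject_id,
                     sprintf("%.1f", hits$identity_pct), hits$aln_len,
                     hits$mismatches, hits$gapopens, hits$qstart, hits$qend,
                     hits$sstart, hits$send,
                     format(hits$evalue, scientific = TRUE, digits = 3),
                     sprintf("%.1f", hits$bitscore), sep = "\t"),
               con, sep = "\n")
  invisible(path)
}
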