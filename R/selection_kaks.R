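# Pairwise Ka/Ks by Nei-Gojobori (1986) pathway counting with Jukes-Cantor
# correction, on a codon alignment back-translated from a global protein
# alignment. Changes to stop codons count as nonsynonymous; stop and
# ambiguous codon columns are removed before counting.

#' Codon-align two CDSs
#'
#' Trims a trailing stop codon, translates (internal stops become `*`),
#' aligns the proteins globally (BLOSUM62, affine gaps open 11 / extend 1)
#' and back-maps the alignment to codons. Columns containing a gap, a stop
#' codon or an ambiguous base in either sequence are removed.
#'
#' @param cds_a,cds_b CDS nucleotide strings, length divisible by 3 after
#'   trimming the trailing stop.
#' @return A `codon_alignment`: codon index vectors `a` and `b` (equal
#'   length), `n_retained`, `n_gap_cols`, `n_stop_cols`.
#' @export
codon_align <- function(cds_a, cds_b) {
  prep <- function(nt) {
    nt <- toupper(nt)
    if (nchar(nt) %% 3 != 0)
      stop("CDS length not divisible by 3 (", nchar(nt), " nt)")
    n <- nchar(nt) %/% 3
    last <- substr(nt, 3 * n - 2, 3 * n)
    if (last %in% c("TAA", "TAG", "TGA")) nt <- substr(nt, 1, 3 * (n - 1))
    if (nchar(nt) == 0) stop("empty CDS after trimming the stop codon")
    nt
  }
  a <- prep(cds_a); b <- prep(cds_b)
  tab <- .codon_tables()
  enc <- function(nt) {
    idx <- .encode_codons(nt)  # NA for codons containing non-ACGT
    idx
  }
  ia <- enc(a); ib <- enc(b)
  aa_of <- function(idx) {
    ch <- ifelse(is.na(idx), "X", tab$aa[idx])  # '*' for internal stops
    paste(ch, collapse = "")
  }
  pa <- aa_of(ia); pb <- aa_of(ib)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ka <- kb <- 0L
  keep_a <- integer(0); keep_b <- integer(0)
  n_gap <- 0L; n_stop <- 0L
  for (i in seq_along(sa)) {
    ga <- sa[i] == "-"; gb <- sb[i] == "-"
    if (!ga) ka <- ka + 1L
    if (!gb) kb <- kb + 1L
    if (ga || gb) { n_gap <- n_gap + 1L; next }
    ca <- ia[ka]; cb <- ib[kb]
    if (is.na(ca) || is.na(cb) || tab$is_stop[ca] || tab$is_stop[cb]) {
      n_stop <- n_stop + 1L; next
    }
    keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
  }
  structure(list(a = keep_a, b = keep_b, n_retained = length(keep_a),
                 n_gap_cols = n_gap, n_stop_cols = n_stop),
            class = "codon_alignment")
}

#' Nei-Gojobori Ka/Ks
#'
#' Synonymous site fractions per codon come from enumerating the nine
#' single-nucleotide changes under the standard code (changes to stop
#' codons count as nonsynonymous); sites are averaged over the two
#' sequences. Differences between codons are averaged over all minimal
#' substitution pathways with equal weights (pathways through stop codons
#' excluded when an alternative exists). Rates are Jukes-Cantor corrected:
#' d = -(3/4) ln(1 - 4p/3).
#'
#' @param aln A `codon_alignment`.
#' @return A `kaks_result`: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `ratio` (dN/dS), `valid` with `reason` (`"saturation"` when a p >=
#'   3/4, `"zero_dS"` when dS = 0).
#' @export
nei_gojobori <- function(aln) {
  if (aln$n_retained == 0) stop("empty codon alignment")
  tab <- .codon_tables()
  S <- (sum(tab$syn_sites[aln$a]) + sum(tab$syn_sites[aln$b])) / 2
  N <- 3 * aln$n_retained - S
  Sd <- sum(tab$pair$sd[cbind(aln$a, aln$b)])
  Nd <- sum(tab$pair$nd[cbind(aln$a, aln$b)])
  pS <- Sd / S; pN <- Nd / N
  valid <- TRUE; reason <- NA_character_
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  if (pS >= 0.75 || pN >= 0.75) {
    valid <- FALSE; reason <- "saturation"
    dS <- if (pS < 0.75) jc(pS) else NA_real_
    dN <- if (pN < 0.75) jc(pN) else NA_real_
  } else {
    dS <- jc(pS); dN <- jc(pN)
    if (dS == 0) { valid <- FALSE; reason <- "zero_dS" }
  }
  ratio <- if (valid) dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, ratio = ratio, valid = valid,
                 reason = reason, n_codons = aln$n_retained),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "Nei-Gojobori over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd))
  if (x$valid)
    cat(sprintf("  dS=%.5f dN=%.5f  dN/dS=%.4f\n", x$dS, x$dN, x$ratio))
  else cat("  ratio undefined:", x$reason, "\n")
  invisible(x)
}

#' Ka/Ks between two CDSs
#'
#' Convenience wrapper: [codon_align()] then [nei_gojobori()].
#'
#' @param cds_a,cds_b CDS nucleotide strings.
#' @return A `kaks_result`.
#' @export
kaks_pair <- function(cds_a, cds_b) nei_gojobori(codon_align(cds_a, cds_b))

#' Selection verdict from a Ka/Ks result
#'
#' @param result A `kaks_result`.
#' @param threshold Ratio threshold (default 1): strictly below means
#'   purifying.
#' @return `"purifying"`, `"neutral_or_relaxed"` or `"undefined"`.
#' @export
purifying_verdict <- function(result, threshold = 1.0) {
  if (!isTRUE(result$valid)) return("undefined")
  if (result$ratio < threshold) "purifying" else "neutral_or_relaxed"
}

#' Ka/Ks table for shared pseudogene families
#'
#' For every family that is pseudogene in all genomes of `lineage` and
#' present in `reference_genome`, computes pairwise Ka/Ks between one
#' lineage representative and the reference member -- the purifying
#' selection test applied to shared pseudogenes.
#'
#' @param gs A [genome_set()] with `nt_seq` present.
#' @param partition A `family_partition`.
#' @param sm A `state_matrix` of final statuses.
#' @param lineage Character vector of genomes sharing the pseudogenes.
#' @param reference_genome Genome supplying the comparison partner.
#' @return data.frame, one row per testable family, with the
#'   `kaks_result` fields and the verdict.
#' @export
shared_pseudogene_kaks <- function(gs, partition, sm, lineage,
                                   reference_genome) {
  st <- sm$states
  fams <- rownames(st)[apply(st[, lineage, drop = FALSE] == "pseudogene", 1,
                             all) & st[, reference_genome] != "absent"]
  genes <- gs$genes
  rows <- lapply(fams, function(f) {
    members <- partition$families[[f]]
    g1 <- members[genes$genome_id[match(members, genes$gene_id)] ==
                  lineage[1]][1]
    g2 <- members[genes$genome_id[match(members, genes$gene_id)] ==
                  reference_genome][1]
    if (is.na(g1) || is.na(g2)) return(NULL)
    n1 <- genes$nt_seq[match(g1, genes$gene_id)]
    n2 <- genes$nt_seq[match(g2, genes$gene_id)]
    if (is.na(n1) || is.na(n2)) return(NULL)
    k <- kaks_pair(n1, n2)
    data.frame(family_id = f, gene_a = g1, gene_b = g2, S = k$S, N = k$N,
               Sd = k$Sd, Nd = k$Nd, pS = k$pS, pN = k$pN, dS = k$dS,
               dN = k$dN, ratio = k$ratio, valid = k$valid,
               verdict = purifying_verdict(k), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(family_id = character(0)))
  do.call(rbind, rows)
}
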