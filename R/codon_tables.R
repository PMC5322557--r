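# Codon-level lookup tables under the standard genetic code (identical, at
# the codon -> amino-acid level, to bacterial table 11). Built once and
# cached: the 9 single-nucleotide neighbours of every codon, their
# synonymous / stop classification, Nei-Gojobori synonymous site fractions,
# and the pathway-averaged difference counts for every codon pair.

.codon_tables <- function() {
  if (!is.null(.ancgene_cache$codon)) return(.ancgene_cache$codon)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)            # 64 codons, TCAG order
  aa <- unname(gc_map)
  is_stop <- aa == "*"
  sense <- which(!is_stop)
  nts <- c("T", "C", "A", "G")
  # 9 single-nucleotide neighbours per codon: j = (pos-1)*3 + alt
  new_codon <- matrix(0L, 64, 9)
  to_nt <- matrix("", 64, 9)
  from_nt <- matrix("", 64, 9)
  pos_of <- rep(1:3, each = 3)
  syn <- matrix(FALSE, 64, 9)
  makes_stop <- matrix(FALSE, 64, 9)
  idx <- setNames(seq_len(64), codons)
  for (c0 in seq_len(64)) {
    chars <- strsplit(codons[c0], "")[[1]]
    j <- 0L
    for (p in 1:3) {
      alts <- setdiff(nts, chars[p])
      for (a in alts) {
        j <- j + 1L
        nc <- chars; nc[p] <- a
        nci <- idx[[paste(nc, collapse = "")]]
        new_codon[c0, j] <- nci
        from_nt[c0, j] <- chars[p]
        to_nt[c0, j] <- a
        makes_stop[c0, j] <- is_stop[nci]
        syn[c0, j] <- (!is_stop[c0]) && (!is_stop[nci]) && aa[nci] == aa[c0]
      }
    }
  }
  # NG86 sites: fractional synonymous sites per codon = (#syn of 9)/3;
  # changes to stop codons count as nonsynonymous (kept in N)
  syn_sites <- rowSums(syn) / 3
  nonsyn_sites <- 3 - syn_sites
  tab <- list(codons = codons, aa = aa, is_stop = is_stop, sense = sense,
              new_codon = new_codon, from_nt = from_nt, to_nt = to_nt,
              pos_of = pos_of, syn = syn, makes_stop = makes_stop,
              syn_sites = syn_sites, nonsyn_sites = nonsyn_sites)
  tab$pair <- .codon_pair_table(tab)
  .ancgene_cache$codon <- tab
  tab
}

# Average synonymous/nonsynonymous difference counts over all minimal
# substitution pathways between two sense codons (equal pathway weights;
# pathways passing through a stop codon are excluded unless all do).
.codon_pair_table <- function(tab) {
  n <- 64
  sd <- matrix(NA_real_, n, n)
  nd <- matrix(NA_real_, n, n)
  chars <- strsplit(tab$codons, "")
  step_class <- function(from, to) {
    # one-nucleotide step between codon strings
    if (tab$aa[from] == "*" || tab$aa[to] == "*") return("stop")
    if (tab$aa[from] == tab$aa[to]) "syn" else "nonsyn"
  }
  for (i in seq_len(n)) {
    if (tab$is_stop[i]) next
    for (j in seq_len(n)) {
      if (tab$is_stop[j]) next
      diff_pos <- which(chars[[i]] != chars[[j]])
      k <- length(diff_pos)
      if (k == 0) { sd[i, j] <- 0; nd[i, j] <- 0; next }
      perms <- if (k == 1) matrix(diff_pos, 1) else {
        p <- expand.grid(rep(list(diff_pos), k))
        p <- p[apply(p, 1, function(r) length(unique(r)) == k), , drop = FALSE]
        as.matrix(p)
      }
      path_sd <- path_nd <- numeric(0)
      for (r in seq_len(nrow(perms))) {
        cur <- chars[[i]]
        s <- 0; ns <- 0; ok <- TRUE
        for (p in perms[r, ]) {
          nxt <- cur; nxt[p] <- chars[[j]][p]
          from_i <- match(paste(cur, collapse = ""), tab$codons)
          to_i <- match(paste(nxt, collapse = ""), tab$codons)
          cl <- step_class(from_i, to_i)
          if (cl == "stop") { ok <- FALSE; break }
          if (cl == "syn") s <- s + 1 else ns <- ns + 1
          cur <- nxt
        }
        if (ok) { path_sd <- c(path_sd, s); path_nd <- c(path_nd, ns) }
      }
      if (length(path_sd) == 0) {
        # every pathway passes through a stop; fall back to counting the
        # stop-crossing steps as nonsynonymous over all pathways
        for (r in seq_len(nrow(perms))) {
          cur <- chars[[i]]; s <- 0; ns <- 0
          for (p in perms[r, ]) {
            nxt <- cur; nxt[p] <- chars[[j]][p]
            from_i <- match(paste(cur, collapse = ""), tab$codons)
            to_i <- match(paste(nxt, collapse = ""), tab$codons)
            cl <- step_class(from_i, to_i)
            if (cl == "syn") s <- s + 1 else ns <- ns + 1
            cur <- nxt
          }
          path_sd <- c(path_sd, s); path_nd <- c(path_nd, ns)
        }
      }
      sd[i, j] <- mean(path_sd)
      nd[i, j] <- mean(path_nd)
    }
  }
  list(sd = sd, nd = nd)
}

# encode a CDS string (length divisible by 3) as codon indices 1..64;
# codons containing characters outside ACGT get NA
.encode_codons <- function(nt) {
  tab <- .codon_tables()
  n <- nchar(nt)
  if (n %% 3 != 0) stop("CDS length not divisible by 3")
  cods <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  match(cods, tab$codons)
}

.decode_codons <- function(idx) {
  tab <- .codon_tables()
  paste(tab$codons[idx], collapse = "")
}

.translate_codons <- function(idx) {
  tab <- .codon_tables()
  paste(tab$aa[idx], collapse = "")
}
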