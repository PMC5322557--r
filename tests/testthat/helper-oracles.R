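# Independent oracles used across the suite. Each re-derives an expected
# result by brute force, staying independent of the code path it checks.

# transitive closure of an undirected edge set by repeated boolean matrix
# squaring; returns a membership vector over `ids`
oracle_components <- function(edges, ids) {
  n <- length(ids)
  A <- diag(TRUE, n)
  dimnames(A) <- list(ids, ids)
  if (nrow(edges)) {
    A[cbind(edges$a, edges$b)] <- TRUE
    A[cbind(edges$b, edges$a)] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0) || all(A2 == (A > 0))) break
    A <- A2
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[A[i, ] > 0] <- cur
    }
  }
  setNames(comp, ids)
}

# exhaustive affine-gap local alignment score (gap of length L costs
# open + ext * L), plain R dynamic programme
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    FF[i, j] <- max(H[i - 1, j] - open - ext, FF[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                   E[i, j], FF[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# brute-force Nei-Gojobori difference counts for one codon pair: enumerate
# every ordering of the differing positions; pathways through stop codons
# are excluded unless all pass through one (then every pathway counts,
# stop-crossing steps as nonsynonymous)
oracle_ng_pair <- function(c1, c2) {
  gc_map <- Biostrings::GENETIC_CODE
  aa <- function(cod) unname(gc_map[cod])
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  dpos <- which(ch1 != ch2)
  k <- length(dpos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(dpos) else {
    out <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), dpos)
    out
  }
  walk <- function(ord) {
    cur <- ch1; s <- 0; ns <- 0; stop_hit <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- ch2[p]
      a1 <- aa(paste(cur, collapse = "")); a2 <- aa(paste(nxt, collapse = ""))
      if (a1 == "*" || a2 == "*") stop_hit <- TRUE
      if (a1 == a2 && a1 != "*") s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    c(s = s, ns = ns, stop = stop_hit)
  }
  res <- t(vapply(perms, walk, c(s = 0, ns = 0, stop = 0)))
  keep <- res[, "stop"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(res))
  c(sd = mean(res[keep, "s"]), nd = mean(res[keep, "ns"]))
}

# random CDS of n codons (ATG first, sense codons, no stop)
random_cds <- function(n, with_stop = FALSE) {
  tab <- ancgene:::.codon_tables()
  cod <- c(match("ATG", tab$codons), sample(tab$sense, n - 1, replace = TRUE))
  s <- paste(tab$codons[cod], collapse = "")
  if (with_stop) s <- paste0(s, "TAA")
  s
}

# random protein of n residues over the 20 standard amino acids
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

blosum62_matrix <- function() ancgene:::.blosum62()

# map a simulated gene id back to its true family
true_family <- function(ids) sub("^[^_]+_(.+)_c[0-9]+$", "\\1", ids)

# are two labelings the same partition (identical blocks, labels ignored)?
same_partition <- function(x, y) {
  ids <- seq_along(x)
  canon <- function(l) sort(vapply(split(ids, l), paste, "", collapse = ","))
  identical(unname(canon(x)), unname(canon(y)))
}

# adjusted Rand index between two labelings (closed form over the
# contingency table); used to cross-check and as a fallback
rand_index_adjusted <- function(x, y) {
  tab <- table(x, y)
  if (all(dim(tab) == c(1, 1))) return(1)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2)) - a
  cc <- sum(choose(colSums(tab), 2)) - a
  d <- choose(sum(tab), 2) - a - b - cc
  exp_a <- (a + b) * (a + cc) / (a + b + cc + d)
  (a - exp_a) / ((a + b + a + cc) / 2 - exp_a)
}
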