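# Lightweight concatenation + distance phylogeny: p-distances with
# pairwise deletion, neighbor-joining, column-resampling bootstrap and a
# monophyly check. A deliberately simple substitute for full ML inference,
# adequate for validating simulated clade signal.

#' Concatenate aligned loci
#'
#' @param loci Named list: `locus -> named character vector` of aligned
#'   sequences (same taxa in every locus, equal lengths within a locus).
#' @return Named character vector of per-taxon concatenated sequences, in
#'   a fixed locus order (list order).
#' @export
concatenate_loci <- function(loci) {
  if (length(loci) == 0) stop("no loci")
  taxa <- sort(names(loci[[1]]))
  for (nm in names(loci)) {
    l <- loci[[nm]]
    if (!setequal(names(l), taxa))
      stop("locus '", nm, "' is missing taxa: ",
           paste(setdiff(taxa, names(l)), collapse = ", "))
    if (length(unique(nchar(l))) != 1)
      stop("locus '", nm, "' sequences differ in length")
  }
  out <- setNames(rep("", length(taxa)), taxa)
  for (nm in names(loci)) out <- paste0(out, loci[[nm]][taxa])
  setNames(out, taxa)
}

#' Pairwise p-distances
#'
#' Proportion of differing sites, ignoring columns with a gap or `N` in
#' either sequence of the pair (pairwise deletion).
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(alignment) {
  n <- length(alignment)
  if (length(unique(nchar(alignment))) != 1)
    stop("sequences must be aligned to equal length")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  bad <- m == "-" | m == "N" | m == "?"
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !bad[i, ] & !bad[j, ]
    if (!any(ok)) stop("no comparable sites between ",
                       names(alignment)[i], " and ", names(alignment)[j])
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical NJ on a distance matrix (at least 4 taxa for a resolved
#' unrooted topology).
#'
#' @param dm Symmetric distance matrix.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  ape::nj(stats::as.dist(dm))
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree and
#' reports, for each internal edge of the original tree, the fraction of
#' replicates containing the same bipartition.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @return List: `tree` (original NJ tree with support as node labels)
#'   and `support` (numeric vector in `[0, 1]`, one per internal node).
#' @export
bootstrap_support <- function(alignment, n = 100, seed = 1) {
  set.seed(seed)
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(chars) <- names(alignment)
  L <- ncol(chars)
  orig <- nj_tree(p_distance(alignment))
  reps <- vector("list", n)
  for (r in seq_len(n)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                           collapse = ""), rownames(chars))
    reps[[r]] <- nj_tree(p_distance(boot))
  }
  cl <- ape::prop.clades(orig, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0
  support <- cl / n
  orig$node.label <- format(support, digits = 3)
  list(tree = orig, support = support)
}

#' Support of one clade in a bootstrap result
#'
#' @param alignment,taxa,outgroup Alignment, the taxa of the clade of
#'   interest, and an outgroup taxon used to root replicate trees.
#' @param n,seed Bootstrap replicates and seed.
#' @return Fraction of replicates in which `taxa` are monophyletic.
#' @export
clade_bootstrap_support <- function(alignment, taxa, outgroup, n = 100,
                                    seed = 1) {
  set.seed(seed)
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(chars) <- names(alignment)
  L <- ncol(chars)
  hits <- 0L
  for (r in seq_len(n)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                           collapse = ""), rownames(chars))
    tr <- nj_tree(p_distance(boot))
    if (is_monophyletic(tr, taxa, outgroup)) hits <- hits + 1L
  }
  hits / n
}

#' Is a set of taxa monophyletic?
#'
#' The tree is rooted on the outgroup first; the query is monophyletic iff
#' it equals the full leaf set of some clade of the rooted tree.
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of tip labels.
#' @param outgroup Tip label used to root the tree.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  miss <- setdiff(c(taxa, outgroup), tree$tip.label)
  if (length(miss)) stop("unknown taxon/taxa: ", paste(miss, collapse = ", "))
  rooted <- ape::root(ape::unroot(tree), outgroup = outgroup,
                      resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}
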