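two_genome_set <- function(seqs_a, seqs_b) {
  na <- length(seqs_a); nb <- length(seqs_b)
  gt <- gene_table(gene_id = c(sprintf("a%02d", seq_len(na)),
                               sprintf("b%02d", seq_len(nb))),
                   genome_id = rep(c("GA", "GB"), c(na, nb)),
                   aa_seq = c(seqs_a, seqs_b))
  genome_set(gt, c(GA = "ingroup", GB = "ingroup"))
}

test_that("identical cross-genome proteins give reciprocal full-identity hits", {
  set.seed(101)
  p <- random_protein(300)
  gs <- two_genome_set(p, p)
  hits <- all_vs_all_align(gs)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$query_id, c("a01", "b01"))
  expect_equal(hits$identity_pct, c(100, 100))
  expect_equal(hits$bitscore[1], hits$bitscore[2])
  expect_equal(hits$qstart, c(1L, 1L))
  expect_equal(hits$qend, c(300L, 300L))
})

test_that("unrelated random proteins produce no hits at default thresholds", {
  set.seed(102)
  n <- 40  # 40 x 40 = 1600 random cross-genome pairs
  gs <- two_genome_set(vapply(rep(300, n), random_protein, ""),
                       vapply(rep(300, n), random_protein, ""))
  hits <- all_vs_all_align(gs)
  expect_equal(nrow(hits), 0)
})

test_that("a truncated copy aligns over the shared prefix at the exact SW score", {
  set.seed(103)
  p <- random_protein(300)
  half <- substr(p, 1, 150)
  gs <- two_genome_set(p, half)
  hits <- all_vs_all_align(gs)
  h <- hits[hits$query_id == "a01", ]
  expect_equal(nrow(h), 1)
  expect_equal(h$qstart, 1L); expect_equal(h$qend, 150L)
  expect_equal(h$sstart, 1L); expect_equal(h$send, 150L)
  # exhaustive Smith-Waterman oracle on the pair
  sw <- oracle_sw_score(p, half, blosum62_matrix())
  raw <- ancgene:::.sw_score_cpp(
    match(strsplit(p, "")[[1]], rownames(blosum62_matrix())) - 1L,
    match(strsplit(half, "")[[1]], rownames(blosum62_matrix())) - 1L,
    blosum62_matrix(), 11L, 1L)
  expect_equal(raw, sw)
  # the banded search found the same optimum
  expect_equal(h$bitscore, (0.267 * sw - log(0.041)) / log(2))
})

test_that("banded search equals exhaustive local alignment on diverged pairs", {
  set.seed(104)
  tab <- ancgene:::.codon_tables()
  alpha <- rownames(blosum62_matrix())
  for (rep in 1:10) {
    anc <- c(tab$sense[1], sample(tab$sense, 199, TRUE))
    a <- ancgene:::.translate_codons(ancgene:::.mutate_codons(anc, 0.05, 0.05)$codons)
    b <- ancgene:::.translate_codons(ancgene:::.mutate_codons(anc, 0.05, 0.05)$codons)
    gs <- two_genome_set(a, b)
    hits <- all_vs_all_align(gs)
    expect_equal(nrow(hits), 2)
    expect_equal(hits$bitscore[1],
                 (0.267 * oracle_sw_score(a, b, blosum62_matrix()) -
                  log(0.041)) / log(2))
  }
})

test_that("best-hit edges pick the top subject per genome with full tie-breaks", {
  mkhit <- function(q, s, bits, ev = 1e-50, id = 90) {
    data.frame(query_id = q, subject_id = s, identity_pct = id,
               aln_len = 100L, mismatches = 0L, gapopens = 0L, qstart = 1L,
               qend = 100L, sstart = 1L, send = 100L, evalue = ev,
               bitscore = bits, stringsAsFactors = FALSE)
  }
  genes <- gene_table(c("a", "b1", "b2", "c1"),
                      genome_id = c("GA", "GB", "GB", "GC"))
  # bitscore dominates
  h <- rbind(mkhit("a", "b1", 200), mkhit("a", "b2", 150),
             mkhit("a", "c1", 90))
  e <- best_hit_edges(h, genes)
  expect_equal(e, data.frame(a = c("a", "a"), b = c("b1", "c1"),
                             stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  # equal bits: lower e-value wins
  h2 <- rbind(mkhit("a", "b1", 200, ev = 1e-40), mkhit("a", "b2", 200, ev = 1e-60))
  expect_equal(best_hit_edges(h2, genes)$b, "b2")
  # equal bits and e-value: higher identity wins
  h3 <- rbind(mkhit("a", "b1", 200, id = 85), mkhit("a", "b2", 200, id = 95))
  expect_equal(best_hit_edges(h3, genes)$b, "b2")
  # full tie: lexicographically smallest subject
  h4 <- rbind(mkhit("a", "b2", 200), mkhit("a", "b1", 200))
  expect_equal(best_hit_edges(h4, genes)$b, "b1")
})

test_that("clustering is transitive closure with singletons covered", {
  edges <- data.frame(a = c("a", "a"), b = c("b", "c"),
                      stringsAsFactors = FALSE)
  part <- cluster_families(edges, c("a", "b", "c", "d", "e"))
  expect_equal(unname(part$membership[c("a", "b", "c")]),
               rep(part$membership[["a"]], 3))
  expect_equal(length(part$families), 3)
  expect_equal(lengths(part$families)[[part$membership[["d"]]]], 1)

  none <- cluster_families(edges[0, ], letters[1:5])
  expect_equal(length(none$families), 5)

  expect_error(cluster_families(data.frame(a = "x", b = "a"), c("a", "b")),
               "unknown")
})

test_that("clustering equals the matrix-squaring transitive-closure oracle", {
  set.seed(105)
  for (rep in 1:10) {
    ids <- sprintf("g%02d", 1:50)
    ne <- sample(10:60, 1)
    edges <- unique(data.frame(a = sample(ids, ne, TRUE),
                               b = sample(ids, ne, TRUE),
                               stringsAsFactors = FALSE))
    edges <- edges[edges$a != edges$b, ]
    part <- cluster_families(edges, ids)
    oc <- oracle_components(edges, ids)
    expect_true(same_partition(unname(part$membership[ids]),
                               unname(oc[ids])))
  }
})

test_that("clustering is independent of edge order", {
  set.seed(106)
  ids <- sprintf("g%02d", 1:30)
  edges <- unique(data.frame(a = sample(ids, 25, TRUE),
                             b = sample(ids, 25, TRUE),
                             stringsAsFactors = FALSE))
  edges <- edges[edges$a != edges$b, ]
  p1 <- cluster_families(edges, ids)
  p2 <- cluster_families(edges[rev(seq_len(nrow(edges))), ], ids)
  expect_identical(p1$membership, p2$membership)
})

test_that("state matrix applies intact dominance, absence and artifact exclusion", {
  genes <- gene_table(c("a1", "a2", "b1", "c1"),
                      genome_id = c("GA", "GA", "GB", "GC"),
                      status = c("intact", "pseudogene", "pseudogene",
                                 "artifact"))
  part <- structure(list(
    families = list(FAM1 = c("a1", "a2", "b1"), FAM2 = "c1"),
    membership = c(a1 = "FAM1", a2 = "FAM1", b1 = "FAM1", c1 = "FAM2")),
    class = "family_partition")
  sm <- build_state_matrix(part, genes, genome_ids = c("GA", "GB", "GC"))
  expect_equal(sm$states["FAM1", ], c(GA = "intact", GB = "pseudogene",
                                      GC = "absent"))
  # artifacts are never counted anywhere
  expect_equal(sm$states["FAM2", ], c(GA = "absent", GB = "absent",
                                      GC = "absent"))
  expect_equal(sm$counts["FAM1", "GA"], 2L)
})

test_that("state report writes Table-style tokens with fragmented flags", {
  genes <- gene_table(c("a1", "a2", "b1"),
                      genome_id = c("GA", "GA", "GB"),
                      status = c("intact", "intact", "pseudogene"))
  part <- structure(list(families = list(FAM1 = c("a1", "a2", "b1")),
                         membership = c(a1 = "FAM1", a2 = "FAM1",
                                        b1 = "FAM1")),
                    class = "family_partition")
  sm <- build_state_matrix(part, genes, c("GA", "GB", "GC"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_state_report(sm, p)
  lines <- readLines(p)
  expect_equal(lines[1], "family_id\tGA\tGB\tGC")
  expect_equal(lines[2], "FAM1\tIntact (Fg)\tPseudogene\tAbsent")
})

test_that("relabelling genomes permutes but never changes family composition", {
  set.seed(107)
  cfg <- evolution_config(ancestral_size = 30, syn_rate = 0, nonsyn_rate = 0,
                          hgt_rate = 0, dup_prob = 0, seed = 41)
  sim <- simulate_evolution(cfg)
  gs <- sim$genomes
  hits1 <- all_vs_all_align(gs)
  p1 <- cluster_families(best_hit_edges(hits1, gs$genes), gs$genes$gene_id)
  # swap two genome labels (and ids stay attached to their sequences)
  gs2 <- gs
  sw <- c(A = "B", B = "A", C = "C", O1 = "O1", O2 = "O2")
  gs2$genes$genome_id <- unname(sw[gs2$genes$genome_id])
  hits2 <- all_vs_all_align(gs2)
  p2 <- cluster_families(best_hit_edges(hits2, gs2$genes), gs2$genes$gene_id)
  same1 <- lapply(p1$families, sort)
  same2 <- lapply(p2$families, sort)
  expect_setequal(unname(vapply(same1, paste, "", collapse = ",")),
                  unname(vapply(same2, paste, "", collapse = ",")))
})
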