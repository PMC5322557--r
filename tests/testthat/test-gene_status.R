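# helpers to build small families by hand
fam_genes <- function(lens, genomes, statuses = "unclassified",
                      domains = NULL, ids = NULL) {
  n <- length(lens)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  if (is.null(domains)) domains <- rep(list(ancgene:::.parse_domains("")), n)
  gene_table(gene_id = ids, genome_id = genomes, start = 1L,
             end = 3L * (lens + 1L), status = statuses,
             aa_seq = vapply(lens, random_protein, ""), domains = domains)
}
one_family <- function(genes) {
  structure(list(families = list(FAM1 = genes$gene_id),
                 membership = setNames(rep("FAM1", nrow(genes)),
                                       genes$gene_id)),
            class = "family_partition")
}

test_that("artifact rule: short, hitless, domainless genes only", {
  set.seed(1)
  doms <- list(ancgene:::.parse_domains(""),
               data.frame(domain_id = "D1", aa_start = 5L, aa_end = 50L,
                          stringsAsFactors = FALSE),
               ancgene:::.parse_domains(""),
               ancgene:::.parse_domains(""))
  g <- fam_genes(c(90, 90, 100, 90), genomes = c("GA", "GB", "GC", "GD"),
                 domains = doms)
  hh <- c(g01 = FALSE, g02 = FALSE, g03 = FALSE, g04 = TRUE)
  calls <- flag_artifacts(g, hh)
  expect_equal(calls$new_status,
               c("artifact", "unclassified", "unclassified", "unclassified"))
  expect_equal(calls$rule_fired[1], "artifact_short_no_evidence")
  expect_equal(calls$rule_fired[2:4], rep("no_change", 3))
  # missing sequence is a hard error
  g$aa_seq[2] <- NA
  expect_error(flag_artifacts(g, hh), "g02")
})

test_that("pseudogene length rule is strict at 80% of the reference median", {
  set.seed(2)
  # references 300 and 310 in other genomes (median 305)
  for (len in c(240, 244, 247)) {
    g <- fam_genes(c(len, 300, 310), c("GA", "GB", "GC"))
    calls <- classify_pseudogenes(g, one_family(g))
    ratio <- len / 305
    expect_equal(calls$reference_length[1], 305)
    expect_equal(calls$length_ratio[1], ratio)
    if (ratio < 0.8) {
      expect_equal(calls$new_status[1], "pseudogene")
      expect_equal(calls$rule_fired[1], "length_lt_80")
    } else {
      expect_equal(calls$new_status[1], "intact")
      expect_equal(calls$rule_fired[1], "no_change")
    }
  }
  # 244/305 = 0.8000: strictly less-than, so intact
  g <- fam_genes(c(244, 305, 305), c("GA", "GB", "GC"))
  calls <- classify_pseudogenes(g, one_family(g))
  expect_equal(calls$length_ratio[1], 0.8)
  expect_equal(calls$new_status[1], "intact")
})

test_that("a short member keeping every ancestral domain stays intact", {
  set.seed(3)
  d <- function(id) data.frame(domain_id = id, aa_start = 10L,
                               aa_end = 100L, stringsAsFactors = FALSE)
  g <- fam_genes(c(150, 300, 310), c("GA", "GB", "GC"),
                 domains = list(d("D1"), d("D1"), d("D1")))
  calls <- classify_pseudogenes(g, one_family(g))
  expect_equal(calls$new_status[1], "intact")
  expect_equal(calls$rule_fired[1], "domain_exception")
  # same member missing the shared domain: pseudogene
  g2 <- fam_genes(c(150, 300, 310), c("GA", "GB", "GC"),
                  domains = list(ancgene:::.parse_domains(""), d("D1"),
                                 d("D1")))
  calls2 <- classify_pseudogenes(g2, one_family(g2))
  expect_equal(calls2$new_status[1], "pseudogene")
  # no shared ancestral domain: the exception cannot fire
  g3 <- fam_genes(c(150, 300, 310), c("GA", "GB", "GC"),
                  domains = list(d("D1"), d("D1"),
                                 ancgene:::.parse_domains("")))
  calls3 <- classify_pseudogenes(g3, one_family(g3))
  expect_equal(calls3$new_status[1], "pseudogene")
})

test_that("members with no cross-genome reference are left unchanged", {
  set.seed(4)
  # two fragments of one genome only
  g <- fam_genes(c(100, 120), c("GA", "GA"))
  calls <- classify_pseudogenes(g, one_family(g))
  expect_equal(calls$new_status, c("unclassified", "unclassified"))
  expect_equal(calls$rule_fired, c("no_change", "no_change"))
})

test_that("truncated members are kept out of the reference pool", {
  set.seed(5)
  # three deep truncations to 70% would pollute a naive median
  g <- fam_genes(c(350, 350, 350, 500, 500),
                 c("GA", "GB", "GC", "GD", "GE"))
  calls <- classify_pseudogenes(g, one_family(g))
  expect_equal(calls$new_status[1:3], rep("pseudogene", 3))
  expect_equal(calls$new_status[4:5], rep("intact", 2))
  expect_equal(calls$reference_length[1], 500)
})

test_that("5' rescue extends to an upstream alternative start", {
  # contig: 30 bp upstream + gene; in-frame GTG 12 bp upstream
  up <- "CCCCCCCCCCCCCCCCCCGTGCCCCCCCCC"  # GTG at positions 19-21
  gene_nt <- paste(rep("GCT", 60), collapse = "")
  contig <- paste0(up, gene_nt)
  g <- gene_table("p1", "GA", start = 31L, end = 31L + 180L - 1L,
                  status = "pseudogene", nt_seq = gene_nt,
                  aa_seq = paste(rep("A", 60), collapse = ""))
  # reference 70 aa: 60 aa alone is 0.857 > 0.8 already, use 80 aa ref
  call <- rescue_five_prime(g[1, ], contig, reference_length = 80,
                            truncation_side = "5prime")
  expect_equal(call$new_status, "intact")
  expect_equal(call$rule_fired, "five_prime_rescue")
  expect_equal(attr(call, "corrected_start"), 31L - 12L)

  # an in-frame stop before any start blocks the rescue
  up2 <- "CCCCCCCCCCCCCCCCCCTAACCCCCCCCC"  # TAA in the scanned frame
  call2 <- rescue_five_prime(g[1, ], paste0(up2, gene_nt), 80, "5prime")
  expect_equal(call2$new_status, "pseudogene")

  # 3'-side truncations are never rescued
  call3 <- rescue_five_prime(g[1, ], contig, 80, "3prime")
  expect_equal(call3$new_status, "pseudogene")
  expect_equal(call3$rule_fired, "no_change")

  # missing contig: warning, no change
  expect_warning(call4 <- rescue_five_prime(g[1, ], NA, 80, "5prime"),
                 "skipped")
  expect_equal(call4$new_status, "pseudogene")
})

test_that("5' rescue works on the minus strand", {
  gene_nt <- paste(rep("GCT", 50), collapse = "")   # coding strand
  # upstream of a minus-strand gene lies AFTER its end on the contig;
  # coding-strand GTG 6 bp upstream = revcomp CAC on the forward strand
  left <- paste(rep("G", 12), collapse = "")
  fwd_gene <- ancgene:::.revcomp(gene_nt)
  contig <- paste0(left, fwd_gene, "GGGCACGGGGGGGGG")
  start <- 13L; end <- 12L + 150L
  g <- gene_table("m1", "GA", start = start, end = end, strand = "-",
                  status = "pseudogene", nt_seq = gene_nt,
                  aa_seq = paste(rep("A", 50), collapse = ""))
  call <- rescue_five_prime(g[1, ], contig, reference_length = 60,
                            truncation_side = "5prime")
  expect_equal(call$new_status, "intact")
  expect_equal(attr(call, "corrected_end"), end + 6L)
})

test_that("contig-edge genes with no stop mutation are considered active", {
  clean <- paste(rep("GCT", 50), collapse = "")
  g1 <- gene_table("e1", "GA", status = "pseudogene", contig_edge = TRUE,
                   end = 150L, nt_seq = clean,
                   aa_seq = paste(rep("A", 50), collapse = ""))
  call <- apply_contig_edge_rule(g1[1, ])
  expect_equal(call$new_status, "intact")
  expect_equal(call$rule_fired, "contig_edge_active")

  with_stop <- paste0(substr(clean, 1, 60), "TAA", substr(clean, 64, 150))
  g2 <- g1; g2$nt_seq <- with_stop
  call2 <- apply_contig_edge_rule(g2[1, ])
  expect_equal(call2$new_status, "pseudogene")

  g3 <- g1; g3$contig_edge <- FALSE
  call3 <- apply_contig_edge_rule(g3[1, ])
  expect_equal(call3$new_status, "pseudogene")
  expect_equal(call3$rule_fired, "no_change")

  # a trailing partial codon (edge truncation) is ignored
  g4 <- g1; g4$nt_seq <- paste0(clean, "TA"); g4$end <- 152L
  expect_equal(apply_contig_edge_rule(g4[1, ])$new_status, "intact")
})

test_that("the full triage is deterministic and idempotent", {
  cfg <- evolution_config(ancestral_size = 40, pseudo_prob = 0.15,
                          loss_prob = 0.05, hgt_rate = 1, dup_prob = 0,
                          syn_rate = 0, nonsyn_rate = 0, seed = 9)
  sim <- simulate_evolution(cfg)
  run1 <- run_pipeline(sim$genomes)
  # feed the classified statuses back through the triage
  gs2 <- sim$genomes
  gs2$genes$status <- unname(run1$statuses[gs2$genes$gene_id])
  cls2 <- classify_gene_status(gs2, run1$partition, run1$hits)
  expect_equal(cls2$statuses, run1$statuses)
})

test_that("on simulated truncations the classifier is perfectly sensitive and specific", {
  cfg <- evolution_config(ancestral_size = 150, pseudo_prob = 0.12,
                          loss_prob = 0.05, hgt_rate = 0, dup_prob = 0,
                          syn_rate = 0, nonsyn_rate = 0, domain_frac = 0,
                          seed = 17)
  sim <- simulate_evolution(cfg)
  run <- run_pipeline(sim$genomes)
  st <- truth_observed_states(sim$truth)
  genes <- sim$genomes$genes
  fam <- true_family(genes$gene_id)
  key <- paste(fam, genes$genome_id)
  truth_obs <- setNames(st$observed, paste(st$family, st$genome))
  got <- unname(run$statuses[genes$gene_id])
  want <- unname(truth_obs[key])
  expect_equal(got, want)
  expect_gt(sum(want == "pseudogene"), 20)
})
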