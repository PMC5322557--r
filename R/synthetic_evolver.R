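# Gene-content evolution simulator: an ancestral repertoire evolving along
# a species tree with per-branch loss, truncating pseudogenization,
# mobile-element acquisition, duplication and codon substitution with
# separate synonymous/nonsynonymous rates. Every event is recorded in a
# truth ledger so downstream inference can be validated exactly.

#' Default five-genome species tree
#'
#' Three ingroup genomes (`A`, `B` forming the named clade `AB`, plus `C`)
#' and two outgroups (`O1`, `O2`), mirroring a genus of three symbiont
#' strains with two progressively distant relatives.
#'
#' @return A rooted `phylo` tree with labelled internal nodes.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = "(((A:1,B:1)N1:1,C:2)ING:1,(O1:1.5,O2:1.5)OUT:1)ROOT;")
}

#' Simulator configuration
#'
#' Per-branch parameters (`loss_prob`, `pseudo_prob`, `hgt_rate`,
#' `dup_prob`, `syn_rate`, `nonsyn_rate`) may be a single number applied to
#' every branch, or a named vector keyed by the child node label of each
#' branch (leaf label or internal node label).
#'
#' @param ancestral_size Number of ancestral gene families.
#' @param tree Rooted `phylo` species tree (internal labels added when
#'   missing).
#' @param roles Named vector `genome -> ingroup|outgroup`.
#' @param clades Named list of ingroup clades.
#' @param loss_prob Per-branch probability that an intact family is lost.
#' @param pseudo_prob Per-branch probability that an intact family is
#'   pseudogenized (truncated to 20-79% of its codons).
#' @param hgt_rate Expected mobile-element acquisitions per branch.
#' @param dup_prob Per-branch probability that an intact family gains a
#'   second within-genome copy (applied on terminal branches only: the
#'   model covers recent duplications).
#' @param syn_rate,nonsyn_rate Expected substitutions per synonymous /
#'   nonsynonymous site per branch.
#' @param codon_len_mean,codon_len_min Gene length distribution (codons,
#'   excluding the stop): `codon_len_min` plus a geometric tail with the
#'   stated mean.
#' @param domain_frac Fraction of ancestral families carrying an annotated
#'   domain.
#' @param seed Integer seed; identical configs give identical output.
#' @param generate_sequences Set `FALSE` for gene-content-only simulations
#'   (much faster; no FASTA material).
#' @return An `evolution_config` list, validated.
#' @export
evolution_config <- function(ancestral_size = 1265,
                             tree = default_species_tree(),
                             roles = c(A = "ingroup", B = "ingroup",
                                       C = "ingroup", O1 = "outgroup",
                                       O2 = "outgroup"),
                             clades = list(AB = c("A", "B")),
                             loss_prob = 0.15, pseudo_prob = 0.05,
                             hgt_rate = 2, dup_prob = 0.01,
                             syn_rate = 0.05, nonsyn_rate = 0.05,
                             codon_len_mean = 300, codon_len_min = 150,
                             domain_frac = 0.3, seed = 1,
                             generate_sequences = TRUE) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  cfg <- list(ancestral_size = as.integer(ancestral_size), tree = tree,
              roles = roles, clades = clades, loss_prob = loss_prob,
              pseudo_prob = pseudo_prob, hgt_rate = hgt_rate,
              dup_prob = dup_prob, syn_rate = syn_rate,
              nonsyn_rate = nonsyn_rate, codon_len_mean = codon_len_mean,
              codon_len_min = as.integer(codon_len_min),
              domain_frac = domain_frac, seed = as.integer(seed),
              generate_sequences = isTRUE(generate_sequences))
  class(cfg) <- "evolution_config"
  validate_evolution_config(cfg)
  cfg
}

#' @rdname evolution_config
#' @param config An `evolution_config`.
#' @export
validate_evolution_config <- function(config) {
  cfg <- config
  if (cfg$ancestral_size < 1) stop("ancestral_size must be >= 1")
  labels <- .branch_child_labels(cfg$tree)
  for (nm in c("loss_prob", "pseudo_prob", "dup_prob")) {
    v <- .per_branch(cfg[[nm]], labels, nm)
    if (any(v < 0 | v > 1)) stop(nm, " must lie in [0, 1]")
  }
  lp <- .per_branch(cfg$loss_prob, labels, "loss_prob")
  pp <- .per_branch(cfg$pseudo_prob, labels, "pseudo_prob")
  if (any(lp + pp > 1))
    stop("loss_prob + pseudo_prob must be <= 1 on every branch")
  for (nm in c("hgt_rate", "syn_rate", "nonsyn_rate")) {
    v <- .per_branch(cfg[[nm]], labels, nm)
    if (any(v < 0)) stop(nm, " must be >= 0")
  }
  if (cfg$codon_len_mean <= cfg$codon_len_min)
    stop("codon_len_mean must exceed codon_len_min")
  if (cfg$domain_frac < 0 || cfg$domain_frac > 1)
    stop("domain_frac must lie in [0, 1]")
  if (!setequal(names(cfg$roles), cfg$tree$tip.label))
    stop("roles must name exactly the tree's tips")
  invisible(cfg)
}

#' Read a simulator configuration from YAML or JSON
#'
#' Field names mirror [evolution_config()]; `tree` may be a Newick string.
#'
#' @param path YAML or JSON file.
#' @return An `evolution_config`.
#' @export
read_evolution_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$tree) && is.character(raw$tree))
    raw$tree <- ape::read.tree(text = raw$tree)
  if (!is.null(raw$roles)) raw$roles <- unlist(raw$roles)
  do.call(evolution_config, raw)
}

# label of the child node of every edge, in tree$edge order
.branch_child_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  lab <- character(length(child))
  is_tip <- child <= ntip
  lab[is_tip] <- tree$tip.label[child[is_tip]]
  lab[!is_tip] <- tree$node.label[child[!is_tip] - ntip]
  lab
}

.per_branch <- function(value, labels, what) {
  if (length(value) == 1 && is.null(names(value)))
    return(setNames(rep(as.numeric(value), length(labels)), labels))
  miss <- setdiff(labels, names(value))
  if (length(miss))
    stop(what, " missing value(s) for branch(es): ", paste(miss, collapse = ", "))
  setNames(as.numeric(value[labels]), labels)
}

# vectorized codon substitution on one CDS for one branch; returns the new
# codons and a log of applied changes (at most one change per codon per
# branch; multiple hits still arise across branches)
.mutate_codons <- function(codons, syn_rate, nonsyn_rate) {
  tab <- .codon_tables()
  len <- length(codons)
  S <- sum(tab$syn_sites[codons]); N <- 3 * len - S
  nS <- rpois(1, syn_rate * S); nN <- rpois(1, nonsyn_rate * N)
  empty <- data.frame(codon_idx = integer(0), nt_pos = integer(0),
                      from = character(0), to = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (nS + nN == 0) return(list(codons = codons, log = empty))
  synm <- tab$syn[codons, , drop = FALSE]
  okns <- !tab$syn[codons, , drop = FALSE] & !tab$makes_stop[codons, , drop = FALSE]
  pick <- function(mat, n) {
    slots <- which(mat)
    if (n >= length(slots)) slots else sample(slots, n)
  }
  chosen <- c(pick(synm, nS), pick(okns, nN))
  types <- rep(c("syn", "nonsyn"), c(min(nS, sum(synm)), min(nN, sum(okns))))
  ord <- sample.int(length(chosen))
  chosen <- chosen[ord]; types <- types[ord]
  ci <- ((chosen - 1) %% len) + 1L       # codon index (column-major matrix)
  jj <- ((chosen - 1) %/% len) + 1L      # neighbour slot 1..9
  keep <- !duplicated(ci)
  ci <- ci[keep]; jj <- jj[keep]; types <- types[keep]
  old <- codons[ci]
  codons[ci] <- tab$new_codon[cbind(old, jj)]
  log <- data.frame(codon_idx = ci,
                    nt_pos = 3L * (ci - 1L) + tab$pos_of[jj],
                    from = tab$from_nt[cbind(old, jj)],
                    to = tab$to_nt[cbind(old, jj)],
                    type = types, stringsAsFactors = FALSE)
  list(codons = codons, log = log)
}

#' Simulate gene-content evolution along a species tree
#'
#' Draws an ancestral repertoire of intact CDSs (ATG start, single terminal
#' stop), then walks the tree applying, per branch and family: loss, else
#' truncating pseudogenization (20-79% of codons retained, destroying an
#' annotated domain with probability 1/2 when one exists), else retention;
#' plus within-genome duplication, mobile-element acquisition (Poisson),
#' and codon substitutions at separate synonymous/nonsynonymous rates. A
#' pseudogene persists downstream and is never re-lost.
#'
#' @param config An [evolution_config()].
#' @return List with `genomes` (a [genome_set()]) and `truth` (a
#'   `truth_table`: family metadata with ingroup-ancestor states, per
#'   (family, genome) true states, the branch event ledger and the
#'   substitution ledger).
#' @export
simulate_evolution <- function(config) {
  cfg <- validate_evolution_config(config)
  set.seed(cfg$seed)
  tab <- .codon_tables()
  tree <- cfg$tree
  ntip <- length(tree$tip.label)
  labels <- .branch_child_labels(tree)
  lp <- .per_branch(cfg$loss_prob, labels, "loss_prob")
  pp <- .per_branch(cfg$pseudo_prob, labels, "pseudo_prob")
  hr <- .per_branch(cfg$hgt_rate, labels, "hgt_rate")
  dp <- .per_branch(cfg$dup_prob, labels, "dup_prob")
  sr <- .per_branch(cfg$syn_rate, labels, "syn_rate")
  nr <- .per_branch(cfg$nonsyn_rate, labels, "nonsyn_rate")

  nfam <- cfg$ancestral_size
  fam_ids <- sprintf("F%05d", seq_len(nfam))
  lens <- cfg$codon_len_min +
    rgeom(nfam, 1 / (cfg$codon_len_mean - cfg$codon_len_min + 1))
  has_dom <- runif(nfam) < cfg$domain_frac
  dom_start <- ifelse(has_dom, pmax(2L, floor(0.25 * lens)), NA_integer_)
  dom_end <- ifelse(has_dom, pmin(lens - 1L, floor(0.60 * lens)), NA_integer_)
  dom_id <- ifelse(has_dom, sprintf("DOM%05d", seq_len(nfam)), NA_character_)
  atg <- match("ATG", tab$codons)
  anc_seqs <- if (cfg$generate_sequences)
    lapply(lens, function(L) c(atg, sample(tab$sense, L - 1, replace = TRUE)))
  else vector("list", nfam)

  # mutable per-copy state carried down the tree
  root_state <- data.frame(family = fam_ids, copy = 1L, state = "intact",
                           len = lens, mobile = "none",
                           dom_id = dom_id, dom_start = dom_start,
                           dom_end = dom_end, ancestral = TRUE,
                           stringsAsFactors = FALSE)
  root_state$codons <- anc_seqs

  mrca_node <- if (sum(cfg$roles == "ingroup") >= 2)
    ape::getMRCA(tree, names(cfg$roles)[cfg$roles == "ingroup"])
  else which(cfg$roles[tree$tip.label] == "ingroup")

  events <- list(); subs <- list(); leaf_states <- list()
  mrca_state <- NULL
  hgt_counter <- 0L
  mobile_pool <- c("phage", "plasmid", "transposase", "toxin_antitoxin")

  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- ntip + 1L

  walk <- function(node, state) {
    if (node == mrca_node) mrca_state <<- state
    if (node <= ntip) { leaf_states[[tree$tip.label[node]]] <<- state; return(invisible()) }
    for (ei in children_of[[as.character(node)]]) {
      child <- tree$edge[ei, 2]
      lab <- labels[ei]
      st <- state
      # family-level loss / pseudogenization (intact families only)
      fams <- unique(st$family[st$state == "intact"])
      u <- runif(length(fams))
      lost <- fams[u < lp[lab]]
      pseudo <- fams[u >= lp[lab] & u < lp[lab] + pp[lab]]
      if (length(lost)) {
        events[[length(events) + 1L]] <<-
          data.frame(branch = lab, type = "loss", family = lost,
                     detail = "", stringsAsFactors = FALSE)
        st <- st[!(st$family %in% lost), , drop = FALSE]
      }
      for (f in pseudo) {
        rows <- which(st$family == f)
        L <- st$len[rows[1]]
        lo <- max(1L, ceiling(0.20 * L))
        hi <- min(floor(0.79 * L), ceiling(0.80 * L) - 1L)
        de <- st$dom_end[rows[1]]
        new_len <- if (!is.na(de) && de > lo && de <= hi) {
          if (runif(1) < 0.5) lo + floor(runif(1) * (de - lo))        # destroy
          else de + floor(runif(1) * (hi - de + 1L))                  # preserve
        } else lo + floor(runif(1) * (hi - lo + 1L))
        new_len <- max(lo, min(hi, new_len))
        for (r in rows) {
          st$len[r] <- new_len
          if (cfg$generate_sequences)
            st$codons[[r]] <- st$codons[[r]][seq_len(new_len)]
          if (!is.na(st$dom_end[r]) && st$dom_end[r] > new_len) {
            st$dom_id[r] <- NA; st$dom_start[r] <- NA; st$dom_end[r] <- NA
          }
        }
        st$state[rows] <- "pseudogene"
        events[[length(events) + 1L]] <<-
          data.frame(branch = lab, type = "pseudogenization", family = f,
                     detail = as.character(new_len), stringsAsFactors = FALSE)
      }
      # duplication of intact families: terminal branches only, so every
      # duplicate is recent (old paralogs would legitimately be split by
      # best-hit clustering and are outside the model)
      fams <- if (child <= ntip) unique(st$family[st$state == "intact"])
              else character(0)
      dups <- fams[runif(length(fams)) < dp[lab]]
      for (f in dups) {
        r <- which(st$family == f)[1]
        newrow <- st[r, , drop = FALSE]
        newrow$copy <- max(st$copy[st$family == f]) + 1L
        st <- rbind(st, newrow)
        events[[length(events) + 1L]] <<-
          data.frame(branch = lab, type = "duplication", family = f,
                     detail = "", stringsAsFactors = FALSE)
      }
      # mobile-element acquisition
      ng <- rpois(1, hr[lab])
      if (ng > 0) {
        for (t in seq_len(ng)) {
          hgt_counter <<- hgt_counter + 1L
          mf <- sprintf("M%04d", hgt_counter)
          L <- cfg$codon_len_min +
            rgeom(1, 1 / (cfg$codon_len_mean - cfg$codon_len_min + 1))
          cat_ <- sample(mobile_pool, 1)
          newrow <- data.frame(family = mf, copy = 1L, state = "intact",
                               len = L, mobile = cat_, dom_id = NA_character_,
                               dom_start = NA_integer_, dom_end = NA_integer_,
                               ancestral = FALSE, stringsAsFactors = FALSE)
          newrow$codons <- if (cfg$generate_sequences)
            list(c(atg, sample(tab$sense, L - 1, replace = TRUE)))
          else list(NULL)
          st <- rbind(st, newrow)
          events[[length(events) + 1L]] <<-
            data.frame(branch = lab, type = "acquisition", family = mf,
                       detail = cat_, stringsAsFactors = FALSE)
        }
      }
      # codon substitutions
      if (cfg$generate_sequences && (sr[lab] > 0 || nr[lab] > 0)) {
        for (r in seq_len(nrow(st))) {
          mut <- .mutate_codons(st$codons[[r]], sr[lab], nr[lab])
          if (nrow(mut$log)) {
            st$codons[[r]] <- mut$codons
            mut$log$branch <- lab
            mut$log$family <- st$family[r]
            mut$log$copy <- st$copy[r]
            subs[[length(subs) + 1L]] <<- mut$log
          }
        }
      }
      walk(child, st)
    }
    invisible()
  }
  walk(root, root_state)

  genome_ids <- tree$tip.label
  gene_rows <- list()
  for (g in genome_ids) {
    st <- leaf_states[[g]]
    if (is.null(st) || nrow(st) == 0) next
    st <- st[order(st$family, st$copy), , drop = FALSE]
    ids <- sprintf("%s_%s_c%d", g, st$family, st$copy)
    nt <- aa <- rep(NA_character_, nrow(st))
    if (cfg$generate_sequences) {
      stops <- match(c("TAA", "TAG", "TGA"), tab$codons)
      for (r in seq_len(nrow(st))) {
        cod <- st$codons[[r]]
        aa[r] <- .translate_codons(cod)
        nt[r] <- if (st$state[r] == "intact")
          paste0(.decode_codons(cod), tab$codons[stops[1 + (r %% 3)]])
        else .decode_codons(cod)
      }
    }
    ntlen <- ifelse(st$state == "intact", 3L * (st$len + 1L), 3L * st$len)
    starts <- cumsum(c(1L, head(ntlen + 100L, -1L)))
    no_dom <- .parse_domains("")
    doms <- lapply(seq_len(nrow(st)), function(r) {
      if (is.na(st$dom_id[r])) no_dom
      else data.frame(domain_id = st$dom_id[r], aa_start = st$dom_start[r],
                      aa_end = st$dom_end[r], stringsAsFactors = FALSE)
    })
    gene_rows[[g]] <- gene_table(
      gene_id = ids, genome_id = g, contig_id = paste0(g, "_chr"),
      start = starts, end = starts + ntlen - 1L, strand = "+",
      status = "unclassified", contig_edge = FALSE,
      mobile_category = st$mobile, nt_seq = nt, aa_seq = aa, domains = doms)
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows)
           else gene_table(character(0), character(0))
  class(genes) <- c("gene_table", "data.frame")
  gs <- genome_set(genes, cfg$roles, cfg$clades, tree)

  # truth ledger
  fam_meta <- data.frame(family = fam_ids, orig_len = lens,
                         mobile_category = "none", domain_id = dom_id,
                         dom_end = dom_end, stringsAsFactors = FALSE)
  anc_state <- rep("absent", nfam)
  if (!is.null(mrca_state)) {
    m <- mrca_state[!duplicated(mrca_state$family), ]
    anc_state[match(m$family[m$family %in% fam_ids], fam_ids)] <-
      m$state[m$family %in% fam_ids]
  }
  fam_meta$mrca_state <- anc_state
  fam_meta$ancestral <- anc_state %in% c("intact", "pseudogene")
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(0), type = character(0),
               family = character(0), detail = character(0))
  mob <- ev[ev$type == "acquisition", , drop = FALSE]
  if (nrow(mob))
    fam_meta <- rbind(fam_meta,
      data.frame(family = mob$family, orig_len = NA_integer_,
                 mobile_category = mob$detail, domain_id = NA_character_,
                 dom_end = NA_integer_, mrca_state = "absent",
                 ancestral = FALSE, stringsAsFactors = FALSE))
  states <- list()
  for (g in genome_ids) {
    st <- leaf_states[[g]]
    if (is.null(st)) st <- root_state[0, ]
    st1 <- st[!duplicated(st$family), , drop = FALSE]
    states[[g]] <- data.frame(family = fam_meta$family, genome = g,
      state = ifelse(fam_meta$family %in% st1$family,
                     st1$state[match(fam_meta$family, st1$family)], "absent"),
      len = ifelse(fam_meta$family %in% st1$family,
                   st1$len[match(fam_meta$family, st1$family)], NA_integer_),
      domain_preserved = ifelse(fam_meta$family %in% st1$family,
                                !is.na(st1$dom_id[match(fam_meta$family, st1$family)]),
                                NA),
      stringsAsFactors = FALSE)
  }
  truth <- structure(list(
    families = fam_meta,
    states = do.call(rbind, states),
    events = ev,
    substitutions = if (length(subs)) do.call(rbind, subs) else
      data.frame(codon_idx = integer(0), nt_pos = integer(0),
                 from = character(0), to = character(0), type = character(0),
                 branch = character(0), family = character(0),
                 copy = integer(0)),
    ancestor_sequences = setNames(anc_seqs, fam_ids),
    mrca_node = mrca_node, tree = tree, seed = cfg$seed),
    class = "truth_table")
  rownames(truth$states) <- NULL
  list(genomes = gs, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", nrow(x$families), "families (",
      sum(x$families$ancestral), "ancestral at the ingroup MRCA ),",
      nrow(x$events), "branch events,", nrow(x$substitutions),
      "substitutions\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits per-genome protein FASTA, CDS FASTA and gene-table TSV (status
#' column `unclassified`: classification is the pipeline's job), the Newick
#' tree, and truth TSVs. Re-running with the same config yields
#' byte-identical files.
#'
#' @param sim Result of [simulate_evolution()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
emit_simulation <- function(sim, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  genes <- sim$genomes$genes
  paths <- character(0)
  for (g in names(sim$genomes$roles)) {
    sub <- genes[genes$genome_id == g, , drop = FALSE]
    p1 <- file.path(outdir, paste0(g, "_proteins.faa"))
    p2 <- file.path(outdir, paste0(g, "_cds.fna"))
    p3 <- file.path(outdir, paste0(g, "_genes.tsv"))
    if (!all(is.na(sub$aa_seq)))
      write_fasta(setNames(sub$aa_seq, sub$gene_id), p1)
    if (!all(is.na(sub$nt_seq)))
      write_fasta(setNames(sub$nt_seq, sub$gene_id), p2)
    write_gene_table(sub, p3, statuses = rep("unclassified", nrow(sub)))
    paths <- c(paths, p1, p2, p3)
  }
  pt <- file.path(outdir, "tree.nwk")
  write_tree(sim$genomes$tree, pt)
  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    con <- file(p, "wb")
    writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
    if (nrow(df))
      writeLines(do.call(paste, c(lapply(unname(df), as.character), sep = "\t")),
                 con, sep = "\n")
    close(con)
    p
  }
  tr <- sim$truth
  paths <- c(paths, pt,
             tsv(tr$families, "truth_families.tsv"),
             tsv(tr$states, "truth_states.tsv"),
             tsv(tr$events, "truth_events.tsv"),
             tsv(tr$substitutions, "truth_substitutions.tsv"))
  invisible(paths)
}

#' Read back an emitted simulation as a genome set
#'
#' @param outdir Directory written by [emit_simulation()].
#' @param roles,clades As for [genome_set()].
#' @return A [genome_set()].
#' @export
read_simulation <- function(outdir, roles, clades = list()) {
  tree <- read_tree(file.path(outdir, "tree.nwk"))
  tabs <- list()
  for (g in names(roles)) {
    gt <- read_gene_table(file.path(outdir, paste0(g, "_genes.tsv")), g)
    aafile <- file.path(outdir, paste0(g, "_proteins.faa"))
    ntfile <- file.path(outdir, paste0(g, "_cds.fna"))
    if (file.exists(aafile)) {
      aa <- read_fasta(aafile, "protein")
      gt$aa_seq <- unname(aa[gt$gene_id])
    }
    if (file.exists(ntfile)) {
      nt <- read_fasta(ntfile, "nucleotide")
      gt$nt_seq <- unname(nt[gt$gene_id])
    }
    tabs[[g]] <- gt
  }
  genes <- do.call(rbind, tabs)
  class(genes) <- c("gene_table", "data.frame")
  genome_set(genes, roles, clades, tree)
}
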