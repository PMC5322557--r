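# Truth-side replay: the expected observable outcome of the annotation
# rules given a simulation's event ledger. Used to validate the inference
# pipeline against ground truth.

#' Expected observed states under the annotation rules
#'
#' Maps the simulator's true per-(family, genome) states to the states the
#' annotation rules can recover: a true pseudogene is observable as a
#' pseudogene only when some other genome carries a true-intact reference
#' member, and not when its truncation preserved the family's annotated
#' domain (the domain exception keeps it intact).
#'
#' The predicate mirrors the stated classification rules on the truth
#' ledger's lengths: the reference pool of a genome's member is the
#' true-intact members of the other genomes when any exist, otherwise all
#' other-genome members, restricted to those within 80% of the longest;
#' the member is observable as a pseudogene iff it is truly one, a
#' reference exists, its length is below 80% of the reference median, and
#' the domain exception does not fire (family domain present, preserved by
#' every reference and by the member).
#'
#' @param truth A `truth_table` from [simulate_evolution()].
#' @return data.frame like `truth$states` with an `observed` column.
#' @export
truth_observed_states <- function(truth) {
  st <- truth$states
  fam <- truth$families
  has_dom <- setNames(!is.na(fam$domain_id), fam$family)
  obs <- st$state
  for (f in unique(st$family)) {
    rows <- which(st$family == f & st$state != "absent")
    for (r in rows) {
      if (st$state[r] != "pseudogene") next
      others <- rows[st$genome[rows] != st$genome[r]]
      pool <- if (any(st$state[others] == "intact"))
        others[st$state[others] == "intact"] else others
      if (length(pool) == 0) { obs[r] <- "intact"; next }
      refs <- pool[st$len[pool] >= 0.8 * max(st$len[pool])]
      ratio <- st$len[r] / median(st$len[refs])
      anc_dom <- isTRUE(has_dom[[f]]) && all(st$domain_preserved[refs])
      preserved <- anc_dom && isTRUE(st$domain_preserved[r])
      if (ratio >= 0.8 || preserved) obs[r] <- "intact"
    }
  }
  st$observed <- obs
  st
}

#' State matrix from a truth table
#'
#' @param truth A `truth_table`.
#' @param observed Use the rule-observable states ([truth_observed_states()])
#'   rather than the raw true states.
#' @return A `state_matrix` keyed by true family ids.
#' @export
truth_state_matrix <- function(truth, observed = TRUE) {
  st <- if (observed) truth_observed_states(truth) else
    transform(truth$states, observed = state)
  genomes <- sort(unique(st$genome))
  fams <- unique(truth$families$family)
  m <- matrix("absent", length(fams), length(genomes),
              dimnames = list(fams, genomes))
  m[cbind(match(st$family, fams), match(st$genome, genomes))] <- st$observed
  counts <- matrix(as.integer(m != "absent"), length(fams), length(genomes),
                   dimnames = dimnames(m))
  structure(list(states = m, counts = counts), class = "state_matrix")
}

#' Truth-side ancestral calls
#'
#' Applies the two ancestral-presence conditions to the rule-observable
#' truth states: the recoverable ancestral set a perfect pipeline should
#' return.
#'
#' @param truth A `truth_table`.
#' @param roles,clades,clade_presence As for [call_ancestral()].
#' @return `ancestral_calls` data.frame keyed by true family ids.
#' @export
truth_ancestral_calls <- function(truth, roles, clades,
                                  clade_presence = "any") {
  sm <- truth_state_matrix(truth, observed = TRUE)
  mob <- setNames(truth$families$mobile_category, truth$families$family)
  call_ancestral(sm, roles, clades, family_mobile = mob,
                 clade_presence = clade_presence)
}

#' Replay recorded events to reconstruct an extant CDS
#'
#' Walks the root-to-tip path, applying the truncation and substitution
#' ledgers in order, and returns the reconstructed CDS (codon string,
#' without a stop codon). Verifying this equals the emitted sequence is
#' the simulator's bookkeeping invariant.
#'
#' @param truth A `truth_table` (from a run with sequences).
#' @param family Family id.
#' @param genome Tip genome id.
#' @return Codon string, or `NA` if the family is absent from the genome.
#' @export
truth_replay_cds <- function(truth, family, genome) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  tip <- match(genome, tree$tip.label)
  if (is.na(tip)) stop("unknown genome: ", genome)
  path_nodes <- ape::nodepath(tree, from = ntip + 1L, to = tip)
  labels <- .branch_child_labels(tree)
  child_nodes <- tree$edge[, 2]
  path_labels <- labels[match(path_nodes[-1], child_nodes)]
  cod <- truth$ancestor_sequences[[family]]
  if (is.null(cod)) return(NA_character_)
  tab <- .codon_tables()
  ev <- truth$events
  subs <- truth$substitutions
  for (lab in path_labels) {
    e <- ev[ev$branch == lab & ev$family == family, , drop = FALSE]
    if (any(e$type == "loss")) return(NA_character_)
    if (any(e$type == "pseudogenization"))
      cod <- cod[seq_len(as.integer(e$detail[e$type == "pseudogenization"][1]))]
    s <- subs[subs$branch == lab & subs$family == family & subs$copy == 1L, ,
              drop = FALSE]
    if (nrow(s)) {
      for (r in seq_len(nrow(s))) {
        ci <- s$codon_idx[r]
        chars <- strsplit(tab$codons[cod[ci]], "")[[1]]
        p <- s$nt_pos[r] - 3L * (ci - 1L)
        if (chars[p] != s$from[r])
          stop("replay mismatch at ", family, " codon ", ci)
        chars[p] <- s$to[r]
        cod[ci] <- match(paste(chars, collapse = ""), tab$codons)
      }
    }
  }
  .decode_codons(cod)
}

#' Losses recorded on the root path of each genome
#'
#' @param truth A `truth_table`.
#' @return Named integer vector `genome -> ancestral families lost` on its
#'   root-to-tip path.
#' @export
truth_root_path_losses <- function(truth) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  labels <- .branch_child_labels(tree)
  child_nodes <- tree$edge[, 2]
  anc <- truth$families$family[is.na(truth$families$mobile_category) |
                               truth$families$mobile_category == "none"]
  out <- setNames(integer(length(tree$tip.label)), tree$tip.label)
  for (g in tree$tip.label) {
    path_nodes <- ape::nodepath(tree, from = ntip + 1L,
                                to = match(g, tree$tip.label))
    pl <- labels[match(path_nodes[-1], child_nodes)]
    ev <- truth$events
    out[g] <- sum(ev$type == "loss" & ev$branch %in% pl &
                  ev$family %in% anc)
  }
  out
}
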