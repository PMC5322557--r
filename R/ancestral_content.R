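# Ancestral gene-content inference for the ingroup genus: the two presence
# conditions, the ancestrally-inactivated flag, the mobile-element
# exclusion, lineage-specific event assignment and the loss-count
# comparison test.

#' Ingroup lineages from roles and clades
#'
#' Named clades plus one singleton lineage per ingroup genome not covered
#' by a clade.
#'
#' @param roles Named vector `genome -> ingroup|outgroup`.
#' @param clades Named list of ingroup clades.
#' @return Named list `lineage -> genomes`.
#' @export
ingroup_lineages <- function(roles, clades = list()) {
  ing <- names(roles)[roles == "ingroup"]
  covered <- unlist(clades, use.names = FALSE)
  bad <- setdiff(covered, ing)
  if (length(bad)) stop("clade member(s) not in the ingroup: ",
                        paste(bad, collapse = ", "))
  lin <- clades
  for (g in setdiff(ing, covered)) lin[[g]] <- g
  if (length(lin) < 2)
    stop("at least two ingroup lineages are required")
  lin
}

#' Per-family mobile category
#'
#' A family counts as mobile when every member carries a mobile category;
#' mixed families are treated as non-mobile. Exempt categories (APSE,
#' pHD5AT) take precedence when present.
#'
#' @param partition A `family_partition`.
#' @param genes Gene table.
#' @return Named character vector `family -> category` (`"none"` for
#'   non-mobile families).
#' @export
family_mobile_category <- function(partition, genes) {
  cat_of <- setNames(genes$mobile_category, genes$gene_id)
  vapply(partition$families, function(members) {
    cats <- cat_of[members]
    cats <- cats[!is.na(cats)]
    if (length(cats) == 0 || any(cats == "none")) return("none")
    ex <- intersect(c("APSE", "pHD5AT"), cats)
    if (length(ex)) ex[1] else cats[1]
  }, "")
}

#' Call the ancestral gene content
#'
#' A family is ancestral when either condition fires: C1 -- present (intact
#' or pseudogene) in every ingroup lineage and intact in at least one
#' ingroup genome; C2 -- intact in at least one ingroup lineage and present
#' in at least one outgroup genome. A family present in every ingroup
#' genome but intact in none is flagged ancestrally inactivated (reported
#' separately, not counted ancestral). Families whose members are all
#' mobile elements are excluded unless the category is APSE or pHD5AT.
#'
#' @param sm A `state_matrix` covering all ingroup and outgroup genomes.
#' @param roles Named vector `genome -> ingroup|outgroup`.
#' @param clades Named list of ingroup clades (see [ingroup_lineages()]).
#' @param family_mobile Named vector `family -> mobile category` (e.g. from
#'   [family_mobile_category()]); missing families default to `"none"`.
#' @param clade_presence `"any"` (default): a clade counts as carrying /
#'   intact for a state when at least one of its genomes does; `"all"`:
#'   every genome must.
#' @return `ancestral_calls` data.frame: `family_id`, `ancestral`,
#'   `condition` (`C1`/`C2`/`both`/`none`), `ancestrally_inactivated`,
#'   `excluded_mobile`.
#' @export
call_ancestral <- function(sm, roles, clades, family_mobile = NULL,
                           clade_presence = c("any", "all")) {
  clade_presence <- match.arg(clade_presence)
  lin <- ingroup_lineages(roles, clades)
  genomes <- colnames(sm$states)
  miss <- setdiff(names(roles), genomes)
  if (length(miss)) stop("state matrix lacks genome(s): ",
                         paste(miss, collapse = ", "))
  ing <- names(roles)[roles == "ingroup"]
  out <- names(roles)[roles == "outgroup"]
  st <- sm$states
  fams <- rownames(st)
  if (is.null(family_mobile)) family_mobile <- setNames(character(0), character(0))
  mob <- setNames(rep("none", length(fams)), fams)
  mob[names(family_mobile)[names(family_mobile) %in% fams]] <-
    family_mobile[names(family_mobile) %in% fams]
  excluded <- mob %in% c("phage", "plasmid", "transposase", "toxin_antitoxin")
  agg <- if (clade_presence == "any") function(m) apply(m, 1, any)
         else function(m) apply(m, 1, all)
  pres <- st != "absent"
  intact <- st == "intact"
  lin_present <- sapply(lin, function(gg) agg(pres[, gg, drop = FALSE]))
  lin_intact <- sapply(lin, function(gg) agg(intact[, gg, drop = FALSE]))
  if (is.null(dim(lin_present))) {  # single family edge case
    lin_present <- matrix(lin_present, nrow = length(fams))
    lin_intact <- matrix(lin_intact, nrow = length(fams))
  }
  out_present <- if (length(out))
    apply(pres[, out, drop = FALSE], 1, any) else rep(FALSE, length(fams))
  c1 <- apply(lin_present, 1, all) &
    apply(intact[, ing, drop = FALSE], 1, any)
  c2 <- apply(lin_intact, 1, any) & out_present
  anc_inact <- apply(pres[, ing, drop = FALSE], 1, all) &
    !apply(intact[, ing, drop = FALSE], 1, any)
  ancestral <- (c1 | c2) & !excluded
  condition <- rep("none", length(fams))
  condition[ancestral & c1 & !c2] <- "C1"
  condition[ancestral & c2 & !c1] <- "C2"
  condition[ancestral & c1 & c2] <- "both"
  structure(data.frame(family_id = fams, ancestral = ancestral,
                       condition = condition,
                       ancestrally_inactivated = anc_inact & !excluded,
                       excluded_mobile = excluded,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ancestral_calls", "data.frame"))
}

#' Assign lineage-specific events
#'
#' Per ingroup lineage, every ancestral family is classified as lost
#' (absent from all its genomes), inactivated (present but pseudogene-only
#' in the lineage; presence in any genome overrides absence, intact
#' overrides pseudogene) or retained (intact somewhere in the lineage).
#' Acquisitions are non-ancestral, non-excluded families present in the
#' lineage and absent from every other ingroup lineage and all outgroups.
#'
#' @param calls An `ancestral_calls` data.frame.
#' @param sm The `state_matrix` the calls came from.
#' @param roles,clades As for [call_ancestral()].
#' @return A `lineage_events` list: per lineage, counts and family id
#'   lists for losses, inactivations, retained and acquisitions, plus the
#'   ancestral set size.
#' @export
assign_lineage_events <- function(calls, sm, roles, clades) {
  lin <- ingroup_lineages(roles, clades)
  out <- names(roles)[roles == "outgroup"]
  st <- sm$states
  anc <- calls$family_id[calls$ancestral]
  acq_pool <- calls$family_id[!calls$ancestral & !calls$excluded_mobile]
  res <- list()
  for (ln in names(lin)) {
    gg <- lin[[ln]]
    others <- unlist(lin[setdiff(names(lin), ln)], use.names = FALSE)
    sub <- st[anc, gg, drop = FALSE]
    lost <- anc[apply(sub == "absent", 1, all)]
    retained <- anc[apply(sub == "intact", 1, any)]
    inact <- setdiff(anc, c(lost, retained))
    pool <- st[acq_pool, , drop = FALSE]
    acq <- acq_pool[apply(pool[, gg, drop = FALSE] != "absent", 1, any) &
                    apply(pool[, others, drop = FALSE] == "absent", 1, all) &
                    apply(pool[, out, drop = FALSE] == "absent", 1, all)]
    res[[ln]] <- list(losses = lost, inactivations = inact,
                      retained = retained, acquisitions = acq)
  }
  structure(list(lineages = res, n_ancestral = length(anc)),
            class = "lineage_events")
}

#' @export
print.lineage_events <- function(x, ...) {
  cat("lineage_events over", x$n_ancestral, "ancestral families:\n")
  for (ln in names(x$lineages)) {
    e <- x$lineages[[ln]]
    cat(sprintf("  %s: %d lost, %d inactivated, %d retained, %d acquired\n",
                ln, length(e$losses), length(e$inactivations),
                length(e$retained), length(e$acquisitions)))
  }
  invisible(x)
}

#' Compare loss counts between two lineages
#'
#' Pearson chi-square without continuity correction on the 2x2 table
#' (lost vs not-lost) x (lineage A vs lineage B), 1 degree of freedom.
#' A goodness-of-fit variant on the raw loss counts (expected 50:50) is
#' available via `method = "gof"`.
#'
#' @param events A `lineage_events` object.
#' @param lineage_a,lineage_b Lineage names.
#' @param method `"contingency"` (default) or `"gof"`.
#' @return A `loss_comparison`: counts, `chi2`, `df`, `p_value`, `valid`
#'   (FALSE with a `reason` when a margin is zero).
#' @export
compare_loss_counts <- function(events, lineage_a, lineage_b,
                                method = c("contingency", "gof")) {
  method <- match.arg(method)
  ea <- events$lineages[[lineage_a]]; eb <- events$lineages[[lineage_b]]
  if (is.null(ea) || is.null(eb)) stop("unknown lineage name")
  n <- events$n_ancestral
  la <- length(ea$losses); lb <- length(eb$losses)
  tab <- matrix(c(la, n - la, lb, n - lb), 2, 2, byrow = TRUE,
                dimnames = list(c(lineage_a, lineage_b),
                                c("lost", "not_lost")))
  if (method == "gof") {
    if (la + lb == 0)
      return(structure(list(table = tab, chi2 = NA_real_, df = 1L,
                            p_value = NA_real_, valid = FALSE,
                            reason = "no losses", method = method),
                       class = "loss_comparison"))
    ct <- suppressWarnings(stats::chisq.test(c(la, lb), p = c(0.5, 0.5)))
    return(structure(list(table = tab, chi2 = unname(ct$statistic), df = 1L,
                          p_value = ct$p.value, valid = TRUE,
                          reason = NA_character_, method = method),
                     class = "loss_comparison"))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(structure(list(table = tab, chi2 = NA_real_, df = 1L,
                          p_value = NA_real_, valid = FALSE,
                          reason = "zero margin", method = method),
                     class = "loss_comparison"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, chi2 = unname(ct$statistic), df = 1L,
                 p_value = ct$p.value, valid = TRUE,
                 reason = NA_character_, method = method),
            class = "loss_comparison")
}

#' @export
print.loss_comparison <- function(x, ...) {
  print(x$table)
  if (x$valid)
    cat(sprintf("Pearson chi-square = %.4g, df = %d, p = %.4g\n",
                x$chi2, x$df, x$p_value))
  else cat("statistic undefined:", x$reason, "\n")
  invisible(x)
}

#' Write ancestral-content outputs
#'
#' @param calls `ancestral_calls`.
#' @param events `lineage_events`.
#' @param comparison Optional `loss_comparison`.
#' @param outdir Output directory.
#' @export
write_ancestral_outputs <- function(calls, events, comparison = NULL,
                                    outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.table(calls, file.path(outdir, "ancestral_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rows <- do.call(rbind, lapply(names(events$lineages), function(ln) {
    e <- events$lineages[[ln]]
    data.frame(lineage = ln,
               losses = length(e$losses),
               inactivations = length(e$inactivations),
               retained = length(e$retained),
               acquisitions = length(e$acquisitions),
               loss_families = paste(e$losses, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, file.path(outdir, "lineage_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(calls$family_id[calls$ancestrally_inactivated],
             file.path(outdir, "ancestrally_inactivated.txt"))
  if (!is.null(comparison))
    jsonlite::write_json(list(table = comparison$table,
                              chi2 = comparison$chi2, df = comparison$df,
                              p_value = comparison$p_value,
                              valid = comparison$valid),
                         file.path(outdir, "loss_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
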