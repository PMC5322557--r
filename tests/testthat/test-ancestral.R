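mk_sm <- function(states) {
  # states: named list family -> named character vector over genomes
  genomes <- names(states[[1]])
  m <- do.call(rbind, states)
  rownames(m) <- names(states)
  structure(list(states = m,
                 counts = matrix(as.integer(m != "absent"), nrow(m),
                                 ncol(m), dimnames = dimnames(m))),
            class = "state_matrix")
}
ROLES <- c(A = "ingroup", B = "ingroup", C = "ingroup",
           O1 = "outgroup", O2 = "outgroup")
CLADES <- list(AB = c("A", "B"))

test_that("the two presence conditions and the inactivation flag fire as stated", {
  sm <- mk_sm(list(
    # C1: present in both ingroup lineages, intact somewhere in the ingroup
    f_c1 = c(A = "intact", B = "absent", C = "pseudogene",
             O1 = "absent", O2 = "absent"),
    # C2: intact in one lineage only, present in an outgroup
    f_c2 = c(A = "absent", B = "absent", C = "intact",
             O1 = "pseudogene", O2 = "absent"),
    # pseudogene in all three ingroup genomes: not ancestral, flagged
    f_inact = c(A = "pseudogene", B = "pseudogene", C = "pseudogene",
                O1 = "absent", O2 = "absent"),
    # intact in one lineage, absent elsewhere: neither condition
    f_none = c(A = "intact", B = "intact", C = "absent",
               O1 = "absent", O2 = "absent")))
  calls <- call_ancestral(sm, ROLES, CLADES)
  got <- setNames(calls$condition, calls$family_id)
  expect_equal(got[["f_c1"]], "C1")
  expect_equal(got[["f_c2"]], "C2")
  expect_equal(got[["f_inact"]], "none")
  expect_equal(got[["f_none"]], "none")
  expect_equal(calls$ancestral, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(calls$ancestrally_inactivated, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("mobile families are excluded unless APSE or pHD5AT", {
  sm <- mk_sm(list(
    f_tra = c(A = "intact", B = "absent", C = "absent",
              O1 = "absent", O2 = "absent"),
    f_apse = c(A = "intact", B = "intact", C = "pseudogene",
               O1 = "absent", O2 = "absent"),
    f_phage = c(A = "intact", B = "intact", C = "intact",
                O1 = "intact", O2 = "intact")))
  mob <- c(f_tra = "transposase", f_apse = "APSE", f_phage = "phage")
  calls <- call_ancestral(sm, ROLES, CLADES, family_mobile = mob)
  expect_equal(calls$excluded_mobile, c(TRUE, FALSE, TRUE))
  # the phage family meets C1+C2 on states but stays excluded
  expect_equal(calls$ancestral, c(FALSE, TRUE, FALSE))
  expect_equal(calls$condition[3], "none")
})

test_that("clade presence mode 'all' tightens C1", {
  sm <- mk_sm(list(
    f = c(A = "intact", B = "absent", C = "pseudogene",
          O1 = "absent", O2 = "absent")))
  expect_true(call_ancestral(sm, ROLES, CLADES,
                             clade_presence = "any")$ancestral)
  expect_false(call_ancestral(sm, ROLES, CLADES,
                              clade_presence = "all")$ancestral)
})

test_that("adding an outgroup genome can only keep or grow the ancestral set", {
  set.seed(201)
  states <- c("intact", "pseudogene", "absent")
  for (rep in 1:30) {
    m <- matrix(sample(states, 5 * 12, TRUE,
                       prob = c(0.45, 0.2, 0.35)), 12, 5,
                dimnames = list(sprintf("f%02d", 1:12),
                                c("A", "B", "C", "O1", "O2")))
    sm_small <- structure(list(states = m[, 1:4, drop = FALSE],
                               counts = matrix(1L, 12, 4)),
                          class = "state_matrix")
    sm_full <- structure(list(states = m, counts = matrix(1L, 12, 5)),
                         class = "state_matrix")
    roles4 <- ROLES[1:4]
    a1 <- call_ancestral(sm_small, roles4, CLADES)
    a2 <- call_ancestral(sm_full, ROLES, CLADES)
    expect_true(all(a2$ancestral[a1$ancestral]))
  }
})

test_that("lineage events partition the ancestral set", {
  sm <- mk_sm(list(
    kept = c(A = "intact", B = "intact", C = "intact",
             O1 = "intact", O2 = "absent"),
    lostB = c(A = "absent", B = "absent", C = "intact",
              O1 = "intact", O2 = "intact"),
    inactAB = c(A = "pseudogene", B = "absent", C = "intact",
                O1 = "intact", O2 = "absent"),
    acqC = c(A = "absent", B = "absent", C = "intact",
             O1 = "absent", O2 = "absent")))
  calls <- call_ancestral(sm, ROLES, CLADES)
  ev <- assign_lineage_events(calls, sm, ROLES, CLADES)
  expect_equal(ev$n_ancestral, 3)
  ab <- ev$lineages$AB; cc <- ev$lineages$C
  expect_setequal(ab$losses, "lostB")
  # pseudogene in one clade genome, absent in the other: inactivation
  expect_setequal(ab$inactivations, "inactAB")
  expect_setequal(ab$retained, "kept")
  expect_setequal(cc$retained, c("kept", "lostB", "inactAB"))
  expect_setequal(cc$acquisitions, "acqC")
  expect_length(ab$acquisitions, 0)
  for (ln in names(ev$lineages)) {
    e <- ev$lineages[[ln]]
    expect_equal(length(e$losses) + length(e$inactivations) +
                 length(e$retained), ev$n_ancestral)
  }
})

test_that("the loss-count chi-square matches the closed form", {
  ev <- structure(list(lineages = list(
    L1 = list(losses = sprintf("f%d", 1:30), inactivations = character(0),
              retained = sprintf("r%d", 1:70), acquisitions = character(0)),
    L2 = list(losses = sprintf("g%d", 1:10), inactivations = character(0),
              retained = sprintf("s%d", 1:90), acquisitions = character(0))),
    n_ancestral = 100L), class = "lineage_events")
  cmp <- compare_loss_counts(ev, "L1", "L2")
  # closed-form Pearson on [[30,70],[10,90]]
  expect_equal(cmp$chi2, 12.5)
  expect_equal(cmp$df, 1L)
  expect_equal(cmp$p_value, pchisq(12.5, 1, lower.tail = FALSE))
  expect_equal(cmp$p_value, 4.07e-4, tolerance = 1e-2)

  # identical rows: no signal
  ev$lineages$L2 <- ev$lineages$L1
  cmp2 <- compare_loss_counts(ev, "L1", "L2")
  expect_equal(cmp2$chi2, 0)
  expect_equal(cmp2$p_value, 1)

  # zero margin: flagged undefined
  ev$lineages$L1$losses <- character(0)
  ev$lineages$L2$losses <- character(0)
  cmp3 <- compare_loss_counts(ev, "L1", "L2")
  expect_false(cmp3$valid)
  expect_equal(cmp3$reason, "zero margin")

  # goodness-of-fit variant on raw loss counts
  ev$lineages$L1$losses <- sprintf("f%d", 1:30)
  ev$lineages$L2$losses <- sprintf("g%d", 1:10)
  g <- compare_loss_counts(ev, "L1", "L2", method = "gof")
  expect_equal(g$chi2, (30 - 20)^2 / 20 + (10 - 20)^2 / 20)
})

test_that("recovered lineage losses equal the truth ledger on simulated data", {
  lp <- c(A = 0.1, B = 0.1, C = 0.25, O1 = 0.05, O2 = 0.05,
          N1 = 0.1, ING = 0, OUT = 0)
  cfg <- evolution_config(ancestral_size = 400, loss_prob = lp,
                          pseudo_prob = 0.05, hgt_rate = 1, dup_prob = 0,
                          syn_rate = 0, nonsyn_rate = 0, seed = 77)
  sim <- simulate_evolution(cfg)
  run <- run_pipeline(sim$genomes)
  tc <- truth_ancestral_calls(sim$truth, sim$genomes$roles,
                              sim$genomes$clades)
  tsm <- truth_state_matrix(sim$truth)
  tev <- assign_lineage_events(tc, tsm, sim$genomes$roles,
                               sim$genomes$clades)
  iev <- run$lineage_events
  # same loss counts per lineage as the truth replay
  for (ln in names(tev$lineages)) {
    expect_equal(length(iev$lineages[[ln]]$losses),
                 length(tev$lineages[[ln]]$losses), label = ln)
    expect_equal(length(iev$lineages[[ln]]$inactivations),
                 length(tev$lineages[[ln]]$inactivations), label = ln)
  }
  expect_equal(iev$n_ancestral, tev$n_ancestral)
})
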