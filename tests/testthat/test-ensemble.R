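table1 <- load_crossdock_example()

test_that("aggregation takes the best score across members and ignores failures", {
  agg <- aggregate_scores(table1$matrix, table1$matrix$conformation_ids)
  expect_equal(agg[["3G0W"]], -11.2)
  expect_equal(agg[["2PNU"]], -14.2)  # four failed cells ignored
  # a ligand failing on all chosen members is failed for the ensemble
  agg2 <- aggregate_scores(table1$matrix, c("3B66", "3G0W"))
  expect_true(is.na(agg2[["2PNU"]]))
  expect_error(aggregate_scores(table1$matrix, "nope"), "unknown conformation")
  expect_error(aggregate_scores(table1$matrix, character(0)), "non-empty")
})

test_that("aggregation is monotone: adding members can only improve scores", {
  set.seed(21)
  for (rep in 1:20) {
    sc <- random_screen(10, 6, fail_p = 0.3)
    conf <- sc$matrix$conformation_ids
    small <- sample(conf, 2)
    big <- union(small, sample(conf, 3))
    a_small <- aggregate_scores(sc$matrix, small)
    a_big <- aggregate_scores(sc$matrix, big)
    # failed treated as +Inf for the comparison
    a_small[is.na(a_small)] <- Inf
    a_big[is.na(a_big)] <- Inf
    expect_true(all(a_big <= a_small))
  }
})

test_that("full-pool aggregation recovers each ligand's native-structure score", {
  # cross-docking property: every ligand scores best on its native structure,
  # so the full-ensemble minimum sits on the diagonal of the table
  agg <- aggregate_scores(table1$matrix, table1$matrix$conformation_ids)
  for (l in table1$matrix$ligand_ids)
    expect_equal(agg[[l]], table1$matrix$scores[l, l])
})

test_that("evaluate_ensemble computes single and summed AUC objectives", {
  # actives dock at -12 everywhere, decoys always fail -> perfect enrichment
  s <- matrix(c(-12, -12, NA, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "D"), c("c1", "c2")))
  m <- score_matrix(s)
  lab <- ligand_labels(c("A", "D"), c("antagonist", "decoy"))
  r <- evaluate_ensemble(m, lab, c("c1", "c2"),
                         ensemble_objective("auc_vs_decoys", "antagonist"))
  expect_equal(r$objective_total, 1)

  # identical score distributions for active and other class -> term two 0.5
  s2 <- matrix(rep(c(-9, -9, -2), 2), 3, 2,
               dimnames = list(c("A", "B", "D"), c("c1", "c2")))
  m2 <- score_matrix(s2)
  lab2 <- ligand_labels(c("A", "B", "D"),
                        c("antagonist", "agonist", "decoy"))
  r2 <- evaluate_ensemble(m2, lab2, c("c1", "c2"),
                          ensemble_objective("summed_auc", "antagonist", "agonist"))
  expect_equal(unname(r2$objective_values["vs_other"]), 0.5)
  expect_equal(r2$objective_total, sum(r2$objective_values))

  # missing class is a hard error
  lab3 <- ligand_labels(c("A", "B", "D"),
                        c("agonist", "agonist", "decoy"))
  expect_error(
    evaluate_ensemble(m2, lab3, "c1",
                      ensemble_objective("auc_vs_decoys", "antagonist")),
    "no ligands of class antagonist")
})

test_that("evaluate_ensemble agrees with hand pairwise counting on a small screen", {
  set.seed(22)
  sc <- random_screen(6, 3, fail_p = 0.25,
                      classes = c("antagonist", "antagonist", "decoy",
                                  "decoy", "decoy", "agonist"))
  memb <- sc$matrix$conformation_ids[1:2]
  r <- evaluate_ensemble(sc$matrix, sc$labels, memb,
                         ensemble_objective("auc_vs_decoys", "antagonist"))
  agg <- aggregate_scores(sc$matrix, memb)
  expect_equal(unname(r$objective_values["vs_decoys"]),
               oracle_auc(agg[sc$classes == "antagonist"],
                          agg[sc$classes == "decoy"]))
})

test_that("objective constructor validates classes", {
  expect_error(ensemble_objective("auc_vs_decoys", "inhibitor"), "unknown")
  expect_error(ensemble_objective("summed_auc", "agonist", "agonist"), "differ")
  expect_error(ensemble_objective("summed_auc", "agonist"), "other_class")
})

test_that("exhaustive search degenerate sizes behave", {
  set.seed(23)
  sc <- random_screen(8, 4)
  obj <- ensemble_objective("auc_vs_decoys", "agonist")
  full <- exhaustive_search(sc$matrix, sc$labels, k = 4, objective = obj)
  expect_equal(nrow(full$candidates), 1)
  expect_setequal(full$best$members, sc$matrix$conformation_ids)

  single <- exhaustive_search(sc$matrix, sc$labels, k = 1, objective = obj)
  expect_equal(nrow(single$candidates), 4)
  # the winner is the best single conformation
  per_conf <- vapply(sc$matrix$conformation_ids, function(cid)
    evaluate_ensemble(sc$matrix, sc$labels, cid, obj)$objective_total,
    numeric(1))
  expect_equal(single$best$objective_total, max(per_conf))
  expect_error(exhaustive_search(sc$matrix, sc$labels, k = 5, objective = obj),
               "k must satisfy")
})

test_that("exhaustive search winner matches an independent enumeration oracle", {
  set.seed(24)
  for (rep in 1:10) {
    n_conf <- sample(4:6, 1)
    sc <- random_screen(9, n_conf, fail_p = 0.3)
    k <- sample(2:3, 1)
    obj <- ensemble_objective("auc_vs_decoys", "antagonist")
    got <- exhaustive_search(sc$matrix, sc$labels, k = k, objective = obj)
    want <- oracle_exhaustive(sc$matrix$scores, sc$matrix$failed,
                              sc$classes, k, "antagonist")
    expect_equal(sort(got$best$members), want$members)
    expect_equal(got$best$objective_total, want$auc, tolerance = 1e-12)
    # the winner dominates its own ranked candidate list
    expect_true(all(got$best$objective_total >=
                      got$candidates$objective_total - 1e-12))
  }
})

test_that("search is deterministic: identical inputs give identical winners", {
  set.seed(25)
  sc <- random_screen(10, 6, fail_p = 0.2)
  obj <- ensemble_objective("summed_auc", "antagonist", "agonist")
  a <- exhaustive_search(sc$matrix, sc$labels, k = 3, objective = obj)
  b <- exhaustive_search(sc$matrix, sc$labels, k = 3, objective = obj)
  expect_identical(a$best$members, b$best$members)
  expect_identical(a$candidates, b$candidates)
})
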