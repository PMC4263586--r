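test_that("the genotoxicity rule requires elevation then >=50% mortality", {
  rules <- rtca_rules()
  # rises to 1.3 by 10 h then falls to 0.30 by 40 h: positive
  up_down <- ratio_pair(pwl(c(0, 10, 40, 54), c(1, 1.3, 0.30, 0.30)))
  g <- call_genotoxicity(list("100" = up_down$treated), up_down$control,
                         rules = rules, compound_id = "pos")
  expect_true(g$positive)
  expect_false(g$equivocal)
  expect_equal(g$evidence_concentration, 100)
  expect_gt(g$peak_excess, 1.25)

  # flat at control: negative, not equivocal
  flat <- ratio_pair(function(u) rep(1, length(u)))
  g0 <- call_genotoxicity(list("100" = flat$treated), flat$control)
  expect_false(g0$positive)
  expect_false(g0$equivocal)

  # elevation then a bottom of 0.53 at every dose: negative AND equivocal
  near <- ratio_pair(pwl(c(0, 8, 30, 54), c(1, 1.2, 0.53, 0.53)))
  g1 <- call_genotoxicity(list("1000" = near$treated, "500" = near$treated),
                          near$control)
  expect_false(g1$positive)
  expect_true(g1$equivocal)

  # mortality without prior elevation is not a genotoxic signature
  down <- ratio_pair(pwl(c(0, 20, 54), c(1, 0.2, 0.1)))
  g2 <- call_genotoxicity(list("100" = down$treated), down$control)
  expect_false(g2$positive)

  # window must fit the recorded extent
  short <- ratio_pair(function(u) rep(1, length(u)), duration = 40)
  expect_error(call_genotoxicity(list("1" = short$treated), short$control),
               "exceeds the recorded trace extent")
})

test_that("evidence concentration is the lowest positive dose", {
  hit <- ratio_pair(pwl(c(0, 10, 40, 54), c(1, 1.3, 0.3, 0.3)))
  flat <- ratio_pair(function(u) rep(1, length(u)))
  g <- call_genotoxicity(list("100" = hit$treated, "10" = hit$treated,
                              "1" = flat$treated), hit$control)
  expect_true(g$positive)
  expect_equal(g$evidence_concentration, 10)
})

test_that("noise-free plates call dna_damaging compounds and only them", {
  pan <- simulate_mechanism_panel(
    n_per_class = 8,
    classes = c("dna_damaging", "cytotoxic", "nuclear_receptor", "control"),
    design = simulation_design(noise_sd = 0), seed = 17)
  calls <- do.call(rbind, lapply(pan$plates, genotox_plate))
  ev <- evaluate_predictivity(calls, pan$truth)
  expect_equal(ev$pooled$sensitivity, 100)
  expect_equal(ev$pooled$specificity, 100)
})

test_that("lowering the mortality threshold never creates new positives", {
  pan <- simulate_mechanism_panel(
    n_per_class = 6,
    classes = c("dna_damaging", "cytotoxic", "nuclear_receptor"),
    design = simulation_design(noise_sd = 0.05), seed = 23)
  loose <- do.call(rbind, lapply(pan$plates, genotox_plate,
                                 rules = rtca_rules(mortality_ratio = 0.5)))
  strict <- do.call(rbind, lapply(pan$plates, genotox_plate,
                                  rules = rtca_rules(mortality_ratio = 0.35)))
  new_pos <- strict$compound_id[strict$positive &
                                  !loose$positive[match(strict$compound_id,
                                                        loose$compound_id)]]
  expect_length(new_pos, 0L)
})

test_that("predictivity arithmetic matches hand counts and pools by sum", {
  mk_calls <- function(project, tp, fn, fp, tn) {
    ids <- sprintf("%s_%02d", project, seq_len(tp + fn + fp + tn))
    data.frame(compound_id = ids,
               positive = rep(c(TRUE, FALSE, TRUE, FALSE),
                              c(tp, fn, fp, tn)),
               equivocal = FALSE,
               truth = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fn, fp, tn)),
               project = project, stringsAsFactors = FALSE)
  }
  d <- rbind(mk_calls("CNS1", 14, 8, 1, 12), mk_calls("CNS2", 0, 7, 1, 38))
  labels <- data.frame(compound_id = d$compound_id,
                       genotoxic_reference = d$truth)
  grouping <- data.frame(compound_id = d$compound_id, group = d$project)
  ev <- evaluate_predictivity(d[, c("compound_id", "positive", "equivocal")],
                              labels, grouping)
  expect_equal(ev$groups$CNS1$sensitivity, 63.6)
  expect_equal(ev$groups$CNS1$specificity, 92.3)
  expect_equal(ev$groups$CNS1$concordance, 74.3)
  expect_equal(ev$groups$CNS2$sensitivity, 0)
  expect_equal(ev$groups$CNS2$specificity, 97.4)
  expect_equal(ev$groups$CNS2$concordance, 82.6)
  expect_equal(ev$pooled$sensitivity, 48.3)
  expect_equal(ev$pooled$specificity, 96.2)
  expect_equal(ev$pooled$concordance, 79.0)
  # pooled counts are the per-group sums
  for (fld in c("tp", "fp", "tn", "fn")) {
    expect_equal(ev$pooled[[fld]],
                 ev$groups$CNS1[[fld]] + ev$groups$CNS2[[fld]])
  }
  # unlabeled compound is named in the error
  bad <- d[, c("compound_id", "positive", "equivocal")]
  bad$compound_id[1] <- "mystery"
  expect_error(evaluate_predictivity(bad, labels), "mystery")
})

test_that("empty denominators report not-applicable, never divide by zero", {
  cs <- confusion_summary(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_equal(cs$specificity, 100)
  expect_true(is.na(cs$sensitivity))
  expect_equal(cs$concordance, 100)
  expect_error(confusion_summary(-1, 0, 0, 0), "non-negative")
})
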