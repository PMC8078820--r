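test_that("top-kL selection counts, saturation, and tie-breaking are deterministic", {
  withr::local_seed(1)
  # 500 eligible pairs over L = 100 -> exactly 150 selected
  elig <- which(outer(1:100, 1:100, function(a, b) b - a >= 6), arr.ind = TRUE)
  pick <- elig[sample(nrow(elig), 500), ]
  ps <- prediction_set("t", 100, pick[, 1], pick[, 2], runif(500))
  expect_equal(nrow(top_k_l(ps, factor = 1.5)), 150L)
  # saturation: 10 eligible pairs, request 150
  ps10 <- prediction_set("t", 100, pick[1:10, 1], pick[1:10, 2], runif(10))
  expect_equal(nrow(top_k_l(ps10, factor = 1.5)), 10L)
  # equal scores on (2,9) and (1,20): (1,20) ranks first
  tie <- prediction_set("t", 30, c(2, 1), c(9, 20), c(0.8, 0.8))
  sel <- top_k_l(tie, factor = 1 / 30)  # k = 1
  expect_equal(c(sel$i, sel$j), c(1, 20))
  expect_error(top_k_l(ps, L = 0), "L must be")
  expect_error(top_k_l(ps, factor = -1), "factor")
})

test_that("PPV counts correct selections and is NA when nothing is selected", {
  truth <- contact_map(40, cbind(c(1, 2, 3, 4), c(10, 12, 14, 16)))
  own <- data.frame(i = truth$pairs[, 1], j = truth$pairs[, 2])
  expect_equal(ppv(own, truth)$ppv, 1.0)
  three_of_four <- data.frame(i = c(1, 2, 3, 5), j = c(10, 12, 14, 20))
  expect_equal(ppv(three_of_four, truth)$ppv, 0.75)
  empty <- ppv(data.frame(i = integer(), j = integer()), truth)
  expect_true(is.na(empty$ppv))
  expect_equal(empty$n_selected, 0L)
})

test_that("random-score PPV approaches eligible contact density", {
  # analytic expectation: with exchangeable random scores, each selected
  # pair is true with probability (number of contacts / eligible pairs)
  withr::local_seed(21)
  st <- make_structure(solenoid_params("beta_solenoid", n_units = 6, seed = 3))
  truth <- true_contacts(st$residues)
  elig <- which(outer(seq_len(truth$L), seq_len(truth$L),
                      function(a, b) b - a >= 6), arr.ind = TRUE)
  density <- nrow(truth$pairs) / nrow(elig)
  n_seeds <- 60
  ppvs <- replicate(n_seeds, {
    ps <- prediction_set("r", truth$L, elig[, 1], elig[, 2], runif(nrow(elig)))
    ppv(top_k_l(ps, truth = truth), truth)$ppv
  })
  k <- round(1.5 * truth$L)
  se <- sqrt(density * (1 - density) / (n_seeds * k))
  expect_lt(abs(mean(ppvs) - density), 3 * se + 0.01)
})

test_that("PPV is invariant under rank-preserving score rescaling", {
  withr::local_seed(5)
  st <- make_structure(solenoid_params("alpha_solenoid", n_units = 4, seed = 8))
  truth <- true_contacts(st$residues)
  ps <- make_prediction(truth, st$annotation, prediction_noise(0.5, 0.2, seed = 9))
  p1 <- ppv(top_k_l(ps, truth = truth), truth)$ppv
  ps2 <- prediction_set("r", truth$L, ps$i, ps$j, plogis(5 * (ps$score - 0.5)))
  p2 <- ppv(top_k_l(ps2, truth = truth), truth)$ppv
  expect_equal(p1, p2)
})

test_that("stratified PPV selects matched counts and scores each stratum", {
  ann <- two_unit_ann()
  intra <- cbind(c(1:6, 31:36), c(11:16, 41:46))
  inter <- cbind(21:25, 31:35)
  truth <- contact_map(60, rbind(intra, inter))
  # predictions identical to truth
  ps <- prediction_set("p1", 60, truth$pairs[, 1], truth$pairs[, 2],
                       rep(0.9, nrow(truth$pairs)))
  sp <- stratified_ppv(ps, truth, ann)
  expect_equal(sp$ppv_intra$n_selected, 12L)  # matched to the true counts
  expect_equal(sp$ppv_inter$n_selected, 5L)
  expect_equal(sp$ppv_intra$ppv, 1.0)
  expect_equal(sp$ppv_inter$ppv, 1.0)
  expect_equal(sp$inter_fraction, 5 / 17)

  # planted errors only in INTER pairs: 2 wrong inter predictions outrank 2 true
  wrong_inter <- cbind(c(10, 12), c(50, 52))  # inter, not in truth
  ps2 <- prediction_set("p2", 60,
                        c(truth$pairs[, 1], wrong_inter[, 1]),
                        c(truth$pairs[, 2], wrong_inter[, 2]),
                        c(rep(0.8, 12), rep(0.8, 3), 0.1, 0.1, 0.95, 0.95))
  sp2 <- stratified_ppv(ps2, truth, ann)
  expect_equal(sp2$ppv_intra$ppv, 1.0)
  expect_equal(sp2$ppv_inter$ppv, 3 / 5)
})

test_that("stratified PPV agrees with an exhaustive small-instance oracle", {
  withr::local_seed(13)
  ann <- two_unit_ann()
  for (rep in 1:10) {
    elig <- which(outer(1:60, 1:60, function(a, b) b - a >= 6), arr.ind = TRUE)
    truth <- contact_map(60, elig[sample(nrow(elig), 30), ])
    scored <- elig[sample(nrow(elig), 200), ]
    ps <- prediction_set("o", 60, scored[, 1], scored[, 2], runif(200))
    sp <- stratified_ppv(ps, truth, ann)
    # oracle: enumerate, classify, sort within stratum, count hits directly
    cls_pred <- classify_pair(ann, ps$i, ps$j)
    cls_true <- classify_pair(ann, truth$pairs[, 1], truth$pairs[, 2])
    for (lab in c("INTRA", "INTER")) {
      n_true <- sum(cls_true == lab)
      sub <- ps[cls_pred == lab, ]
      sub <- sub[order(-sub$score, sub$i, sub$j), ][seq_len(min(n_true, sum(cls_pred == lab))), ]
      hits <- sum(is_contact(truth, sub$i, sub$j))
      got <- if (lab == "INTRA") sp$ppv_intra else sp$ppv_inter
      expect_equal(got$n_selected, nrow(sub))
      expect_equal(got$n_correct, hits)
    }
  }
})

test_that("a stratum with zero true contacts reports NA, not zero", {
  ann <- two_unit_ann()
  truth <- contact_map(60, cbind(1:5, 11:15))  # intra only
  ps <- prediction_set("p", 60, c(1, 5), c(11, 40), c(0.9, 0.9))
  sp <- stratified_ppv(ps, truth, ann)
  expect_true(is.na(sp$ppv_inter$ppv))
  # only one intra prediction available: selection saturates below the 5 true
  expect_equal(sp$ppv_intra$n_selected, 1L)
  expect_equal(sp$ppv_intra$ppv, 1.0)
})

test_that("the Neff running average truncates its centred window correctly", {
  rec <- data.frame(neff = c(5, 1, 4, 2, 3), ppv = c(0.5, 0.1, 0.4, 0.2, 0.3))
  # window 1: identity on the sorted points
  expect_equal(neff_precision_curve(rec, 1)$mean_ppv, c(0.1, 0.2, 0.3, 0.4, 0.5))
  # constant input is a fixed point
  const <- data.frame(neff = 1:10, ppv = rep(0.6, 10))
  expect_equal(neff_precision_curve(const, 50)$mean_ppv, rep(0.6, 10))
  # window 3: hand-computed truncated means on the sorted series
  got <- neff_precision_curve(rec, 3)$mean_ppv
  expect_equal(got, c(mean(c(0.1, 0.2)), mean(c(0.1, 0.2, 0.3)),
                      mean(c(0.2, 0.3, 0.4)), mean(c(0.3, 0.4, 0.5)),
                      mean(c(0.4, 0.5))))
  expect_error(neff_precision_curve(rec[0, ]), "empty")
  expect_error(neff_precision_curve(rec, 0), "window")
})

test_that("the running average is a contraction of the raw precisions", {
  withr::local_seed(17)
  rec <- data.frame(neff = runif(80, 0, 50), ppv = runif(80))
  for (w in c(2, 7, 50)) {
    curve <- neff_precision_curve(rec, w)
    expect_true(all(curve$mean_ppv >= min(rec$ppv) - 1e-12))
    expect_true(all(curve$mean_ppv <= max(rec$ppv) + 1e-12))
  }
})

test_that("periodicity artefact score is zero without false positives", {
  st <- make_structure(solenoid_params("alpha_solenoid", n_units = 4, seed = 2))
  truth <- true_contacts(st$residues)
  ps <- prediction_set("p", truth$L, truth$pairs[, 1], truth$pairs[, 2],
                       rep(1, nrow(truth$pairs)))
  expect_equal(periodicity_artefact_score(ps, truth, st$annotation), 0)
})

test_that("false positives planted exactly at the unit period score 1.0", {
  ann <- two_unit_ann()  # mean unit length 30
  truth <- contact_map(60, cbind(c(1, 2), c(10, 12)))
  fp <- cbind(c(3, 5, 8), c(33, 35, 38))  # separation exactly 30
  ps <- prediction_set("p", 60, c(truth$pairs[, 1], fp[, 1]),
                       c(truth$pairs[, 2], fp[, 2]), rep(0.9, 5))
  expect_equal(periodicity_artefact_score(ps, truth, ann), 1.0)
  single <- repeat_annotation("s", c(1, 60), rbind(c(1, 60)))
  expect_error(periodicity_artefact_score(ps, truth, single), ">= 2 units")
})

test_that("model correctness uses an inclusive TM 0.5 threshold", {
  expect_true(call_model_correct(0.5))
  expect_false(call_model_correct(0.49))
  expect_true(call_model_correct(1.0))
  expect_equal(call_model_correct(c(0.2, 0.5, 0.8)), c(FALSE, TRUE, TRUE))
  expect_error(call_model_correct(1.2), "\\[0, 1\\]")
})
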