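test_that("structure generation is deterministic given the seed", {
  p <- solenoid_params("alpha_solenoid", n_units = 4, seed = 12)
  a <- make_structure(p)
  b <- make_structure(p)
  expect_identical(a, b)
  c <- make_structure(solenoid_params("alpha_solenoid", n_units = 4, seed = 13))
  expect_false(identical(a$residues, c$residues))
})

test_that("generated annotations satisfy the repeat-annotation invariants", {
  for (g in c("alpha_solenoid", "beta_solenoid", "closed_ring", "beads_on_string")) {
    st <- make_structure(solenoid_params(g, n_units = 5, seed = 3,
                                         insertion_lengths = c(0, 4, 0, 2)))
    ann <- st$annotation
    expect_s3_class(ann, "repeat_annotation")  # constructor enforces invariants
    expect_equal(nrow(ann$units), 5L)
    expect_equal(ann$region[2], nrow(st$residues))
    # annotated insertions never fall inside a unit
    if (nrow(ann$insertions)) {
      in_unit <- unlist(lapply(seq_len(nrow(ann$units)), function(k)
        ann$units[k, 1]:ann$units[k, 2]))
      ins_res <- unlist(lapply(seq_len(nrow(ann$insertions)), function(m)
        ann$insertions[m, 1]:ann$insertions[m, 2]))
      expect_length(intersect(in_unit, ins_res), 0)
    }
    cm <- true_contacts(st$residues)
    expect_gt(nrow(cm$pairs), 0)  # smoke invariant
    expect_true(all(cm$pairs[, 2] - cm$pairs[, 1] >= 6))
  }
})

test_that("beta-solenoid default units are substantially shorter than alpha", {
  expect_equal(solenoid_params("beta_solenoid")$unit_length, 12L)
  expect_equal(solenoid_params("alpha_solenoid")$unit_length, 30L)
})

test_that("beads-on-string geometry forbids inter-unit contacts", {
  st <- make_structure(solenoid_params("beads_on_string", n_units = 3, seed = 1))
  cnt <- count_true_by_class(true_contacts(st$residues), st$annotation)
  expect_equal(cnt[["n_inter"]], 0L)
  expect_gt(cnt[["n_intra"]], 0L)
})

test_that("closed rings wrap around: unit 1 contacts units 2 and n", {
  st <- make_structure(solenoid_params("closed_ring", n_units = 6, seed = 1))
  cm <- true_contacts(st$residues)
  u <- st$annotation$units
  unit_of <- function(idx) findInterval(idx, u[, 1])
  pu <- cbind(unit_of(cm$pairs[, 1]), unit_of(cm$pairs[, 2]))
  partners_of_1 <- sort(unique(c(pu[pu[, 1] == 1, 2], pu[pu[, 2] == 1, 1])))
  expect_true(all(c(2, 6) %in% partners_of_1))
})

test_that("insertion residues form no contacts and shift unit spans", {
  p <- solenoid_params("alpha_solenoid", n_units = 3, seed = 4,
                       insertion_lengths = c(5, 0))
  st <- make_structure(p)
  expect_equal(st$annotation$units[, 1], c(1L, 36L, 66L))
  cm <- true_contacts(st$residues)
  ins <- 31:35
  expect_false(any(cm$pairs %in% ins))
})

test_that("planted prediction precision is realized at the top-1.5L selection", {
  st <- make_structure(solenoid_params("alpha_solenoid", n_units = 6, seed = 5))
  truth <- true_contacts(st$residues)
  for (p in c(0.4, 1.0)) {
    ps <- make_prediction(truth, st$annotation,
                          prediction_noise(p, 0, seed = 6), factor = 1.5)
    k <- round(1.5 * truth$L)
    got <- ppv(top_k_l(ps, truth = truth), truth)
    expect_equal(got$n_selected, k)
    expect_equal(got$ppv, round(p * k) / k, tolerance = 1e-12)
  }
  # precision = 1.0 at top-|truth|: every selected pair is true
  ps1 <- make_prediction(truth, st$annotation,
                         prediction_noise(1, 0, seed = 7),
                         factor = nrow(truth$pairs) / truth$L)
  sel <- top_k_l(ps1, truth = truth, factor = nrow(truth$pairs) / truth$L)
  expect_equal(ppv(sel, truth)$ppv, 1.0)
})

test_that("unreachable precision targets fail with the achievable maximum", {
  st <- make_structure(solenoid_params("beads_on_string", n_units = 2, seed = 2))
  truth <- true_contacts(st$residues)  # few contacts relative to 1.5 L
  expect_error(make_prediction(truth, st$annotation,
                               prediction_noise(1, 0, seed = 1)),
               "max achievable")
})

test_that("planted artefact fractions are exposed to the artefact score", {
  st <- make_structure(solenoid_params("alpha_solenoid", n_units = 6, seed = 8))
  truth <- true_contacts(st$residues)
  for (a in c(0, 0.8)) {
    ps <- make_prediction(truth, st$annotation,
                          prediction_noise(0.6, a, seed = 9))
    score <- periodicity_artefact_score(ps, truth, st$annotation)
    expect_equal(score, round(a * (round(1.5 * truth$L) -
                                     round(0.6 * round(1.5 * truth$L)))) /
                          (round(1.5 * truth$L) -
                             round(0.6 * round(1.5 * truth$L))),
                 tolerance = 1e-12)
  }
})

test_that("the QA generator matches its documented label formula", {
  co <- c(b0 = 0.1, b_pcons = 0.3, b_qlocal = 0.3, b_length = 0.2)
  tab <- make_qa_table(50, co, noise_sd = 0, seed = 11)
  manual <- pmin(1, pmax(0, co[["b0"]] + co[["b_pcons"]] * tab$pcons_global +
                           co[["b_qlocal"]] * tab$qmean_local_mean +
                           co[["b_length"]] * plogis((tab$length - 300) / 130)))
  expect_equal(tab$tm, manual, tolerance = 1e-12)
  flat <- make_qa_table(20, c(b0 = 0.4, b_pcons = 0, b_qlocal = 0, b_length = 0),
                        noise_sd = 0, seed = 12)
  expect_equal(flat$tm, rep(0.4, 20))
})

test_that("empirical label spread matches the generator's analytic value", {
  co <- c(b0 = 0.1, b_pcons = 0.3, b_qlocal = 0.3, b_length = 0.2)
  sd_noise <- 0.05
  # independent oracle: numeric integration of each component's variance
  v_unif <- 1 / 12
  mu_sig <- integrate(function(l) plogis((l - 300) / 130) / 560, 40, 600)$value
  v_sig <- integrate(function(l) (plogis((l - 300) / 130) - mu_sig)^2 / 560,
                     40, 600)$value
  sd_analytic <- sqrt(co[["b_pcons"]]^2 * v_unif + co[["b_qlocal"]]^2 * v_unif +
                        co[["b_length"]]^2 * v_sig + sd_noise^2)
  tab <- make_qa_table(800, co, noise_sd = sd_noise, seed = 13)
  expect_lt(abs(sd(tab$tm) - sd_analytic) / sd_analytic, 0.1)
})

test_that("parameter invariants of the generators are enforced", {
  expect_error(solenoid_params("alpha_solenoid", n_units = 1), "n_units")
  expect_error(solenoid_params("alpha_solenoid", unit_length = 3), "unit_length")
  expect_error(solenoid_params("beads_on_string", rise = 10), "20 Angstrom")
  expect_error(prediction_noise(precision = 0), "precision")
  expect_error(prediction_noise(artefact_rate = 1), "artefact_rate")
  expect_error(make_qa_table(0), "n must be")
})
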