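#' Simulate a benchmark bundle of synthetic repeat proteins
#'
#' Writes, for each requested protein, a tabular coordinate fixture, a
#' CASP-RR prediction with planted precision and periodic artefacts, and a
#' small alignment; plus one shared annotation file, a labelled QA feature
#' table, and a manifest tying them together. Idempotent given `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param proteins data frame with columns `geometry` and `n_units`; one
#'   synthetic protein per row. Default: two proteins per geometry.
#' @param precision,artefact_rate prediction-noise settings applied to every
#'   protein (see [prediction_noise()]).
#' @param n_qa number of rows in the QA feature table.
#' @param qa_noise_sd label noise of the QA generator.
#' @param seed master seed; per-protein seeds are derived from it.
#' @return Path to the manifest file, invisibly.
#' @export
run_simulate <- function(out_dir,
                         proteins = default_protein_grid(),
                         precision = 0.7, artefact_rate = 0.3,
                         n_qa = 800L, qa_noise_sd = 0.05, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_param("run_simulate: cannot create %s", out_dir)
  anns <- list()
  rows <- list()
  for (r in seq_len(nrow(proteins))) {
    pseed <- seed * 1000L + r
    sp <- solenoid_params(geometry = proteins$geometry[r],
                          n_units = proteins$n_units[r], seed = pseed)
    st <- make_structure(sp)
    truth <- true_contacts(st$residues)
    ps <- make_prediction(truth, st$annotation,
                          prediction_noise(precision, artefact_rate,
                                           seed = pseed + 1L))
    pid <- st$annotation$protein_id
    coord_file <- paste0(pid, ".coords.tsv")
    rr_file <- paste0(pid, ".rr")
    msa_file <- paste0(pid, ".msa.fasta")
    write_coordinate_table(st$residues, file.path(out_dir, coord_file))
    write_rr(ps, file.path(out_dir, rr_file))
    msa <- make_msa(12L, truth$L, mutation_rate = 0.05 + 0.03 * (r %% 8),
                    seed = pseed + 2L)
    writeLines(as.vector(rbind(sprintf(">seq%02d", seq_along(msa)), msa)),
               file.path(out_dir, msa_file))
    anns[[pid]] <- st$annotation
    rows[[r]] <- data.frame(protein_id = pid,
                            class = st$annotation$repeat_class,
                            split = "complete", method = "synthetic",
                            structure = coord_file, prediction = rr_file,
                            msa = msa_file, stringsAsFactors = FALSE)
  }
  write_annotations(anns, file.path(out_dir, "annotations.tsv"))
  write_qa_table(make_qa_table(n_qa, noise_sd = qa_noise_sd, seed = seed),
                 file.path(out_dir, "qa_table.tsv"))
  manifest <- do.call(rbind, rows)
  manifest$annotations <- "annotations.tsv"
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}

#' Default protein grid for the simulator
#' @return Data frame with `geometry` and `n_units` columns.
#' @export
default_protein_grid <- function() {
  data.frame(
    geometry = rep(c("alpha_solenoid", "beta_solenoid", "closed_ring",
                     "beads_on_string"), each = 2L),
    n_units = c(4L, 6L, 6L, 8L, 6L, 8L, 3L, 4L),
    stringsAsFactors = FALSE)
}

#' Evaluate predicted contacts over a simulated or user-supplied manifest
#'
#' For each manifest row: derives true contacts from the coordinates,
#' scores the prediction at the top `factor * L` selection (overall PPV),
#' computes the matched-count intra/inter-unit stratified PPV, the
#' periodic-artefact score, and the alignment Neff proxy. Per-class mean
#' PPVs are appended as a second table.
#'
#' @param manifest path to a manifest written by [run_simulate()] (columns
#'   `protein_id`, `class`, `split`, `method`, `structure`, `prediction`,
#'   `msa`, `annotations`; paths relative to the manifest).
#' @param out optional directory to write `ppv_report.tsv` and
#'   `class_means.tsv`.
#' @param cutoff,separation_min contact definition (defaults 8 Angstrom, 6).
#' @param factor top-kL selection factor (default 1.5).
#' @param strict if `TRUE`, a missing counterpart file is an error; else the
#'   protein is skipped with a message.
#' @return A list with `report` (per-protein data frame) and `class_means`.
#' @export
run_evaluate <- function(manifest, out = NULL, cutoff = 8.0,
                         separation_min = 6L, factor = 1.5, strict = FALSE) {
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  base <- dirname(manifest)
  anns_cache <- list()
  rows <- list()
  skipped <- character()
  for (r in seq_len(nrow(man))) {
    pid <- man$protein_id[r]
    paths <- file.path(base, c(man$structure[r], man$prediction[r],
                               man$annotations[r]))
    if (!all(file.exists(paths))) {
      msg <- sprintf("run_evaluate: missing file(s) for %s: %s", pid,
                     paste(paths[!file.exists(paths)], collapse = ", "))
      if (strict) stop_param("%s", msg)
      message(msg, " -- skipped")
      skipped <- c(skipped, pid)
      next
    }
    ann_file <- file.path(base, man$annotations[r])
    if (is.null(anns_cache[[ann_file]]))
      anns_cache[[ann_file]] <- read_annotations(ann_file)
    ann <- anns_cache[[ann_file]][[pid]]
    if (is.null(ann)) {
      if (strict) stop_param("run_evaluate: no annotation for %s", pid)
      message("run_evaluate: no annotation for ", pid, " -- skipped")
      skipped <- c(skipped, pid)
      next
    }
    rs <- read_coordinates(file.path(base, man$structure[r]))
    truth <- true_contacts(rs, cutoff = cutoff, separation_min = separation_min)
    ps <- read_rr(file.path(base, man$prediction[r]), L = truth$L,
                  protein_id = pid)
    overall <- ppv(top_k_l(ps, truth = truth, factor = factor), truth, pid)
    strat <- stratified_ppv(ps, truth, ann)
    art <- if (nrow(ann$units) >= 2L)
      periodicity_artefact_score(ps, truth, ann, factor = factor) else NA_real_
    neff <- NA_real_
    if ("msa" %in% names(man) && file.exists(file.path(base, man$msa[r])))
      neff <- compute_neff(read_alignment(file.path(base, man$msa[r])),
                           L = truth$L, protein_id = pid)$neff
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, class = man$class[r], split = man$split[r],
      method = man$method[r], L = truth$L, n_contacts = nrow(truth$pairs),
      ppv = overall$ppv, ppv_intra = strat$ppv_intra$ppv,
      ppv_inter = strat$ppv_inter$ppv,
      inter_fraction = strat$inter_fraction, neff = neff,
      artefact_score = art, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_param("run_evaluate: no evaluable proteins in %s", manifest)
  report <- do.call(rbind, rows)
  class_means <- stats::aggregate(
    report[, c("ppv", "ppv_intra", "ppv_inter", "inter_fraction")],
    by = list(class = report$class), FUN = mean, na.rm = TRUE)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_report <- function(df, file)
      utils::write.table(format(df, digits = 6, trim = TRUE),
                         file.path(out, file), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    write_report(report, "ppv_report.tsv")
    write_report(class_means, "class_means.tsv")
  }
  list(report = report, class_means = class_means, skipped = skipped)
}

#' Cross-validate and fit the QA forest over a feature table
#'
#' @param qa_table path to a labelled QA table (see [read_qa_table()]) or
#'   the data frame itself.
#' @param out optional directory for `qa_cv_report.tsv`,
#'   `qa_importance.tsv` and the persisted model `qa_model.rds`.
#' @param folds,n_trees,max_depth,seed settings as in [qa_cross_validate()].
#' @return A list with `cv` (a `qa_cv`), `model` (a [qa_forest()]) and
#'   `importance`.
#' @export
run_qa <- function(qa_table, out = NULL, folds = 5L, n_trees = 240L,
                   max_depth = 60L, seed = 1L) {
  records <- if (is.character(qa_table)) read_qa_table(qa_table) else qa_table
  check_qa_records(records, labelled = TRUE)
  cv <- qa_cross_validate(records, folds = folds, n_trees = n_trees,
                          max_depth = max_depth, seed = seed)
  model <- qa_forest(records, n_trees = n_trees, max_depth = max_depth,
                     seed = seed)
  imp <- feature_importance(model)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cv_out <- rbind(cbind(fold = as.character(cv$per_fold$fold),
                          cv$per_fold[, c("n", "mae", "pearson_r", "accuracy")]),
                    data.frame(fold = "mean", n = sum(cv$per_fold$n),
                               mae = cv$mean[["mae"]],
                               pearson_r = cv$mean[["pearson_r"]],
                               accuracy = cv$mean[["accuracy"]]))
    utils::write.table(format(cv_out, digits = 6, trim = TRUE),
                       file.path(out, "qa_cv_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(format(imp, digits = 6, trim = TRUE),
                       file.path(out, "qa_importance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_qa_model(model, file.path(out, "qa_model.rds"))
  }
  list(cv = cv, model = model, importance = imp)
}
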