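#' Select the top-scoring k*L predicted contacts
#'
#' Ranks eligible predicted pairs by score and keeps the top
#' `round(factor * L)` (round half away from zero), the standard "top 1.5 L"
#' selection. Eligibility matches the truth's constraints: sequence
#' separation at least `separation_min` and neither residue masked. Ties are
#' broken deterministically by lower `i`, then lower `j`.
#'
#' @param ps a [prediction_set()].
#' @param L region length (defaults to the prediction set's `L`).
#' @param factor selection factor (default 1.5).
#' @param truth optional [contact_map()] providing `separation_min` and the
#'   mask; defaults to separation 6, no mask.
#' @return A data frame of the selected pairs (`i`, `j`, `score`), ranked.
#' @export
top_k_l <- function(ps, L = NULL, factor = 1.5, truth = NULL) {
  stopifnot(inherits(ps, "prediction_set"))
  L <- L %||% attr(ps, "L")
  if (!is_count(L) || L <= 0) stop_param("top_k_l: L must be a positive integer")
  if (!is.numeric(factor) || factor <= 0) stop_param("top_k_l: factor must be > 0")
  sep_min <- if (is.null(truth)) 6L else truth$separation_min
  mask <- if (is.null(truth)) integer() else truth$mask
  elig <- ps$j - ps$i >= sep_min & !(ps$i %in% mask) & !(ps$j %in% mask)
  cand <- ps[elig, , drop = FALSE]
  k <- min(round_half_up(factor * L), nrow(cand))
  ord <- order(-cand$score, cand$i, cand$j)
  out <- cand[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Positive predictive value of a selection
#'
#' @param selected data frame of selected pairs (columns `i`, `j`), e.g.
#'   from [top_k_l()].
#' @param truth a [contact_map()].
#' @param protein_id identifier carried into the result.
#' @return A list of class `ppv_result` with `n_selected`, `n_correct` and
#'   `ppv` (`NA` when nothing was selected, not 0).
#' @export
ppv <- function(selected, truth, protein_id = "protein") {
  stopifnot(inherits(truth, "contact_map"))
  n_sel <- nrow(selected)
  n_cor <- if (n_sel == 0L) 0L else sum(is_contact(truth, selected$i, selected$j))
  structure(list(protein_id = protein_id, n_selected = n_sel,
                 n_correct = as.integer(n_cor),
                 ppv = if (n_sel > 0L) n_cor / n_sel else NA_real_),
            class = "ppv_result")
}

#' @export
print.ppv_result <- function(x, ...) {
  cat(sprintf("ppv_result '%s': %d/%d correct, PPV = %s\n", x$protein_id,
              x$n_correct, x$n_selected,
              if (is.na(x$ppv)) "NA" else sprintf("%.3f", x$ppv)))
  invisible(x)
}

#' Matched-count intra/inter-unit stratified precision
#'
#' Counts the true intra- and inter-unit contacts, then selects the same
#' number of top-scoring predicted pairs within each stratum (unclassified
#' pairs are ignored) and scores each selection against the truth. A stratum
#' with zero true contacts yields an `NA` PPV rather than 0.
#'
#' @param ps a [prediction_set()].
#' @param truth a [contact_map()].
#' @param ann a [repeat_annotation()].
#' @return A list of class `stratified_ppv` with `ppv_intra`, `ppv_inter`
#'   (each a `ppv_result`) and `inter_fraction` =
#'   `n_inter / (n_intra + n_inter)` of the true contacts.
#' @export
stratified_ppv <- function(ps, truth, ann) {
  stopifnot(inherits(ps, "prediction_set"), inherits(truth, "contact_map"),
            inherits(ann, "repeat_annotation"))
  counts <- count_true_by_class(truth, ann)
  elig <- ps$j - ps$i >= truth$separation_min &
    !(ps$i %in% truth$mask) & !(ps$j %in% truth$mask) &
    ps$i >= ann$region[1] & ps$j <= ann$region[2]
  cand <- ps[elig, , drop = FALSE]
  cls <- if (nrow(cand)) classify_pair(ann, cand$i, cand$j) else character()
  take <- function(label, n_true) {
    sub <- cand[cls == label, , drop = FALSE]
    ord <- order(-sub$score, sub$i, sub$j)
    sel <- sub[ord[seq_len(min(n_true, nrow(sub)))], , drop = FALSE]
    if (n_true == 0L)
      structure(list(protein_id = attr(ps, "protein_id"), n_selected = 0L,
                     n_correct = 0L, ppv = NA_real_), class = "ppv_result")
    else ppv(sel, truth, attr(ps, "protein_id"))
  }
  tot <- counts[["n_intra"]] + counts[["n_inter"]]
  structure(list(ppv_intra = take("INTRA", counts[["n_intra"]]),
                 ppv_inter = take("INTER", counts[["n_inter"]]),
                 n_true_intra = counts[["n_intra"]],
                 n_true_inter = counts[["n_inter"]],
                 inter_fraction = if (tot > 0L) counts[["n_inter"]] / tot else NA_real_),
            class = "stratified_ppv")
}

#' @export
print.stratified_ppv <- function(x, ...) {
  fmt <- function(p) if (is.na(p$ppv)) "NA" else sprintf("%.3f", p$ppv)
  cat(sprintf("stratified_ppv: intra %s (n=%d), inter %s (n=%d), inter fraction %.3f\n",
              fmt(x$ppv_intra), x$n_true_intra, fmt(x$ppv_inter),
              x$n_true_inter, x$inter_fraction))
  invisible(x)
}

#' Running-average precision over Neff
#'
#' Sorts per-protein records by Neff and smooths the PPV with a centred
#' moving average of `window` records, truncated at the ends (the value at
#' rank r averages the available records in the window centred at r).
#'
#' @param records data frame with columns `neff` and `ppv`.
#' @param window window size in records (default 50).
#' @return Data frame with columns `neff` and `mean_ppv`, sorted by `neff`.
#' @export
neff_precision_curve <- function(records, window = 50L) {
  if (is.null(nrow(records)) || nrow(records) == 0L)
    stop_param("neff_precision_curve: empty input")
  if (!is_count(window) || window < 1)
    stop_param("neff_precision_curve: window must be >= 1")
  ord <- order(records$neff)
  neff <- records$neff[ord]
  p <- records$ppv[ord]
  n <- length(p)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  mean_ppv <- vapply(seq_len(n), function(r) {
    lo <- max(1L, r - half_lo)
    hi <- min(n, r + half_hi)
    mean(p[lo:hi])
  }, numeric(1))
  data.frame(neff = neff, mean_ppv = mean_ppv)
}

#' Periodic-artefact score of false-positive contacts
#'
#' Coevolution-based predictors often place false contacts on diagonals at
#' multiples of the repeat period (equivalent positions in successive
#' units). This score is the fraction of false positives, within the top
#' `factor * L` selection, whose sequence separation lies within `tol`
#' residues of a positive multiple of the mean unit length.
#'
#' @param ps a [prediction_set()].
#' @param truth a [contact_map()].
#' @param ann a [repeat_annotation()] with at least 2 units.
#' @param factor top-kL selection factor (default 1.5).
#' @param tol tolerance in residues around each period multiple (default 1).
#' @return A number in [0, 1]; 0 when the selection has no false positives.
#' @export
periodicity_artefact_score <- function(ps, truth, ann, factor = 1.5, tol = 1L) {
  stopifnot(inherits(ann, "repeat_annotation"))
  if (nrow(ann$units) < 2L)
    stop_param("periodicity_artefact_score: need >= 2 units")
  sel <- top_k_l(ps, truth = truth, factor = factor)
  if (nrow(sel) == 0L) return(0)
  fp <- sel[!is_contact(truth, sel$i, sel$j), , drop = FALSE]
  if (nrow(fp) == 0L) return(0)
  u <- mean(ann$units[, 2] - ann$units[, 1] + 1)
  mean(is_periodic_separation(fp$j - fp$i, u, tol))
}

# TRUE where separation is within tol of a positive multiple of period u
is_periodic_separation <- function(sep, u, tol = 1L) {
  m <- pmax(1, round(sep / u))
  abs(sep - m * u) <= tol
}

#' Call a model correct at the standard TM-score threshold
#'
#' A model is called correct when its TM-score is at least 0.5, the
#' conventional same-fold threshold.
#'
#' @param tm TM-score(s) in [0, 1].
#' @return Logical vector.
#' @export
call_model_correct <- function(tm) {
  if (any(!is.finite(tm)) || any(tm < 0) || any(tm > 1))
    stop_param("call_model_correct: TM-score must lie in [0, 1]")
  tm >= 0.5
}
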