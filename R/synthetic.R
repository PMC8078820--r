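#' Parameters for a synthetic solenoid structure
#'
#' Describes a parametric repeat protein built from a hairpin unit template
#' repeated with per-unit geometry. The four geometries embody the main
#' repeat architectures: `alpha_solenoid` and `beta_solenoid` stack units
#' along an axis (class III extended repeats; beta-solenoid units are
#' substantially shorter than alpha, 12 vs 30 residues by default);
#' `closed_ring` arranges units around a closed circle so the last unit
#' contacts the first (class IV closed repeats); `beads_on_string` separates
#' compact unit blobs by more than 20 Angstrom, so inter-unit contacts are
#' geometrically impossible (class V).
#'
#' @param geometry one of `"alpha_solenoid"`, `"beta_solenoid"`,
#'   `"closed_ring"`, `"beads_on_string"`.
#' @param n_units number of repeat units (>= 2).
#' @param unit_length residues per unit (>= 4); geometry-specific default.
#' @param rise inter-unit spacing in Angstrom (stacking rise, ring spacing,
#'   or bead gap depending on geometry).
#' @param twist per-unit twist in degrees (stacked geometries).
#' @param insertion_lengths integer vector of insertion lengths between
#'   consecutive units (length `n_units - 1`, recycled).
#' @param seed RNG seed for residue identities and clash-resolving jitter.
#' @return A list of class `solenoid_params`.
#' @export
solenoid_params <- function(geometry = c("alpha_solenoid", "beta_solenoid",
                                         "closed_ring", "beads_on_string"),
                            n_units = 6L, unit_length = NULL, rise = NULL,
                            twist = NULL, insertion_lengths = 0L, seed = 1L) {
  geometry <- match.arg(geometry)
  defaults <- switch(geometry,
    alpha_solenoid  = list(unit_length = 30L, rise = 7.5, twist = 3),
    beta_solenoid   = list(unit_length = 12L, rise = 7.5, twist = 0),
    closed_ring     = list(unit_length = 16L, rise = 7.5, twist = 0),
    beads_on_string = list(unit_length = 20L, rise = 22,  twist = 0))
  unit_length <- unit_length %||% defaults$unit_length
  rise <- rise %||% defaults$rise
  twist <- twist %||% defaults$twist
  if (!is_count(n_units) || n_units < 2) stop_param("solenoid_params: n_units must be >= 2")
  if (!is_count(unit_length) || unit_length < 4)
    stop_param("solenoid_params: unit_length must be >= 4")
  if (geometry == "beads_on_string" && rise < 20)
    stop_param("solenoid_params: beads_on_string requires gaps >= 20 Angstrom")
  insertion_lengths <- as.integer(rep_len(insertion_lengths, n_units - 1L))
  if (any(insertion_lengths < 0)) stop_param("solenoid_params: negative insertion length")
  structure(list(geometry = geometry, n_units = as.integer(n_units),
                 unit_length = as.integer(unit_length), rise = rise,
                 twist = twist, insertion_lengths = insertion_lengths,
                 seed = as.integer(seed)),
            class = "solenoid_params")
}

# hairpin unit template: two antiparallel strands 4.8 Angstrom apart,
# 3.4 Angstrom per residue along the long axis ("x" or "z")
unit_template <- function(unit_length, axis = c("x", "z")) {
  axis <- match.arg(axis)
  h <- ceiling(unit_length / 2)
  p <- seq_len(unit_length)
  long <- ifelse(p <= h, 3.4 * (p - 1), 3.4 * (unit_length - p))
  off <- ifelse(p <= h, 0, 4.8)
  tpl <- if (axis == "x") cbind(long, off, 0) else cbind(0, off, long)
  sweep(tpl, 2, colMeans(tpl))  # centre at the origin
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Generate a synthetic repeat structure with its annotation
#'
#' Places one representative atom per residue on a parametric repeated-unit
#' scaffold (see [solenoid_params()]) and returns coordinates together with
#' the exactly matching repeat annotation. Insertion residues between units
#' are placed well away from the repeat scaffold, so they form no contacts.
#' If the raw geometry produces atom clashes closer than 2 Angstrom, the
#' build is retried with small random jitter, failing after 10 attempts.
#'
#' @param p a [solenoid_params()].
#' @return A list with elements `residues` (a [residue_set()]) and
#'   `annotation` (a [repeat_annotation()]).
#' @export
make_structure <- function(p) {
  stopifnot(inherits(p, "solenoid_params"))
  ul <- p$unit_length
  ins <- p$insertion_lengths
  L <- p$n_units * ul + sum(ins)
  # sequence layout: unit 1, insertion 1, unit 2, ...
  unit_starts <- 1L + (seq_len(p$n_units) - 1L) * ul +
    c(0L, cumsum(ins))[seq_len(p$n_units)]
  units <- cbind(unit_starts, unit_starts + ul - 1L)
  insertions <- NULL
  if (any(ins > 0)) {
    s <- units[-nrow(units), 2][ins > 0] + 1L
    insertions <- cbind(s, s + ins[ins > 0] - 1L)
  }
  ann <- repeat_annotation(sprintf("syn_%s_%d", p$geometry, p$seed),
                           c(1L, L), units,
                           repeat_class = switch(p$geometry,
                             alpha_solenoid = "III.1", beta_solenoid = "III.3",
                             closed_ring = "IV.4", beads_on_string = "V.1"),
                           insertions = insertions)
  base_coords <- solenoid_coordinates(p, units, insertions, L)
  with_seed(p$seed, {
    aa <- sample(c("A", "C", "D", "E", "F", "H", "I", "K", "L", "M", "N",
                   "Q", "R", "S", "T", "V", "W", "Y"), L, replace = TRUE)
    coords <- base_coords
    for (attempt in seq_len(10L)) {
      d <- stats::dist(coords)
      if (min(d) >= 2) break
      if (attempt == 10L)
        stop_param("make_structure: atom clashes persist after 10 jitter attempts")
      coords <- base_coords + matrix(stats::rnorm(3 * L, sd = 0.3), L, 3)
    }
    list(residues = residue_set(ann$protein_id, seq_len(L), aa, coords),
         annotation = ann)
  })
}

solenoid_coordinates <- function(p, units, insertions, L) {
  coords <- matrix(NA_real_, L, 3)
  ul <- p$unit_length
  if (p$geometry %in% c("alpha_solenoid", "beta_solenoid")) {
    tpl <- unit_template(ul, "x")
    for (k in seq_len(p$n_units)) {
      placed <- tpl %*% t(rot_z((k - 1) * p$twist))
      placed[, 3] <- placed[, 3] + (k - 1) * p$rise
      coords[units[k, 1]:units[k, 2], ] <- placed
    }
  } else if (p$geometry == "closed_ring") {
    tpl <- unit_template(ul, "z")  # long axis perpendicular to the ring plane
    R <- p$rise / (2 * sin(pi / p$n_units))
    for (k in seq_len(p$n_units)) {
      th <- 2 * pi * (k - 1) / p$n_units
      placed <- sweep(tpl, 2, c(R * cos(th), R * sin(th), 0), `+`)
      coords[units[k, 1]:units[k, 2], ] <- placed
    }
  } else {  # beads_on_string
    tpl <- unit_template(ul, "x")
    extent <- diff(range(tpl[, 1]))
    for (k in seq_len(p$n_units)) {
      placed <- tpl
      placed[, 1] <- placed[, 1] + (k - 1) * (extent + p$rise)
      coords[units[k, 1]:units[k, 2], ] <- placed
    }
  }
  # insertion residues: an extended stretch far below the scaffold
  if (!is.null(insertions)) for (m in seq_len(nrow(insertions))) {
    idx <- insertions[m, 1]:insertions[m, 2]
    coords[idx, ] <- cbind(3.8 * seq_along(idx) + 200 * m, -40, -40)
  }
  coords
}

#' Prediction-noise parameters for the synthetic generator
#'
#' @param precision expected precision of the top `factor * L` selection,
#'   in (0, 1].
#' @param artefact_rate fraction of planted false positives placed at
#'   separations within 1 residue of a multiple of the mean unit length
#'   (the periodic-diagonal artefact), in [0, 1).
#' @param score_sharpness concentration of scores away from the 0.5
#'   decision band (> 0; larger = sharper).
#' @param seed RNG seed.
#' @return A list of class `prediction_noise`.
#' @export
prediction_noise <- function(precision = 0.7, artefact_rate = 0.3,
                             score_sharpness = 4, seed = 1L) {
  if (!is.numeric(precision) || precision <= 0 || precision > 1)
    stop_param("prediction_noise: precision must lie in (0, 1]")
  if (!is.numeric(artefact_rate) || artefact_rate < 0 || artefact_rate >= 1)
    stop_param("prediction_noise: artefact_rate must lie in [0, 1)")
  if (!is.numeric(score_sharpness) || score_sharpness <= 0)
    stop_param("prediction_noise: score_sharpness must be > 0")
  structure(list(precision = precision, artefact_rate = artefact_rate,
                 score_sharpness = score_sharpness, seed = as.integer(seed)),
            class = "prediction_noise")
}

#' Generate a synthetic prediction with planted precision and artefacts
#'
#' Builds a scored prediction set whose top `factor * L` selection has the
#' requested precision: the selection holds `round(precision * k)` true
#' contacts plus false positives, of which a fraction `artefact_rate` sit at
#' separations within 1 residue of a multiple of the mean unit length
#' (periodic diagonals) and the rest at non-periodic separations. True
#' contacts left out of the selection receive low scores (false negatives).
#'
#' @param truth a [contact_map()].
#' @param ann a [repeat_annotation()].
#' @param noise a [prediction_noise()].
#' @param factor selection factor defining the precision target (default 1.5).
#' @return A [prediction_set()].
#' @export
make_prediction <- function(truth, ann, noise, factor = 1.5) {
  stopifnot(inherits(truth, "contact_map"), inherits(ann, "repeat_annotation"),
            inherits(noise, "prediction_noise"))
  L <- truth$L
  elig <- eligible_pairs(L, truth$separation_min, truth$mask)
  n_elig <- nrow(elig)
  k <- min(round_half_up(factor * L), n_elig)
  n_true <- nrow(truth$pairs)
  n_t <- round_half_up(noise$precision * k)
  if (n_t > n_true)
    stop_param("make_prediction: precision %.2f unreachable; max achievable %.3f (%d true contacts, selection %d)",
               noise$precision, n_true / k, n_true, k)
  n_f <- k - n_t
  is_true <- is_contact(truth, elig[, 1], elig[, 2])
  false_idx <- which(!is_true)
  u <- mean(ann$units[, 2] - ann$units[, 1] + 1)
  periodic <- is_periodic_separation(elig[, 2] - elig[, 1], u, 1L)
  n_art <- round_half_up(noise$artefact_rate * n_f)
  art_pool <- false_idx[periodic[false_idx]]
  plain_pool <- false_idx[!periodic[false_idx]]
  if (length(art_pool) < n_art || length(plain_pool) < n_f - n_art)
    stop_param("make_prediction: not enough eligible false pairs for the requested noise")
  with_seed(noise$seed, {
    true_rows <- which(is_true)
    sel_true <- if (n_t > 0) sample(true_rows, n_t) else integer()
    sel_art <- if (n_art > 0) sample(art_pool, n_art) else integer()
    sel_plain <- if (n_f - n_art > 0) sample(plain_pool, n_f - n_art) else integer()
    sel <- c(sel_true, sel_art, sel_plain)
    # background: remaining true contacts (false negatives) plus a sample of
    # false pairs, all scored below the selection band
    rest_true <- setdiff(true_rows, sel_true)
    rest_false <- setdiff(false_idx, c(sel_art, sel_plain))
    bg <- c(rest_true,
            if (length(rest_false)) sample(rest_false, min(k, length(rest_false)))
            else integer())
    s <- noise$score_sharpness
    hi <- 0.5 + 0.5 * stats::rbeta(length(sel), s, 1)
    lo <- 0.5 * stats::rbeta(length(bg), 1, s)
    prediction_set(ann$protein_id, L, c(elig[sel, 1], elig[bg, 1]),
                   c(elig[sel, 2], elig[bg, 2]), c(hi, lo))
  })
}

# all unordered pairs with j - i >= sep_min and neither index masked
eligible_pairs <- function(L, sep_min = 6L, mask = integer()) {
  idx <- setdiff(seq_len(L), mask)
  n <- length(idx)
  if (n < 2L) return(cbind(i = integer(), j = integer()))
  a <- rep.int(idx, n)
  b <- rep(idx, each = n)
  keep <- b - a >= sep_min
  cbind(i = a[keep], j = b[keep])
}

#' Generate a synthetic labelled QA feature table
#'
#' Draws the nine QA features from documented ranges and sets the TM-score
#' label to a linear-plus-saturating combination of three of them
#' (`pcons_global`, `qmean_local_mean`, and a logistic saturation of
#' `length`) plus Gaussian noise, clipped to [0, 1]:
#' `tm = clip(b0 + b_pcons * pcons_global + b_qlocal * qmean_local_mean +
#' b_length * plogis((length - 300) / 130) + N(0, noise_sd))`.
#' By default the remaining features are noisy correlates of the signal
#' features, as real QA summaries are; with
#' `independent_distractors = TRUE` they are drawn independently (the
#' "three-signal" variant, where the planted signal is fully identifiable
#' from the importance ranking). Note `log_length` is always the exact log
#' of `length`, so the two carry the same signal. Generator parameters are
#' recorded in the table's attributes.
#'
#' @param n number of records.
#' @param coefficients named numeric vector `b0`, `b_pcons`, `b_qlocal`,
#'   `b_length`.
#' @param noise_sd label noise standard deviation (default 0.05).
#' @param independent_distractors draw the six non-signal features
#'   independently of the signal (default `FALSE`).
#' @param seed RNG seed.
#' @return A labelled QA data frame (`model_id`, [qa_features()], `tm`).
#' @export
make_qa_table <- function(n, coefficients = c(b0 = 0.1, b_pcons = 0.3,
                                              b_qlocal = 0.3, b_length = 0.2),
                          noise_sd = 0.05, independent_distractors = FALSE,
                          seed = 1L) {
  if (!is_count(n) || n < 1) stop_param("make_qa_table: n must be >= 1")
  if (noise_sd < 0) stop_param("make_qa_table: noise_sd must be >= 0")
  need <- c("b0", "b_pcons", "b_qlocal", "b_length")
  if (!all(need %in% names(coefficients)))
    stop_param("make_qa_table: coefficients must name %s", paste(need, collapse = ", "))
  with_seed(seed, {
    pcons <- stats::runif(n)
    qlm <- stats::runif(n)
    len <- round(stats::runif(n, 40, 600))
    tab <- if (independent_distractors)
      data.frame(
        model_id = sprintf("model_%04d", seq_len(n)),
        pcons_global = pcons,
        qmean_global = stats::runif(n),
        qmean_local_mean = qlm,
        qmean_local_median = stats::runif(n),
        qmean_local_min = stats::runif(n, 0, 0.7),
        qmean_local_frac06 = stats::runif(n),
        length = len,
        log_length = log(len),
        neff = exp(stats::rnorm(n, mean = 4, sd = 1)),
        stringsAsFactors = FALSE)
    else
      data.frame(
        model_id = sprintf("model_%04d", seq_len(n)),
        pcons_global = pcons,
        qmean_global = clip01(0.3 * qlm + 0.7 * stats::runif(n)),
        qmean_local_mean = qlm,
        qmean_local_median = clip01(qlm + stats::rnorm(n, sd = 0.15)),
        qmean_local_min = clip01(qlm - stats::runif(n, 0.05, 0.45)),
        qmean_local_frac06 = clip01(stats::plogis((qlm - 0.6) * 6) +
                                      stats::rnorm(n, sd = 0.12)),
        length = len,
        log_length = log(len),
        neff = exp(stats::rnorm(n, mean = 4, sd = 1)),
        stringsAsFactors = FALSE)
    tab$tm <- clip01(coefficients[["b0"]] +
                       coefficients[["b_pcons"]] * pcons +
                       coefficients[["b_qlocal"]] * qlm +
                       coefficients[["b_length"]] * stats::plogis((len - 300) / 130) +
                       stats::rnorm(n, sd = noise_sd))
    attr(tab, "generator") <- list(coefficients = coefficients,
                                   noise_sd = noise_sd,
                                   independent_distractors = independent_distractors,
                                   seed = seed)
    tab
  })
}

#' Generate a small synthetic alignment with tunable diversity
#'
#' Mutates a random master sequence at a per-position rate per sequence;
#' used to exercise [compute_neff()] without real MSAs.
#'
#' @param n_sequences alignment depth.
#' @param width alignment width.
#' @param mutation_rate per-position substitution probability.
#' @param seed RNG seed.
#' @return Character vector of aligned sequences.
#' @export
make_msa <- function(n_sequences, width, mutation_rate = 0.2, seed = 1L) {
  if (!is_count(n_sequences) || n_sequences < 1)
    stop_param("make_msa: n_sequences must be >= 1")
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  with_seed(seed, {
    master <- sample(alphabet, width, replace = TRUE)
    vapply(seq_len(n_sequences), function(s) {
      mut <- stats::runif(width) < mutation_rate
      seqv <- master
      seqv[mut] <- sample(alphabet, sum(mut), replace = TRUE)
      paste(seqv, collapse = "")
    }, "")
  })
}
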