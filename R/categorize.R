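# Candidate component sets per task phase: the strongest components of the
# demixed decomposition (measurement: time PC 1 + stimulus PC 1;
# reproduction: time PCs 1-3 + stimulus PC 1).
phase_candidates <- function(phase) {
  switch(phase,
         measurement = c("PC1", "stimPC1"),
         reproduction = c("PC1", "PC2", "PC3", "stimPC1"),
         stop("phase must be 'measurement' or 'reproduction'"))
}

default_ev_threshold <- function(phase) {
  switch(phase, measurement = 6, reproduction = 28)
}

# Pull a unit's score and component trace set for one named candidate.
candidate_parts <- function(decomp, unit, cand) {
  if (cand == "stimPC1") {
    list(score = decomp$stim_scores[unit, 1L],
         traces = decomp$stim_components[1L, , ])
  } else {
    k <- as.integer(sub("PC", "", cand))
    tr <- matrix(rep(decomp$time_components[k, ], each = length(decomp$stimuli)),
                 length(decomp$stimuli), decomp$n_bins)
    list(score = decomp$time_scores[unit, k], traces = tr)
  }
}

#' Reconstruct a unit's responses from a component subset
#'
#' Linear combination of the selected components weighted by the unit's
#' scores, compared to the unit's actual per-stimulus traces. Explained
#' variance is `1 - SS_residual / SS_total` in percent (0 for the empty
#' subset).
#'
#' @param decomp A [demixed_pca()] result.
#' @param unit Unit index.
#' @param subset Character vector of candidate names (`"PC1"`, `"PC2"`,
#'   `"PC3"`, `"stimPC1"`); may be empty.
#' @return List with `reconstruction` (stimuli x bins matrix) and `ev`
#'   (percent).
#' @export
reconstruct_unit <- function(decomp, unit, subset) {
  stopifnot(inherits(decomp, "decomp_result"), decomp$kind == "demixed")
  n_stim <- length(decomp$stimuli)
  rec <- matrix(0, n_stim, decomp$n_bins)
  for (cand in subset) {
    p <- candidate_parts(decomp, unit, cand)
    rec <- rec + p$score * p$traces
  }
  actual <- decomp$values[unit, , , drop = TRUE]
  if (n_stim == 1L) actual <- matrix(actual, nrow = 1L)
  ss_tot <- sum(actual^2)
  ev <- if (ss_tot == 0) 0 else 100 * (1 - sum((actual - rec)^2) / ss_tot)
  list(reconstruction = rec, ev = ev)
}

#' Assign a response-type category to one unit
#'
#' If the reconstruction from the full candidate set explains less variance
#' than `ev_threshold`, the unit is "unrelated activity" (empty set).
#' Otherwise the strongest component (largest absolute score) always
#' contributes, and any other candidate `j` contributes when the angle
#' `atan(|score_j| / |score_strongest|)` exceeds `angle_threshold` degrees
#' (22.5 deg corresponds to an absolute score ratio above tan(22.5 deg)
#' ~ 0.414). The absolute-value rule makes categories invariant to component
#' sign flips.
#'
#' @param decomp A [demixed_pca()] result.
#' @param unit Unit index.
#' @param candidates Candidate component names; defaults per `phase`.
#' @param phase `"measurement"` or `"reproduction"`, used for candidate and
#'   threshold defaults.
#' @param ev_threshold Explained-variance gate in percent (defaults: 6
#'   measurement, 28 reproduction).
#' @param angle_threshold Contribution angle in degrees (default 22.5).
#' @return List of class `category_assignment`: `unit`, `category` (character
#'   vector of contributing components, empty = unrelated), `label`, `ev`,
#'   `scores`.
#' @export
assign_category <- function(decomp, unit, phase = "measurement",
                            candidates = phase_candidates(phase),
                            ev_threshold = default_ev_threshold(phase),
                            angle_threshold = 22.5) {
  scores <- vapply(candidates, function(cand) {
    candidate_parts(decomp, unit, cand)$score
  }, 1.0)
  ev <- reconstruct_unit(decomp, unit, candidates)$ev
  if (ev < ev_threshold || all(scores == 0)) {
    cat_set <- character(0)
  } else {
    strongest <- which.max(abs(scores))
    ang <- atan2(abs(scores), abs(scores[strongest])) * 180 / pi
    cat_set <- candidates[ang > angle_threshold | seq_along(scores) == strongest]
  }
  structure(list(unit = unit, category = cat_set,
                 label = category_label(cat_set), ev = ev, scores = scores),
            class = "category_assignment")
}

category_label <- function(cat_set) {
  if (length(cat_set) == 0L) "unrelated" else paste(sort(cat_set), collapse = "+")
}

#' Categorize all units of a decomposition
#'
#' @inheritParams assign_category
#' @return data.frame with `unit`, `label`, `ev` and one logical column per
#'   candidate.
#' @export
categorize_units <- function(decomp, phase = "measurement",
                             candidates = phase_candidates(phase),
                             ev_threshold = default_ev_threshold(phase),
                             angle_threshold = 22.5) {
  rows <- lapply(seq_len(decomp$n_units), function(u) {
    a <- assign_category(decomp, u, phase, candidates, ev_threshold,
                         angle_threshold)
    flags <- as.list(candidates %in% a$category)
    names(flags) <- candidates
    cbind(data.frame(unit = u, label = a$label, ev = a$ev), flags)
  })
  do.call(rbind, rows)
}

#' Number of possible response categories
#'
#' The category lattice over `n` candidate components is its power set
#' (including the empty "unrelated activity" set): `2^n` categories, e.g. 4
#' for two components and 16 for four.
#'
#' @param n_components Number of candidate components (>= 0).
#' @return Integer count.
#' @export
category_space_size <- function(n_components) {
  if (n_components < 0) stop("n_components must be non-negative")
  2^n_components
}

# All category labels over a candidate set.
all_category_labels <- function(candidates) {
  n <- length(candidates)
  labs <- character(2^n)
  for (i in seq_len(2^n)) {
    sel <- candidates[bitwAnd(i - 1L, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
    labs[i] <- category_label(sel)
  }
  unique(labs)
}

#' Chance category counts from shuffled surrogates
#'
#' Builds surrogate populations by shuffling traces across stimuli and cells
#' (every unit x stimulus trace is reassigned at random), re-runs the demixed
#' decomposition and the categorization on each surrogate, and compares the
#' observed per-category counts to the surrogate count distributions with
#' empirical two-sided p-values and an enrichment direction flag.
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()].
#' @param phase Candidate/threshold defaults, as in [assign_category()].
#' @param runs Number of surrogates (>= 100 recommended).
#' @param seed Optional integer seed.
#' @param ... Passed on to [categorize_units()].
#' @return data.frame with `label`, `observed`, surrogate `mean`, empirical
#'   `p` and `direction` (">", "<" or "=").
#' @export
chance_category_counts <- function(sdf, phase = "measurement", runs = 1000,
                                   seed = NULL, ...) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  candidates <- phase_candidates(phase)
  labs <- all_category_labels(candidates)
  count_categories <- function(tensor) {
    d <- demixed_pca(tensor,
                     n_time_pcs = sum(grepl("^PC", candidates)),
                     n_stim_pcs = sum(grepl("^stimPC", candidates)))
    cat_df <- categorize_units(d, phase = phase, candidates = candidates, ...)
    table(factor(cat_df$label, levels = labs))
  }
  observed <- count_categories(sdf)
  n_units <- sdf$n_units; n_stim <- length(sdf$stimuli)
  sur <- with_seed_opt(seed, {
    vapply(seq_len(runs), function(b) {
      flat <- matrix(aperm(sdf$values, c(3, 1, 2)),
                     nrow = sdf$n_bins)  # bins x (units*stimuli)
      flat <- flat[, sample.int(ncol(flat))]
      shuf <- aperm(array(flat, dim = c(sdf$n_bins, n_units, n_stim)),
                    c(2, 3, 1))
      as.numeric(count_categories(sdf_tensor(shuf, sdf$stimuli, sdf$durations,
                                             zscored = TRUE)))
    }, numeric(length(labs)))
  })
  p <- vapply(seq_along(labs), function(i) {
    lo <- (1 + sum(sur[i, ] <= observed[i])) / (runs + 1)
    hi <- (1 + sum(sur[i, ] >= observed[i])) / (runs + 1)
    min(1, 2 * min(lo, hi))
  }, 1.0)
  dir <- ifelse(observed > rowMeans(sur), ">",
                ifelse(observed < rowMeans(sur), "<", "="))
  data.frame(label = labs, observed = as.numeric(observed),
             surrogate_mean = rowMeans(sur), p = p, direction = dir)
}

#' Category transition table between task phases
#'
#' Contingency counts of measurement-phase vs reproduction-phase category
#' labels for the same unit set, plus phase-activity shares derived from the
#' unrelated-vs-active split per phase.
#'
#' @param assign_meas,assign_repro [categorize_units()] tables over the same
#'   units.
#' @return List with `table` (contingency matrix) and `activity_shares`
#'   (fractions: both, measurement_only, reproduction_only, neither).
#' @export
transition_table <- function(assign_meas, assign_repro) {
  if (!identical(assign_meas$unit, assign_repro$unit)) {
    stop("both assignments must cover the same units in the same order")
  }
  tab <- table(measurement = assign_meas$label,
               reproduction = assign_repro$label)
  act_m <- assign_meas$label != "unrelated"
  act_r <- assign_repro$label != "unrelated"
  shares <- c(both = mean(act_m & act_r),
              measurement_only = mean(act_m & !act_r),
              reproduction_only = mean(!act_m & act_r),
              neither = mean(!act_m & !act_r))
  list(table = tab, activity_shares = shares)
}
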