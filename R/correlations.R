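#' Correlation battery on SDF tensors
#'
#' Pearson correlations on time-normalized, z-scored SDF tensors. Modes:
#' \describe{
#'   \item{pairwise_cells}{one r per unit pair, over each unit's concatenated
#'     stimulus traces (within one tensor); diagonal excluded.}
#'   \item{population_vector_bins}{one r per stimulus x bin, across units,
#'     between the corresponding time bins of `sdf_a` (e.g. measurement) and
#'     `sdf_b` (e.g. reproduction).}
#'   \item{cell_cross_phase}{one r per unit, between its concatenated traces
#'     in `sdf_a` and `sdf_b`.}
#'   \item{population_stimulus_pairs}{one r per stimulus pair, over all
#'     units x bins, within one tensor.}
#'   \item{cell_stimulus_pairs}{one r per unit per stimulus pair, between the
#'     unit's traces at the two stimuli, within one tensor.}
#' }
#' Significance of each entry is the standard t-distribution test for a
#' Pearson correlation (two-sided); zero-variance entries are undefined and
#' excluded from significant fractions.
#'
#' @param sdf_a A z-scored [sdf_tensor()].
#' @param sdf_b Second tensor for the cross-phase modes (same shape).
#' @param mode One of the modes above.
#' @return An object of class `correlation_report`: data.frame `entries`
#'   (identifier columns plus `r`, `p`, `n`) and the `mode`.
#' @export
correlate <- function(sdf_a, sdf_b = NULL,
                      mode = c("pairwise_cells", "population_vector_bins",
                               "cell_cross_phase", "population_stimulus_pairs",
                               "cell_stimulus_pairs")) {
  stopifnot(inherits(sdf_a, "sdf_tensor"))
  mode <- match.arg(mode)
  two_tensor <- mode %in% c("population_vector_bins", "cell_cross_phase")
  if (two_tensor) {
    stopifnot(inherits(sdf_b, "sdf_tensor"),
              identical(dim(sdf_a$values), dim(sdf_b$values)))
  }
  n_units <- sdf_a$n_units
  n_stim <- length(sdf_a$stimuli)
  n_bins <- sdf_a$n_bins

  entries <- switch(mode,
    pairwise_cells = {
      flat <- matrix(aperm(sdf_a$values, c(2, 3, 1)), ncol = n_units)
      pairs <- utils::combn(n_units, 2L)
      res <- apply(pairs, 2L, function(ij) {
        z <- pearson_rp(flat[, ij[1L]], flat[, ij[2L]])
        c(z$r, z$p, z$n)
      })
      data.frame(unit_a = pairs[1L, ], unit_b = pairs[2L, ],
                 r = res[1L, ], p = res[2L, ], n = res[3L, ])
    },
    population_vector_bins = {
      out <- expand.grid(stimulus = sdf_a$stimuli, bin = seq_len(n_bins))
      res <- mapply(function(s, b) {
        j <- match(s, sdf_a$stimuli)
        z <- pearson_rp(sdf_a$values[, j, b], sdf_b$values[, j, b])
        c(z$r, z$p, z$n)
      }, out$stimulus, out$bin)
      cbind(out, data.frame(r = res[1L, ], p = res[2L, ], n = res[3L, ]))
    },
    cell_cross_phase = {
      res <- vapply(seq_len(n_units), function(u) {
        z <- pearson_rp(as.numeric(sdf_a$values[u, , ]),
                        as.numeric(sdf_b$values[u, , ]))
        c(z$r, z$p, z$n)
      }, numeric(3L))
      data.frame(unit = seq_len(n_units),
                 r = res[1L, ], p = res[2L, ], n = res[3L, ])
    },
    population_stimulus_pairs = {
      pairs <- utils::combn(n_stim, 2L)
      res <- apply(pairs, 2L, function(jk) {
        z <- pearson_rp(as.numeric(sdf_a$values[, jk[1L], ]),
                        as.numeric(sdf_a$values[, jk[2L], ]))
        c(z$r, z$p, z$n)
      })
      data.frame(stimulus_a = sdf_a$stimuli[pairs[1L, ]],
                 stimulus_b = sdf_a$stimuli[pairs[2L, ]],
                 r = res[1L, ], p = res[2L, ], n = res[3L, ])
    },
    cell_stimulus_pairs = {
      pairs <- utils::combn(n_stim, 2L)
      out <- expand.grid(unit = seq_len(n_units), pair = seq_len(ncol(pairs)))
      res <- mapply(function(u, pr) {
        jk <- pairs[, pr]
        z <- pearson_rp(sdf_a$values[u, jk[1L], ], sdf_a$values[u, jk[2L], ])
        c(z$r, z$p, z$n)
      }, out$unit, out$pair)
      data.frame(unit = out$unit,
                 stimulus_a = sdf_a$stimuli[pairs[1L, out$pair]],
                 stimulus_b = sdf_a$stimuli[pairs[2L, out$pair]],
                 r = res[1L, ], p = res[2L, ], n = res[3L, ])
    }
  )
  structure(list(entries = entries, mode = mode), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report (%s): %d entries, %.1f%% significant\n",
              x$mode, nrow(x$entries), 100 * significant_fraction(x)))
  invisible(x)
}

#' Fraction of significant correlation entries
#'
#' @param report A [correlate()] result.
#' @param alpha Significance level (default 0.05).
#' @return Share of defined entries with `p < alpha` (NaN when none defined).
#' @export
significant_fraction <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "correlation_report"))
  p <- report$entries$p
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(NaN)
  mean(p < alpha)
}

#' Per-unit average cross-stimulus correlation
#'
#' Mean of a unit's stimulus-pair correlations (the `cell_stimulus_pairs`
#' mode), one summary value per unit.
#'
#' @param report A `cell_stimulus_pairs` [correlate()] result.
#' @return data.frame with `unit` and `mean_r`.
#' @export
mean_cross_stimulus_correlation <- function(report) {
  stopifnot(inherits(report, "correlation_report"),
            report$mode == "cell_stimulus_pairs")
  e <- report$entries
  agg <- stats::aggregate(r ~ unit, data = e, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  names(agg)[2L] <- "mean_r"
  agg
}
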