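#' Cumulative transcriptional output of one trace
#'
#' The total output of an allele over a cycle is the area under its
#' normalized-intensity trajectory. On the uniform time grids used here a
#' plain sum over time points is proportional to the trapezoid rule up to
#' edge terms, so the sum is the default; set \code{dt_weighted = TRUE}
#' to multiply by the sampling interval.
#'
#' @param values normalized intensity series (finite).
#' @param dt_weighted multiply the sum by the time step.
#' @param dt_min time step in minutes (required when
#'   \code{dt_weighted = TRUE}).
#' @return scalar cumulative output.
#' @examples
#' cumulative_output(seq(0, 1, length.out = 11))  # 5.5
#' @export
cumulative_output <- function(values, dt_weighted = FALSE, dt_min = NULL) {
  if (!length(values)) stop("empty trace", call. = FALSE)
  if (any(!is.finite(values))) stop("trace must be finite", call. = FALSE)
  s <- sum(values)
  if (dt_weighted) {
    if (is.null(dt_min)) stop("'dt_min' required when dt_weighted",
                              call. = FALSE)
    s <- s * dt_min
  }
  s
}

#' Per-cell cumulative outputs of both alleles
#'
#' @param traces trace table (see \code{\link{activation_records}}).
#' @param dt_weighted,dt_min passed to \code{\link{cumulative_output}}.
#' @return data frame with \code{cell_id}, \code{cycle}, \code{output1},
#'   \code{output2}.
#' @export
allele_outputs <- function(traces, dt_weighted = FALSE, dt_min = NULL) {
  traces <- ensure_normalized(traces)
  cells <- unique(traces$cell_id)
  do.call(rbind, lapply(cells, function(cid) {
    cell <- traces[traces$cell_id == cid, ]
    outs <- vapply(1:2, function(a) {
      al <- cell[cell$allele == a, ]
      cumulative_output(al$normalized[order(al$t_min)],
                        dt_weighted = dt_weighted, dt_min = dt_min)
    }, 0)
    data.frame(cell_id = cid, cycle = cell$cycle[1],
               output1 = outs[1], output2 = outs[2])
  }))
}

#' Correlation of allelic outputs
#'
#' Pearson's r, Spearman's rho, and the least-squares slope of allele-2
#' output on allele-1 output across cells. A strong correlation (points
#' on the diagonal) indicates output variability shared by both alleles,
#' i.e. extrinsic noise; scatter off the diagonal reflects
#' allele-autonomous intrinsic noise.
#'
#' @param output1,output2 cumulative outputs per cell (or a data frame
#'   from \code{\link{allele_outputs}} as first argument).
#' @return A \code{correlation_report}: list with \code{r}, \code{rho},
#'   \code{k} (slope), \code{n}, \code{p} (two-tailed, for r) and
#'   \code{degenerate} (TRUE when an output has zero variance).
#' @export
allele_correlation <- function(output1, output2 = NULL) {
  if (is.data.frame(output1)) {
    output2 <- output1$output2
    output1 <- output1$output1
  }
  n <- length(output1)
  stopifnot(length(output2) == n)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(output1) == 0 || sd(output2) == 0) {
    return(structure(list(r = NA_real_, rho = NA_real_, k = NA_real_,
                          n = n, p = NA_real_, degenerate = TRUE),
                     class = "correlation_report"))
  }
  ct <- cor.test(output1, output2, method = "pearson")
  structure(list(r = unname(ct$estimate),
                 rho = cor(output1, output2, method = "spearman"),
                 k = unname(coef(lm(output2 ~ output1))[2]),
                 n = n, p = ct$p.value, degenerate = FALSE),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  if (x$degenerate) {
    cat("<correlation_report> degenerate (zero variance), n =", x$n, "\n")
  } else {
    cat(sprintf("<correlation_report> r = %.3f, rho = %.3f, k = %.3f, n = %d, p = %.3g\n",
                x$r, x$rho, x$k, x$n, x$p))
  }
  invisible(x)
}

#' Random-pair control for the allelic-output correlation
#'
#' Re-pairs allele 1 of each cell with allele 2 of a \emph{different},
#' randomly chosen cell (a derangement, so no cell is paired with itself)
#' and recomputes the correlation. Shared-cell (extrinsic) structure is
#' destroyed by the shuffle, so the control correlation is expected to be
#' near zero however strong the within-cell correlation is.
#'
#' @param outputs data frame from \code{\link{allele_outputs}} (or
#'   vectors via \code{output1}, \code{output2}).
#' @param n_shuffles number of random pairings; reported statistics are
#'   averaged over shuffles.
#' @param seed integer seed for the permutation(s).
#' @param output1,output2 alternative vector interface.
#' @return A \code{correlation_report} (averaged over shuffles) with an
#'   extra \code{n_shuffles} field and, when \code{n_shuffles > 1},
#'   \code{r_each}.
#' @export
random_pair_control <- function(outputs = NULL, n_shuffles = 1L,
                                seed = NULL, output1 = NULL,
                                output2 = NULL) {
  if (!is.null(outputs)) {
    output1 <- outputs$output1
    output2 <- outputs$output2
  }
  n <- length(output1)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  reports <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(s) {
      perm <- derangement(n)
      allele_correlation(output1, output2[perm])
    })
  })
  degenerate <- any(vapply(reports, `[[`, TRUE, "degenerate"))
  if (degenerate)
    return(structure(list(r = NA_real_, rho = NA_real_, k = NA_real_,
                          n = n, p = NA_real_, degenerate = TRUE,
                          n_shuffles = n_shuffles),
                     class = "correlation_report"))
  avg <- function(f) mean(vapply(reports, `[[`, 0, f))
  structure(list(r = avg("r"), rho = avg("rho"), k = avg("k"), n = n,
                 p = avg("p"), degenerate = FALSE,
                 n_shuffles = n_shuffles,
                 r_each = vapply(reports, `[[`, 0, "r")),
            class = "correlation_report")
}

# uniform random permutation with no fixed point
derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Inter-allelic correlation at each time point
#'
#' At every time point, Pearson's r is computed across cells between the
#' normalized intensities of allele 1 and allele 2. When traces from two
#' cycles are supplied, the collected per-timepoint r values of the two
#' cycles are compared by an unpaired two-tailed t test on the
#' coefficients themselves (set \code{fisher_z = TRUE} to compare
#' variance-stabilized z-transformed coefficients instead).
#'
#' @param traces trace table; may contain one or two cycles.
#' @param min_cells minimum cells per time point (points with fewer are
#'   skipped with a warning).
#' @param fisher_z apply Fisher's z transform before the between-cycle
#'   test.
#' @return list with \code{series} (data frame \code{cycle}, \code{t_min},
#'   \code{r}, \code{n}) and \code{test} (\code{htest} or \code{NULL}).
#' @export
per_timepoint_correlation <- function(traces, min_cells = 3L,
                                      fisher_z = FALSE) {
  traces <- ensure_normalized(traces)
  series <- list()
  skipped <- 0L
  for (cyc in unique(traces$cycle)) {
    tc <- traces[traces$cycle == cyc, ]
    for (tp in sort(unique(tc$t_min))) {
      a1 <- tc[tc$t_min == tp & tc$allele == 1, ]
      a2 <- tc[tc$t_min == tp & tc$allele == 2, ]
      m <- merge(a1[, c("cell_id", "normalized")],
                 a2[, c("cell_id", "normalized")], by = "cell_id")
      if (nrow(m) < min_cells) { skipped <- skipped + 1L; next }
      if (sd(m$normalized.x) == 0 || sd(m$normalized.y) == 0) {
        skipped <- skipped + 1L; next
      }
      series[[length(series) + 1L]] <- data.frame(
        cycle = cyc, t_min = tp,
        r = cor(m$normalized.x, m$normalized.y), n = nrow(m),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped)
    warning(skipped, " time point(s) skipped (too few cells or zero variance)",
            call. = FALSE)
  series <- if (length(series)) do.call(rbind, series) else
    data.frame(cycle = character(), t_min = numeric(), r = numeric(),
               n = integer())
  cycles <- unique(series$cycle)
  test <- NULL
  if (length(cycles) >= 2) {
    r1 <- series$r[series$cycle == cycles[1]]
    r2 <- series$r[series$cycle == cycles[2]]
    if (fisher_z) { r1 <- atanh(pmin(pmax(r1, -1 + 1e-12), 1 - 1e-12))
                    r2 <- atanh(pmin(pmax(r2, -1 + 1e-12), 1 - 1e-12)) }
    if (length(r1) >= 2 && length(r2) >= 2)
      test <- t.test(r1, r2, var.equal = FALSE)
  }
  list(series = series, test = test)
}

#' Inter-allelic difference expression over time
#'
#' Per time point, the mean absolute difference between the two alleles'
#' normalized intensities across cells, with a paired two-tailed t test of
#' allele 1 against allele 2 at that time point.
#'
#' @param traces trace table.
#' @param min_cells minimum paired cells per time point.
#' @return data frame with \code{cycle}, \code{t_min}, \code{mean_abs_diff},
#'   \code{p_paired}, \code{n}.
#' @export
allele_difference_series <- function(traces, min_cells = 3L) {
  traces <- ensure_normalized(traces)
  out <- list()
  for (cyc in unique(traces$cycle)) {
    tc <- traces[traces$cycle == cyc, ]
    for (tp in sort(unique(tc$t_min))) {
      a1 <- tc[tc$t_min == tp & tc$allele == 1, ]
      a2 <- tc[tc$t_min == tp & tc$allele == 2, ]
      m <- merge(a1[, c("cell_id", "normalized")],
                 a2[, c("cell_id", "normalized")], by = "cell_id")
      if (nrow(m) < min_cells) next
      diffs <- m$normalized.x - m$normalized.y
      p <- if (sd(diffs) == 0) {
        if (all(diffs == 0)) 1 else 0
      } else t.test(m$normalized.x, m$normalized.y, paired = TRUE)$p.value
      out[[length(out) + 1L]] <- data.frame(
        cycle = cyc, t_min = tp, mean_abs_diff = mean(abs(diffs)),
        p_paired = p, n = nrow(m), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(cycle = character(), t_min = numeric(),
               mean_abs_diff = numeric(), p_paired = numeric(),
               n = integer())
}
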