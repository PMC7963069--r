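#' Score a benchmark fit against simulation ground truth
#'
#' Tabulates empirical power and type I error of an AEI or differential-AEI
#' fit on a simulated dataset, separated by cell type and by the true AEI
#' magnitude bin, plus an overall (pooled across cell types) row per bin.
#' For an `aei_fit`, a test is null when the true AEI of its (gene, cell
#' type) pair is exactly 0.5; the binning variable is the AEI magnitude
#' `max(a, 1 - a)` so opposite-direction imbalance bins by its strength.
#' For a `daei_fit`, a test is null when the true differential-AEI shift is
#' zero, and power bins by the healthy-group AEI level. Direction recovery
#' is the fraction of significant non-null tests whose estimated sign
#' matches the true direction of imbalance.
#'
#' @param fit An [aei_fit][test_aei] or [daei_fit][test_daei] on data from
#'   [simulate_dataset()] / [simulate_two_condition()].
#' @param truth The dataset's `truth` element (class `sim_truth`).
#' @param alpha Significance level for the raw-p decision (default 0.05).
#' @param bins AEI magnitude bin edges (default `c(0.5, 0.6, 0.7, 1)`).
#' @param decision `"p"` thresholds raw p-values at `alpha`; `"q"`
#'   thresholds BH q-values.
#' @return List of class `benchmark_eval`: `power` (cell type x bin),
#'   `type1` (per cell type), `overall` (per bin, pooled), `direction`
#'   (direction-recovery rate, `NaN` when nothing is detected), `alpha`,
#'   `decision`, and `n_tested`.
#' @export
evaluate_benchmark <- function(fit, truth, alpha = 0.05,
                               bins = c(0.5, 0.6, 0.7, 1),
                               decision = c("p", "q")) {
  decision <- match.arg(decision)
  stopifnot(inherits(fit, "aei_fit"), inherits(truth, "sim_truth"))
  r <- fit$results
  missing <- setdiff(unique(r$gene_id), rownames(truth$aei))
  if (length(missing))
    stop_ctaei("fit contains genes absent from the truth: ",
               paste(utils::head(missing, 3L), collapse = ", "))
  key <- cbind(r$gene_id, r$cell_type)
  if (inherits(fit, "daei_fit")) {
    effect <- truth$delta[key]
    level <- truth$aei_healthy[key]
    is_null <- effect == 0
    magnitude <- pmax(level, 1 - level)
    true_sign <- sign(effect)
  } else {
    a <- truth$aei[key]
    is_null <- a == 0.5
    magnitude <- pmax(a, 1 - a)
    true_sign <- sign(a - 0.5)
  }
  pvals <- if (decision == "q") r$q else r$p
  tested <- !is.na(pvals)
  sig <- tested & pvals < alpha

  bin_of <- cut(magnitude, breaks = bins, right = FALSE,
                include.lowest = TRUE)
  tally <- function(sel) {
    n <- sum(sel & tested)
    if (n == 0L) return(c(n = 0L, rate = NA_real_))
    c(n = n, rate = sum(sig[sel]) / n)
  }
  cts <- fit$cell_types
  lev <- levels(bin_of)
  power <- do.call(rbind, lapply(cts, function(ct) {
    do.call(rbind, lapply(lev, function(b) {
      t <- tally(!is_null & r$cell_type == ct & !is.na(bin_of) &
                   bin_of == b)
      data.frame(cell_type = ct, bin = b, n = t[["n"]],
                 power = t[["rate"]], stringsAsFactors = FALSE)
    }))
  }))
  type1 <- do.call(rbind, lapply(cts, function(ct) {
    t <- tally(is_null & r$cell_type == ct)
    data.frame(cell_type = ct, n = t[["n"]], type1_error = t[["rate"]],
               stringsAsFactors = FALSE)
  }))
  overall <- do.call(rbind, lapply(lev, function(b) {
    t <- tally(!is_null & !is.na(bin_of) & bin_of == b)
    data.frame(bin = b, n = t[["n"]], power = t[["rate"]],
               stringsAsFactors = FALSE)
  }))
  detected <- sig & !is_null & !is.na(r$estimate)
  direction <- if (any(detected)) {
    mean(sign(r$estimate[detected]) == true_sign[detected])
  } else NaN
  structure(list(power = power, type1 = type1, overall = overall,
                 direction = direction, alpha = alpha, decision = decision,
                 n_tested = sum(tested)),
            class = "benchmark_eval")
}

#' @export
print.benchmark_eval <- function(x, ...) {
  cat("Benchmark evaluation (", x$decision, " < ", x$alpha, ", ",
      x$n_tested, " tests)\n", sep = "")
  cat("Overall power by true AEI magnitude bin:\n")
  print(x$overall, row.names = FALSE)
  cat("Type I error by cell type:\n")
  print(x$type1, row.names = FALSE)
  if (!is.nan(x$direction))
    cat("Direction recovery among detected tests:",
        round(x$direction, 3), "\n")
  invisible(x)
}
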