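# Result rendering: the per-outcome / per-strategy summary table in the layout
# of the published analysis.

#' Summary table of lifetime costs and benefits
#'
#' Renders a [run_cea()] result as the standard per-outcome and per-strategy
#' table: discounted cost, discounted life-years, discounted QALYs, and the
#' probability of each diagnostic outcome, followed by the two strategy rows
#' and the incremental comparison. Currency is kept at full precision in the
#' returned data.frame; the print method displays whole dollars and
#' three-decimal QALYs.
#'
#' @param res a `cea_result` from [run_cea()].
#' @param path optional path; when given, the table is also written as CSV.
#' @return an object of class `cea_table` (a data.frame).
#' @export
render_table2 <- function(res, path = NULL) {
  stopifnot(inherits(res, "cea_result"))
  pr <- res$probs
  o <- res$outcomes
  row <- function(label, out, prob = NA_real_) {
    data.frame(row = label, cost = out$cost, life_years = out$disc_life_years,
               qalys = out$qalys, probability = prob, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("true_positive", o$TP, pr$p_tp),
    row("false_negative", o$FN, pr$p_fn),
    row("false_positive", o$FP, pr$p_fp),
    row("true_negative", o$TN, pr$p_tn),
    row("do_nothing", res$do_nothing),
    row("biomarker", res$biomarker),
    data.frame(row = "incremental", cost = res$incremental$delta_cost,
               life_years = NA_real_, qalys = res$incremental$delta_qalys,
               probability = NA_real_, stringsAsFactors = FALSE)
  )
  attr(tab, "icer") <- res$incremental$icer
  attr(tab, "classification") <- res$incremental$classification
  class(tab) <- c("cea_table", "data.frame")
  if (!is.null(path)) {
    write.csv(as.data.frame(tab), path, row.names = FALSE)
  }
  tab
}

#' @export
print.cea_table <- function(x, ...) {
  cat("Lifetime discounted costs and benefits by diagnostic outcome\n")
  fmt <- function(i) {
    sprintf("  %-15s $%10s  LYs %6.3f  QALYs %6.3f%s",
            x$row[i], format(round(x$cost[i]), big.mark = ","),
            x$life_years[i], x$qalys[i],
            if (is.na(x$probability[i])) "" else
              sprintf("  (%5.1f%%)", 100 * x$probability[i]))
  }
  for (i in 1:4) cat(fmt(i), "\n")
  cat("By diagnostic strategy\n")
  for (i in 5:6) {
    cat(sprintf("  %-15s $%10s  QALYs %6.3f\n", x$row[i],
                format(round(x$cost[i]), big.mark = ","), x$qalys[i]))
  }
  icer <- attr(x, "icer")
  cat(sprintf("  incremental     $%10s  QALYs %+6.3f  [%s]\n",
              format(round(x$cost[7]), big.mark = ","), x$qalys[7],
              if (is.na(icer)) attr(x, "classification") else
                sprintf("ICER $%s/QALY", format(round(icer), big.mark = ","))))
  invisible(x)
}
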