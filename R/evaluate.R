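#' Per-cell-type root mean square error between two compositions
#'
#' Spots and types are aligned by identifier, never by position; any
#' mismatch in either universe is an error that lists the difference.
#'
#' @param truth,est Spots x types composition matrices (or [deconvolve()]
#'   fits) over identical spot and type universes.
#' @return Named numeric vector, one RMSE per cell type.
#' @export
rmse <- function(truth, est) {
  al <- align_compositions(truth, est)
  sqrt(colMeans((al$truth - al$est)^2))
}

align_compositions <- function(truth, est) {
  truth <- as_composition(truth); est <- as_composition(est)
  d1 <- setdiff(rownames(truth), rownames(est))
  d2 <- setdiff(rownames(est), rownames(truth))
  d3 <- setdiff(colnames(truth), colnames(est))
  d4 <- setdiff(colnames(est), colnames(truth))
  if (length(c(d1, d2, d3, d4)))
    stop_input(paste0("composition universes differ — ",
                      "spots only in truth: {%s}; only in estimate: {%s}; ",
                      "types only in truth: {%s}; only in estimate: {%s}"),
               paste(d1, collapse = ","), paste(d2, collapse = ","),
               paste(d3, collapse = ","), paste(d4, collapse = ","))
  list(truth = truth, est = est[rownames(truth), colnames(truth), drop = FALSE])
}

#' RMSE split by cell-type presence and absence
#'
#' For every cell type, spots are divided into those where the type truly
#' occurs (`truth > 0`; errors there measure sensitivity) and those where it
#' does not (errors there measure specificity — spurious assignment of an
#' absent type), and RMSE is computed separately on each subset. Ground
#' truth fractions are exact rationals, so presence is `> 0` with no
#' tolerance. An empty subset yields `NA` for its RMSE.
#'
#' @inheritParams rmse
#' @return An `rmse_report` data.frame with columns `type`, `rmse_overall`,
#'   `rmse_present`, `rmse_absent`, `n_present`, `n_absent`.
#' @export
rmse_by_presence <- function(truth, est) {
  al <- align_compositions(truth, est)
  types <- colnames(al$truth)
  rows <- lapply(types, function(k) {
    err2 <- (al$truth[, k] - al$est[, k])^2
    present <- al$truth[, k] > 0
    data.frame(type = k,
               rmse_overall = sqrt(mean(err2)),
               rmse_present = if (any(present)) sqrt(mean(err2[present])) else NA_real_,
               rmse_absent = if (any(!present)) sqrt(mean(err2[!present])) else NA_real_,
               n_present = sum(present), n_absent = sum(!present),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rmse_report", "data.frame")
  out
}

#' @export
print.rmse_report <- function(x, ...) {
  cat("RMSE by cell-type presence/absence\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an RMSE report as a delimited table
#'
#' @param report An `rmse_report` from [rmse_by_presence()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_rmse_report <- function(report, path, sep = "\t") {
  con <- file(path, open = "wb"); on.exit(close(con))
  num <- function(v) ifelse(is.na(v), "NA", format_num(v))
  writeLines(c(paste(names(report), collapse = sep),
               paste(report$type, num(report$rmse_overall),
                     num(report$rmse_present), num(report$rmse_absent),
                     report$n_present, report$n_absent, sep = sep)),
             con = con, sep = "\n")
  invisible(path)
}

#' Scatter plot of true versus estimated fractions for one cell type
#'
#' @inheritParams rmse
#' @param type Cell type to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_concordance <- function(truth, est, type, ...) {
  al <- align_compositions(truth, est)
  if (!type %in% colnames(al$truth)) stop_input("unknown cell type '%s'", type)
  graphics::plot(al$truth[, type], al$est[, type],
                 xlab = "true fraction", ylab = "estimated fraction",
                 main = type, xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(NULL)
}
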