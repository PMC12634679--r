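# Figures of merit for paired experimental/calculated free-energy tables,
# with case-resampling bootstrap confidence intervals.

#' Point figures of merit for a benchmark table
#'
#' Quantitative statistics (MAE, squared Pearson correlation, Spearman rho
#' with average ranks for ties, Kendall tau-b) are computed over the
#' quantitative records only. Classification statistics (accuracy as the
#' percentage of records whose experimental and calculated values fall on
#' the same side of the threshold, and the Matthews correlation coefficient
#' of the stabilizing/destabilizing confusion matrix) also use the
#' quantitative records; when every record falls in one class the MCC is
#' undefined and reported as NA.
#'
#' @param table a \linkS4class{BenchmarkTable} or a data.frame with columns
#'   \code{ddg_exp} and \code{ddg_calc}.
#' @param threshold classification threshold in kcal mol^-1 (default 0:
#'   destabilizing means positive Delta Delta G).
#' @return named list: \code{mae}, \code{r2}, \code{rho}, \code{tau},
#'   \code{accuracy} (percent), \code{mcc}, \code{n}.
#' @examples
#' tab <- hydrationBenchmark()
#' figuresOfMerit(tab)[c("tau", "rho", "r2")]
#' @export
figuresOfMerit <- function(table, threshold = 0) {
  r <- if (is(table, "BenchmarkTable")) records(table, quantitativeOnly = TRUE)
       else table
  x <- r$ddg_exp
  y <- r$ddg_calc
  n <- length(x)
  if (n < 2L) stop("need at least 2 quantitative records")
  conf <- .confusion(x, y, threshold)
  list(mae = mean(abs(y - x)),
       r2 = stats::cor(x, y)^2,
       rho = stats::cor(x, y, method = "spearman"),
       tau = stats::cor(x, y, method = "kendall"),
       accuracy = 100 * unname(conf[["TP"]] + conf[["TN"]]) / n,
       mcc = .mcc(conf),
       n = n)
}

.confusion <- function(x, y, threshold) {
  xp <- x > threshold  # destabilizing = positive class
  yp <- y > threshold
  c(TP = sum(xp & yp), TN = sum(!xp & !yp),
    FP = sum(!xp & yp), FN = sum(xp & !yp))
}

.mcc <- function(conf) {
  tp <- conf[["TP"]]; tn <- conf[["TN"]]
  fp <- conf[["FP"]]; fn <- conf[["FN"]]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Bootstrap confidence interval for one figure of merit
#'
#' Case-resampling bootstrap over the quantitative records: the statistic is
#' recomputed on each resample and the percentile bounds of the configured
#' confidence mass are reported together with the mean over resamples.
#' Resamples on which the statistic is undefined (e.g. a single-class MCC or
#' zero-variance correlation) are redrawn, up to a cap of 10x the requested
#' resample count.
#'
#' @param table a \linkS4class{BenchmarkTable} or compatible data.frame.
#' @param statistic one of "mae", "r2", "rho", "tau", "accuracy", "mcc".
#' @param spec a \linkS4class{BootstrapSpec}.
#' @param threshold classification threshold passed to the statistic.
#' @return named list: \code{point} (full-table value), \code{mean}
#'   (bootstrap average), \code{low}, \code{high}.
#' @export
bootstrapCI <- function(table, statistic = c("mae", "r2", "rho", "tau",
                                             "accuracy", "mcc"),
                        spec = new("BootstrapSpec"), threshold = 0) {
  statistic <- match.arg(statistic)
  r <- if (is(table, "BenchmarkTable")) records(table, quantitativeOnly = TRUE)
       else table
  point <- figuresOfMerit(r, threshold)[[statistic]]
  if (!is.finite(point))
    stop(sprintf("statistic '%s' is undefined on the full table", statistic))
  one <- function(idx) {
    rr <- r[idx, , drop = FALSE]
    if (stats::var(rr$ddg_exp) == 0 || stats::var(rr$ddg_calc) == 0)
      return(NA_real_)
    figuresOfMerit(rr, threshold)[[statistic]]
  }
  n <- nrow(r)
  vals <- numeric(spec@resamples)
  drawn <- 0L
  cap <- 10L * spec@resamples
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@seed)
  i <- 1L
  while (i <= spec@resamples) {
    if (drawn >= cap)
      stop(sprintf("statistic '%s' undefined on too many resamples", statistic))
    v <- one(sample.int(n, n, replace = TRUE))
    drawn <- drawn + 1L
    if (is.finite(v)) { vals[i] <- v; i <- i + 1L }
  }
  a <- (1 - spec@confidence) / 2
  q <- unname(stats::quantile(vals, c(a, 1 - a), type = 7))
  list(point = point, mean = mean(vals), low = q[1L], high = q[2L])
}

#' Full figures-of-merit report with bootstrap intervals
#'
#' @param table a \linkS4class{BenchmarkTable}.
#' @param spec a \linkS4class{BootstrapSpec}.
#' @param threshold classification threshold.
#' @return data.frame with one row per statistic: point value, bootstrap
#'   mean, and the confidence bounds.
#' @export
benchmarkReport <- function(table, spec = new("BootstrapSpec"),
                            threshold = 0) {
  fom <- figuresOfMerit(table, threshold)
  stats_ <- c("mae", "r2", "rho", "tau", "accuracy", "mcc")
  rows <- lapply(stats_, function(s) {
    if (!is.finite(fom[[s]]))
      return(data.frame(statistic = s, point = NA_real_, mean = NA_real_,
                        low = NA_real_, high = NA_real_))
    ci <- bootstrapCI(table, s, spec, threshold)
    data.frame(statistic = s, point = ci$point, mean = ci$mean,
               low = ci$low, high = ci$high)
  })
  do.call(rbind, rows)
}
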