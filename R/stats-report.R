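#' Genotype fixed-effect linear model on per-larva metrics
#'
#' Fits ordinary least squares `metric ~ genotype` with treatment coding,
#' the control genotype as reference, each larva one statistical unit.
#' With two groups the genotype effect is exactly the difference of group
#' means and its t statistic equals the pooled-variance two-sample t.
#'
#' @param metrics data.frame with a `genotype` column and the metric column.
#' @param metric name of the metric column (e.g. `"stride_length_mean"`).
#' @param reference reference (control) genotype level.
#' @return object of class `genotype_fit`: list with the underlying `lm`
#'   fit (`$fit`) and a `contrasts` data.frame (genotype, estimate, se, t,
#'   p) of each genotype's effect versus the reference.
#' @export
fit_genotype_model <- function(metrics, metric, reference) {
  if (!metric %in% names(metrics)) stop("metric column not found: ", metric)
  if (!"genotype" %in% names(metrics)) stop("metrics need a 'genotype' column")
  d <- metrics[is.finite(metrics[[metric]]), c(metric, "genotype")]
  d$genotype <- stats::relevel(factor(d$genotype), ref = reference)
  if (nlevels(d$genotype) < 2) stop("need at least 2 genotypes")
  tab <- table(d$genotype)
  if (any(tab < 2)) stop("each genotype needs n >= 2")
  names(d)[1] <- "value"
  fit <- stats::lm(value ~ genotype, data = d)
  cf <- summary(fit)$coefficients
  rows <- grep("^genotype", rownames(cf))
  contrasts <- data.frame(
    genotype = sub("^genotype", "", rownames(cf)[rows]),
    estimate = cf[rows, 1], se = cf[rows, 2],
    t = cf[rows, 3], p = cf[rows, 4],
    row.names = NULL
  )
  structure(list(fit = fit, metric = metric, reference = reference,
                 contrasts = contrasts),
            class = "genotype_fit")
}

#' @export
print.genotype_fit <- function(x, ...) {
  cat(sprintf("Linear model: %s ~ genotype (reference: %s)\n",
              x$metric, x$reference))
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.genotype_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.genotype_fit <- function(object, ...) stats::coef(object$fit, ...)

# Tukey box-plot descriptors for one numeric vector
tukey_descriptors <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  n <- sum(is.finite(v))
  notch <- 1.57 * iqr / sqrt(n)
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = if (length(inside)) min(inside) else NA_real_,
       whisker_hi = if (length(inside)) max(inside) else NA_real_,
       notch_lo = q[2] - notch, notch_hi = q[2] + notch)
}

#' Cohort summary: mean, SEM and Tukey box descriptors
#'
#' Per genotype and per metric: n, mean, SEM (`sd/sqrt(n)`; `NA` and
#' flagged when n = 1), and the Tukey box-plot descriptors — median,
#' quartiles, whiskers at the most extreme points within 1.5 IQR of the
#' box, and the 95% median notch `median +/- 1.57 IQR / sqrt(n)`.
#'
#' @param metrics per-larva (or per-nucleus) data.frame with `genotype`.
#' @param metric_cols metric columns to summarise; defaults to the three
#'   locomotion metrics present in a `cohort_kinematics` table.
#' @return data.frame of class `cohort_summary`, one row per
#'   genotype x metric.
#' @export
summarize_cohort <- function(metrics,
                             metric_cols = intersect(
                               c("walking_rate", "stride_length_mean",
                                 "stride_duration_mean"), names(metrics))) {
  if (!"genotype" %in% names(metrics)) stop("metrics need a 'genotype' column")
  if (length(metric_cols) == 0) stop("no metric columns to summarise")
  out <- list()
  for (m in metric_cols) {
    for (g in unique(metrics$genotype)) {
      v <- metrics[[m]][metrics$genotype == g]
      v <- v[is.finite(v)]
      n <- length(v)
      td <- if (n > 0) tukey_descriptors(v) else
        list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
             whisker_lo = NA_real_, whisker_hi = NA_real_,
             notch_lo = NA_real_, notch_hi = NA_real_)
      out[[length(out) + 1]] <- data.frame(
        genotype = g, metric = m, n = n,
        mean = if (n > 0) mean(v) else NA_real_,
        sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
        sem_defined = n > 1,
        median = td$median, q1 = td$q1, q3 = td$q3,
        whisker_lo = td$whisker_lo, whisker_hi = td$whisker_hi,
        notch_lo = td$notch_lo, notch_hi = td$notch_hi,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out),
            class = c("cohort_summary", "data.frame"))
}

#' Render a cohort report
#'
#' Writes the summary table as CSV and JSON and one Tukey box plot per
#' metric (PNG, falling back to PDF on devices without PNG support).
#' Deterministic given its inputs.
#'
#' @param metrics per-larva metrics data.frame with `genotype`.
#' @param out_dir output directory, created if needed.
#' @param metric_cols metric columns (see [summarize_cohort()]).
#' @return invisibly, the character vector of files written.
#' @export
render_report <- function(metrics, out_dir,
                          metric_cols = intersect(
                            c("walking_rate", "stride_length_mean",
                              "stride_duration_mean"), names(metrics))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  csv <- file.path(out_dir, "summary.csv")
  jsn <- file.path(out_dir, "summary.json")
  if (nrow(metrics) == 0 || length(metric_cols) == 0) {
    empty <- data.frame(genotype = character(0), metric = character(0),
                        n = integer(0), mean = numeric(0), sem = numeric(0))
    utils::write.csv(empty, csv, row.names = FALSE)
    jsonlite::write_json(list(), jsn, auto_unbox = TRUE)
    return(invisible(c(csv, jsn)))
  }
  summ <- summarize_cohort(metrics, metric_cols)
  utils::write.csv(as.data.frame(summ), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(summ), jsn, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  files <- c(csv, jsn)
  for (m in metric_cols) {
    ok <- is.finite(metrics[[m]])
    fig <- file.path(out_dir, paste0(m, "_boxplot.png"))
    opened <- tryCatch({ grDevices::png(fig, width = 600, height = 480); TRUE },
                       error = function(e) FALSE)
    if (!opened) {
      fig <- file.path(out_dir, paste0(m, "_boxplot.pdf"))
      grDevices::pdf(fig, width = 6, height = 5)
    }
    # small groups can push the median notch outside the hinges; harmless
    suppressWarnings(
      graphics::boxplot(metrics[[m]][ok] ~ factor(metrics$genotype[ok]),
                        notch = TRUE, xlab = "genotype", ylab = m,
                        main = paste("Tukey box plot:", m)))
    pts <- summarize_cohort(metrics[ok, , drop = FALSE], m)
    graphics::points(seq_len(nrow(pts)), pts$mean, pch = 18, col = "red")
    grDevices::dev.off()
    files <- c(files, fig)
  }
  invisible(files)
}
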