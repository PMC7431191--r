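#' Sum-slices projection
#'
#' Collapses a two-channel z-stack to one 2D image per channel by pixelwise
#' summation over z, preserving integrated intensity (the projection used
#' before ROI quantification of nascent-transcript signal).
#'
#' @param stack an `image_stack` (array `c(channel, z, y, x)`).
#' @return named list of 2D matrices, one per channel.
#' @export
sum_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack") || (is.array(stack) && length(dim(stack)) == 4))
  d <- dim(stack)
  if (d[2] < 1) stop("stack needs at least one z-slice")
  ch <- attr(stack, "channels") %||% paste0("ch", seq_len(d[1]))
  out <- lapply(seq_len(d[1]), function(c) {
    sl <- stack[c, , , , drop = FALSE]
    dim(sl) <- d[2:4]
    apply(sl, c(2, 3), sum)
  })
  names(out) <- ch
  out
}

#' Background threshold with soft subtraction
#'
#' Removes background from a projected channel image: a per-image threshold
#' is computed (default: a percentile of the pixel distribution — with
#' sparse foci the median estimates the background level), pixels at or
#' below it are zeroed, and the threshold is subtracted from the remaining
#' pixels ("soft" subtraction, so integrated focus signal above background
#' is preserved rather than inflated by the background pedestal).
#'
#' @param image 2D numeric matrix.
#' @param method `"percentile"` (threshold = `quantile(image, p)`) or
#'   `"fixed"` (threshold = `value`).
#' @param params list; `p` for percentile (default 0.5), `value` for fixed.
#' @return the background-subtracted image, with the threshold used stored
#'   as attribute `"threshold"`.
#' @export
apply_threshold <- function(image, method = c("percentile", "fixed"),
                            params = list()) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  thr <- switch(method,
    percentile = stats::quantile(image, params$p %||% 0.5, names = FALSE),
    fixed = params$value %||% stop("fixed method requires params$value"))
  out <- pmax(image - thr, 0)
  attr(out, "threshold") <- thr
  out
}

#' Per-nucleus integrated intensity ratio
#'
#' Integrates the thresholded col and nau projections over one nuclear ROI
#' (mask label) and forms the col/nau ratio. The same ROI is applied to
#' both channels. A nucleus with zero nau signal is flagged invalid and
#' excluded from group summaries.
#'
#' @param proj_col,proj_nau background-subtracted 2D projections
#'   (see [apply_threshold()]), identically thresholded in method.
#' @param mask integer-labelled matrix, same `(y, x)` shape.
#' @param nucleus_id label to measure.
#' @return one-row data.frame of class `nucleus_measurement`:
#'   `nucleus_id`, `I_col`, `I_nau`, `R`, `valid`.
#' @export
roi_ratio <- function(proj_col, proj_nau, mask, nucleus_id) {
  if (!all(dim(proj_col) == dim(mask)) || !all(dim(proj_nau) == dim(mask)))
    stop("projection and mask shapes disagree")
  sel <- mask == nucleus_id
  if (!any(sel)) stop(sprintf("mask label %s not found", nucleus_id))
  I_col <- sum(proj_col[sel])
  I_nau <- sum(proj_nau[sel])
  valid <- I_nau > 0
  structure(data.frame(
    nucleus_id = nucleus_id, I_col = I_col, I_nau = I_nau,
    R = if (valid) I_col / I_nau else NA_real_,
    valid = valid
  ), class = c("nucleus_measurement", "data.frame"))
}

#' Quantify every nucleus of a stack
#'
#' Full quantification chain: sum-slices projection, per-channel background
#' thresholding, and ROI-integrated col/nau ratio for every mask label.
#'
#' @param stack an `image_stack`.
#' @param mask integer-labelled `(y, x)` matrix.
#' @param method,params threshold settings passed to [apply_threshold()].
#' @param stage,genotype labels copied onto every measurement row.
#' @return data.frame of class `nucleus_measurements`, one row per nucleus,
#'   with threshold metadata in attribute `"thresholds"`.
#' @export
quantify_stack <- function(stack, mask, method = "percentile",
                           params = list(p = 0.5),
                           stage = NA_character_, genotype = NA_character_) {
  proj <- sum_projection(stack)
  ch <- names(proj)
  if (!all(c("col", "nau") %in% ch))
    stop("stack must carry 'col' and 'nau' channels")
  pc <- apply_threshold(proj$col, method = method, params = params)
  pn <- apply_threshold(proj$nau, method = method, params = params)
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  if (length(labels) == 0) {
    warning("mask contains no labels; empty measurement set")
    out <- data.frame(nucleus_id = integer(0), I_col = numeric(0),
                      I_nau = numeric(0), R = numeric(0), valid = logical(0),
                      stage = character(0), genotype = character(0))
    return(structure(out,
                     thresholds = c(col = attr(pc, "threshold"),
                                    nau = attr(pn, "threshold")),
                     class = c("nucleus_measurements", "data.frame")))
  } else {
    out <- do.call(rbind, lapply(labels, function(l)
      roi_ratio(pc, pn, mask, l)))
  }
  out$stage <- stage
  out$genotype <- genotype
  structure(out,
            thresholds = c(col = attr(pc, "threshold"),
                           nau = attr(pn, "threshold")),
            class = c("nucleus_measurements", "data.frame"))
}

#' Compare two groups of nucleus ratios
#'
#' Two-sample unpaired t-test (pooled variance) on per-nucleus ratios, with
#' mean +/- SEM group summaries. Invalid measurements are excluded;
#' zero-variance groups are flagged and the test skipped.
#'
#' @param groupA,groupB `nucleus_measurements` tables (or numeric vectors
#'   of ratios).
#' @return list of class `fish_comparison`: `summaryA`, `summaryB` (each
#'   `mean`, `sem`, `n`), `t`, `df`, `p`, `degenerate` flag.
#' @export
group_compare <- function(groupA, groupB) {
  ratios <- function(g) {
    if (is.data.frame(g)) g$R[is.finite(g$R) & (g$valid %||% TRUE)] else
      g[is.finite(g)]
  }
  a <- ratios(groupA); b <- ratios(groupB)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  summ <- function(v) list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                           n = length(v))
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
    t <- 0; p <- 1; df <- length(a) + length(b) - 2
  } else if (degenerate) {
    t <- Inf; p <- 0; df <- length(a) + length(b) - 2
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    t <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  }
  structure(list(summaryA = summ(a), summaryB = summ(b),
                 t = t, df = df, p = p, degenerate = degenerate),
            class = "fish_comparison")
}

#' @export
print.fish_comparison <- function(x, ...) {
  cat(sprintf("Group A: %.3f +/- %.3f (n = %d)\n",
              x$summaryA$mean, x$summaryA$sem, x$summaryA$n))
  cat(sprintf("Group B: %.3f +/- %.3f (n = %d)\n",
              x$summaryB$mean, x$summaryB$sem, x$summaryB$n))
  cat(sprintf("Unpaired t-test: t = %.3f, df = %g, p = %.3g%s\n",
              x$t, x$df, x$p,
              if (x$degenerate) " (degenerate zero-variance groups)" else ""))
  invisible(x)
}
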