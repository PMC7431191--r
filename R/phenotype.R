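#' Sample per-segment phenotype calls
#'
#' Draws `n_segments` independent multinomial phenotype calls (normal,
#' branched, transformed, absent) at the given proportions, assigning
#' abdominal segment ids A1-A7 cyclically and grouping every 7 segments
#' into one embryo/larva.
#'
#' @param props a [phenotype_proportions()] object.
#' @param n_segments number of segment calls to draw.
#' @param seed integer seed.
#' @param genotype label attached to every row.
#' @return data.frame of class `phenotype_table` with columns `animal_id`,
#'   `segment_id`, `genotype`, `category` (factor over the four levels).
#' @export
sample_phenotypes <- function(props, n_segments, seed, genotype = "control") {
  stopifnot(inherits(props, "phenotype_proportions"))
  if (n_segments < 1) stop("'n_segments' must be >= 1")
  set.seed(as.integer(seed))
  lev <- phenotype_levels()
  calls <- sample(lev, n_segments, replace = TRUE, prob = unclass(props))
  idx <- seq_len(n_segments) - 1L
  structure(data.frame(
    animal_id = sprintf("%s_e%02d", genotype, idx %/% 7L + 1L),
    segment_id = paste0("A", idx %% 7L + 1L),
    genotype = genotype,
    category = factor(calls, levels = lev),
    stringsAsFactors = FALSE
  ), class = c("phenotype_table", "data.frame"))
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - hw), upper = min(1, centre + hw))
}

#' Tally phenotype proportions per genotype
#'
#' Counts per-segment phenotype calls for each genotype and reports the
#' category proportions with Wilson score 95% confidence intervals, at the
#' segment level (each segment an independent trial) and, because segments
#' of one animal may be correlated, also as per-animal-averaged
#' proportions.
#'
#' @param table a `phenotype_table` (columns `genotype`, `category`, and
#'   `animal_id` for the per-animal view).
#' @param conf confidence level for the Wilson intervals.
#' @return list of class `phenotype_tally`: `segments` (data.frame
#'   genotype, category, k, n, proportion, ci_lower, ci_upper) and
#'   `animals` (per-animal-averaged proportions per genotype).
#' @export
tally_phenotypes <- function(table, conf = 0.95) {
  if (nrow(table) == 0) stop("empty phenotype table")
  if (!all(c("genotype", "category") %in% names(table)))
    stop("phenotype table needs 'genotype' and 'category' columns")
  lev <- phenotype_levels()
  cat_f <- factor(as.character(table$category), levels = lev)
  if (anyNA(cat_f))
    stop("unknown phenotype category; allowed: ", paste(lev, collapse = ", "))

  seg <- do.call(rbind, lapply(split(cat_f, table$genotype), function(v) {
    k <- as.integer(table(v)); n <- length(v)
    ci <- t(vapply(k, wilson_ci, numeric(2), n = n, conf = conf))
    data.frame(category = lev, k = k, n = n, proportion = k / n,
               ci_lower = ci[, 1], ci_upper = ci[, 2])
  }))
  seg <- cbind(genotype = rep(names(split(cat_f, table$genotype)),
                              each = length(lev)), seg)
  rownames(seg) <- NULL

  animals <- NULL
  if ("animal_id" %in% names(table)) {
    per_animal <- lapply(split(table, table$genotype), function(d) {
      props <- t(vapply(split(factor(as.character(d$category), levels = lev),
                              d$animal_id),
                        function(v) as.integer(table(v)) / length(v),
                        numeric(length(lev))))
      data.frame(category = lev, mean_proportion = colMeans(props),
                 n_animals = nrow(props))
    })
    animals <- do.call(rbind, per_animal)
    animals <- cbind(genotype = rep(names(per_animal), each = length(lev)),
                     animals)
    rownames(animals) <- NULL
  }
  structure(list(segments = seg, animals = animals, conf = conf),
            class = "phenotype_tally")
}

#' @export
print.phenotype_tally <- function(x, ...) {
  cat("Per-segment phenotype proportions (Wilson",
      sprintf("%.0f%% CI)\n", 100 * x$conf))
  print(x$segments, row.names = FALSE)
  invisible(x)
}
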