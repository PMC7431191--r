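# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# draw from Normal(mean, sd) rejected below `lower`; sd = 0 collapses to mean
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated normal rejection failed to converge")
  }
  out
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# per-object sub-seed scheme: seed * 10007 + counter, reduced into integer
# range (documented contract; distinct base seeds get disjoint sub-seed
# streams, and cohort generation is order-independent)
derive_subseed <- function(seed, index) {
  s <- (as.numeric(seed) * 10007 + as.numeric(index)) %% 2147483647
  as.integer(s)
}
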