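# Species/vessel group comparison: Mann-Whitney U with exact or
# approximate p-values, median/IQR summaries, and the paired helicity
# intensity vs TAWSS export.

#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum test with midrank tie handling. Reports
#' `U = min(U1, U2)` where `U1 + U2 = n1 * n2`. The two-sided p-value is
#' exact (full enumeration of rank assignments) when the samples are
#' tie-free and `choose(n1 + n2, n1) <= 2e5`, otherwise a normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y numeric samples (each nonempty).
#' @return list with `U`, `p`, `method` (`"exact"` or `"normal_approx"`),
#'   `n1`, `n2`.
#' @export
mannWhitneyU <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopInput("both samples must be nonempty")
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  # fully tied pooled sample: the rank-sum variance is zero and the normal
  # approximation is 0/0; there is no evidence of a difference
  if (length(unique(c(x, y))) == 1)
    return(list(U = n1 * n2 / 2, p = 1, method = "normal_approx",
                n1 = n1, n2 = n2))
  ties <- any(duplicated(c(x, y)))
  exactOK <- !ties && choose(n1 + n2, n1) <= 2e5
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exactOK, correct = TRUE, alternative = "two.sided"))
  list(U = min(u1, u2), p = min(wt$p.value, 1),
       method = if (exactOK) "exact" else "normal_approx",
       n1 = n1, n2 = n2)
}

#' Compare species groups per descriptor and vessel type
#'
#' For every descriptor x vessel-type cell with both species present
#' (n >= 2 each after dropping missing values), computes group medians
#' and interquartile ranges (25th/75th percentiles, linear-interpolation
#' convention) and the two-sided Mann-Whitney U test. Raw p-values are
#' reported; no multiple-testing adjustment is applied, and the report
#' carries a note saying so.
#'
#' @param table a cohort descriptor table (see [makeCohort()]): columns
#'   `vessel_id`, `species` in `human`/`swine`, `vessel_type` in
#'   `RCA`/`LAD`/`LCX`, plus descriptor columns.
#' @param alpha significance level for the flag (default 0.05).
#' @param descriptors descriptor columns to compare; defaults to the
#'   intersection of [descriptorNames()] with the table's columns.
#' @return a [ComparisonReport-class].
#' @export
groupCompare <- function(table, alpha = 0.05, descriptors = NULL) {
  req <- c("vessel_id", "species", "vessel_type")
  if (!all(req %in% names(table)))
    stopInput("table must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(table$vessel_id)) stopInput("duplicated vessel_id")
  if (!all(table$species %in% c("human", "swine")))
    stopInput("unknown species label(s): %s",
              paste(setdiff(unique(table$species), c("human", "swine")), collapse = ", "))
  if (!all(table$vessel_type %in% c("RCA", "LAD", "LCX")))
    stopInput("unknown vessel_type label(s): %s",
              paste(setdiff(unique(table$vessel_type), c("RCA", "LAD", "LCX")), collapse = ", "))
  if (is.null(descriptors))
    descriptors <- intersect(descriptorNames(), names(table))
  if (!length(descriptors)) stopInput("no descriptor columns found")

  rows <- list()
  for (de in descriptors) {
    for (ve in c("RCA", "LAD", "LCX")) {
      sel <- table$vessel_type == ve
      if (!any(sel)) next
      xh <- table[[de]][sel & table$species == "human"]
      xs <- table[[de]][sel & table$species == "swine"]
      xh <- xh[is.finite(xh)]; xs <- xs[is.finite(xs)]
      if (length(xh) < 2 || length(xs) < 2) {
        warning(sprintf("cell %s/%s skipped: insufficient n (human %d, swine %d)",
                        de, ve, length(xh), length(xs)))
        next
      }
      qh <- quantile(xh, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      qs <- quantile(xs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      mw <- mannWhitneyU(xh, xs)
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = de, vessel_type = ve,
        n_human = mw$n1, n_swine = mw$n2,
        median_human = qh[2], q25_human = qh[1], q75_human = qh[3],
        median_swine = qs[2], q25_swine = qs[1], q75_swine = qs[3],
        U = mw$U, p = mw$p, significant = mw$p < alpha,
        method = mw$method, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(descriptor = character(0))
  rownames(res) <- NULL
  new("ComparisonReport", results = res, alpha = alpha,
      note = "raw two-sided p-values; no multiple-testing adjustment")
}

#' Paired helicity intensity vs TAWSS export
#'
#' Extracts (species, vessel_type, h2, tawss) tuples and reports the
#' Spearman rank correlation of h2 with TAWSS per species as a
#' descriptive statistic (NA when either variable is constant).
#'
#' @param table a cohort descriptor table with `h2` and `tawss` columns.
#' @return list with `pairs` (data.frame) and `spearman` (data.frame with
#'   `species`, `rho`, `n`).
#' @export
exportH2Tawss <- function(table) {
  if (!all(c("h2", "tawss") %in% names(table)))
    stopInput("table must contain h2 and tawss columns")
  pairs <- table[, c("species", "vessel_type", "h2", "tawss")]
  pairs <- pairs[is.finite(pairs$h2) & is.finite(pairs$tawss), ]
  sp <- unique(pairs$species)
  rho <- vapply(sp, function(s) {
    d <- pairs[pairs$species == s, ]
    if (nrow(d) < 3 || sd(d$h2) == 0 || sd(d$tawss) == 0) return(NA_real_)
    stats::cor(d$h2, d$tawss, method = "spearman")
  }, numeric(1))
  n <- vapply(sp, function(s) sum(pairs$species == s), integer(1))
  list(pairs = pairs,
       spearman = data.frame(species = sp, rho = unname(rho), n = unname(n),
                             stringsAsFactors = FALSE))
}
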