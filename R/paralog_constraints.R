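#' Remove synonymously saturated gene pairs
#'
#' Synonymous sites saturate for old duplicates, making omega unreliable, so
#' downstream selection analyses keep only pairs with finite Ks strictly
#' below the cutoff (default 1.1). Pairs with missing Ks, or flagged
#' saturated, are removed. Order is preserved.
#'
#' @param pairs A `pair_table` with a `ks` column (optionally a `saturated`
#'   logical column).
#' @param ks_max Exclusive upper bound on Ks.
#' @return The filtered `pair_table`.
#' @export
filter_unsaturated <- function(pairs, ks_max = 1.1) {
  stopifnot(is.data.frame(pairs), "ks" %in% names(pairs))
  keep <- !is.na(pairs$ks) & is.finite(pairs$ks) & pairs$ks < ks_max
  if ("saturated" %in% names(pairs)) {
    keep <- keep & !isTRUE_vec(pairs$saturated)
  }
  pairs[keep, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Classify selection mode from omega
#'
#' Thresholds follow the gamma-rates modified Yang-Nielsen convention:
#' purifying (negative) selection at omega <= 0.3, neutral at
#' 0.3 < omega < 3, positive at omega >= 3. Missing omega maps to
#' `undefined`.
#'
#' @param omega Numeric vector of nonnegative omega values (`NA` allowed).
#' @param thresholds Length-2 vector `c(purifying_max, positive_min)`.
#' @return Factor with levels `purifying`, `neutral`, `positive`,
#'   `undefined`.
#' @examples
#' classify_selection(c(0.0262, 0.9937, 3, NA))
#' @export
classify_selection <- function(omega, thresholds = c(0.3, 3)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  if (any(!is.na(omega) & omega < 0)) stop("omega must be nonnegative")
  labels <- ifelse(is.na(omega), "undefined",
                   ifelse(omega <= thresholds[1], "purifying",
                          ifelse(omega < thresholds[2], "neutral",
                                 "positive")))
  factor(labels, levels = c("purifying", "neutral", "positive", "undefined"))
}

#' Replicon relation of a gene pair
#'
#' Classifies where the two copies of a pair live: within chromosome I,
#' within chromosome II, between the two chromosomes, within the plasmids,
#' or between a chromosome and a plasmid. Symmetric in its arguments.
#'
#' @param r1,r2 Replicon labels (vectors recycle): `CI`, `CII`, or plasmids
#'   `PA`--`PE`.
#' @return Factor with levels `within-CI`, `within-CII`, `between-CI-CII`,
#'   `within-plasmids`, `chromosome-plasmid`.
#' @examples
#' replicon_relation(c("CI", "PA", "PD"), c("CII", "PD", "CII"))
#' @export
replicon_relation <- function(r1, r2) {
  bad <- setdiff(unique(c(r1, r2)), REPLICON_LEVELS)
  if (length(bad)) stop("unknown replicon label(s): ",
                        paste(bad, collapse = ", "))
  both_chrom <- r1 %in% CHROMOSOMES & r2 %in% CHROMOSOMES
  both_plasmid <- r1 %in% PLASMIDS & r2 %in% PLASMIDS
  labels <- ifelse(both_chrom & r1 == r2 & r1 == "CI", "within-CI",
            ifelse(both_chrom & r1 == r2 & r1 == "CII", "within-CII",
            ifelse(both_chrom, "between-CI-CII",
            ifelse(both_plasmid, "within-plasmids", "chromosome-plasmid"))))
  factor(labels, levels = c("within-CI", "within-CII", "between-CI-CII",
                            "within-plasmids", "chromosome-plasmid"))
}

#' Mean and standard deviation of omega by replicon relation
#'
#' Groups pairs by [replicon_relation()] and reports the arithmetic mean and
#' the sample (n - 1) standard deviation of omega per nonempty group; the sd
#' is `NA` for singleton groups.
#'
#' @param pairs A `pair_table` with finite `omega`, `replicon1`, `replicon2`.
#' @return Data frame with columns `group`, `n`, `mean_omega`, `sd_omega`.
#' @export
summarize_omega_by_group <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(group = character(0), n = integer(0),
                      mean_omega = numeric(0), sd_omega = numeric(0)))
  }
  stopifnot(all(is.finite(pairs$omega)))
  rel <- replicon_relation(pairs$replicon1, pairs$replicon2)
  groups <- levels(rel)[levels(rel) %in% rel]
  rows <- lapply(groups, function(g) {
    w <- pairs$omega[rel == g]
    data.frame(group = g, n = length(w), mean_omega = mean(w),
               sd_omega = if (length(w) > 1) sd(w) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative frequency of gene-pair lengths by class
#'
#' Bins lengths into `(0,100]`, `(100,200]`, ... windows (printed as
#' `1-100`, `101-200`, ...) and normalises counts within each paralog class
#' so the frequencies of each class sum to 1.
#'
#' @param pairs A `pair_table` with positive integer `length` and `class`.
#' @param bin_width Bin width (default 100).
#' @return Data frame with columns `class`, `bin`, `count`, `frequency`.
#' @export
length_bin_frequencies <- function(pairs, bin_width = 100) {
  stopifnot(nrow(pairs) > 0, all(!is.na(pairs$length)))
  if (any(pairs$length <= 0)) stop("lengths must be positive")
  idx <- ceiling(pairs$length / bin_width)
  lab <- sprintf("%d-%d", (idx - 1L) * bin_width + 1L, idx * bin_width)
  rows <- lapply(unique(pairs$class), function(cl) {
    sel <- pairs$class == cl
    tab <- table(lab[sel])
    ord <- order(as.integer(sub("-.*", "", names(tab))))
    data.frame(class = cl, bin = names(tab)[ord],
               count = as.integer(tab)[ord],
               frequency = as.integer(tab)[ord] / sum(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test comparing the empirical distributions of two samples; D is
#' the maximum absolute difference of the empirical CDFs and the p-value
#' uses the asymptotic Kolmogorov distribution with the standard effective
#' sample-size correction.
#'
#' @param x,y Numeric samples with at least one value each.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Correlation between a substitution rate and amino-acid divergence
#'
#' Pearson correlation of `ka` or `ks` against percent divergence over the
#' pairs where both are present, with the p-value from the t-transform of R
#' on n - 2 degrees of freedom.
#'
#' @param pairs A `pair_table` with `divergence` and the chosen rate column.
#' @param rate_field `"ka"` or `"ks"`.
#' @return A list with `r`, `p_value`, and `n` (pairs used).
#' @export
rate_divergence_correlation <- function(pairs, rate_field = c("ka", "ks")) {
  rate_field <- match.arg(rate_field)
  x <- pairs[[rate_field]]
  y <- pairs$divergence
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 pairs with both values present")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    stop("correlation undefined: zero variance in ",
         if (sd(x[ok]) == 0) rate_field else "divergence")
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
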