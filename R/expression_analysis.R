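#' Average replicates into a gene-by-condition matrix
#'
#' @param tab An `expr_table` from [read_expression_table()] or
#'   [simulate_expression()].
#' @return Numeric matrix, genes x conditions, with the per-condition
#'   arithmetic mean of the replicates.
#' @export
average_replicates <- function(tab) {
  stopifnot(inherits(tab, "expr_table"))
  conds <- unique(tab$conditions)
  out <- vapply(conds, function(cn) {
    rowMeans(tab$data[, tab$conditions == cn, drop = FALSE])
  }, numeric(nrow(tab$data)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(tab$data)))
  colnames(out) <- conds
  out
}

#' Z-score each row of an expression matrix
#'
#' Per row (gene): subtract the mean, divide by the sample (n - 1) standard
#' deviation, so every gene's profile over conditions has mean 0 and sample
#' variance 1. This keeps relative up/down regulation and discards scale.
#'
#' @param m Numeric matrix, genes x conditions; no row may be constant.
#' @return Matrix of the same shape with z-scored rows.
#' @export
zscore_rows <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop("constant expression row(s): ",
         paste(rownames(m)[sds == 0] %||% which(sds == 0), collapse = ", "))
  }
  sweep(sweep(m, 1, rowMeans(m)), 1, sds, "/")
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`; 1 when the profiles point in the same direction,
#' 0 when orthogonal.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return Number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector")
  min(max(sum(u * v) / (nu * nv), -1), 1)
}

#' Pearson correlation and its log-ratio transform
#'
#' Computes Pearson's R between two expression profiles and the transform
#' `ln((1 + R) / (1 - R))` used to put R on a scale suitable for linear
#' regression. When |R| = 1 the transform is flagged infinite rather than
#' clipped.
#'
#' @param u,v Non-constant numeric vectors of equal length >= 3.
#' @return A list with `r`, `transformed_r` (`Inf`/`-Inf` when |R| = 1), and
#'   `infinite` (logical flag).
#' @export
pearson_and_transform <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 3)
  if (sd(u) == 0 || sd(v) == 0) stop("Pearson R undefined for a constant vector")
  r <- cor(u, v)
  if (abs(r) >= 1 - 1e-15) {
    list(r = sign(r), transformed_r = sign(r) * Inf, infinite = TRUE)
  } else {
    list(r = r, transformed_r = log((1 + r) / (1 - r)), infinite = FALSE)
  }
}

#' Cosine/divergence quadrant of a gene pair
#'
#' Partitions pairs by expression similarity and protein divergence:
#' A = cosine > 0.5 and divergence <= 50; B = cosine > 0.5 and
#' divergence > 50; C = cosine <= 0.5 and divergence <= 50; D = cosine <=
#' 0.5 and divergence > 50.
#'
#' @param cosine Cosine similarity in \[-1, 1\] (vectorised).
#' @param divergence_pct Percent amino-acid divergence in \[0, 100\].
#' @param cosine_threshold Cosine above this is "high" (default 0.5).
#' @param divergence_threshold Divergence at or below this is "low"
#'   (default 50).
#' @return Factor with levels `A`, `B`, `C`, `D`.
#' @examples
#' classify_quadrant(c(0.9805, 0.45), c(13, 62))
#' @export
classify_quadrant <- function(cosine, divergence_pct,
                              cosine_threshold = 0.5,
                              divergence_threshold = 50) {
  if (any(is.na(cosine)) || any(abs(cosine) > 1)) {
    stop("cosine must lie in [-1, 1]")
  }
  if (any(is.na(divergence_pct)) ||
      any(divergence_pct < 0 | divergence_pct > 100)) {
    stop("divergence must lie in [0, 100]")
  }
  high_cos <- cosine > cosine_threshold
  low_div <- divergence_pct <= divergence_threshold
  labels <- ifelse(high_cos & low_div, "A",
            ifelse(high_cos & !low_div, "B",
            ifelse(!high_cos & low_div, "C", "D")))
  factor(labels, levels = c("A", "B", "C", "D"))
}

#' Best-cosine gene matches between two profile sets
#'
#' For each profile in `setA`, finds the maximum cosine similarity over all
#' profiles in `setB` (the mirror of a BLAST-style best-hit search), and
#' summarises the best cosines by mean and sample sd.
#'
#' @param setA,setB Numeric matrices with one profile per row (gene ids as
#'   row names).
#' @return A list with `best` (data frame: `gene`, `match`, `cosine`),
#'   `mean`, and `sd` (`NA` when `setA` has one row).
#' @export
gene_best_match <- function(setA, setB) {
  stopifnot(is.matrix(setA), is.matrix(setB), nrow(setA) > 0, nrow(setB) > 0)
  normA <- setA / sqrt(rowSums(setA^2))
  normB <- setB / sqrt(rowSums(setB^2))
  sim <- normA %*% t(normB)
  best_j <- apply(sim, 1, which.max)  # ties: lowest index
  best <- data.frame(gene = rownames(setA) %||% seq_len(nrow(setA)),
                     match = (rownames(setB) %||% seq_len(nrow(setB)))[best_j],
                     cosine = sim[cbind(seq_len(nrow(sim)), best_j)],
                     stringsAsFactors = FALSE)
  list(best = best, mean = mean(best$cosine),
       sd = if (nrow(best) > 1) sd(best$cosine) else NA_real_)
}

#' Linear regression of an expression measure on a structural constraint
#'
#' Ordinary least squares of `y_field` on `x_field` over the complete
#' records, with Pearson's R and its two-sided p-value (t-distribution,
#' n - 2 df). `expression_divergence` is defined as 1 - cosine. Records with
#' an infinite transformed R are dropped with a warning.
#'
#' @param records Data frame holding the chosen columns (e.g. the per-pair
#'   stats joined with Ka/Ks results).
#' @param x_field One of `"ka"`, `"ks"`, `"omega"`.
#' @param y_field One of `"transformed_r"`, `"expression_divergence"`.
#' @return A list with `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
regress_expression_vs_constraint <- function(records,
                                             x_field = c("ka", "ks", "omega"),
                                             y_field = c("transformed_r",
                                                         "expression_divergence")) {
  x_field <- match.arg(x_field)
  y_field <- match.arg(y_field)
  x <- records[[x_field]]
  y <- if (y_field == "expression_divergence" &&
           !"expression_divergence" %in% names(records)) {
    1 - records$cosine
  } else {
    records[[y_field]]
  }
  inf <- !is.na(y) & is.infinite(y)
  if (any(inf)) {
    warning(sum(inf), " record(s) with |R| = 1 dropped from regression")
    y[inf] <- NA
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete records")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    stop("regression degenerate: zero variance in ",
         if (sd(x[ok]) == 0) x_field else y_field)
  }
  fit <- lm(y[ok] ~ x[ok])
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Per-pair expression statistics
#'
#' Averages replicates, z-scores each gene over the conditions, and computes
#' for every pair in the table with both genes present: cosine similarity,
#' Pearson R and its transform, and (when a `divergence` column is present)
#' the cosine/divergence quadrant. Pairs with either gene absent from the
#' expression table are dropped with a warning.
#'
#' @param tab An `expr_table`.
#' @param pairs A `pair_table`.
#' @return Data frame: `gene1`, `gene2`, `class`, `cosine`, `pearson_r`,
#'   `transformed_r`, and `quadrant` if divergence was available.
#' @export
pair_expression_stats <- function(tab, pairs) {
  avg <- average_replicates(tab)
  z <- zscore_rows(avg)
  present <- pairs$gene1 %in% rownames(z) & pairs$gene2 %in% rownames(z)
  if (!all(present)) {
    warning(sum(!present), " pair(s) dropped: gene(s) absent from the ",
            "expression table")
  }
  p <- pairs[present, , drop = FALSE]
  stats <- lapply(seq_len(nrow(p)), function(i) {
    u <- z[p$gene1[i], ]
    v <- z[p$gene2[i], ]
    pr <- pearson_and_transform(u, v)
    data.frame(gene1 = p$gene1[i], gene2 = p$gene2[i], class = p$class[i],
               cosine = cosine_similarity(u, v), pearson_r = pr$r,
               transformed_r = pr$transformed_r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  if ("divergence" %in% names(p) && !all(is.na(p$divergence))) {
    out$quadrant <- classify_quadrant(out$cosine, p$divergence)
  }
  out
}
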