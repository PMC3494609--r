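#' Tamura-Nei (1993) model parameters
#'
#' Container for the TN93 nucleotide model: base frequencies, the purine
#' (A<->G) and pyrimidine (C<->T) transition/transversion rate ratios, and an
#' optional gamma shape for among-site rate variation.
#'
#' @param pi Numeric length-4 vector of frequencies, order A, C, G, T.
#' @param kappa_R Purine transition/transversion rate ratio (> 0).
#' @param kappa_Y Pyrimidine transition/transversion rate ratio (> 0).
#' @param gamma_shape Positive gamma shape, or `NULL` for uniform rates.
#' @return An object of class `tn93_params`.
#' @export
tn93_params <- function(pi = rep(0.25, 4), kappa_R = 1, kappa_Y = 1,
                        gamma_shape = NULL) {
  stopifnot(length(pi) == 4, all(pi > 0), abs(sum(pi) - 1) < 1e-9,
            kappa_R > 0, kappa_Y > 0)
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0)
  structure(list(pi = setNames(as.numeric(pi), BASES),
                 kappa_R = as.numeric(kappa_R),
                 kappa_Y = as.numeric(kappa_Y),
                 gamma_shape = gamma_shape),
            class = "tn93_params")
}

# Multiple-hit correction term: -log(x) under uniform rates, or the gamma
# analogue alpha * (x^(-1/alpha) - 1). NA signals saturation (x <= 0).
mh_correct <- function(x, gamma_shape = NULL) {
  if (is.na(x) || x <= 0) return(NA_real_)
  if (is.null(gamma_shape)) -log(x) else gamma_shape * (x^(-1 / gamma_shape) - 1)
}

#' TN93 multiple-hit corrected distance
#'
#' Corrects observed proportions of A<->G transitional (`p1`), C<->T
#' transitional (`p2`) and transversional (`q`) differences into an expected
#' number of substitutions per site under the Tamura-Nei (1993) model. When
#' `params$gamma_shape` is set, each logarithmic correction is replaced by
#' its gamma-rates analogue `alpha * (x^(-1/alpha) - 1)`.
#'
#' @param p1 Proportion of sites with an A<->G difference.
#' @param p2 Proportion of sites with a C<->T difference.
#' @param q Proportion of sites with a transversional difference.
#' @param params A [tn93_params()] object.
#' @return Distance in substitutions per site, or `NA_real_` when any
#'   correction argument is <= 0 (saturation).
#' @export
tn93_distance <- function(p1, p2, q, params) {
  stopifnot(inherits(params, "tn93_params"),
            p1 >= 0, p2 >= 0, q >= 0, p1 + p2 + q <= 1 + 1e-12)
  pi <- params$pi
  piR <- pi[["A"]] + pi[["G"]]
  piY <- pi[["C"]] + pi[["T"]]
  g <- params$gamma_shape
  a1 <- mh_correct(1 - piR * p1 / (2 * pi[["A"]] * pi[["G"]]) - q / (2 * piR), g)
  a2 <- mh_correct(1 - piY * p2 / (2 * pi[["C"]] * pi[["T"]]) - q / (2 * piY), g)
  b <- mh_correct(1 - q / (2 * piR * piY), g)
  if (anyNA(c(a1, a2, b))) return(NA_real_)
  k1 <- 2 * pi[["A"]] * pi[["G"]] / piR
  k2 <- 2 * pi[["C"]] * pi[["T"]] / piY
  k3 <- 2 * (piR * piY -
               pi[["A"]] * pi[["G"]] * piY / piR -
               pi[["C"]] * pi[["T"]] * piR / piY)
  d <- k1 * a1 + k2 * a2 + k3 * b
  max(d, 0)
}

#' Estimate TN93 parameters from a codon alignment
#'
#' Base frequencies are the pooled observed frequencies over both sequences.
#' `kappa_R` and `kappa_Y` come from the TN93-corrected transitional and
#' transversional distances over all aligned nucleotide positions:
#' `kappa_R = (a1 - piY * b) / (piR * b)` and symmetrically for `kappa_Y`,
#' where `a1`, `a2`, `b` are the corrected A<->G, C<->T and transversion
#' terms. Floors (1e-4) and a no-difference/saturation fallback of 1 keep
#' all outputs positive and finite.
#'
#' @param ca A codon alignment from [build_codon_alignment()].
#' @param gamma_shape Optional gamma shape carried into the parameters and
#'   used for the corrections.
#' @return A [tn93_params()] object.
#' @export
estimate_tn93_params <- function(ca, gamma_shape = NULL) {
  stopifnot(inherits(ca, "codon_alignment"))
  s1 <- strsplit(paste(ca$codons1, collapse = ""), "")[[1]]
  s2 <- strsplit(paste(ca$codons2, collapse = ""), "")[[1]]
  counts <- table(factor(c(s1, s2), levels = BASES))
  pi <- pmax(as.numeric(counts) / sum(counts), 1e-4)
  pi <- pi / sum(pi)
  names(pi) <- BASES
  n <- length(s1)
  diff <- s1 != s2
  p1 <- sum(diff & is_transition_AG(s1, s2)) / n
  p2 <- sum(diff & is_transition_CT(s1, s2)) / n
  q <- sum(diff & !is_transition_AG(s1, s2) & !is_transition_CT(s1, s2)) / n
  piR <- pi[["A"]] + pi[["G"]]
  piY <- pi[["C"]] + pi[["T"]]
  if (p1 + p2 + q == 0) {  # identical sequences: no information, fall back
    return(tn93_params(pi = pi, kappa_R = 1, kappa_Y = 1,
                       gamma_shape = gamma_shape))
  }
  # transitions observed but no transversions would make b = 0 and the
  # ratios undefined; a half-count pseudo-transversion keeps them finite
  if (q == 0) q <- 0.5 / n
  a1 <- mh_correct(1 - piR * p1 / (2 * pi[["A"]] * pi[["G"]]) - q / (2 * piR),
                   gamma_shape)
  a2 <- mh_correct(1 - piY * p2 / (2 * pi[["C"]] * pi[["T"]]) - q / (2 * piY),
                   gamma_shape)
  b <- mh_correct(1 - q / (2 * piR * piY), gamma_shape)
  kR <- if (is.na(a1) || is.na(b) || b <= 0) 1 else (a1 - piY * b) / (piR * b)
  kY <- if (is.na(a2) || is.na(b) || b <= 0) 1 else (a2 - piR * b) / (piY * b)
  tn93_params(pi = pi, kappa_R = max(kR, 1e-4), kappa_Y = max(kY, 1e-4),
              gamma_shape = gamma_shape)
}

#' @export
print.tn93_params <- function(x, ...) {
  cat("TN93 parameters\n  pi:", paste(sprintf("%s=%.4f", BASES, x$pi),
                                      collapse = " "),
      "\n  kappa_R:", format(x$kappa_R), " kappa_Y:", format(x$kappa_Y),
      "\n  gamma shape:", if (is.null(x$gamma_shape)) "none (uniform rates)"
      else format(x$gamma_shape), "\n")
  invisible(x)
}
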