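#' Translate an in-frame coding sequence
#'
#' Uses the standard genetic code (translation table 1). A single terminal
#' stop codon is stripped; an internal stop is an error (pseudogene or frame
#' problem) reported with its codon index.
#'
#' @param seq Nucleotide string, length a positive multiple of 3, `ACGT` only.
#' @param id Identifier used in error messages.
#' @return Protein string (one-letter amino-acid codes, no stop).
#' @examples
#' translate_codons("ATGGCC")  # "MA"
#' translate_codons("ATGTAA")  # "M", terminal stop stripped
#' @export
translate_codons <- function(seq, id = "<sequence>") {
  validate_coding_sequence(seq, id)
  codons <- split_codons(seq)
  aa <- unname(genetic_code()[codons])
  n <- length(aa)
  internal_stop <- which(aa[-n] == "*")
  if (length(internal_stop)) {
    stop("sequence '", id, "' has an internal stop at codon ",
         internal_stop[1])
  }
  if (aa[n] == "*") aa <- aa[-n]
  if (!length(aa)) {
    stop("sequence '", id, "' encodes only a stop codon")
  }
  paste(aa, collapse = "")
}

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

split_codons <- function(seq) {
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

#' Globally align two protein sequences
#'
#' End-to-end (Needleman-Wunsch) optimal alignment under BLOSUM62 with
#' affine gap penalties (open 10, extend 1, half-bit units), computed with
#' \pkg{Biostrings}. Deterministic: one optimal traceback is returned.
#'
#' @param p1,p2 Non-empty protein strings.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A list of class `protein_alignment` with elements `aligned1`,
#'   `aligned2` (equal-length strings with `-` gaps) and `score`.
#' @export
align_protein_pair <- function(p1, p2, gap_open = 10, gap_extend = 1) {
  if (!nzchar(p1) || !nzchar(p2)) stop("cannot align an empty protein")
  mat <- blosum62()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(aligned1 = as.character(Biostrings::pattern(al)),
                 aligned2 = as.character(Biostrings::subject(al)),
                 score = Biostrings::score(al)),
            class = "protein_alignment")
}

#' Percent amino-acid divergence of an alignment
#'
#' 100 x (mismatched columns) / (columns where both residues are present);
#' columns containing a gap are excluded.
#'
#' @param aln A `protein_alignment`.
#' @return Percentage in \[0, 100\].
#' @export
amino_acid_divergence <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  a <- strsplit(aln$aligned1, "")[[1]]
  b <- strsplit(aln$aligned2, "")[[1]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("divergence undefined: no ungapped columns")
  100 * mean(a[keep] != b[keep])
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Maps each ungapped alignment column back to the underlying codon pair;
#' columns with a gap in either row are dropped, codon order is preserved.
#' The translations of `dna1`/`dna2` must equal the aligned proteins with
#' gaps removed.
#'
#' @param aln A `protein_alignment`.
#' @param dna1,dna2 The original coding sequences.
#' @return A list of class `codon_alignment` with equal-length character
#'   vectors `codons1`, `codons2` of 3-letter codons.
#' @export
build_codon_alignment <- function(aln, dna1, dna2) {
  stopifnot(inherits(aln, "protein_alignment"))
  a1 <- strsplit(aln$aligned1, "")[[1]]
  a2 <- strsplit(aln$aligned2, "")[[1]]
  p1 <- translate_codons(dna1, "dna1")
  p2 <- translate_codons(dna2, "dna2")
  check_backtranslation(a1, p1, "first")
  check_backtranslation(a2, p2, "second")
  cod1 <- split_codons(dna1)[seq_len(nchar(p1))]
  cod2 <- split_codons(dna2)[seq_len(nchar(p2))]
  i1 <- cumsum(a1 != "-")
  i2 <- cumsum(a2 != "-")
  keep <- a1 != "-" & a2 != "-"
  structure(list(codons1 = cod1[i1[keep]], codons2 = cod2[i2[keep]]),
            class = "codon_alignment")
}

check_backtranslation <- function(aligned_chars, protein, which_seq) {
  ungapped <- paste(aligned_chars[aligned_chars != "-"], collapse = "")
  if (ungapped != protein) {
    mis <- which(strsplit(ungapped, "")[[1]] !=
                   strsplit(protein, "")[[1]])[1]
    stop("protein/DNA mismatch for the ", which_seq,
         " sequence at residue ", mis %||% nchar(protein))
  }
  invisible(TRUE)
}

# ---- site counting -------------------------------------------------------

# Relative TN93 mutation-rate weight for base x -> y (NULL params: NG86,
# all single-nucleotide changes equally weighted).
mutation_weight <- function(x, y, params = NULL) {
  if (is.null(params)) return(1)
  w <- params$pi[[y]]
  if (is_transition_AG(x, y)) w * params$kappa_R
  else if (is_transition_CT(x, y)) w * params$kappa_Y
  else w
}

# Synonymous site count (0..3) of one sense codon: per position, the rate
# fraction of non-stop single-nucleotide changes that are synonymous.
# Changes to stop codons are excluded from numerator and denominator, so
# each position contributes exactly one site and S + N = 3 per codon.
codon_syn_sites <- function(codon, params = NULL) {
  code <- genetic_code()
  aa0 <- code[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn_w <- tot_w <- 0
    for (y in setdiff(BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- y
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] == "*") next
      w <- mutation_weight(chars[pos], y, params)
      tot_w <- tot_w + w
      if (code[[mutc]] == aa0) syn_w <- syn_w + w
    }
    if (tot_w > 0) s <- s + syn_w / tot_w
  }
  s
}

# Average synonymous sites over both sequences of a codon alignment.
count_sites <- function(ca, params = NULL) {
  codons <- c(ca$codons1, ca$codons2)
  uniq <- unique(codons)
  per <- vapply(uniq, codon_syn_sites, numeric(1), params = params)
  s <- sum(per[match(codons, uniq)]) / 2
  list(S = s, N = 3 * length(ca$codons1) - s)
}

# ---- difference counting (pathway averaging) ----------------------------

.path_cache <- new.env(parent = emptyenv())

PERMS <- list(list(1L),
              list(c(1L, 2L), c(2L, 1L)),
              list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                   c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

DIFF_CLASSES <- c("syn_AG", "syn_CT", "syn_TV", "nonsyn_AG", "nonsyn_CT",
                  "nonsyn_TV")

# Pathway-averaged classification of the differences between two sense
# codons into synonymous/nonsynonymous x (A<->G transition, C<->T
# transition, transversion). All minimal substitution pathways are
# enumerated; pathways passing through a stop codon are excluded (when every
# pathway is blocked, all are used). Each surviving pathway gets equal
# weight. Result is cached: it depends only on the codon pair.
classify_codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(setNames(numeric(6), DIFF_CLASSES))
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .path_cache[[key]]
  if (!is.null(hit)) return(hit)
  code <- genetic_code()
  x <- strsplit(c1, "")[[1]]
  y <- strsplit(c2, "")[[1]]
  dpos <- which(x != y)
  paths <- lapply(PERMS[[length(dpos)]], function(ord) dpos[ord])
  tally <- function(order_positions) {
    cur <- x
    counts <- setNames(numeric(6), DIFF_CLASSES)
    for (pos in order_positions) {
      nxt <- cur
      nxt[pos] <- y[pos]
      ccur <- paste(cur, collapse = "")
      cnxt <- paste(nxt, collapse = "")
      if (code[[cnxt]] == "*") return(NULL)  # blocked pathway
      syn <- code[[ccur]] == code[[cnxt]]
      type <- if (is_transition_AG(cur[pos], y[pos])) "AG"
              else if (is_transition_CT(cur[pos], y[pos])) "CT"
              else "TV"
      cls <- paste0(if (syn) "syn_" else "nonsyn_", type)
      counts[cls] <- counts[cls] + 1
      cur <- nxt
    }
    counts
  }
  tallies <- lapply(paths, tally)
  ok <- !vapply(tallies, is.null, logical(1))
  if (!any(ok)) {  # all pathways hit a stop: fall back to counting through
    tallies <- lapply(paths, function(p) {
      counts <- setNames(numeric(6), DIFF_CLASSES)
      cur <- x
      for (pos in p) {
        nxt <- cur; nxt[pos] <- y[pos]
        syn <- code[[paste(cur, collapse = "")]] ==
          code[[paste(nxt, collapse = "")]]
        type <- if (is_transition_AG(cur[pos], y[pos])) "AG"
                else if (is_transition_CT(cur[pos], y[pos])) "CT"
                else "TV"
        cls <- paste0(if (syn) "syn_" else "nonsyn_", type)
        counts[cls] <- counts[cls] + 1
        cur <- nxt
      }
      counts
    })
    ok <- rep(TRUE, length(tallies))
  }
  avg <- Reduce(`+`, tallies[ok]) / sum(ok)
  .path_cache[[key]] <- avg
  avg
}

count_diffs <- function(ca) {
  total <- setNames(numeric(6), DIFF_CLASSES)
  differing <- which(ca$codons1 != ca$codons2)
  for (i in differing) {
    total <- total + classify_codon_diffs(ca$codons1[i], ca$codons2[i])
  }
  total
}

# ---- estimators ----------------------------------------------------------

new_kaks_estimate <- function(S, N, Sd, Nd, ka, ks, method, params = NULL) {
  saturated <- is.na(ka) || is.na(ks)
  omega <- if (saturated || ks <= 0) NA_real_ else ka / ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd,
                 ka = ka, ks = ks, omega = omega,
                 method = method, saturated = saturated, params = params),
            class = "kaks_estimate")
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: Ka=%s Ks=%s omega=%s%s\n", x$method,
              format(x$ka), format(x$ks),
              if (is.na(x$omega)) "undefined" else format(x$omega),
              if (x$saturated) " [saturated]" else ""))
  cat(sprintf("  S=%.2f N=%.2f Sd=%.3f Nd=%.3f\n", x$S, x$N, x$Sd, x$Nd))
  invisible(x)
}

jc_correct <- function(p) {
  x <- 1 - 4 * p / 3
  if (x <= 0) NA_real_ else max(-0.75 * log(x), 0)
}

#' Nei-Gojobori (1986) Ka/Ks estimate
#'
#' Unweighted site counting (each codon position's synonymous fraction over
#' its non-stop single-nucleotide changes), pathway-averaged difference
#' counting, and Jukes-Cantor correction of pN and pS. Serves as the
#' unbiased-limit baseline for the TN93-weighted estimator.
#'
#' @param ca A `codon_alignment` with at least 2 codon columns.
#' @return A `kaks_estimate` (fields `S`, `N`, `Sd`, `Nd`, `ka`, `ks`,
#'   `omega`, `method`, `saturated`). `ka`/`ks` are `NA` with
#'   `saturated = TRUE` when `pN` or `pS` >= 3/4; `omega` is `NA`
#'   ("undefined") when `ks` is 0.
#' @export
ng86_kaks <- function(ca) {
  stopifnot(inherits(ca, "codon_alignment"))
  if (length(ca$codons1) < 2) stop("need at least 2 codon columns")
  sites <- count_sites(ca, params = NULL)
  d <- count_diffs(ca)
  Sd <- sum(d[c("syn_AG", "syn_CT", "syn_TV")])
  Nd <- sum(d[c("nonsyn_AG", "nonsyn_CT", "nonsyn_TV")])
  ks <- jc_correct(Sd / sites$S)
  ka <- jc_correct(Nd / sites$N)
  new_kaks_estimate(sites$S, sites$N, Sd, Nd, ka, ks, "NG86")
}

#' Modified Yang-Nielsen Ka/Ks estimate under the Tamura-Nei model
#'
#' Three TN93-weighted steps: (1) estimate base frequencies and the two
#' transition/transversion ratios from the alignment; (2) count synonymous
#' and nonsynonymous sites with each codon position's synonymous fraction
#' weighted by the TN93 relative rates; (3) split the pathway-averaged
#' differences into A<->G / C<->T transitional and transversional
#' proportions at synonymous and nonsynonymous sites, and correct each class
#' with [tn93_distance()] to obtain Ks and Ka.
#'
#' @param ca A `codon_alignment` with at least 2 codon columns.
#' @param gamma_shape Optional gamma shape; when set, every multiple-hit
#'   logarithmic correction is replaced by its gamma-rates analogue and the
#'   method tag becomes `gMYN`.
#' @param params Optional pre-estimated [tn93_params()]; by default they are
#'   estimated from `ca`.
#' @return A `kaks_estimate`; see [ng86_kaks()] for the saturation and
#'   undefined-omega conventions.
#' @export
myn_kaks <- function(ca, gamma_shape = NULL, params = NULL) {
  stopifnot(inherits(ca, "codon_alignment"))
  if (length(ca$codons1) < 2) stop("need at least 2 codon columns")
  if (is.null(params)) params <- estimate_tn93_params(ca, gamma_shape)
  sites <- count_sites(ca, params = params)
  d <- count_diffs(ca)
  Sd <- sum(d[c("syn_AG", "syn_CT", "syn_TV")])
  Nd <- sum(d[c("nonsyn_AG", "nonsyn_CT", "nonsyn_TV")])
  ks <- if (Sd > sites$S) NA_real_ else
    tn93_distance(d[["syn_AG"]] / sites$S, d[["syn_CT"]] / sites$S,
                  d[["syn_TV"]] / sites$S, params)
  ka <- if (Nd > sites$N) NA_real_ else
    tn93_distance(d[["nonsyn_AG"]] / sites$N, d[["nonsyn_CT"]] / sites$N,
                  d[["nonsyn_TV"]] / sites$N, params)
  method <- if (is.null(gamma_shape)) "MYN" else "gMYN"
  new_kaks_estimate(sites$S, sites$N, Sd, Nd, ka, ks, method, params)
}

#' Gamma-rates modified Yang-Nielsen estimate
#'
#' [myn_kaks()] with every multiple-hit log correction replaced by the gamma
#' analogue `alpha * (x^(-1/alpha) - 1)`, modelling gamma-distributed rate
#' variation across sites with shape `gamma_shape`. As `gamma_shape` grows
#' the estimate converges to the plain MYN estimate.
#'
#' @inheritParams myn_kaks
#' @param gamma_shape Positive gamma shape (default 1).
#' @return A `kaks_estimate` with method tag `gMYN`.
#' @export
gamma_myn_kaks <- function(ca, gamma_shape = 1) {
  stopifnot(gamma_shape > 0)
  myn_kaks(ca, gamma_shape = gamma_shape)
}

#' Full Ka/Ks pipeline for one pair of coding sequences
#'
#' Translate both sequences, align the proteins globally, back-translate to
#' a gap-free codon alignment, and estimate Ka, Ks and omega with the chosen
#' method. Also returns the percent amino-acid divergence of the protein
#' alignment and the number of aligned codon columns.
#'
#' @param dna1,dna2 In-frame coding sequences.
#' @param method One of `"gMYN"`, `"MYN"`, `"NG86"`.
#' @param gamma_shape Gamma shape used when `method = "gMYN"`.
#' @return A list with `estimate` (a `kaks_estimate`), `divergence`
#'   (percent), and `n_codons` (aligned codon columns).
#' @export
pair_kaks_pipeline <- function(dna1, dna2, method = c("gMYN", "MYN", "NG86"),
                               gamma_shape = 1) {
  method <- match.arg(method)
  p1 <- translate_codons(dna1, "dna1")
  p2 <- translate_codons(dna2, "dna2")
  aln <- align_protein_pair(p1, p2)
  ca <- build_codon_alignment(aln, dna1, dna2)
  est <- switch(method,
                NG86 = ng86_kaks(ca),
                MYN = myn_kaks(ca),
                gMYN = gamma_myn_kaks(ca, gamma_shape))
  list(estimate = est, divergence = amino_acid_divergence(aln),
       n_codons = length(ca$codons1))
}

#' Ka/Ks estimates for every pair in a gene-pair table
#'
#' @param seqs Named character vector of coding sequences (see
#'   [read_fasta()]).
#' @param pairs A `pair_table` (see [read_pair_table()]).
#' @param method,gamma_shape Passed to [pair_kaks_pipeline()].
#' @return A data frame with one row per pair: `gene1`, `gene2`, `length`
#'   (aligned codon columns), `divergence`, `ka`, `ks`, `omega`, `method`,
#'   `saturated`.
#' @export
kaks_table <- function(seqs, pairs, method = "gMYN", gamma_shape = 1) {
  missing_genes <- setdiff(unique(c(pairs$gene1, pairs$gene2)), names(seqs))
  if (length(missing_genes)) {
    stop("sequences missing for genes: ",
         paste(missing_genes, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- pair_kaks_pipeline(seqs[[pairs$gene1[i]]], seqs[[pairs$gene2[i]]],
                              method = method, gamma_shape = gamma_shape)
    e <- res$estimate
    data.frame(gene1 = pairs$gene1[i], gene2 = pairs$gene2[i],
               length = res$n_codons, divergence = res$divergence,
               ka = e$ka, ks = e$ks, omega = e$omega, method = e$method,
               saturated = e$saturated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
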