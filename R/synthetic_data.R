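#' Simulate a pair of coding sequences with known Ka/Ks
#'
#' Draws an ancestral sequence of sense codons from products of the base
#' frequencies (stop codons rejected) and evolves two independent lineages
#' by a continuous-time codon process with single-nucleotide steps: relative
#' rates follow TN93 (`kappa_R` for A<->G, `kappa_Y` for C<->T, 1 for
#' transversions, times the target base frequency), nonsynonymous steps are
#' multiplied by `omega`, and steps into stop codons are forbidden. Lineage
#' durations are calibrated from the generator's own rate table so that the
#' expected pairwise synonymous substitutions per synonymous site equal
#' `ks`; since nonsynonymous steps carry the factor `omega` against the same
#' site weighting, the expected Ka/Ks ratio is `omega` by construction.
#'
#' @param n_codons Number of codons (>= 10).
#' @param ks Target pairwise synonymous substitutions per synonymous site.
#' @param omega Target Ka/Ks (>= 0; 0 forbids nonsynonymous change).
#' @param kappa_R,kappa_Y Transition/transversion rate ratios (> 0).
#' @param pi Base frequencies (A, C, G, T), summing to 1.
#' @param seed Integer seed; the simulation is reproducible from it.
#' @param gamma_site_shape Optional gamma shape: each codon gets a rate
#'   multiplier drawn from Gamma(shape, shape) (mean 1), shared by both
#'   lineages, emulating among-site rate variation.
#' @return A list with `seq1`, `seq2` (nucleotide strings), and `truth`
#'   (targets, realised synonymous/nonsynonymous event counts, lineage time,
#'   synonymous site total of the ancestor).
#' @export
simulate_codon_pair <- function(n_codons, ks, omega, kappa_R = 4,
                                kappa_Y = 4, pi = rep(0.25, 4), seed = 1,
                                gamma_site_shape = NULL) {
  stopifnot(n_codons >= 10, ks >= 0, omega >= 0)
  params <- tn93_params(pi = pi, kappa_R = kappa_R, kappa_Y = kappa_Y)
  if (!is.null(gamma_site_shape)) stopifnot(gamma_site_shape > 0)
  set.seed(seed)
  moves <- codon_move_table(params, omega)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  # ancestor: product-of-frequencies codons, stops rejected
  codon_prob <- vapply(sense, function(cd) {
    prod(params$pi[strsplit(cd, "")[[1]]])
  }, numeric(1))
  anc <- sample(sense, n_codons, replace = TRUE,
                prob = codon_prob / sum(codon_prob))
  # calibration: time per lineage so expected pairwise syn subs/site = ks
  syn_sites <- vapply(anc, function(cd) moves[[cd]]$syn_sites, numeric(1))
  syn_rate <- vapply(anc, function(cd) moves[[cd]]$syn_rate, numeric(1))
  if (sum(syn_rate) <= 0) stop("no synonymous change possible; cannot calibrate")
  t_lineage <- (ks / 2) * sum(syn_sites) / sum(syn_rate)
  rate_mult <- if (is.null(gamma_site_shape)) rep(1, n_codons) else
    rgamma(n_codons, shape = gamma_site_shape, rate = gamma_site_shape)
  evolve <- function() {
    out <- anc
    events <- c(syn = 0, nonsyn = 0)
    for (i in seq_len(n_codons)) {
      state <- out[i]
      t <- 0
      repeat {
        mv <- moves[[state]]
        lambda <- rate_mult[i] * mv$total
        if (lambda <= 0) break
        t <- t + rexp(1, lambda)
        if (t > t_lineage) break
        j <- sample.int(length(mv$rates), 1, prob = mv$rates)
        events[if (mv$syn[j]) "syn" else "nonsyn"] <-
          events[if (mv$syn[j]) "syn" else "nonsyn"] + 1
        state <- mv$targets[j]
      }
      out[i] <- state
    }
    list(seq = paste(out, collapse = ""), events = events)
  }
  l1 <- evolve()
  l2 <- evolve()
  list(seq1 = l1$seq, seq2 = l2$seq,
       truth = list(ks_target = ks, omega_target = omega,
                    kappa_R = kappa_R, kappa_Y = kappa_Y, pi = params$pi,
                    gamma_site_shape = gamma_site_shape,
                    t_lineage = t_lineage,
                    syn_events = unname(l1$events["syn"] + l2$events["syn"]),
                    nonsyn_events = unname(l1$events["nonsyn"] +
                                             l2$events["nonsyn"]),
                    syn_sites = sum(syn_sites), seed = seed))
}

# Per sense codon: reachable single-nucleotide neighbours with their rates
# (TN93 weight x omega for nonsynonymous), the synonymous event rate, and
# the (omega-free) synonymous site count used for calibration.
codon_move_table <- function(params, omega) {
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  tbl <- lapply(sense, function(cd) {
    chars <- strsplit(cd, "")[[1]]
    targets <- character(0); rates <- numeric(0); syn <- logical(0)
    for (pos in 1:3) {
      for (y in setdiff(BASES, chars[pos])) {
        mut <- chars; mut[pos] <- y
        mutc <- paste(mut, collapse = "")
        if (code[[mutc]] == "*") next
        is_syn <- code[[mutc]] == code[[cd]]
        w <- mutation_weight(chars[pos], y, params)
        targets <- c(targets, mutc)
        rates <- c(rates, if (is_syn) w else w * omega)
        syn <- c(syn, is_syn)
      }
    }
    list(targets = targets, rates = rates, syn = syn, total = sum(rates),
         syn_rate = sum(rates[syn]),
         syn_sites = codon_syn_sites(cd, params))
  })
  names(tbl) <- sense
  tbl
}

# Default growth-condition labels, mirroring a 7-condition microarray design
# (aerobic, semiaerobic, anaerobic dark/DMSO, three light intensities, dark).
default_conditions <- function(n) {
  if (n == 7) {
    c("aerobic", "semiaerobic", "anaerobic_DMSO", "photo3W", "photo10W",
      "photo100W", "dark_DMSO")
  } else {
    paste0("cond", seq_len(n))
  }
}

#' Simulate a replicated expression matrix with latent cluster structure
#'
#' Builds `n_patterns` well-spread unit-norm condition profiles (greedy
#' maximin selection from a random pool), assigns each gene pair to a
#' pattern in round-robin order, sets copy 1 to the pattern and copy 2 to a
#' unit vector at angle `acos(within_pair_cosine)` from it (rotated inside a
#' random plane), and adds homoscedastic Gaussian noise to every
#' condition-replicate measurement.
#'
#' @param n_pairs Number of gene pairs (two genes each).
#' @param n_conditions Number of growth conditions (default 7).
#' @param n_replicates Replicates per condition (default 3).
#' @param n_patterns Number of latent patterns (default 16; must be <=
#'   `n_pairs`).
#' @param within_pair_cosine Target raw cosine between the two copies of a
#'   pair, in \[0, 1\].
#' @param noise_sd Gaussian noise sd added per measurement.
#' @param seed Integer seed.
#' @return A list with `table` (an `expr_table`), `pairs` (a `pair_table`
#'   for the simulated genes, classes split between `in` and `out`), and
#'   `truth` (patterns, per-pair pattern index, realised raw and post-z-score
#'   noiseless cosines).
#' @export
simulate_expression <- function(n_pairs, n_conditions = 7, n_replicates = 3,
                                n_patterns = 16, within_pair_cosine = 0.9,
                                noise_sd = 0.1, seed = 1) {
  stopifnot(n_patterns <= n_pairs, n_conditions >= 2, n_replicates >= 1,
            noise_sd >= 0)
  if (within_pair_cosine < 0 || within_pair_cosine > 1) {
    stop("within_pair_cosine must lie in [0, 1]")
  }
  set.seed(seed)
  patterns <- spread_unit_vectors(n_patterns, n_conditions)
  cval <- within_pair_cosine
  pattern_of_pair <- ((seq_len(n_pairs) - 1L) %% n_patterns) + 1L
  gene_ids <- as.vector(rbind(sprintf("pair%03d_a", seq_len(n_pairs)),
                              sprintf("pair%03d_b", seq_len(n_pairs))))
  profiles <- matrix(0, 2 * n_pairs, n_conditions)
  raw_cos <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    v1 <- patterns[pattern_of_pair[i], ]
    w <- rnorm(n_conditions)
    w <- w - sum(w * v1) * v1
    while (sqrt(sum(w^2)) < 1e-8) {
      w <- rnorm(n_conditions)
      w <- w - sum(w * v1) * v1
    }
    w <- w / sqrt(sum(w^2))
    v2 <- cval * v1 + sqrt(1 - cval^2) * w
    profiles[2 * i - 1, ] <- v1
    profiles[2 * i, ] <- v2
    raw_cos[i] <- sum(v1 * v2)
  }
  rownames(profiles) <- gene_ids
  conds <- default_conditions(n_conditions)
  data <- matrix(0, 2 * n_pairs, n_conditions * n_replicates,
                 dimnames = list(gene_ids, paste0(
                   rep(conds, each = n_replicates), ".",
                   rep(seq_len(n_replicates), n_conditions))))
  for (j in seq_len(n_conditions)) {
    for (r in seq_len(n_replicates)) {
      data[, (j - 1L) * n_replicates + r] <-
        profiles[, j] + rnorm(2 * n_pairs, sd = noise_sd)
    }
  }
  tab <- structure(list(data = data,
                        conditions = rep(conds, each = n_replicates),
                        n_replicates = as.integer(n_replicates)),
                   class = "expr_table")
  # realised cosines of the noiseless profiles after z-scoring
  z <- zscore_rows(profiles)
  z_cos <- vapply(seq_len(n_pairs), function(i) {
    cosine_similarity(z[2 * i - 1, ], z[2 * i, ])
  }, numeric(1))
  pair_tab <- data.frame(
    gene1 = gene_ids[seq(1, 2 * n_pairs, 2)],
    gene2 = gene_ids[seq(2, 2 * n_pairs, 2)],
    class = rep(c("in", "out"), length.out = n_pairs),
    replicon1 = sample(REPLICON_LEVELS, n_pairs, replace = TRUE),
    replicon2 = sample(REPLICON_LEVELS, n_pairs, replace = TRUE),
    stringsAsFactors = FALSE)
  class(pair_tab) <- c("pair_table", "data.frame")
  list(table = tab, pairs = pair_tab,
       truth = list(patterns = patterns, pattern_of_pair = pattern_of_pair,
                    raw_cosine = raw_cos, zscored_cosine = z_cos,
                    noise_sd = noise_sd, seed = seed))
}

# Greedy maximin selection of n well-spread unit vectors in d dimensions
# from a random pool: deterministic given the RNG state.
spread_unit_vectors <- function(n, d, pool_size = max(1000L, 50L * n)) {
  pool <- matrix(rnorm(pool_size * d), pool_size, d)
  pool <- pool / sqrt(rowSums(pool^2))
  chosen <- 1L
  for (i in seq_len(n - 1L)) {
    sims <- pool %*% t(pool[chosen, , drop = FALSE])
    worst <- apply(sims, 1, max)
    worst[chosen] <- Inf
    chosen <- c(chosen, which.min(worst))
  }
  pool[chosen, , drop = FALSE]
}
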