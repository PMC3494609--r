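test_that("translate_codons follows the standard code and stop rules", {
  expect_identical(translate_codons("ATGGCC"), "MA")
  expect_identical(translate_codons("ATGTAA"), "M")
  expect_error(translate_codons("ATGTAAGCC"), "internal stop at codon 2")
  expect_error(translate_codons("TAA"), "only a stop")
})

test_that("protein alignment is optimal, global, and handles gaps", {
  id <- align_protein_pair("MAV", "MAV")
  expect_identical(id$aligned1, "MAV")
  expect_identical(id$aligned2, "MAV")

  # brute-force oracle: every global alignment of MAV vs MV is one of the
  # three single-gap placements; enumerate their affine BLOSUM62 scores.
  b62 <- local({
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  score_aln <- function(a, b) {
    s <- 0; in_gap <- FALSE
    for (i in seq_len(nchar(a))) {
      ca <- substr(a, i, i); cb <- substr(b, i, i)
      if (ca == "-" || cb == "-") {
        s <- s - (if (in_gap) 1 else 11)
        in_gap <- TRUE
      } else {
        s <- s + b62[ca, cb]; in_gap <- FALSE
      }
    }
    s
  }
  candidates <- list(c("MAV", "-MV"), c("MAV", "M-V"), c("MAV", "MV-"))
  best <- max(vapply(candidates, function(p) score_aln(p[1], p[2]),
                     numeric(1)))
  got <- align_protein_pair("MAV", "MV")
  expect_equal(got$score, best)
  expect_equal(score_aln(got$aligned1, got$aligned2), best)
  expect_error(align_protein_pair("M", ""), "empty")
})

test_that("back-translation maps columns and drops gapped ones", {
  aln <- align_protein_pair("MA", "MA")
  ca <- build_codon_alignment(aln, "ATGGCC", "ATGGCG")
  expect_identical(ca$codons1, c("ATG", "GCC"))
  expect_identical(ca$codons2, c("ATG", "GCG"))

  # gap column dropped: MAV vs MV aligns with one gap
  aln2 <- align_protein_pair("MAV", "MV")
  ca2 <- build_codon_alignment(aln2, "ATGGCCGTT", "ATGGTT")
  expect_length(ca2$codons1, 2)
  expect_length(ca2$codons2, 2)

  bad <- structure(list(aligned1 = "MA", aligned2 = "MA", score = 0),
                   class = "protein_alignment")
  expect_error(build_codon_alignment(bad, "ATGTCC", "ATGGCC"),
               "protein/DNA mismatch")
})

test_that("amino_acid_divergence counts mismatches over ungapped columns", {
  mk <- function(a, b) structure(list(aligned1 = a, aligned2 = b, score = 0),
                                 class = "protein_alignment")
  expect_equal(amino_acid_divergence(mk("MAVL", "MIVL")), 25)
  expect_equal(amino_acid_divergence(mk(strrep("A", 100), strrep("A", 100))), 0)
  expect_equal(amino_acid_divergence(mk("MA-L", "M-VL")), 0)  # gaps excluded
  expect_error(amino_acid_divergence(mk("-A", "A-")), "no ungapped")
})

test_that("tn93_distance matches the JC69 closed form under uniform rates", {
  par <- tn93_params()
  for (p in c(0.01, 0.1, 0.3, 0.5)) {
    expect_equal(tn93_distance(p / 6, p / 6, 2 * p / 3, par),
                 -0.75 * log(1 - 4 * p / 3), tolerance = 1e-9)
  }
  expect_equal(tn93_distance(0, 0, 0, par), 0)
  # transversion saturation: 1 - Q/(2 piR piY) <= 0
  expect_true(is.na(tn93_distance(0, 0, 0.5, par)))
})

test_that("TN93 parameter estimation: fallbacks, monotonicity, recovery", {
  ca <- make_ca("ACGTACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGTACGT")
  par <- estimate_tn93_params(ca)
  expect_equal(unname(par$pi), rep(0.25, 4))
  expect_equal(par$kappa_R, 1)
  expect_equal(par$kappa_Y, 1)

  # A<->G-only differences push kappa_R above kappa_Y
  ca2 <- make_ca("AAAGATAAAGATAAAGATAAAGATAAAGATAAAGAT",
                 "AAGGATAAAGATAAGGATAAAGATAAGGATAAAGAT")
  par2 <- estimate_tn93_params(ca2)
  expect_gt(par2$kappa_R, par2$kappa_Y)

  # simulation recovery at kappa_R = kappa_Y = 4 on 10,000 codons; neutral
  # evolution, since selection suppresses (mostly nonsynonymous)
  # transversions and would bias the ratio upward
  sim <- simulate_codon_pair(10000, ks = 0.4, omega = 1,
                             kappa_R = 4, kappa_Y = 4, seed = 99)
  ca3 <- make_ca(sim$seq1, sim$seq2)
  par3 <- estimate_tn93_params(ca3)
  expect_lt(abs(par3$kappa_R - 4) / 4, 0.15)
  expect_lt(abs(par3$kappa_Y - 4) / 4, 0.15)
})

test_that("NG86 reproduces the hand-computed Gly-Gly example", {
  est <- ng86_kaks(make_ca("GGTGGA", "GGCGGA"))
  expect_equal(est$S, 2)
  expect_equal(est$N, 4)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$ka, 0)
  expect_equal(est$ks, -0.75 * log(1 - 4 * 0.5 / 3), tolerance = 1e-12)
  expect_equal(est$omega, 0)
})

test_that("estimator invariants: zero law, symmetry, site conservation", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    sim <- simulate_codon_pair(max(n, 10), ks = runif(1, 0.05, 0.6),
                               omega = runif(1, 0, 1.5),
                               kappa_R = runif(1, 1, 6),
                               kappa_Y = runif(1, 1, 6),
                               seed = 1000 + rep)
    ca <- make_ca(sim$seq1, sim$seq2)
    ca_rev <- make_ca(sim$seq2, sim$seq1)
    for (fn in list(ng86_kaks, myn_kaks,
                    function(x) gamma_myn_kaks(x, 1))) {
      a <- fn(ca)
      b <- fn(ca_rev)
      expect_equal(a$S + a$N, 3 * length(ca$codons1), tolerance = 1e-6)
      expect_equal(a[c("S", "N", "Sd", "Nd", "ka", "ks")],
                   b[c("S", "N", "Sd", "Nd", "ka", "ks")], tolerance = 1e-12)
    }
    ident <- make_ca(sim$seq1, sim$seq1)
    z <- myn_kaks(ident)
    expect_equal(c(z$Sd, z$Nd, z$ka, z$ks), c(0, 0, 0, 0))
    expect_true(is.na(z$omega))  # ks = 0: omega undefined
  }
})

test_that("NG86 pathway averaging matches the exhaustive-path oracle", {
  set.seed(42)
  for (trial in 1:300) {
    c1 <- random_sense_codons(1)
    c2 <- random_sense_codons(1)
    got <- paralogscope:::classify_codon_diffs(c1, c2)
    want <- oracle_pathway_counts(c1, c2)
    if (is.null(want)) next  # all pathways stop-blocked; fallback path used
    expect_equal(sum(got[c("syn_AG", "syn_CT", "syn_TV")]), want$Sd,
                 tolerance = 1e-12, label = paste(c1, c2))
    expect_equal(sum(got[c("nonsyn_AG", "nonsyn_CT", "nonsyn_TV")]), want$Nd,
                 tolerance = 1e-12, label = paste(c1, c2))
  }
  # and at the sequence level over short random pairs
  for (trial in 1:50) {
    n <- sample(2:5, 1)
    s1 <- paste(random_sense_codons(n), collapse = "")
    s2 <- paste(random_sense_codons(n), collapse = "")
    ca <- make_ca(s1, s2)
    est <- ng86_kaks(ca)
    oracle <- Map(oracle_pathway_counts, ca$codons1, ca$codons2)
    usable <- !vapply(oracle, is.null, logical(1))
    if (!all(usable)) next
    expect_equal(est$Sd, sum(vapply(oracle, `[[`, numeric(1), "Sd")),
                 tolerance = 1e-12)
    expect_equal(est$Nd, sum(vapply(oracle, `[[`, numeric(1), "Nd")),
                 tolerance = 1e-12)
  }
})

test_that("MYN agrees with NG86 in the unbiased limit", {
  sim <- simulate_codon_pair(500, ks = 0.3, omega = 0.5,
                             kappa_R = 1, kappa_Y = 1, seed = 2024)
  ca <- make_ca(sim$seq1, sim$seq2)
  ng <- ng86_kaks(ca)
  my <- myn_kaks(ca, params = tn93_params())  # kappas forced to 1, uniform pi
  expect_lt(abs(my$ka - ng$ka), 0.01)
  expect_lt(abs(my$ks - ng$ks), 0.02)
})

test_that("gamma-MYN limits: shape -> Inf recovers MYN; smaller shape never decreases distance", {
  sim <- simulate_codon_pair(200, ks = 0.4, omega = 0.4, seed = 5)
  ca <- make_ca(sim$seq1, sim$seq2)
  my <- myn_kaks(ca)
  gl <- gamma_myn_kaks(ca, gamma_shape = 1e6)
  expect_equal(gl$ka, my$ka, tolerance = 1e-4)
  expect_equal(gl$ks, my$ks, tolerance = 1e-4)
  expect_identical(gl$method, "gMYN")

  shapes <- c(1e6, 100, 10, 2, 1, 0.5)
  ks_by_shape <- vapply(shapes,
                        function(a) gamma_myn_kaks(ca, a)$ks, numeric(1))
  ka_by_shape <- vapply(shapes,
                        function(a) gamma_myn_kaks(ca, a)$ka, numeric(1))
  expect_true(all(diff(ks_by_shape) >= -1e-12))
  expect_true(all(diff(ka_by_shape) >= -1e-12))
})

test_that("gamma-MYN recovers omega on data with gamma-distributed site rates", {
  # matched model: generator draws Gamma(1, 1) rate multipliers per codon,
  # estimator corrects with shape 1
  est <- vapply(1:30, function(i) {
    s <- simulate_codon_pair(300, ks = 0.5, omega = 0.3, seed = 50000 + i,
                             gamma_site_shape = 1)
    pair_kaks_pipeline(s$seq1, s$seq2, method = "gMYN",
                       gamma_shape = 1)$estimate$omega
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3) / 0.3, 0.2)
})

test_that("pair_kaks_pipeline composes the stages and propagates errors", {
  out <- pair_kaks_pipeline("ATGGCCAAA", "ATGGCCAAA", method = "MYN")
  expect_equal(out$estimate$ka, 0)
  expect_equal(out$estimate$ks, 0)
  expect_equal(out$divergence, 0)
  expect_error(pair_kaks_pipeline("ATGTAAGCC", "ATGGCCAAA"), "internal stop")

  sim <- simulate_codon_pair(300, ks = 0.4, omega = 0.2, seed = 77)
  res <- pair_kaks_pipeline(sim$seq1, sim$seq2, method = "MYN")
  expect_lt(abs(res$estimate$ks - 0.4), 0.15)
  expect_lt(abs(res$estimate$omega - 0.2), 0.1)
  expect_equal(res$n_codons, 300)
})
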