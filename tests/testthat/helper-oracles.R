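# Shared fixtures and independent oracles for the test suite.

GC <- Biostrings::GENETIC_CODE

# Quick codon-alignment construction from two in-frame sequences assumed
# already codon-homologous (no gaps).
make_ca <- function(s1, s2) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  structure(list(codons1 = split3(s1), codons2 = split3(s2)),
            class = "codon_alignment")
}

random_sense_codons <- function(n) {
  sense <- names(GC)[GC != "*"]
  sample(sense, n, replace = TRUE)
}

# Independent pathway oracle: recursively enumerates every minimal
# substitution pathway between two sense codons (depth-first over the order
# in which differing positions are resolved), drops pathways that visit a
# stop codon, and averages per-pathway synonymous / nonsynonymous step
# counts. Independent of the package's permutation-table implementation.
oracle_pathway_counts <- function(c1, c2) {
  x <- strsplit(c1, "")[[1]]
  y <- strsplit(c2, "")[[1]]
  walk <- function(cur, remaining) {
    if (!length(remaining)) {
      return(list(list(syn = 0, nonsyn = 0)))
    }
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- y[pos]
      if (GC[[paste(nxt, collapse = "")]] == "*") next
      syn_step <- GC[[paste(cur, collapse = "")]] ==
        GC[[paste(nxt, collapse = "")]]
      for (tail in walk(nxt, setdiff(remaining, pos))) {
        out[[length(out) + 1]] <- list(syn = tail$syn + syn_step,
                                       nonsyn = tail$nonsyn + !syn_step)
      }
    }
    out
  }
  paths <- walk(x, which(x != y))
  if (!length(paths)) return(NULL)  # every pathway blocked by a stop
  list(Sd = mean(vapply(paths, `[[`, numeric(1), "syn")),
       Nd = mean(vapply(paths, `[[`, numeric(1), "nonsyn")),
       n_paths = length(paths))
}

# Plain Rand index between two labelings.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

inparalog_table_path <- function() {
  system.file("extdata", "rsphaeroides_inparalogs.tsv",
              package = "paralogscope", mustWork = TRUE)
}
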