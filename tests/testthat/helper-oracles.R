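# Independent oracles used throughout the suite. They deliberately avoid the
# package's own code paths: translation goes through Biostrings, counting
# oracles enumerate every event explicitly.

# translation oracle (Biostrings, bacterial code); mirrors the package's
# alternative-start convention so round trips are comparable
oracle_translate <- function(cds) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "error"))
  first <- substr(cds, 1, 3)
  if (first %in% c("GTG", "TTG")) substr(aa, 1, 1) <- "M"
  aa
}

# every single-nucleotide mutant of a CDS, as a character vector with
# attributes giving position and alt base
all_snv_mutants <- function(cds) {
  n <- nchar(cds)
  chars <- strsplit(cds, "")[[1]]
  pos <- rep(seq_len(n), each = 3L)
  alts <- unlist(lapply(chars, function(b) setdiff(c("A", "C", "G", "T"), b)))
  muts <- vapply(seq_along(pos), function(i) {
    x <- cds
    substr(x, pos[i], pos[i]) <- alts[i]
    x
  }, character(1))
  data.frame(pos = pos, alt = alts, mut = muts, stringsAsFactors = FALSE)
}

oracle_translate_many <- function(seqs) {
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seqs),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "error"))
}

# brute-force stop-gain count: translate every mutant CDS, count mutants whose
# protein gains a '*' at the mutated (interior) codon
oracle_stop_gain <- function(cds) {
  m <- all_snv_mutants(cds)
  ncod <- nchar(cds) / 3
  codon <- (m$pos - 1) %/% 3 + 1
  interior <- codon > 1 & codon < ncod
  prot <- oracle_translate_many(m$mut[interior])
  sum(substr(prot, codon[interior], codon[interior]) == "*")
}

# brute-force region-restricted missense count
oracle_missense <- function(cds, aa_idx) {
  m <- all_snv_mutants(cds)
  codon <- (m$pos - 1) %/% 3 + 1
  keep <- codon %in% aa_idx
  p0 <- oracle_translate(cds)
  prot <- oracle_translate_many(m$mut[keep])
  a0 <- substr(rep(p0, sum(keep)), codon[keep], codon[keep])
  a1 <- substr(prot, codon[keep], codon[keep])
  sum(a1 != a0 & a1 != "*" & a0 != "*")
}

# direct-repeat oracle, two-sided:
#  (i) soundness: every reported pair is an exact, maximal repeat
#  (ii) completeness: for each separation d, the number of length-`min`
#       windows matching at separation d equals the sum over reported maximal
#       runs at that d of (repeat_len - min + 1)
oracle_check_repeats <- function(seq, hits, min_len, max_del) {
  n <- nchar(seq)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    expect_gte(h$repeat_len, min_len)
    expect_lte(h$deletion_len, max_del)
    expect_identical(substr(seq, h$left_start, h$left_start + h$repeat_len - 1),
                     substr(seq, h$right_start, h$right_start + h$repeat_len - 1))
    expect_equal(h$deletion_len, h$right_start - h$left_start)
    # maximality left
    if (h$left_start > 1) {
      expect_false(substr(seq, h$left_start - 1, h$left_start - 1) ==
                     substr(seq, h$right_start - 1, h$right_start - 1))
    }
    # maximality right
    re <- h$right_start + h$repeat_len
    if (re <= n) {
      expect_false(substr(seq, h$left_start + h$repeat_len,
                          h$left_start + h$repeat_len) == substr(seq, re, re))
    }
    expect_identical(h$frame_preserving, h$deletion_len %% 3 == 0)
  }
  for (d in seq_len(min(max_del, n - min_len))) {
    i <- seq_len(n - d - min_len + 1)
    win_match <- substring(seq, i, i + min_len - 1) ==
      substring(seq, i + d, i + d + min_len - 1)
    hd <- hits[hits$deletion_len == d, , drop = FALSE]
    expect_equal(sum(win_match),
                 sum(pmax(hd$repeat_len - min_len + 1, 0)),
                 info = paste("separation", d))
  }
  invisible(TRUE)
}

# network-logic oracle: numeric activity score computed independently of the
# package's rule cascade
oracle_ws_output <- function(spec, states) {
  comps <- names(spec$components)
  st <- setNames(rep("wildtype", length(comps)), comps)
  st[names(states)] <- states
  if (isTRUE(spec$deleted)) return("none")
  if (is.na(spec$dgc)) return("basal")
  dgc_ok <- !(st[spec$dgc] %in% c("absent", "lof", "lof_frame_breaking"))
  polar_block <- FALSE
  for (src in names(spec$polar)) {
    if (st[src] == "lof_frame_breaking" && spec$polar[[src]] == spec$dgc) {
      polar_block <- TRUE
    }
  }
  if (!dgc_ok || polar_block) return("none")
  act <- sum(st == "activating")
  neg <- names(spec$components)[spec$components == "negative_regulator"]
  derepressed <- sum(st[neg] %in% c("lof", "lof_frame_breaking", "absent"))
  if (act + derepressed > 0) "high" else "basal"
}

# exact multinomial p oracle for k <= 3 by direct nested loops
oracle_multinom_p <- function(observed, probs) {
  n <- sum(observed)
  p_obs <- dmultinom(observed, prob = probs)
  tot <- 0
  if (length(probs) == 2L) {
    for (i in 0:n) {
      m <- dmultinom(c(i, n - i), prob = probs)
      if (m <= p_obs * (1 + 1e-9)) tot <- tot + m
    }
  } else {
    for (i in 0:n) for (j in 0:(n - i)) {
      m <- dmultinom(c(i, j, n - i - j), prob = probs)
      if (m <= p_obs * (1 + 1e-9)) tot <- tot + m
    }
  }
  tot
}

random_cds <- function(n_codons, seed) gen_cds(n_codons, gc_content = 0.55,
                                               seed = seed)

fixture_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pf5_fixtures()
    cache
  }
})
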