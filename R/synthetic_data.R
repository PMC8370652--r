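#' Generate a random valid coding sequence
#'
#' Starts with ATG, ends with a stop codon, no internal in-frame stop,
#' approximate GC content as requested. Pure function of `(n_codons,
#' gc_content, seed)`.
#'
#' @param n_codons total codons including start and stop (>= 2).
#' @param gc_content target GC fraction.
#' @param seed RNG seed.
#' @return CDS string of length `3 * n_codons`.
#' @export
gen_cds <- function(n_codons, gc_content = 0.5, seed = 1) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 2L) stop("n_codons must be >= 2", call. = FALSE)
  set.seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  n_interior <- n_codons - 2L
  interior <- character(n_interior)
  if (n_interior > 0L) {
    draw <- function(k) {
      m <- matrix(sample(names(p), 3L * k, replace = TRUE, prob = p),
                  nrow = 3L)
      apply(m, 2L, paste, collapse = "")
    }
    interior <- draw(n_interior)
    repeat {
      bad <- which(interior %in% .stop_codons)
      if (!length(bad)) break
      interior[bad] <- draw(length(bad))
    }
  }
  stop_codon <- sample(.stop_codons, 1L)
  paste0("ATG", paste(interior, collapse = ""), stop_codon)
}

#' Plant an exact direct repeat into a CDS
#'
#' Copies `repeat_len` bases starting at `position` to
#' `position + separation`, so the scanner reports a pair with
#' `deletion_len = separation`. The result must remain a valid CDS; the
#' operation fails (rather than silently redraws) if planting introduces an
#' internal stop or hits a sequence boundary.
#'
#' @param cds_seq valid CDS string.
#' @param repeat_len length of the repeated unit (bp).
#' @param separation distance between copy starts (= deletion length).
#' @param position 1-based start of the left copy.
#' @return modified CDS string.
#' @export
plant_repeat <- function(cds_seq, repeat_len, separation, position) {
  L <- nchar(cds_seq)
  right <- position + separation
  if (position < 1L || right + repeat_len - 1L > L - 3L) {
    stop("planting region outside CDS interior", call. = FALSE)
  }
  unit <- substr(cds_seq, position, position + repeat_len - 1L)
  out <- cds_seq
  substr(out, right, right + repeat_len - 1L) <- unit
  errs <- validate_cds(out)
  if (length(errs)) {
    stop("cannot plant repeat without violating CDS validity: ",
         paste(errs, collapse = "; "), call. = FALSE)
  }
  out
}

#' Replace one codon of a CDS (fixture construction helper)
#' @param cds_seq valid CDS string.
#' @param codon_index 1-based codon to replace (not first or last).
#' @param codon replacement codon.
#' @return modified, revalidated CDS string.
#' @export
plant_codon <- function(cds_seq, codon_index, codon) {
  ncod <- nchar(cds_seq) %/% 3L
  if (codon_index <= 1L || codon_index >= ncod) {
    stop("can only replace interior codons", call. = FALSE)
  }
  pos <- 3L * (codon_index - 1L) + 1L
  out <- cds_seq
  substr(out, pos, pos + 2L) <- codon
  errs <- validate_cds(out)
  if (length(errs)) {
    stop("planting codon breaks CDS validity: ",
         paste(errs, collapse = "; "), call. = FALSE)
  }
  out
}

#' Generate competition-assay CFU counts with known truth
#'
#' The true mutant:reference ratio follows `R(t) = R(0) * exp(s * t)`;
#' observed counts are multinomial platings of `sampling_depth` colonies at
#' each timepoint (binomial between mutant and reference). With
#' `no_noise = TRUE` the expected counts are returned, so the estimator
#' inverts the generator exactly.
#'
#' @param true_s true selection coefficient per generation.
#' @param initial_ratio mutant:reference ratio at t0 (1/100 for invasion
#'   assays, 1 for competition assays).
#' @param generations assay duration in whole-population generations.
#' @param sampling_depth colonies counted per timepoint.
#' @param n_replicates independent replicates.
#' @param seed RNG seed.
#' @param no_noise return expected counts instead of sampling.
#' @param strain_id,reference_id,assay labels for the output table.
#' @return data.frame in the CFU TSV dialect.
#' @export
gen_competition_counts <- function(true_s, initial_ratio = 1,
                                   generations = 10, sampling_depth = 1e4,
                                   n_replicates = 4, seed = 1,
                                   no_noise = FALSE,
                                   strain_id = "mutant",
                                   reference_id = "reference",
                                   assay = if (initial_ratio < 0.5) "invasion"
                                           else "competition") {
  stopifnot(sampling_depth >= 1, initial_ratio > 0)
  set.seed(seed)
  f0 <- initial_ratio / (1 + initial_ratio)
  r1 <- initial_ratio * exp(true_s * generations)
  f1 <- r1 / (1 + r1)
  rows <- lapply(seq_len(n_replicates), function(i) {
    if (no_noise) {
      m0 <- sampling_depth * f0; m1 <- sampling_depth * f1
    } else {
      m0 <- stats::rbinom(1L, sampling_depth, f0)
      m1 <- stats::rbinom(1L, sampling_depth, f1)
    }
    data.frame(strain_id = strain_id, reference_id = reference_id,
               assay = assay, replicate = i,
               t0_mutant = m0, t0_reference = sampling_depth - m0,
               t1_mutant = m1, t1_reference = sampling_depth - m1,
               dilution_t0 = 1, dilution_t1 = 1,
               generations = generations, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "wsforecast")
  if (!nzchar(path)) stop("bundled fixture not found: ", file, call. = FALSE)
  path
}

#' Bundled synthetic Pf-5-style fixtures
#'
#' Loads the frozen synthetic stand-in fixtures that emulate the published
#' mutant catalogue: the gene-model table (synthetic coding sequences with the
#' documented codons planted), the region set (reconstructed), the 43-record
#' wild-type mutant table, the 7-record triple-deletion table and the
#' competition-assay CFU table. Every row carries a provenance tag.
#'
#' @return list with `gene_models` (a `ws_gene_set`), `regions`,
#'   `mutants_wt`, `mutants_triple`, `cfu`, `config_path`.
#' @export
pf5_fixtures <- function() {
  gm <- load_gene_models(.extdata("pf5_genes_synthetic.tsv"))
  regions <- load_regions(.extdata("pf5_regions_synthetic.tsv"), gm)
  mut <- load_mutant_table(.extdata("pf5_mutants_synthetic.tsv"), gm)
  cfu <- load_cfu_table(.extdata("pf5_competition_synthetic.tsv"))
  list(gene_models = gm,
       regions = regions,
       mutants_wt = mut[mut$experiment == "wt", ],
       mutants_triple = mut[mut$experiment == "triple_deletion", ],
       cfu = cfu,
       config_path = .extdata("null_model_config.json"))
}

#' Default per-gene constraint set for the Pf-5-style model
#'
#' wspF: any loss of function; awsX: frame-preserving events only (polarity
#' onto awsR); receptors/kinases/DGCs: region-restricted substitutions;
#' structural operon members: no WS target.
#'
#' @return named character vector gene -> constraint.
#' @export
pf5_constraints <- function() {
  c(wspA = "regions_only", wspE = "regions_only", wspF = "any_lof",
    wspR = "regions_only", awsX = "inframe_only", awsR = "regions_only",
    awsO = "regions_only", mwsR = "regions_only", dgcH = "regions_only")
}
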