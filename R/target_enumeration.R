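# Precomputed single-nucleotide mutation summaries per codon: for each of the
# 64 codons, the number of the 9 possible single-base substitutions that are
# stop-gaining, missense (amino-acid changing, non-stop) or synonymous.
.codon_sub_summary <- local({
  bases <- c("A", "C", "G", "T")
  codons <- names(.genetic_code_11)
  res <- data.frame(codon = codons, stop_gain = 0L, missense = 0L,
                    synonymous = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(codons)) {
    cd <- codons[i]
    aa0 <- .genetic_code_11[[cd]]
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        m <- cd
        substr(m, p, p) <- b
        aa1 <- .genetic_code_11[[m]]
        if (aa1 == "*" && aa0 != "*") {
          res$stop_gain[i] <- res$stop_gain[i] + 1L
        } else if (aa1 == aa0) {
          res$synonymous[i] <- res$synonymous[i] + 1L
        } else if (aa0 != "*" && aa1 != "*") {
          res$missense[i] <- res$missense[i] + 1L
        }
      }
    }
  }
  rownames(res) <- codons
  res
})

#' Count stop-gain substitution sites in a CDS
#'
#' Number of distinct single-nucleotide substitutions in the interior codons
#' (codon 2 to L-1; the start codon and the annotated stop are excluded) whose
#' mutant codon is a stop (TAA/TAG/TGA).
#'
#' @param cds_seq valid CDS string.
#' @param per_codon also return the per-codon breakdown.
#' @return integer count, or (with `per_codon = TRUE`) a list with `total` and
#'   a data.frame `breakdown`.
#' @export
count_stop_gain_sites <- function(cds_seq, per_codon = FALSE) {
  errs <- validate_cds(cds_seq)
  if (length(errs)) stop("invalid CDS: ", paste(errs, collapse = "; "),
                         call. = FALSE)
  codons <- codon_split(cds_seq)
  L <- length(codons)
  interior <- if (L > 2L) codons[2:(L - 1L)] else character(0)
  counts <- .codon_sub_summary[interior, "stop_gain"]
  total <- sum(counts)
  if (!per_codon) return(total)
  list(total = total,
       breakdown = data.frame(codon_index = seq_along(interior) + 1L,
                              codon = interior, stop_gain = counts))
}

#' Weighted count of frame-breaking indel sites
#'
#' Each CDS position carries one +/-1 bp frame-breaking indel opportunity of
#' weight 1; positions inside homopolymer runs of at least `min_run` nt get
#' weight `h` instead (slipped-strand mispairing bias).
#'
#' @param cds_seq valid CDS string.
#' @param indel_model list with `h` (homopolymer multiplier, >= 0) and
#'   `min_run` (default 4).
#' @return numeric weighted site count; equals `nchar(cds_seq)` for `h = 1`.
#' @export
count_frameshift_sites <- function(cds_seq, indel_model = list(h = 1, min_run = 4)) {
  .check_dna(cds_seq, "cds_seq")
  h <- indel_model$h %||% 1
  min_run <- indel_model$min_run %||% 4
  if (h < 0) stop("negative homopolymer weights rejected", call. = FALSE)
  L <- nchar(cds_seq)
  runs <- rle(strsplit(cds_seq, "")[[1]])
  hot <- sum(runs$lengths[runs$lengths >= min_run])
  L + hot * (h - 1)
}

#' Scan a sequence for direct-repeat deletion opportunities
#'
#' Finds all maximal exact direct-repeat pairs (left copy, right copy) with
#' repeat length >= `min_repeat_len` and separation (= deletion length) at most
#' `max_deletion_len`. A replication-slippage deletion between the two copies
#' removes `deletion_len = right_start - left_start` bp; it is frame-preserving
#' iff `deletion_len %% 3 == 0`. Overlapping and nested pairs are all reported
#' (no greedy suppression); output is sorted by (left_start, deletion_len).
#'
#' @param seq DNA string.
#' @param min_repeat_len minimum repeat unit length (>= 4).
#' @param max_deletion_len maximum separation searched.
#' @return data.frame with columns `repeat_seq, repeat_len, left_start,
#'   right_start, deletion_len, frame_preserving`.
#' @export
scan_direct_repeats <- function(seq, min_repeat_len = 6L,
                                max_deletion_len = 500L) {
  .check_dna(seq, "seq")
  min_repeat_len <- as.integer(min_repeat_len)
  if (min_repeat_len < 4L) stop("min_repeat_len must be >= 4", call. = FALSE)
  n <- nchar(seq)
  empty <- data.frame(repeat_seq = character(), repeat_len = integer(),
                      left_start = integer(), right_start = integer(),
                      deletion_len = integer(), frame_preserving = logical(),
                      stringsAsFactors = FALSE)
  if (n < min_repeat_len + 1L) return(empty)
  chars <- strsplit(seq, "")[[1]]
  out <- vector("list", 0L)
  for (d in seq_len(min(max_deletion_len, n - min_repeat_len))) {
    m <- chars[seq_len(n - d)] == chars[(d + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_repeat_len)
    if (length(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        repeat_len = r$lengths[keep],
        left_start = starts[keep],
        right_start = starts[keep] + d,
        deletion_len = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$repeat_seq <- substring(seq, res$left_start,
                              res$left_start + res$repeat_len - 1L)
  res$frame_preserving <- res$deletion_len %% 3L == 0L
  res <- res[order(res$left_start, res$deletion_len),
             c("repeat_seq", "repeat_len", "left_start", "right_start",
               "deletion_len", "frame_preserving")]
  rownames(res) <- NULL
  res
}

#' Region-restricted missense target size
#'
#' Number of single-nucleotide substitutions within the given amino-acid
#' regions that change the encoded amino acid without creating a stop
#' (non-synonymous, non-nonsense). The initiator codon contributes no
#' missense opportunities: substitutions there alter translation initiation
#' (table 11 admits several alternative starts, all rendered as Met), so they
#' are loss-of-initiation events, not amino-acid replacements.
#'
#' @param cds_seq valid CDS string.
#' @param regions data.frame with `start`/`end` residue columns (`aa_range`
#'   rows of the region fixture), or NULL/empty for 0.
#' @return integer count.
#' @export
restricted_missense_target <- function(cds_seq, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(0L)
  codons <- codon_split(cds_seq)
  nprot <- length(codons) - 1L
  idx <- sort(unique(unlist(lapply(seq_len(nrow(regions)), function(i) {
    if (regions$end[i] > nprot || regions$start[i] < 1L) {
      stop(sprintf("region %d-%d outside protein (1..%d)",
                   regions$start[i], regions$end[i], nprot), call. = FALSE)
    }
    seq.int(regions$start[i], regions$end[i])
  }))))
  idx <- setdiff(idx, 1L)  # initiator codon: loss of initiation, not missense
  sum(.codon_sub_summary[codons[idx], "missense"])
}

.region_rows <- function(regions, gene_name, class, kind = "aa_range") {
  if (is.null(regions) || nrow(regions) == 0L) {
    return(data.frame(gene_name = character(), kind = character(),
                      start = integer(), end = integer(),
                      allowed_classes = character(), stringsAsFactors = FALSE))
  }
  hit <- regions$gene_name == gene_name & regions$kind == kind &
    vapply(strsplit(regions$allowed_classes, ","),
           function(cl) class %in% trimws(cl), logical(1))
  regions[hit, , drop = FALSE]
}

#' Per-gene, per-class mutational target sizes
#'
#' Applies a gene's constraint set to turn raw sequence counts into
#' WS-enabling target sizes:
#' \describe{
#'   \item{any_lof}{nonsense + frame-breaking indels anywhere, plus in-frame
#'     direct-repeat deletions, plus missense restricted to the gene's
#'     missense regions (if any).}
#'   \item{inframe_only}{only frame-preserving events (AwsX: a frame-breaking
#'     lesion is polar onto the downstream DGC and yields no WS): in-frame
#'     repeat deletions and missense in the listed regions; nonsense and
#'     frameshift targets are 0.}
#'   \item{regions_only}{missense (and, where the region allows it, in-frame
#'     deletions) within the listed regions only.}
#'   \item{none}{all targets 0.}
#' }
#'
#' @param gene a `ws_gene`.
#' @param constraint one of `"any_lof"`, `"inframe_only"`, `"regions_only"`,
#'   `"none"`.
#' @param regions region fixture data.frame (see [load_regions()]).
#' @param indel_model passed to [count_frameshift_sites()].
#' @param repeat_params list with `min_repeat_len`, `max_deletion_len` for the
#'   direct-repeat scanner.
#' @return named numeric vector of per-class targets
#'   (`nonsense, frameshift_indel, inframe_indel, missense, promoter_point`).
#' @export
lof_target <- function(gene, constraint, regions = NULL,
                       indel_model = list(h = 1, min_run = 4),
                       repeat_params = list(min_repeat_len = 6L,
                                            max_deletion_len = 500L)) {
  constraint <- match.arg(constraint,
                          c("any_lof", "inframe_only", "regions_only", "none"))
  out <- c(nonsense = 0, frameshift_indel = 0, inframe_indel = 0,
           missense = 0, promoter_point = 0)
  if (constraint == "none") return(out)
  reps <- scan_direct_repeats(gene$cds_seq,
                              repeat_params$min_repeat_len,
                              repeat_params$max_deletion_len)
  inframe_all <- sum(reps$frame_preserving)
  mis_regions <- .region_rows(regions, gene$gene_name, "missense")
  mis <- restricted_missense_target(gene$cds_seq, mis_regions)
  if (constraint == "any_lof") {
    out["nonsense"] <- count_stop_gain_sites(gene$cds_seq)
    out["frameshift_indel"] <- count_frameshift_sites(gene$cds_seq, indel_model)
    out["inframe_indel"] <- inframe_all
    out["missense"] <- mis
  } else if (constraint == "inframe_only") {
    out["inframe_indel"] <- inframe_all
    out["missense"] <- mis
  } else { # regions_only
    infr_regions <- .region_rows(regions, gene$gene_name, "inframe_indel")
    if (nrow(infr_regions) > 0L) {
      # in-frame repeat deletions whose left copy starts inside the region
      nt_lo <- 3L * (infr_regions$start - 1L) + 1L
      nt_hi <- 3L * infr_regions$end
      inside <- rep(FALSE, nrow(reps))
      for (k in seq_along(nt_lo)) {
        inside <- inside | (reps$left_start >= nt_lo[k] &
                              reps$left_start <= nt_hi[k])
      }
      out["inframe_indel"] <- sum(reps$frame_preserving & inside)
    }
    out["missense"] <- mis
  }
  # promoter opportunities: one point target per upstream-window bp when an
  # upstream region is annotated for the gene
  up <- .region_rows(regions, gene$gene_name, "promoter_point",
                     kind = "upstream")
  if (nrow(up) > 0L) {
    out["promoter_point"] <- sum(3L * (up$end - up$start + 1L))
  }
  out
}

#' Build the full target-size table for a gene set
#'
#' @param gene_models a `ws_gene_set`.
#' @param constraints named character vector gene -> constraint label; genes
#'   absent from it get `"none"`.
#' @param regions region fixture data.frame.
#' @param indel_model,repeat_params see [lof_target()].
#' @return data.frame (class `ws_target_table`) with columns
#'   `gene_name, pathway, mclass, count`.
#' @export
target_size_table <- function(gene_models, constraints, regions = NULL,
                              indel_model = list(h = 1, min_run = 4),
                              repeat_params = list(min_repeat_len = 6L,
                                                   max_deletion_len = 500L)) {
  rows <- lapply(names(gene_models), function(gn) {
    g <- gene_models[[gn]]
    cons <- if (gn %in% names(constraints)) constraints[[gn]] else "none"
    tg <- lof_target(g, cons, regions, indel_model, repeat_params)
    data.frame(gene_name = gn, pathway = g$pathway, mclass = names(tg),
               count = unname(tg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$count < 0)) stop("negative target size", call. = FALSE)
  class(out) <- c("ws_target_table", class(out))
  out
}

#' Write a target table as TSV and JSON
#' @param targets a `ws_target_table`.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @export
write_target_table <- function(targets, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(targets, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(targets, json_path, digits = NA)
  }
  invisible(targets)
}
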