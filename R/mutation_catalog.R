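.mclasses <- c("missense", "nonsense", "frameshift_indel", "inframe_indel",
               "synonymous", "promoter_point", "promoter_capture",
               "intergenic_other")

#' Construct a mutation record
#'
#' One observed (or simulated) mutation. `coord_system` selects the coordinate
#' convention: `cds_nt` (1-based position in the coding sequence),
#' `upstream_nt` (<= 0, relative to the first CDS base) or `protein_aa`
#' (residue number; `ref`/`alt` are then amino-acid letters).
#' For pure insertions `ref = ""`; for pure deletions `alt = ""`.
#'
#' @param isolate_id isolate label.
#' @param gene_name gene or region reference (exactly one).
#' @param coord_system `"cds_nt"`, `"upstream_nt"` or `"protein_aa"`.
#' @param position integer position in that system.
#' @param ref,alt reference / alternate alleles (DNA, or aa for `protein_aa`).
#' @param structural_flag optional `"promoter_capture"` for rearrangements
#'   joining an operon to a foreign promoter.
#' @param experiment experiment label (e.g. `"wt"`, `"triple_deletion"`).
#' @return one-row data.frame of class `ws_mutation`.
#' @export
mutation_record <- function(isolate_id, gene_name, coord_system, position,
                            ref = "", alt = "", structural_flag = "",
                            experiment = "wt") {
  coord_system <- match.arg(coord_system,
                            c("cds_nt", "upstream_nt", "protein_aa"))
  if (nzchar(structural_flag) && structural_flag != "promoter_capture") {
    stop("unknown structural_flag: ", structural_flag, call. = FALSE)
  }
  out <- data.frame(isolate_id = as.character(isolate_id),
                    gene_name = as.character(gene_name),
                    coord_system = coord_system,
                    position = as.integer(position),
                    ref = toupper(as.character(ref)),
                    alt = toupper(as.character(alt)),
                    structural_flag = as.character(structural_flag),
                    experiment = as.character(experiment),
                    stringsAsFactors = FALSE)
  class(out) <- c("ws_mutation", class(out))
  out
}

#' Load a mutant table TSV
#'
#' Strict dialect: UTF-8, tab-separated, `#` comment lines; columns
#' `isolate_id, experiment, gene_name, coord_system, position, ref, alt,
#' structural_flag` (extra columns such as `notes`/`provenance` are kept but
#' ignored by the classifier, with a warning for truly unknown ones).
#'
#' @param path TSV path.
#' @param gene_models optional `ws_gene_set`; when given, gene names are
#'   checked and `cds_nt` reference alleles verified against the model.
#' @param experiment optional filter on the `experiment` column.
#' @return data.frame of mutation records (row numbers preserved in
#'   `source_line`).
#' @export
load_mutant_table <- function(path, gene_models = NULL, experiment = NULL) {
  if (!file.exists(path)) stop("mutant table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("isolate_id", "experiment", "gene_name", "coord_system",
            "position", "ref", "alt", "structural_flag")
  if (!all(need %in% names(raw))) {
    stop("mutant table lacks columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  known <- c(need, "notes", "provenance")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown mutant-table columns: ",
            paste(extra, collapse = ", "))
  }
  raw$position <- suppressWarnings(as.integer(raw$position))
  bad <- which(is.na(raw$position))
  if (length(bad)) {
    stop("malformed position at data row(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  raw$source_line <- seq_len(nrow(raw))
  if (!is.null(experiment)) raw <- raw[raw$experiment == experiment, ]
  if (!is.null(gene_models)) {
    unknown <- setdiff(unique(raw$gene_name), names(gene_models))
    if (length(unknown)) {
      stop("unknown gene_name in mutant table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  raw
}

.aa_at <- function(gene, codon_index) {
  substr(translate_cds(gene$cds_seq), codon_index, codon_index)
}

#' Classify a mutation's functional effect
#'
#' The minimal variant-effect annotator. Substitutions inside a CDS are
#' classified by translating the affected codon before and after
#' (synonymous / missense / nonsense); indels by frame arithmetic
#' (`|len(ref) - len(alt)| mod 3`); point changes within the upstream window
#' are `promoter_point`; records with `structural_flag = "promoter_capture"`
#' are `promoter_capture`. Positions outside both the CDS and the upstream
#' window degrade to `intergenic_other` with a warning. Frame-breaking or
#' nonsense lesions in a gene with a `polar_partner` set
#' `disrupts_downstream = TRUE` (AwsX polarity onto AwsR).
#'
#' @param record one-row mutation record (see [mutation_record()]).
#' @param gene_models a `ws_gene_set`.
#' @return list of class `ws_effect` with fields `record`, `mclass`,
#'   `protein_change`, `frame_preserving`, `disrupts_downstream`, `pathway`,
#'   `gene_name`, `site_label`.
#' @export
classify_mutation <- function(record, gene_models) {
  r <- as.list(record[1, ])
  gene <- get_gene(gene_models, r$gene_name)
  ref <- toupper(r$ref %||% "")
  alt <- toupper(r$alt %||% "")
  mclass <- NULL
  protein_change <- NA_character_
  frame_preserving <- NA
  pos <- r$position

  if (nzchar(r$structural_flag %||% "")) {
    mclass <- "promoter_capture"
    site <- sprintf("%s:capture@%d", gene$gene_name, pos)
  } else if (r$coord_system == "upstream_nt") {
    if (pos > 0L) stop("upstream_nt positions must be <= 0", call. = FALSE)
    if (-pos >= gene$upstream_window) {
      warning(sprintf("isolate %s: position %d outside upstream window (%d bp) of %s; classified intergenic_other",
                      r$isolate_id, pos, gene$upstream_window, gene$gene_name))
      mclass <- "intergenic_other"
    } else {
      mclass <- "promoter_point"
    }
    site <- sprintf("%s:up%d:%s>%s", gene$gene_name, pos, ref, alt)
  } else if (r$coord_system == "protein_aa") {
    if (pos < 1L || pos > protein_length(gene)) {
      stop("protein position outside protein", call. = FALSE)
    }
    obs <- .aa_at(gene, pos)
    if (nzchar(ref) && ref != obs) {
      stop(sprintf("isolate %s: reference residue mismatch at %s aa %d (model %s, record %s)",
                   r$isolate_id, gene$gene_name, pos, obs, ref), call. = FALSE)
    }
    mclass <- if (alt == "*") "nonsense"
              else if (alt == obs) "synonymous" else "missense"
    protein_change <- sprintf("%s%d%s", obs, pos, alt)
    site <- sprintf("%s:%s", gene$gene_name, protein_change)
  } else {
    L <- nchar(gene$cds_seq)
    if (pos < 1L || pos > L) {
      stop(sprintf("isolate %s: cds_nt position %d outside CDS of %s (1..%d)",
                   r$isolate_id, pos, gene$gene_name, L), call. = FALSE)
    }
    if (nzchar(ref)) {
      have <- substr(gene$cds_seq, pos, pos + nchar(ref) - 1L)
      if (have != ref) {
        stop(sprintf("isolate %s: reference mismatch at %s cds position %d (model %s, record %s)",
                     r$isolate_id, gene$gene_name, pos, have, ref),
             call. = FALSE)
      }
    }
    dlen <- abs(nchar(ref) - nchar(alt))
    if (dlen == 0L) {
      if (nchar(ref) != 1L) {
        stop("multi-nucleotide substitutions are not supported", call. = FALSE)
      }
      pc <- position_to_codon(pos, L)
      codon <- codon_split(gene$cds_seq)[[pc$codon_index]]
      mut_codon <- codon
      substr(mut_codon, pc$offset, pc$offset) <- alt
      aa0 <- unname(.genetic_code_11[codon])
      if (pc$codon_index == 1L && codon %in% .start_codons) aa0 <- "M"
      aa1 <- unname(.genetic_code_11[mut_codon])
      # initiator convention: a start-to-start change keeps Met; a change to a
      # non-start codon is recorded as missense M1x (loss of initiation)
      if (pc$codon_index == 1L && mut_codon %in% .start_codons) aa1 <- "M"
      mclass <- if (aa1 == aa0) "synonymous"
                else if (aa1 == "*") "nonsense" else "missense"
      protein_change <- sprintf("%s%d%s", aa0, pc$codon_index, aa1)
      site <- sprintf("%s:%s", gene$gene_name, protein_change)
    } else {
      frame_preserving <- (dlen %% 3L == 0L)
      mclass <- if (frame_preserving) "inframe_indel" else "frameshift_indel"
      kindlab <- if (nchar(ref) > nchar(alt)) "del" else "ins"
      site <- sprintf("%s:%s%d@%d", gene$gene_name, kindlab, dlen, pos)
    }
  }
  if (mclass %in% c("nonsense", "frameshift_indel")) frame_preserving <- FALSE
  if (mclass %in% c("missense", "synonymous", "inframe_indel") &&
      is.na(frame_preserving)) {
    frame_preserving <- TRUE
  }
  disrupts <- !is.na(gene$polar_partner) &&
    isTRUE(mclass %in% c("nonsense", "frameshift_indel"))
  structure(list(record = r, mclass = mclass, protein_change = protein_change,
                 frame_preserving = frame_preserving,
                 disrupts_downstream = disrupts,
                 pathway = gene$pathway, gene_name = gene$gene_name,
                 site_label = site), class = "ws_effect")
}

#' Classify every row of a mutant table
#' @param records data.frame of mutation records.
#' @param gene_models a `ws_gene_set`.
#' @return list of `ws_effect`.
#' @export
classify_mutations <- function(records, gene_models) {
  lapply(seq_len(nrow(records)),
         function(i) classify_mutation(records[i, , drop = FALSE], gene_models))
}

#' Aggregate classified effects into an observed spectrum
#'
#' Counts per (gene, mutation class), plus pathway and gene marginals.
#' Promoter captures upstream of an operon are assigned to that operon's
#' pathway. Synonymous effects are flagged non-adaptive and excluded from the
#' WS spectrum (with `include_synonymous = FALSE`, the default).
#'
#' @param effects list of `ws_effect` (from [classify_mutations()]).
#' @param gene_models a `ws_gene_set`.
#' @param include_synonymous keep synonymous calls in the table.
#' @return object of class `ws_spectrum`: list with `counts` (gene x class
#'   data.frame), `gene_marginal`, `pathway_marginal`, `n_total`.
#' @export
build_spectrum <- function(effects, gene_models, include_synonymous = FALSE) {
  if (!include_synonymous) {
    effects <- Filter(function(e) e$mclass != "synonymous", effects)
  }
  if (length(effects) == 0L) {
    return(structure(list(
      counts = data.frame(gene_name = character(), mclass = character(),
                          count = integer()),
      gene_marginal = integer(0), pathway_marginal = integer(0),
      n_total = 0L), class = "ws_spectrum"))
  }
  gene <- vapply(effects, `[[`, character(1), "gene_name")
  cls <- vapply(effects, `[[`, character(1), "mclass")
  pw <- vapply(effects, `[[`, character(1), "pathway")
  tab <- as.data.frame(table(gene_name = gene, mclass = cls),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  names(tab)[3] <- "count"
  rownames(tab) <- NULL
  structure(list(
    counts = tab,
    gene_marginal = sort(tapply(rep(1L, length(gene)), gene, sum),
                         decreasing = TRUE),
    pathway_marginal = sort(tapply(rep(1L, length(pw)), pw, sum),
                            decreasing = TRUE),
    n_total = length(effects)), class = "ws_spectrum")
}

#' @export
print.ws_spectrum <- function(x, ...) {
  cat(sprintf("<ws_spectrum> n_total = %d\n", x$n_total))
  if (x$n_total > 0) {
    cat("pathways: ",
        paste(sprintf("%s=%d", names(x$pathway_marginal), x$pathway_marginal),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Most recurrent identical mutations
#'
#' Counts exactly identical changes (same gene and same protein change or
#' allele description); ties broken lexicographically by the change label.
#'
#' @param effects list of `ws_effect`.
#' @return data.frame with `change` and `count`, sorted by decreasing count.
#' @export
top_recurrent <- function(effects) {
  if (length(effects) == 0L) {
    return(data.frame(change = character(), count = integer()))
  }
  lab <- vapply(effects, `[[`, character(1), "site_label")
  tab <- table(lab)
  out <- data.frame(change = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$change), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Count coding disruptions of negative regulation
#'
#' The "disrupt negative regulation" summary: coding-sequence effects
#' (missense / nonsense / indel) in the regulators and interacting proteins of
#' the three main DGC pathways, excluding promoter events.
#'
#' @param effects list of `ws_effect`.
#' @param genes genes counted (default wspF, wspE, awsX, awsR, mwsR).
#' @return integer count.
#' @export
count_negative_regulation_disruptions <- function(
    effects, genes = c("wspF", "wspE", "awsX", "awsR", "mwsR")) {
  coding <- c("missense", "nonsense", "frameshift_indel", "inframe_indel")
  sum(vapply(effects, function(e) {
    e$gene_name %in% genes && e$mclass %in% coding
  }, logical(1)))
}

#' Serialize a spectrum to JSON
#' @param spectrum a `ws_spectrum`.
#' @param path output path.
#' @param provenance optional provenance list stored alongside the counts.
#' @export
write_spectrum_json <- function(spectrum, path, provenance = list()) {
  jsonlite::write_json(list(
    counts = spectrum$counts,
    gene_marginal = as.list(spectrum$gene_marginal),
    pathway_marginal = as.list(spectrum$pathway_marginal),
    n_total = spectrum$n_total,
    provenance = provenance), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
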