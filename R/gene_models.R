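#' Construct a gene model
#'
#' A `ws_gene` bundles a strand-resolved coding sequence with its operon and
#' pathway membership and the functional role the mutation-class logic needs
#' (negative regulator, diguanylate cyclase, interacting protein, ...).
#' Coordinates are 1-based inclusive throughout; `cds_seq` is always the coding
#' strand. Positions <= 0 relative to the first CDS base denote the upstream
#' regulatory window (`upstream_window` bp, default 300).
#'
#' @param gene_name short label, e.g. `"wspF"`.
#' @param cds_seq DNA string over A,C,G,T.
#' @param locus_tag optional locus tag (e.g. `"PFL_0087"`); empty if unknown.
#' @param strand `"+"` or `"-"` (informational; `cds_seq` is pre-resolved).
#' @param genomic_start,genomic_end optional 1-based genomic coordinates.
#' @param operon operon label.
#' @param pathway one of `"Wsp"`, `"Aws"`, `"Mws"`, `"DgcH"`, `"PFL_3078"`,
#'   `"other"`.
#' @param role one of `"negative_regulator"`, `"dgc"`, `"interacting"`,
#'   `"promoter_only"`, `"structural"`.
#' @param upstream_window regulatory window length in bp attributed upstream of
#'   this gene/operon.
#' @param polar_partner optional downstream gene whose expression a
#'   frame-breaking lesion in this gene would disrupt (polarity; used for AwsX
#'   suppressing AwsR).
#' @param validate check CDS invariants (start codon, terminal stop, no internal
#'   in-frame stop, length divisible by 3).
#' @return object of class `ws_gene`.
#' @export
gene_model <- function(gene_name, cds_seq, locus_tag = "", strand = "+",
                       genomic_start = NA_integer_, genomic_end = NA_integer_,
                       operon = gene_name, pathway = "other",
                       role = "structural", upstream_window = 300L,
                       polar_partner = NA_character_, validate = TRUE) {
  pathway <- match.arg(pathway,
                       c("Wsp", "Aws", "Mws", "DgcH", "PFL_3078", "other"))
  role <- match.arg(role, c("negative_regulator", "dgc", "interacting",
                            "promoter_only", "structural"))
  stopifnot(strand %in% c("+", "-"))
  g <- structure(list(
    gene_name = as.character(gene_name),
    locus_tag = as.character(locus_tag),
    cds_seq = toupper(as.character(cds_seq)),
    strand = strand,
    genomic_start = genomic_start,
    genomic_end = genomic_end,
    operon = as.character(operon),
    pathway = pathway,
    role = role,
    upstream_window = as.integer(upstream_window),
    polar_partner = polar_partner
  ), class = "ws_gene")
  if (validate) {
    errs <- validate_cds(g$cds_seq)
    if (length(errs)) {
      stop("invalid CDS for gene '", g$gene_name, "': ",
           paste(errs, collapse = "; "), call. = FALSE)
    }
  }
  g
}

#' Validate CDS invariants
#'
#' @param cds_seq DNA string.
#' @return character vector of violations (length 0 when valid). All
#'   violations are listed, not just the first.
#' @export
validate_cds <- function(cds_seq) {
  errs <- character()
  if (grepl("[^ACGT]", cds_seq)) {
    errs <- c(errs, "characters outside {A,C,G,T}")
    return(errs)
  }
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) {
    errs <- c(errs, sprintf("length %d not divisible by 3", n))
    return(errs)
  }
  if (n < 6L) errs <- c(errs, "shorter than two codons")
  codons <- codon_split(cds_seq)
  if (n >= 3L && !(codons[1L] %in% .start_codons)) {
    errs <- c(errs, sprintf("does not start with a start codon (ATG/GTG/TTG): %s",
                            codons[1L]))
  }
  if (n >= 3L && !(codons[length(codons)] %in% .stop_codons)) {
    errs <- c(errs, sprintf("does not end with a stop codon: %s",
                            codons[length(codons)]))
  }
  if (n >= 9L) {
    interior <- codons[2:(length(codons) - 1L)]
    hits <- which(interior %in% .stop_codons)
    if (length(hits)) {
      errs <- c(errs, sprintf("internal in-frame stop at codon %s",
                              paste(hits + 1L, collapse = ",")))
    }
  }
  errs
}

#' @export
print.ws_gene <- function(x, ...) {
  cat(sprintf("<ws_gene> %s (%s) pathway=%s role=%s, %d bp / %d aa\n",
              x$gene_name,
              if (nzchar(x$locus_tag)) x$locus_tag else "no locus tag",
              x$pathway, x$role, nchar(x$cds_seq), nchar(x$cds_seq) %/% 3L - 1L))
  invisible(x)
}

#' Protein length (excluding the terminal stop)
#' @param gene a `ws_gene`.
#' @return integer number of residues.
#' @export
protein_length <- function(gene) nchar(gene$cds_seq) %/% 3L - 1L

# --- FASTA / annotation ingestion --------------------------------------------

#' Read a (small) FASTA file
#'
#' Minimal plain-text FASTA reader used for the bundled fixtures; the first
#' whitespace-delimited token of each header is the record identifier.
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(toupper(gsub("\\s", "", seqs)), ids)
}

.parse_gff3_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) == 9L && f[3L] == "CDS",
                 logical(1))
  fields <- fields[keep]
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) >= 3L) m[3L] else ""
  }
  do.call(rbind, lapply(fields, function(f) {
    data.frame(gene_name = attr_val(f[9L], "gene"),
               locus_tag = attr_val(f[9L], "locus_tag"),
               seq_id = attr_val(f[9L], "ID"),
               operon = attr_val(f[9L], "operon"),
               pathway = attr_val(f[9L], "pathway"),
               role = attr_val(f[9L], "role"),
               upstream_window = attr_val(f[9L], "upstream_window"),
               polar_partner = attr_val(f[9L], "polar_partner"),
               strand = f[7L], stringsAsFactors = FALSE)
  }))
}

#' Load gene models from sequences plus annotation
#'
#' Two input layouts are supported: (i) a FASTA file plus a GFF3 annotation
#' whose CDS features carry `gene=`/`locus_tag=` attributes used for joining
#' (plus optional `pathway=`, `role=`, `operon=`, `upstream_window=`,
#' `polar_partner=`); or (ii) a single bundled-fixture TSV with columns
#' `gene_name, locus_tag, operon, pathway, role, upstream_window, cds_seq`
#' (optional `polar_partner`, `provenance`). In both cases every model is
#' validated and lookup by gene name and locus tag must be unique.
#'
#' @param annotation_path GFF3 or fixture-TSV path.
#' @param fasta_path FASTA path (required for GFF3 input, ignored for TSV with
#'   a `cds_seq` column).
#' @return named list of `ws_gene` objects (class `ws_gene_set`), keyed by
#'   gene name.
#' @export
load_gene_models <- function(annotation_path, fasta_path = NULL) {
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path, call. = FALSE)
  }
  first <- readLines(annotation_path, n = 5L, warn = FALSE)
  is_gff <- any(grepl("^##gff-version", first)) ||
    grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)
  if (is_gff) {
    ann <- .parse_gff3_annotation(annotation_path)
    if (is.null(fasta_path)) {
      stop("GFF3 annotation requires a FASTA file", call. = FALSE)
    }
    seqs <- read_fasta(fasta_path)
    key <- ifelse(nzchar(ann$seq_id), ann$seq_id, ann$gene_name)
    missing <- key[!(key %in% names(seqs))]
    if (length(missing)) {
      stop("missing sequence for annotated gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ann$cds_seq <- unname(seqs[key])
  } else {
    ann <- utils::read.delim(annotation_path, comment.char = "#",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("gene_name", "operon", "pathway", "role", "cds_seq")
    if (!all(need %in% names(ann))) {
      stop("fixture TSV lacks required columns: ",
           paste(setdiff(need, names(ann)), collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(ann$gene_name)) {
    stop("duplicate gene_name in annotation: ",
         paste(unique(ann$gene_name[duplicated(ann$gene_name)]),
               collapse = ", "), call. = FALSE)
  }
  tags <- ann$locus_tag[nzchar(ann$locus_tag %||% "")]
  if (anyDuplicated(tags)) {
    stop("duplicate locus_tag in annotation", call. = FALSE)
  }
  models <- lapply(seq_len(nrow(ann)), function(i) {
    r <- as.list(ann[i, ])
    gene_model(
      gene_name = r$gene_name,
      cds_seq = r$cds_seq,
      locus_tag = r$locus_tag %||% "",
      strand = if (!is.null(r$strand) && nzchar(r$strand)) r$strand else "+",
      operon = if (nzchar(r$operon %||% "")) r$operon else r$gene_name,
      pathway = if (nzchar(r$pathway %||% "")) r$pathway else "other",
      role = if (nzchar(r$role %||% "")) r$role else "structural",
      upstream_window = if (nzchar(r$upstream_window %||% "")) {
        as.integer(r$upstream_window)
      } else 300L,
      polar_partner = if (nzchar(r$polar_partner %||% "")) {
        r$polar_partner
      } else NA_character_
    )
  })
  names(models) <- ann$gene_name
  structure(models, class = "ws_gene_set")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Look up a gene model by name or locus tag
#' @param gene_models a `ws_gene_set`.
#' @param id gene name or locus tag.
#' @return the matching `ws_gene`; error if absent.
#' @export
get_gene <- function(gene_models, id) {
  if (id %in% names(gene_models)) return(gene_models[[id]])
  tags <- vapply(gene_models, `[[`, character(1), "locus_tag")
  hit <- which(tags == id)
  if (length(hit) == 1L) return(gene_models[[hit]])
  stop("unknown gene or locus tag: '", id, "'", call. = FALSE)
}

#' @export
print.ws_gene_set <- function(x, ...) {
  cat(sprintf("<ws_gene_set> %d genes: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Define a predicted region within (or upstream of) a gene
#'
#' Regions carry the mutational classes predicted to be WS-enabling there.
#' `aa_range` coordinates are protein residues; `nt_range` are CDS nucleotide
#' positions; `upstream` coordinates are <= 0 relative to the first CDS base.
#'
#' @param gene_name gene the region belongs to.
#' @param kind `"aa_range"`, `"nt_range"` or `"upstream"`.
#' @param start,end 1-based inclusive bounds in the coordinate system of
#'   `kind` (non-positive for `"upstream"`).
#' @param allowed_classes character vector of mutation classes predicted in the
#'   region (subset of `missense`, `nonsense`, `frameshift_indel`,
#'   `inframe_indel`, `promoter_point`, `promoter_capture`).
#' @return one-row data.frame.
#' @export
region <- function(gene_name, kind, start, end, allowed_classes) {
  kind <- match.arg(kind, c("aa_range", "nt_range", "upstream"))
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("region start > end", call. = FALSE)
  if (kind == "upstream" && end > 0L) {
    stop("upstream regions must have end <= 0", call. = FALSE)
  }
  data.frame(gene_name = gene_name, kind = kind, start = start, end = end,
             allowed_classes = paste(allowed_classes, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Load a region-definition TSV
#'
#' Columns: `gene_name, kind, start, end, allowed_classes` (comma-separated
#' classes); `#` comment lines allowed. aa ranges are checked against protein
#' lengths when gene models are supplied.
#'
#' @param path TSV path.
#' @param gene_models optional `ws_gene_set` for bounds checking.
#' @return data.frame of regions.
#' @export
load_regions <- function(path, gene_models = NULL) {
  reg <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_name", "kind", "start", "end", "allowed_classes")
  if (!all(need %in% names(reg))) {
    stop("region TSV lacks columns: ",
         paste(setdiff(need, names(reg)), collapse = ", "), call. = FALSE)
  }
  if (!is.null(gene_models)) {
    for (i in seq_len(nrow(reg))) {
      if (reg$kind[i] == "aa_range") {
        g <- get_gene(gene_models, reg$gene_name[i])
        if (reg$end[i] > protein_length(g)) {
          stop(sprintf("region %s:%d-%d exceeds protein length %d",
                       reg$gene_name[i], reg$start[i], reg$end[i],
                       protein_length(g)), call. = FALSE)
        }
      }
    }
  }
  reg
}
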