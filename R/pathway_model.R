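#' Default c-di-GMP pathway specifications
#'
#' Encodes the qualitative network logic of the three main wrinkly-spreader
#' pathways plus the rare routes carried at zero default weight:
#' \itemize{
#'   \item Wsp: WspA receptor -> (WspB/C/D scaffold) -> WspE kinase -> WspR
#'     DGC, with WspF the negative regulator (methylesterase).
#'   \item Aws: AwsO outer-membrane sensor, AwsX periplasmic inhibitor
#'     (negative regulator, polar onto AwsR), AwsR inner-membrane DGC.
#'   \item Mws: MwsR, a fused DGC-phosphodiesterase; loss of the
#'     phosphodiesterase/regulatory moiety is modelled as an `activating`
#'     state of the fused protein, whole-gene loss as `lof`.
#'   \item DgcH (PFL_0087) and the PFL_3078 polysaccharide promoter route.
#' }
#'
#' @param deleted character vector of pathway labels deleted from the genome.
#' @return named list of pathway specs (class `ws_pathway_specs`).
#' @export
pathway_specs <- function(deleted = character()) {
  spec <- list(
    Wsp = list(
      pathway = "Wsp",
      components = c(wspA = "interacting", wspB = "structural",
                     wspC = "structural", wspD = "structural",
                     wspE = "interacting", wspF = "negative_regulator",
                     wspR = "dgc"),
      dgc = "wspR", polar = character(0)),
    Aws = list(
      pathway = "Aws",
      components = c(awsO = "interacting", awsX = "negative_regulator",
                     awsR = "dgc"),
      dgc = "awsR", polar = c(awsX = "awsR")),
    Mws = list(
      pathway = "Mws",
      components = c(mwsR = "dgc_fused"),
      dgc = "mwsR", polar = character(0)),
    DgcH = list(
      pathway = "DgcH",
      components = c(dgcH = "dgc"),
      dgc = "dgcH", polar = character(0)),
    PFL_3078 = list(
      pathway = "PFL_3078",
      components = c(PFL_3078 = "structural"),
      dgc = NA_character_, polar = character(0))
  )
  for (p in names(spec)) spec[[p]]$deleted <- p %in% deleted
  structure(spec, class = "ws_pathway_specs")
}

.component_states <- c("wildtype", "lof", "lof_frame_breaking", "activating",
                       "absent")

#' Pathway output under a component-state assignment
#'
#' Rule-based genotype-to-phenotype logic for one pathway. States:
#' `wildtype`, `lof` (frame-preserving or point loss of function),
#' `lof_frame_breaking` (polar onto downstream operon partners),
#' `activating` (intragenic activation, incl. loss of the MwsR
#' phosphodiesterase moiety), `absent` (deleted).
#'
#' Output is `"none"` when the pathway cannot produce c-di-GMP at all (operon
#' deleted; DGC absent or inactivated; negative-regulator lesion polar onto
#' the DGC), `"high"` when the perturbation constitutively activates the DGC
#' (negative-regulator loss of function; activating lesion in the DGC or an
#' interacting component), and `"basal"` otherwise.
#'
#' @param spec one pathway spec from [pathway_specs()].
#' @param component_states named character vector component -> state;
#'   components not named are `wildtype`.
#' @return `"basal"`, `"high"` or `"none"`.
#' @export
ws_output <- function(spec, component_states = character()) {
  comps <- names(spec$components)
  states <- stats::setNames(rep("wildtype", length(comps)), comps)
  if (length(component_states)) {
    unknown_comp <- setdiff(names(component_states), comps)
    if (length(unknown_comp)) {
      stop("unknown component(s): ", paste(unknown_comp, collapse = ", "),
           call. = FALSE)
    }
    bad <- setdiff(component_states, .component_states)
    if (length(bad)) {
      stop("unknown component state(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    states[names(component_states)] <- component_states
  }
  if (isTRUE(spec$deleted)) return("none")
  dgc <- spec$dgc
  if (is.na(dgc)) return("basal")  # promoter-only route: no DGC logic
  if (states[dgc] %in% c("absent", "lof", "lof_frame_breaking")) return("none")
  # polar suppression: frame-breaking lesion upstream of the DGC in the operon
  for (src in names(spec$polar)) {
    if (states[src] == "lof_frame_breaking" && spec$polar[[src]] == dgc) {
      return("none")
    }
  }
  if (any(states == "activating")) return("high")
  roles <- spec$components
  neg <- names(roles)[roles == "negative_regulator"]
  if (length(neg) && any(states[neg] %in% c("lof", "lof_frame_breaking",
                                            "absent"))) {
    return("high")
  }
  "basal"
}

#' Map a (gene, mutation class) pair to a component state
#'
#' @param role component role (from the pathway spec).
#' @param mclass mutation class.
#' @param polar TRUE when the gene sits upstream of an operon partner so that
#'   frame-breaking lesions are polar.
#' @return a component state label.
#' @export
class_to_state <- function(role, mclass, polar = FALSE) {
  switch(mclass,
    nonsense = ,
    frameshift_indel = if (polar) "lof_frame_breaking" else "lof",
    inframe_indel = ,
    missense = switch(role,
      negative_regulator = "lof",
      dgc = , dgc_fused = , interacting = "activating",
      structural = "lof"),
    promoter_point = , promoter_capture = "wildtype",
    synonymous = "wildtype",
    "wildtype")
}

#' Is a (gene, class) perturbation WS-enabling?
#'
#' TRUE iff setting the single component's state implied by the mutation class
#' (all others wildtype) drives [ws_output()] to `"high"`. Promoter classes
#' are handled by rate weights, not network logic, and return FALSE here.
#'
#' @param gene_name component gene.
#' @param mclass mutation class.
#' @param specs pathway specs.
#' @return logical.
#' @export
ws_enabling <- function(gene_name, mclass, specs = pathway_specs()) {
  for (spec in specs) {
    if (gene_name %in% names(spec$components)) {
      role <- spec$components[[gene_name]]
      polar <- gene_name %in% names(spec$polar)
      st <- class_to_state(role, mclass, polar)
      if (st == "wildtype") return(FALSE)
      return(ws_output(spec, stats::setNames(st, gene_name)) == "high")
    }
  }
  FALSE
}

#' Null-model parameters
#'
#' @param rates named numeric: relative event rates for `substitution` (point
#'   substitutions: missense/nonsense targets), `indel` (+/-1 bp and
#'   repeat-deletion events: frameshift/in-frame targets) and
#'   `promoter_point`. At least one must be positive.
#' @param gene_weights named numeric per-gene multipliers (default 1); rare
#'   routes (dgcH, PFL_3078 promoter) are carried at weight 0 in the wild-type
#'   model and enabled in knockout scenarios.
#' @param normalization_scope `"three_pathways"` (Wsp/Aws/Mws, the scale the
#'   predicted fractions are printed on) or `"all_targets"`.
#' @param hot_spot_multipliers optional data.frame(gene_name, left_start,
#'   multiplier) applied to in-frame repeat-deletion events; default none.
#' @param calibration free-text record of any calibrated rate ratio.
#' @return list of class `ws_null_params`.
#' @export
null_model_params <- function(rates = c(substitution = 1, indel = 1,
                                        promoter_point = 0),
                              gene_weights = numeric(),
                              normalization_scope = "three_pathways",
                              hot_spot_multipliers = NULL,
                              calibration = "") {
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (!any(rates > 0)) stop("at least one positive rate", call. = FALSE)
  normalization_scope <- match.arg(normalization_scope,
                                   c("three_pathways", "all_targets"))
  structure(list(rates = rates, gene_weights = gene_weights,
                 normalization_scope = normalization_scope,
                 hot_spot_multipliers = hot_spot_multipliers,
                 calibration = calibration), class = "ws_null_params")
}

#' Read null-model parameters from a JSON config
#' @param path JSON file with keys `rates`, `gene_weights`,
#'   `normalization_scope`, `calibration`.
#' @return `ws_null_params`.
#' @export
load_null_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  null_model_params(
    rates = unlist(cfg$rates),
    gene_weights = if (!is.null(cfg$gene_weights)) unlist(cfg$gene_weights)
                   else numeric(),
    normalization_scope = cfg$normalization_scope %||% "three_pathways",
    calibration = cfg$calibration %||% "")
}

.class_rate <- function(mclass, rates) {
  switch(mclass,
    missense = , nonsense = , synonymous = rates[["substitution"]],
    frameshift_indel = , inframe_indel = rates[["indel"]],
    promoter_point = rates[["promoter_point"]],
    0)
}

#' Predict the multinomial mutant spectrum from targets and rates
#'
#' The null model: each WS-enabling (gene, class) pair contributes
#' `r_class * T_class(gene) * w_gene` to the gene's rate; probabilities are
#' the normalized rates over the chosen scope. Deleted pathways are excluded
#' before normalization.
#'
#' @param targets a `ws_target_table` (see [target_size_table()]).
#' @param params `ws_null_params`.
#' @param specs pathway specs (deletions encoded here).
#' @return list of class `ws_predicted_spectrum` with `gene_probs`,
#'   `pathway_probs`, `rate_weights` (unnormalized), `mu_relative`.
#' @export
predict_spectrum <- function(targets, params = null_model_params(),
                             specs = pathway_specs()) {
  stopifnot(inherits(targets, "ws_target_table") || is.data.frame(targets))
  deleted <- names(specs)[vapply(specs, function(s) isTRUE(s$deleted),
                                 logical(1))]
  t <- targets[!(targets$pathway %in% deleted), , drop = FALSE]
  scope <- params$normalization_scope
  if (scope == "three_pathways") {
    t <- t[t$pathway %in% c("Wsp", "Aws", "Mws"), , drop = FALSE]
  }
  if (nrow(t) == 0L) stop("no targets in scope", call. = FALSE)
  enab <- mapply(ws_enabling, t$gene_name, t$mclass,
                 MoreArgs = list(specs = specs))
  # promoter-point targets are carried by rate weight alone (no network state)
  enab <- enab | (t$mclass == "promoter_point")
  gw <- vapply(t$gene_name, function(g) {
    if (g %in% names(params$gene_weights)) params$gene_weights[[g]] else 1
  }, numeric(1))
  rc <- vapply(t$mclass, .class_rate, numeric(1), rates = params$rates)
  w <- ifelse(enab, rc * t$count * gw, 0)
  gene_w <- tapply(w, t$gene_name, sum)
  gene_w <- gene_w[gene_w > 0 | TRUE]
  total <- sum(gene_w)
  if (total <= 0) {
    stop("undefined spectrum: all rate-weighted targets are zero",
         call. = FALSE)
  }
  gene_probs <- gene_w / total
  gene_probs <- stats::setNames(as.numeric(gene_probs), names(gene_probs))
  pw <- t$pathway[match(names(gene_probs), t$gene_name)]
  pathway_probs <- tapply(gene_probs, pw, sum)
  pathway_probs <- stats::setNames(as.numeric(pathway_probs),
                                   names(pathway_probs))
  structure(list(gene_probs = gene_probs[order(names(gene_probs))],
                 pathway_probs = pathway_probs[order(-pathway_probs)],
                 rate_weights = stats::setNames(as.numeric(gene_w),
                                                names(gene_w)),
                 mu_relative = total),
            class = "ws_predicted_spectrum")
}

#' @export
print.ws_predicted_spectrum <- function(x, ...) {
  cat("<ws_predicted_spectrum>\n pathways: ",
      paste(sprintf("%s=%.1f%%", names(x$pathway_probs),
                    100 * x$pathway_probs), collapse = ", "), "\n")
  invisible(x)
}

#' Rank genes by predicted probability
#' @param predicted a `ws_predicted_spectrum`.
#' @return character vector of gene names, highest probability first; ties
#'   broken alphabetically (stable).
#' @export
rank_genes <- function(predicted) {
  p <- predicted$gene_probs
  names(p)[order(-p, names(p))]
}
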