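#' Selection coefficient from competition counts
#'
#' Implements the change in logarithmic ratio over time,
#' `s = ln(R(t) / R(0)) / t`, with `R` the mutant:reference CFU ratio after
#' dilution correction and `t` the number of whole-population generations
#' during the assay. `s = 0` is equal fitness; positive is increased fitness.
#'
#' Zeros: a zero mutant count at t0 leaves the ratio undefined (error); a zero
#' mutant count at t1 is reported as a left-censored estimate with a flagged
#' upper bound computed from a count of 1. A `pseudocount` of +0.5 on all four
#' counts can be enabled explicitly (off by default, because silent
#' pseudocounts bias small-s estimates).
#'
#' @param t0_mutant,t0_reference,t1_mutant,t1_reference CFU counts.
#' @param generations whole-population generations `t` (> 0).
#' @param dilution_t0,dilution_t1 plating dilution factors per timepoint;
#'   shared within a timepoint, so they cancel from the ratio, but are
#'   accepted for interface completeness.
#' @param pseudocount add 0.5 to all counts (flagged correction).
#' @return list of class `ws_selection`: `s`, `censored`, `bound`.
#' @examples
#' selection_coefficient(100, 10000, 1649, 100000, generations = 5)$s  # ~0.1
#' @export
selection_coefficient <- function(t0_mutant, t0_reference, t1_mutant,
                                  t1_reference, generations,
                                  dilution_t0 = 1, dilution_t1 = 1,
                                  pseudocount = FALSE) {
  if (generations <= 0) stop("generations must be > 0", call. = FALSE)
  if (t0_reference <= 0 || t1_reference <= 0) {
    stop("reference counts must be positive at both timepoints", call. = FALSE)
  }
  if (pseudocount) {
    t0_mutant <- t0_mutant + 0.5; t0_reference <- t0_reference + 0.5
    t1_mutant <- t1_mutant + 0.5; t1_reference <- t1_reference + 0.5
  }
  if (t0_mutant <= 0) {
    stop("zero mutant count at t0: ratio undefined (consider pseudocount = TRUE)",
         call. = FALSE)
  }
  # computed as a sum of individual logs so that dilution factors cancel and
  # swapping mutant and reference negates s bit-exactly
  log_ratio_change <- function(m1) {
    (log(m1) - log(t1_reference)) - (log(t0_mutant) - log(t0_reference))
  }
  censored <- FALSE
  bound <- NA_real_
  if (t1_mutant <= 0) {
    censored <- TRUE
    bound <- log_ratio_change(1) / generations
    s <- NA_real_
  } else {
    s <- log_ratio_change(t1_mutant) / generations
  }
  structure(list(s = s, censored = censored, bound = bound,
                 generations = generations), class = "ws_selection")
}

#' Selection coefficients for every row of a CFU table
#'
#' @param counts data.frame in the CFU TSV dialect: columns `strain_id,
#'   reference_id, assay, replicate, t0_mutant, t0_reference, t1_mutant,
#'   t1_reference, dilution_t0, dilution_t1, generations`.
#' @param pseudocount see [selection_coefficient()].
#' @return the input with columns `s`, `censored`, `bound` appended.
#' @export
selection_coefficients <- function(counts, pseudocount = FALSE) {
  est <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    selection_coefficient(r$t0_mutant, r$t0_reference, r$t1_mutant,
                          r$t1_reference, r$generations,
                          r$dilution_t0 %||% 1, r$dilution_t1 %||% 1,
                          pseudocount)
  })
  counts$s <- vapply(est, `[[`, numeric(1), "s")
  counts$censored <- vapply(est, `[[`, logical(1), "censored")
  counts$bound <- vapply(est, `[[`, numeric(1), "bound")
  counts
}

#' Load a competition-assay CFU TSV
#' @param path TSV path (UTF-8, tab-separated, `#` comments).
#' @return data.frame.
#' @export
load_cfu_table <- function(path) {
  if (!file.exists(path)) stop("CFU table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("strain_id", "reference_id", "assay", "replicate", "t0_mutant",
            "t0_reference", "t1_mutant", "t1_reference", "generations")
  if (!all(need %in% names(tab))) {
    stop("CFU table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab
}

#' Per-strain fitness summary and pairwise comparisons
#'
#' Mean, SD and t-based CI of `s` per strain, plus two-sided pairwise t-tests
#' of every strain against a named reference at level `alpha`, uncorrected
#' (the reproduction default) with Holm-adjusted p-values reported alongside.
#'
#' @param estimates data.frame with `strain_id` and `s` (e.g. from
#'   [selection_coefficients()]); censored rows are dropped with a message.
#' @param reference strain compared against (NULL skips comparisons).
#' @param alpha significance level for the labels.
#' @param conf_level CI level.
#' @return list with `summary` (per-strain data.frame) and `comparisons`.
#' @export
summarize_fitness <- function(estimates, reference = NULL, alpha = 0.05,
                              conf_level = 0.95) {
  if (any(is.na(estimates$s))) {
    message("dropping ", sum(is.na(estimates$s)), " censored estimate(s)")
    estimates <- estimates[!is.na(estimates$s), ]
  }
  by_strain <- split(estimates$s, estimates$strain_id)
  summ <- do.call(rbind, lapply(names(by_strain), function(st) {
    x <- by_strain[[st]]
    n <- length(x)
    m <- mean(x)
    sdev <- if (n >= 2L) stats::sd(x) else NA_real_
    if (n >= 2L && sdev > 0) {
      half <- stats::qt(1 - (1 - conf_level) / 2, n - 1L) * sdev / sqrt(n)
    } else {
      half <- 0
    }
    data.frame(strain_id = st, n = n, mean_s = m, sd = sdev,
               ci_lo = m - half, ci_hi = m + half,
               single_replicate = n < 2L, stringsAsFactors = FALSE)
  }))
  comparisons <- NULL
  if (!is.null(reference)) {
    if (!(reference %in% names(by_strain))) {
      stop("reference strain '", reference, "' absent from estimates",
           call. = FALSE)
    }
    others <- setdiff(names(by_strain), reference)
    comparisons <- do.call(rbind, lapply(others, function(st) {
      x <- by_strain[[st]]; y <- by_strain[[reference]]
      p <- if (length(x) >= 2L && length(y) >= 2L) {
        stats::t.test(x, y, alternative = "two.sided")$p.value
      } else NA_real_
      data.frame(strain_id = st, reference = reference, p = p,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(comparisons) && nrow(comparisons)) {
      comparisons$p_holm <- stats::p.adjust(comparisons$p, method = "holm")
      comparisons$significant <- !is.na(comparisons$p) & comparisons$p < alpha
      comparisons$alpha <- alpha
    }
  }
  list(summary = summ, comparisons = comparisons)
}

#' Classify an estimate as adaptive, neutral or deleterious
#'
#' Adaptive iff the CI excludes 0 from below; deleterious iff it excludes 0
#' from above; neutral when the CI spans 0.
#'
#' @param mean_s point estimate (or a one-row summary from
#'   [summarize_fitness()]).
#' @param ci_lo,ci_hi confidence bounds.
#' @return `"adaptive"`, `"neutral"` or `"deleterious"`.
#' @export
invasion_check <- function(mean_s, ci_lo, ci_hi) {
  if (is.data.frame(mean_s)) {
    ci_lo <- mean_s$ci_lo; ci_hi <- mean_s$ci_hi; mean_s <- mean_s$mean_s
  }
  stopifnot(ci_lo <= mean_s, mean_s <= ci_hi)
  if (ci_lo > 0) "adaptive" else if (ci_hi < 0) "deleterious" else "neutral"
}
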