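#' Whole-population generations between two census sizes
#' @param N0 initial population size.
#' @param Nf final population size.
#' @return `log2(Nf / N0)`.
#' @examples
#' generations_elapsed(1e3, 4e8)  # ~18.6
#' @export
generations_elapsed <- function(N0, Nf) {
  if (N0 <= 0 || Nf <= 0) stop("population sizes must be positive",
                               call. = FALSE)
  if (Nf <= N0) stop("Nf must exceed N0", call. = FALSE)
  log2(Nf / N0)
}

#' Static-microcosm simulation parameters
#'
#' Defaults mirror the experimental design: wells seeded with ~1e3 cells grow
#' to ~4e8; colony screening detects mutant classes above ~1% frequency;
#' 60 wells per experiment (30 central wells on two occasions).
#'
#' @param mu named numeric vector of absolute per-cell per-generation mutation
#'   rates to each mutant class (typically genes, from a predicted spectrum
#'   scaled by a total rate).
#' @param s named numeric selection coefficients per class (per-generation,
#'   Malthusian; same names as `mu`, or a single value recycled).
#' @param N0,Nf initial and final population sizes.
#' @param f_detect detection threshold frequency for colony screening.
#' @param wells wells per experiment.
#' @param sample_rule how the single colony is picked among detected classes:
#'   `"uniform"` (uniformly among detected classes) or `"frequency"`
#'   (proportional to endpoint frequency).
#' @param class_pathway optional named character vector class -> pathway used
#'   by [knockout()] and spectrum summaries.
#' @return list of class `ws_microcosm_params`.
#' @export
microcosm_params <- function(mu, s = 0.5, N0 = 1e3, Nf = 4e8,
                             f_detect = 0.01, wells = 60L,
                             sample_rule = c("uniform", "frequency"),
                             class_pathway = NULL) {
  sample_rule <- match.arg(sample_rule)
  if (any(mu < 0)) stop("mutation rates must be >= 0", call. = FALSE)
  if (N0 <= 0 || Nf <= N0) stop("need 0 < N0 < Nf", call. = FALSE)
  if (f_detect <= 0 || f_detect > 1) stop("need 0 < f_detect <= 1",
                                          call. = FALSE)
  if (is.null(names(mu))) names(mu) <- paste0("class", seq_along(mu))
  if (length(s) == 1L) s <- stats::setNames(rep(s, length(mu)), names(mu))
  stopifnot(all(names(mu) %in% names(s)))
  structure(list(mu = mu, s = s[names(mu)], N0 = N0, Nf = Nf,
                 f_detect = f_detect, wells = as.integer(wells),
                 sample_rule = sample_rule, class_pathway = class_pathway),
            class = "ws_microcosm_params")
}

# deterministic growth bookkeeping shared by the simulator and the analytic
# detection-probability approximation
.well_schedule <- function(params) {
  G <- ceiling(log2(params$Nf / params$N0))
  gens <- seq_len(G)
  N_before <- pmin(params$N0 * 2^(gens - 1L), params$Nf)
  list(G = G, gens = gens, N_before = N_before)
}

#' Simulate one static well
#'
#' Generation-stepped Luria-Delbruck-style scheme: the resident wild type
#' doubles deterministically each generation from `N0` to `Nf`; new mutant
#' lineages of class k arise in generation i as Poisson(mu_k * N_{i-1}) and
#' thereafter grow deterministically by a factor `2 * exp(s_k)` per
#' generation. Endpoint frequencies are lineage totals over (wild type +
#' mutants); classes with frequency >= `f_detect` are detected and a single
#' colony is sampled.
#'
#' @param params `ws_microcosm_params`.
#' @return list of class `ws_well`: `freq` (per class), `detected`
#'   (character), `sampled_mutant` (class label or `NA`).
#' @export
simulate_well <- function(params) {
  sch <- .well_schedule(params)
  k <- length(params$mu)
  # arrivals[class, generation]
  lam <- outer(params$mu, sch$N_before)
  arrivals <- matrix(stats::rpois(length(lam), lam), nrow = k)
  growth <- outer(params$s, sch$gens, function(s, g) {
    (sch$G - g) * (log(2) + s)
  })
  final_sizes <- arrivals * exp(growth)
  class_totals <- rowSums(final_sizes)
  freq <- class_totals / (params$Nf + sum(class_totals))
  names(freq) <- names(params$mu)
  detected <- names(freq)[freq >= params$f_detect]
  sampled <- NA_character_
  if (length(detected) == 1L) {
    sampled <- detected
  } else if (length(detected) > 1L) {
    w <- if (params$sample_rule == "frequency") freq[detected] else NULL
    sampled <- sample(detected, 1L, prob = w)
  }
  structure(list(freq = freq, detected = detected, sampled_mutant = sampled),
            class = "ws_well")
}

#' Simulate a replicate-well experiment
#'
#' @param params `ws_microcosm_params`.
#' @param n_wells number of wells (default `params$wells`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `ws_experiment`: `sampled` (data.frame well,
#'   sampled_mutant), `spectrum` (table of sampled classes over detecting
#'   wells), `detection_fraction`, `n_wells`, `seed`.
#' @export
simulate_experiment <- function(params, n_wells = params$wells, seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic subcommands",
                          call. = FALSE)
  set.seed(seed)
  sampled <- character(n_wells)
  any_det <- logical(n_wells)
  for (i in seq_len(n_wells)) {
    w <- simulate_well(params)
    sampled[i] <- w$sampled_mutant
    any_det[i] <- length(w$detected) > 0L
  }
  spec <- table(factor(sampled[!is.na(sampled)], levels = names(params$mu)))
  structure(list(
    sampled = data.frame(well = seq_len(n_wells), sampled_mutant = sampled,
                         stringsAsFactors = FALSE),
    spectrum = spec,
    detection_fraction = mean(any_det),
    n_wells = n_wells, seed = seed), class = "ws_experiment")
}

#' Zero out the mutational input of whole pathways
#'
#' Models operon deletion: mutation rates of member classes are set to zero;
#' everything else untouched.
#'
#' @param params `ws_microcosm_params` with a `class_pathway` map.
#' @param pathways pathway labels to delete.
#' @return modified `ws_microcosm_params`.
#' @export
knockout <- function(params, pathways) {
  if (length(pathways) == 0L) return(params)
  cp <- params$class_pathway
  if (is.null(cp)) stop("params lack a class_pathway map", call. = FALSE)
  unknown <- setdiff(pathways, unique(cp))
  if (length(unknown)) {
    stop("unknown pathway(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hit <- names(params$mu)[cp[names(params$mu)] %in% pathways]
  params$mu[hit] <- 0
  params
}

#' Analytic (Poisson-approximate) detection probability
#'
#' Probability that at least one mutant lineage reaches the detection
#' threshold, ignoring mutant mass in the denominator: a lineage born in
#' generation i reaches final size `(2 e^s)^(G - i)`, so only sufficiently
#' early arrivals are detectable; their total arrival intensity is summed and
#' detection is `1 - exp(-lambda)`.
#'
#' @param params `ws_microcosm_params`.
#' @param mu_scale multiplier applied to all rates.
#' @return probability in \code{[0, 1]}.
#' @export
detection_probability <- function(params, mu_scale = 1) {
  sch <- .well_schedule(params)
  lam_total <- 0
  for (k in seq_along(params$mu)) {
    sizes <- exp((sch$G - sch$gens) * (log(2) + params$s[[k]]))
    detectable <- sizes / (params$Nf + sizes) >= params$f_detect
    lam_total <- lam_total +
      sum(mu_scale * params$mu[[k]] * sch$N_before[detectable])
  }
  1 - exp(-lam_total)
}

#' Estimate the total mutation rate from an observed detection fraction
#'
#' Monotone bisection of [detection_probability()] in a common scale factor on
#' all class rates, until the match is within `precision`. The relative class
#' composition of `params$mu` is preserved; only the overall scale is fitted.
#'
#' @param observed_detection_fraction fraction of wells with >= 1 detection
#'   (strictly between 0 and 1).
#' @param params `ws_microcosm_params` whose `mu` fixes the relative class
#'   rates (overall scale irrelevant).
#' @param precision tolerance on the detection fraction.
#' @return list with `mu_total` (summed absolute rate), `scale`, `bracket`
#'   (the final bisection interval on the scale), `achieved`.
#' @export
estimate_total_rate <- function(observed_detection_fraction, params,
                                precision = 1e-4) {
  f <- observed_detection_fraction
  if (f <= 0 || f >= 1) stop("detection fraction must be in (0,1)",
                             call. = FALSE)
  if (sum(params$mu) <= 0) stop("params must carry positive rates",
                                call. = FALSE)
  lo <- 0
  hi <- 1
  while (detection_probability(params, hi) < f) {
    hi <- hi * 10
    if (hi > 1e12) {
      stop("detection fraction not bracketable under these parameters",
           call. = FALSE)
    }
  }
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (detection_probability(params, mid) < f) lo <- mid else hi <- mid
    if (abs(detection_probability(params, mid) - f) < precision) break
  }
  scale <- (lo + hi) / 2
  list(mu_total = scale * sum(params$mu), scale = scale,
       bracket = c(lo, hi) * sum(params$mu),
       achieved = detection_probability(params, scale))
}
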