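# Seeded synthetic-trial generator. The default design mirrors the field
# study the pipeline was built around: two regions (Jiangyou, Chenggu), eight
# treatments (five intercrops plus a monoculture control per region), 45
# biological replicates for agronomic traits and 4 for metabolite and soil
# traits, with multiplicative treatment effects and lognormal noise so every
# biomass/content trait stays strictly positive.

#' Construct a trial design
#'
#' @param treatments data frame with columns `treatment`, `region`,
#'   `is_control` (logical; exactly one control per region).
#' @param traits data frame with columns `trait`, `class` (one of
#'   `"agronomic"`, `"metabolite"`, `"soil"`), `control_mean` (> 0) and `cv`
#'   (coefficient of variation, > 0).
#' @param effects data frame with columns `treatment`, `trait`, `effect`
#'   (positive multiplier on the control mean). Pairs not listed default to
#'   1; controls always have effect 1.
#' @param n_replicates named integer vector giving the replicate count per
#'   trait class.
#' @param noise `"lognormal"` (default; multiplicative, keeps traits
#'   positive) or `"normal"` (additive, sd = cv * mean).
#' @param seed default random seed used by [generate_trial].
#' @return A `trial_design` list.
#' @seealso [default_trial_design] for the study-shaped default.
#' @export
trial_design <- function(treatments, traits, effects = NULL,
                         n_replicates = c(agronomic = 45L, metabolite = 4L,
                                          soil = 4L),
                         noise = c("lognormal", "normal"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(all(c("treatment", "region", "is_control") %in% names(treatments)),
            all(c("trait", "class", "control_mean", "cv") %in% names(traits)))
  if (anyDuplicated(treatments$treatment)) {
    stop("treatment labels must be unique")
  }
  ctrl_per_region <- tapply(treatments$is_control, treatments$region, sum)
  if (any(ctrl_per_region != 1)) {
    stop("each region must have exactly one control treatment")
  }
  if (any(traits$control_mean <= 0)) stop("control means must be positive")
  if (any(traits$cv <= 0)) stop("coefficients of variation must be positive")
  if (!all(traits$class %in% names(n_replicates))) {
    stop("n_replicates must cover every trait class")
  }
  if (!is.null(effects)) {
    stopifnot(all(c("treatment", "trait", "effect") %in% names(effects)))
    if (any(effects$effect <= 0)) stop("effects must be positive multipliers")
    unknown <- setdiff(effects$treatment, treatments$treatment)
    if (length(unknown)) {
      stop("effects refer to unknown treatment(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(treatments = treatments, traits = traits, effects = effects,
         n_replicates = n_replicates, noise = noise, seed = as.integer(seed)),
    class = "trial_design"
  )
}

effect_of <- function(design, treatment, trait) {
  if (design$treatments$is_control[match(treatment,
                                         design$treatments$treatment)]) {
    return(1)
  }
  e <- design$effects
  if (is.null(e)) return(1)
  hit <- e$effect[e$treatment == treatment & e$trait == trait]
  if (length(hit)) hit[1] else 1
}

#' Generate a synthetic replicate-level trial dataset
#'
#' For each treatment, trait and replicate, draws
#' `value = control_mean * effect * exp(eps - sigma^2 / 2)` with
#' `eps ~ Normal(0, sigma)` and `sigma = sqrt(log(1 + cv^2))` (lognormal
#' noise). The `-sigma^2/2` location shift makes the multiplier apply to the
#' arithmetic mean, so the configured effect's implied percent increment is
#' recovered exactly in expectation. Under `noise = "normal"` the draw is
#' `mean * effect + Normal(0, cv * mean * effect)` (may go non-positive; use
#' only where that is acceptable). Output is bit-identical for a fixed seed.
#'
#' @param design a [trial_design].
#' @param seed random seed (default: the design's seed).
#' @return Long-format data frame (`region`, `treatment`, `replicate`,
#'   `trait`, `value`) with the seed recorded in attribute `"seed"`.
#' @export
generate_trial <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(seed)
  trts <- design$treatments
  out <- vector("list", nrow(trts) * nrow(design$traits))
  k <- 0L
  for (i in seq_len(nrow(trts))) {
    for (j in seq_len(nrow(design$traits))) {
      tr <- design$traits[j, ]
      n <- design$n_replicates[[tr$class]]
      eff <- effect_of(design, trts$treatment[i], tr$trait)
      mu <- tr$control_mean * eff
      if (design$noise == "lognormal") {
        sigma <- sqrt(log(1 + tr$cv^2))
        value <- mu * exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
      } else {
        value <- mu + stats::rnorm(n, 0, tr$cv * mu)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        region = trts$region[i], treatment = trts$treatment[i],
        replicate = seq_len(n), trait = tr$trait, value = value,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- as.integer(seed)
  res
}

#' The study-shaped default trial design
#'
#' Two regions with eight treatments: J-maize, J-rice and J-control in
#' Jiangyou; C-peanut, C-sesame, C-maize, C-mung bean and C-control in
#' Chenggu. Agronomic traits use 45 replicates, metabolite and soil traits 4.
#' Default effect multipliers are fixtures calibrated so percent increments
#' fall in realistic intercropping ranges (aboveground biomass roughly
#' 83–201% above the control, Fuzi weight 58–179%, Chuanwu weight 45–104%,
#' soil pH gains averaging 8.8% in Jiangyou and 14.9% in Chenggu, disease
#' index reduced) — they emulate the design, they are not field estimates.
#'
#' @param seed default seed carried by the design.
#' @return A [trial_design].
#' @export
default_trial_design <- function(seed = 1L) {
  treatments <- data.frame(
    treatment = c("J-maize", "J-rice", "J-control",
                  "C-peanut", "C-sesame", "C-maize", "C-mung bean",
                  "C-control"),
    region = c(rep("Jiangyou", 3), rep("Chenggu", 5)),
    is_control = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  traits <- rbind(
    data.frame(trait = c("plant height", "stem diameter", "AGB", "FW", "CW",
                         "disease index"),
               class = "agronomic",
               control_mean = c(100, 8, 100, 30, 25, 30),
               cv = c(0.10, 0.12, 0.25, 0.25, 0.25, 0.30)),
    data.frame(trait = c("benzoylhypaconitine", "benzoylaconitine",
                         "benzoylmesaconitine", "hypaconitine", "aconitine",
                         "mesaconitine", "polysaccharide"),
               class = "metabolite",
               control_mean = c(0.15, 0.20, 0.25, 0.10, 0.05, 0.08, 50),
               cv = 0.15),
    data.frame(trait = c("pH", "organic matter", "total nitrogen", "NH4+-N",
                         "NO3--N", "phosphate", "K",
                         "amoA", "nxr", "narG", "nirS", "norB", "nosZ",
                         "nifH", "catalase", "invertase", "urease",
                         "acid phosphatase"),
               class = "soil",
               control_mean = c(6.0, 20, 1.2, 10, 15, 20, 150,
                                2e6, 1e6, 3e6, 2e6, 1e6, 1.5e6,
                                2.5e6, 2.0, 15, 0.8, 1.2),
               cv = c(0.03, rep(0.10, 17)))
  )
  intercrops <- c("J-maize", "J-rice", "C-peanut", "C-sesame", "C-maize",
                  "C-mung bean")
  eff <- function(trait, e) {
    data.frame(treatment = intercrops, trait = trait, effect = e,
               stringsAsFactors = FALSE)
  }
  effects <- rbind(
    # agronomic: increments within the realistic intercropping ranges above
    eff("AGB", c(2.60, 3.00, 2.10, 1.95, 2.30, 1.83)),
    eff("FW", c(2.00, 2.78, 2.20, 1.80, 2.40, 1.58)),
    eff("CW", c(1.70, 1.95, 1.85, 1.60, 2.04, 1.45)),
    eff("plant height", c(1.25, 1.30, 1.02, 1.02, 1.15, 1.00)),
    eff("stem diameter", c(1.20, 1.25, 1.15, 1.12, 1.18, 1.10)),
    eff("disease index", c(0.60, 0.50, 0.70, 0.75, 0.65, 0.80)),
    # metabolites: region-contrasting shifts
    eff("benzoylhypaconitine", c(1.50, 1.60, 1.40, 1.30, 1.35, 1.30)),
    eff("benzoylaconitine", c(0.70, 0.65, 0.85, 0.80, 0.75, 0.85)),
    eff("benzoylmesaconitine", c(0.75, 0.70, 0.85, 0.80, 0.75, 0.85)),
    eff("hypaconitine", c(1.40, 1.35, 0.80, 0.85, 0.75, 0.85)),
    eff("aconitine", c(0.70, 0.65, 1.25, 1.10, 0.70, 1.20)),
    eff("mesaconitine", c(0.75, 0.70, 1.20, 1.10, 0.75, 1.20)),
    eff("polysaccharide", c(1.35, 1.45, 1.25, 1.20, 1.30, 1.20)),
    # soil: pH gains average 8.8% in Jiangyou and 14.9% in Chenggu
    eff("pH", c(1.085, 1.091, 1.120, 1.160, 1.180, 1.136)),
    eff("organic matter", c(1.00, 1.30, 0.85, 0.80, 0.85, 0.90)),
    eff("total nitrogen", c(1.10, 1.20, 0.95, 0.95, 1.00, 1.00)),
    eff("NH4+-N", c(1.30, 1.40, 0.80, 1.25, 1.30, 0.85)),
    eff("NO3--N", c(0.75, 1.30, 1.00, 1.25, 0.80, 1.00)),
    eff("phosphate", c(1.30, 0.80, 1.00, 1.25, 1.30, 1.00)),
    eff("K", c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00)),
    eff("amoA", c(1.40, 1.50, 1.20, 1.25, 1.30, 1.20)),
    eff("nxr", c(0.85, 1.20, 0.80, 0.85, 0.80, 1.10)),
    eff("narG", c(1.30, 1.35, 1.15, 1.20, 1.25, 1.10)),
    eff("nirS", c(1.25, 1.30, 1.15, 1.20, 1.20, 1.10)),
    eff("norB", c(0.85, 1.20, 1.10, 1.15, 1.15, 1.05)),
    eff("nosZ", c(1.20, 1.25, 1.10, 0.90, 1.15, 1.05)),
    eff("nifH", c(1.30, 1.20, 1.15, 1.20, 1.25, 1.10)),
    eff("catalase", c(1.25, 1.30, 1.15, 1.10, 1.20, 1.10)),
    eff("invertase", c(1.20, 1.25, 1.10, 1.15, 1.15, 0.85)),
    eff("urease", c(1.25, 1.30, 1.15, 1.10, 1.20, 1.10)),
    eff("acid phosphatase", c(1.15, 0.85, 0.80, 1.10, 1.15, 1.05))
  )
  trial_design(treatments, traits, effects, seed = seed)
}

#' Assemble a treatment-by-indicator decision matrix from trial data
#'
#' Averages each indicator's trait over replicates within treatment and lays
#' the means out as a [decision_matrix], one row per treatment in order of
#' first appearance. Interval indicators (e.g. soil pH with optimum range
#' 7–8) are left untransformed — the interval handling belongs to
#' [run_topsis].
#'
#' @param data long-format trial data; run [derive_traits] first if the
#'   indicator set refers to derived traits such as `total MDA`.
#' @param indicators an [indicator_set] whose names resolve to traits in
#'   `data`.
#' @return A [decision_matrix] of treatment-level means.
#' @export
generate_indicator_matrix <- function(data, indicators) {
  validate_trial_data(data)
  stopifnot(inherits(indicators, "indicator_set"))
  unknown <- setdiff(indicators$name, unique(data$trait))
  if (length(unknown)) {
    stop("unknown indicator(s) with no matching trait: ",
         paste(unknown, collapse = ", "))
  }
  trts <- unique(data$treatment)
  values <- matrix(NA_real_, length(trts), nrow(indicators),
                   dimnames = list(trts, indicators$name))
  for (nm in indicators$name) {
    sub <- data[data$trait == nm, ]
    m <- tapply(sub$value, sub$treatment, mean)
    if (!all(trts %in% names(m))) {
      stop("trait '", nm, "' is missing for treatment(s): ",
           paste(setdiff(trts, names(m)), collapse = ", "))
    }
    values[, nm] <- m[trts]
  }
  decision_matrix(values, indicators, treatments = trts)
}

#' Default herb growth-and-quality indicator set
#'
#' Six equally weighted indicators of herb performance: Fuzi weight, Chuanwu
#' weight, aboveground biomass, total monoester diterpenoid alkaloids and
#' polysaccharide content as benefit criteria, and disease index as a cost
#' criterion. This is the package's own fixture layout for the six-indicator
#' herb evaluation; the original study's indicator weights are not public.
#'
#' @return An [indicator_set].
#' @export
herb_indicator_config <- function() {
  indicator_set(
    name = c("FW", "CW", "AGB", "total MDA", "polysaccharide",
             "disease index"),
    direction = c("benefit", "benefit", "benefit", "benefit", "benefit",
                  "cost"),
    weight = 1
  )
}

#' Default 17-parameter soil-quality indicator set
#'
#' The soil evaluation layout: pH (interval criterion, optimum range 7–8),
#' organic matter, ammonium and nitrate nitrogen, phosphate, potassium, seven
#' nitrogen-cycling gene abundances (amoA, nxr, narG, nirS, norB, nosZ,
#' nifH) and four soil enzyme activities (catalase, invertase, urease, acid
#' phosphatase), equally weighted, all benefit except the pH interval.
#'
#' @param ph_optimum numeric length-2 optimum soil pH range (default
#'   `c(7, 8)`).
#' @return An [indicator_set].
#' @export
soil_indicator_config <- function(ph_optimum = c(7, 8)) {
  nms <- c("pH", "organic matter", "NH4+-N", "NO3--N", "phosphate", "K",
           "amoA", "nxr", "narG", "nirS", "norB", "nosZ", "nifH",
           "catalase", "invertase", "urease", "acid phosphatase")
  indicator_set(
    name = nms,
    direction = c("interval", rep("benefit", 16)),
    weight = 1,
    interval_low = c(ph_optimum[1], rep(NA_real_, 16)),
    interval_high = c(ph_optimum[2], rep(NA_real_, 16))
  )
}

#' Generate a synthetic sample-by-taxon abundance table
#'
#' Dirichlet-multinomial draws: per sample, taxon proportions are drawn from
#' a Dirichlet distribution with parameters `concentration * prob * n_taxa`
#' and counts from a multinomial at the given depth. Low concentration gives
#' uneven, variable communities; as concentration grows the proportions
#' approach `prob` (so a uniform `prob` approaches perfect evenness).
#'
#' @param n_samples,n_taxa table dimensions (`n_taxa >= 2`).
#' @param concentration positive Dirichlet concentration.
#' @param prob base taxon proportions (default uniform; normalised to sum
#'   to 1).
#' @param depth sequencing depth (total count per sample).
#' @param seed random seed.
#' @param sample_prefix prefix for sample labels.
#' @return Integer matrix, samples in rows, taxa in columns; seed recorded in
#'   attribute `"seed"`.
#' @export
generate_taxon_table <- function(n_samples, n_taxa, concentration = 5,
                                 prob = NULL, depth = 10000L, seed = 1L,
                                 sample_prefix = "S") {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  if (!is.finite(concentration) || concentration <= 0) {
    stop("concentration must be positive")
  }
  if (is.null(prob)) prob <- rep(1 / n_taxa, n_taxa)
  if (length(prob) != n_taxa || any(prob < 0) || sum(prob) <= 0) {
    stop("prob must be a non-negative vector of length n_taxa")
  }
  prob <- prob / sum(prob)
  set.seed(seed)
  alpha <- concentration * prob * n_taxa
  counts <- matrix(0L, n_samples, n_taxa,
                   dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                   paste0("taxon", seq_len(n_taxa))))
  for (i in seq_len(n_samples)) {
    g <- stats::rgamma(n_taxa, shape = alpha)
    while (sum(g) == 0) g <- stats::rgamma(n_taxa, shape = alpha)
    counts[i, ] <- as.integer(stats::rmultinom(1L, depth, g / sum(g)))
  }
  attr(counts, "seed") <- as.integer(seed)
  counts
}
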