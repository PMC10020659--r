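#' Define a set of evaluation indicators
#'
#' An indicator set describes the columns of a decision matrix: each indicator
#' has a direction (benefit: larger is better; cost: smaller is better;
#' interval: best inside an optimum range), a non-negative weight, and — for
#' interval indicators — the bounds of the optimum range. Soil pH with an
#' optimum growth range of 7–8 is the canonical interval case here.
#'
#' Weights need not sum to one; they are normalised to sum to one before use.
#'
#' @param name character vector of unique indicator names.
#' @param direction character vector, one of `"benefit"`, `"cost"`,
#'   `"interval"` per indicator (recycled if length 1).
#' @param weight non-negative numeric weights (default: equal). Recycled if
#'   length 1.
#' @param interval_low,interval_high numeric bounds of the optimum range,
#'   required (and only used) where `direction == "interval"`.
#' @return A data frame of class `indicator_set` with one row per indicator.
#' @examples
#' indicator_set(c("yield", "disease index"), c("benefit", "cost"))
#' @export
indicator_set <- function(name, direction = "benefit", weight = 1,
                          interval_low = NA_real_, interval_high = NA_real_) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("indicator names must be unique")
  }
  n <- length(name)
  direction <- rep_len(as.character(direction), n)
  bad <- setdiff(direction, c("benefit", "cost", "interval"))
  if (length(bad)) {
    stop("unknown indicator direction(s): ", paste(bad, collapse = ", "))
  }
  weight <- rep_len(as.numeric(weight), n)
  if (any(!is.finite(weight)) || any(weight < 0)) {
    stop("indicator weights must be finite and non-negative")
  }
  interval_low <- rep_len(as.numeric(interval_low), n)
  interval_high <- rep_len(as.numeric(interval_high), n)
  iv <- direction == "interval"
  if (any(iv & (is.na(interval_low) | is.na(interval_high)))) {
    stop("interval indicators require both interval_low and interval_high")
  }
  if (any(iv & interval_low > interval_high, na.rm = TRUE)) {
    stop("interval_low must not exceed interval_high")
  }
  out <- data.frame(
    name = name, direction = direction, weight = weight,
    interval_low = interval_low, interval_high = interval_high,
    stringsAsFactors = FALSE
  )
  class(out) <- c("indicator_set", "data.frame")
  out
}

#' Construct a decision matrix
#'
#' The TOPSIS input: one row per treatment (alternative), one column per
#' indicator. All entries must be finite; at least two treatments and one
#' indicator are required.
#'
#' @param values numeric matrix (or coercible) of indicator values; row names
#'   are taken as treatment labels unless `treatments` is given.
#' @param indicators an [indicator_set] whose rows match the columns of
#'   `values` (matched by name when `values` has column names).
#' @param treatments optional character vector of unique treatment labels.
#' @return An object of class `decision_matrix`: a list with elements
#'   `values`, `treatments` and `indicators`.
#' @export
decision_matrix <- function(values, indicators, treatments = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(treatments)) treatments <- rownames(values)
  if (is.null(treatments)) treatments <- paste0("alt", seq_len(nrow(values)))
  treatments <- as.character(treatments)
  if (!inherits(indicators, "indicator_set")) {
    stop("'indicators' must be an indicator_set")
  }
  if (!is.null(colnames(values))) {
    m <- match(colnames(values), indicators$name)
    if (anyNA(m)) {
      stop("matrix column(s) without a matching indicator: ",
           paste(colnames(values)[is.na(m)], collapse = ", "))
    }
    indicators <- indicators[m, , drop = FALSE]
  } else if (ncol(values) == nrow(indicators)) {
    colnames(values) <- indicators$name
  }
  if (ncol(values) != nrow(indicators)) {
    stop("number of matrix columns and indicators differ")
  }
  if (nrow(values) < 2L) stop("a decision matrix needs at least 2 treatments")
  if (ncol(values) < 1L) stop("a decision matrix needs at least 1 indicator")
  if (anyDuplicated(treatments)) stop("treatment labels must be unique")
  if (length(treatments) != nrow(values)) {
    stop("length of treatment labels does not match the number of rows")
  }
  if (any(!is.finite(values))) {
    stop("decision matrix entries must all be finite (no missing values)")
  }
  rownames(values) <- treatments
  structure(
    list(values = values, treatments = treatments, indicators = indicators),
    class = "decision_matrix"
  )
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("Decision matrix: %d treatments x %d indicators\n",
              nrow(x$values), ncol(x$values)))
  dirs <- table(factor(x$indicators$direction,
                       levels = c("benefit", "cost", "interval")))
  cat(sprintf("  directions: %d benefit, %d cost, %d interval\n",
              dirs[["benefit"]], dirs[["cost"]], dirs[["interval"]]))
  print(x$values, ...)
  invisible(x)
}

#' Interval (optimum-range) transformation
#'
#' Maps values of an interval criterion onto `[0, 1]` so that it can be
#' treated as a benefit criterion: values inside the optimum range
#' `[lower_bound, upper_bound]` map to 1, and values outside are penalised
#' linearly by their distance to the nearest bound, scaled by
#' `M = max(lower_bound - min(x), max(x) - upper_bound)`.
#'
#' When every observation lies below the lower bound — the soil pH situation
#' this transform was built for, with an optimum range of pH 7–8 — the formula
#' reduces exactly to `(x - min(x)) / (lower_bound - min(x))`, i.e. the most
#' acidic sample scores 0 and a sample at the bound scores 1.
#'
#' @param values numeric vector of raw observations (at least one).
#' @param lower_bound,upper_bound bounds of the optimum range,
#'   `lower_bound <= upper_bound`.
#' @return A list with `values` (the transformed vector in `[0, 1]`) and
#'   `params`, an `interval_transform_params` record holding the bounds, the
#'   observed range and the scale `M` actually used.
#' @examples
#' transform_interval(c(6.0, 6.5, 6.8), 7, 8)$values # 0.0 0.5 0.8
#' @export
transform_interval <- function(values, lower_bound, upper_bound) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("transform_interval: empty input")
  if (any(!is.finite(values))) stop("transform_interval: non-finite values")
  if (!is.finite(lower_bound) || !is.finite(upper_bound) ||
      lower_bound > upper_bound) {
    stop("transform_interval: need finite lower_bound <= upper_bound")
  }
  lo <- min(values)
  hi <- max(values)
  M <- max(lower_bound - lo, hi - upper_bound)
  out <- rep(1, length(values))
  if (M > 0) {
    below <- values < lower_bound
    above <- values > upper_bound
    out[below] <- 1 - (lower_bound - values[below]) / M
    out[above] <- 1 - (values[above] - upper_bound) / M
  }
  # all inside the optimum range: M <= 0 and everything stays at 1
  params <- structure(
    list(lower_bound = lower_bound, upper_bound = upper_bound,
         observed_min = lo, observed_max = hi, scale = M),
    class = "interval_transform_params"
  )
  list(values = out, params = params)
}

#' Normalise a decision matrix
#'
#' Vector normalisation divides each column by its Euclidean norm (the usual
#' TOPSIS choice; scale-invariant, directions untouched). Min-max
#' normalisation rescales benefit columns by `(x - min)/(max - min)` and cost
#' columns by `(max - x)/(max - min)`, after which every column is a benefit
#' column.
#'
#' Interval indicators must be transformed to benefit (see
#' [transform_interval]) before normalisation; [run_topsis] does this
#' automatically.
#'
#' @param matrix a [decision_matrix] with no interval columns left raw.
#' @param method `"vector"` (default) or `"minmax"`.
#' @return A [decision_matrix] of dimensionless values.
#' @export
normalize_matrix <- function(matrix, method = c("vector", "minmax")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "decision_matrix"))
  v <- matrix$values
  ind <- matrix$indicators
  if (method == "vector") {
    nrm <- sqrt(colSums(v^2))
    zero <- nrm == 0
    if (any(zero)) {
      stop("vector normalization undefined for all-zero column(s): ",
           paste(ind$name[zero], collapse = ", "))
    }
    v <- sweep(v, 2L, nrm, "/")
  } else {
    cmin <- apply(v, 2L, min)
    cmax <- apply(v, 2L, max)
    const <- cmax == cmin
    if (any(const)) {
      stop("minmax normalization undefined for constant column(s): ",
           paste(ind$name[const], collapse = ", "))
    }
    for (j in seq_len(ncol(v))) {
      if (ind$direction[j] == "cost") {
        v[, j] <- (cmax[j] - v[, j]) / (cmax[j] - cmin[j])
      } else {
        v[, j] <- (v[, j] - cmin[j]) / (cmax[j] - cmin[j])
      }
    }
    ind$direction <- "benefit" # cost columns are inverted by minmax
  }
  out <- matrix
  out$values <- v
  out$indicators <- ind
  out
}

#' Positive and negative ideal solutions
#'
#' The positive ideal takes the column maximum for benefit columns and the
#' column minimum for cost columns; the negative ideal is the opposite.
#' Interval columns are assumed already transformed to benefit.
#'
#' @param weighted a weighted, normalised [decision_matrix].
#' @return A list with numeric vectors `positive` and `negative`, one entry
#'   per indicator.
#' @export
ideal_solutions <- function(weighted) {
  stopifnot(inherits(weighted, "decision_matrix"))
  v <- weighted$values
  dir <- weighted$indicators$direction
  cmax <- apply(v, 2L, max)
  cmin <- apply(v, 2L, min)
  is_cost <- dir == "cost"
  positive <- ifelse(is_cost, cmin, cmax)
  negative <- ifelse(is_cost, cmax, cmin)
  names(positive) <- names(negative) <- weighted$indicators$name
  list(positive = positive, negative = negative)
}

#' Euclidean distances to the ideal solutions
#'
#' @param weighted a weighted, normalised [decision_matrix].
#' @param positive_ideal,negative_ideal numeric vectors as returned by
#'   [ideal_solutions].
#' @return A list with numeric vectors `d_plus` and `d_minus` (one entry per
#'   treatment), each non-negative.
#' @export
topsis_distances <- function(weighted, positive_ideal, negative_ideal) {
  stopifnot(inherits(weighted, "decision_matrix"))
  v <- weighted$values
  if (length(positive_ideal) != ncol(v) || length(negative_ideal) != ncol(v)) {
    stop("ideal solution length does not match the number of indicators")
  }
  d_plus <- sqrt(rowSums(sweep(v, 2L, positive_ideal, "-")^2))
  d_minus <- sqrt(rowSums(sweep(v, 2L, negative_ideal, "-")^2))
  names(d_plus) <- names(d_minus) <- weighted$treatments
  list(d_plus = d_plus, d_minus = d_minus)
}

#' Closeness coefficient
#'
#' The comprehensive benefit evaluation index
#' `Ci = Di- / (Di+ + Di-)`: 1 means the alternative sits at the positive
#' ideal, 0 at the negative ideal. Vectorised over alternatives.
#'
#' @param d_plus,d_minus non-negative distances to the positive and negative
#'   ideal solutions.
#' @return Numeric vector of closeness values in `[0, 1]`.
#' @examples
#' closeness(0.023, 0.106) # 0.8217...
#' @export
closeness <- function(d_plus, d_minus) {
  d_plus <- as.numeric(d_plus)
  d_minus <- as.numeric(d_minus)
  if (length(d_plus) != length(d_minus)) {
    stop("d_plus and d_minus must have the same length")
  }
  if (any(!is.finite(d_plus)) || any(!is.finite(d_minus)) ||
      any(d_plus < 0) || any(d_minus < 0)) {
    stop("distances must be finite and non-negative")
  }
  den <- d_plus + d_minus
  if (any(den == 0)) {
    stop("closeness undefined: d_plus and d_minus both zero for ",
         "alternative(s) ", paste(which(den == 0), collapse = ", "))
  }
  d_minus / den
}

#' Rank alternatives by closeness
#'
#' Rank 1 is assigned to the largest closeness value. Ties are broken by
#' stable input order (the earlier alternative gets the better rank), so the
#' result is always a permutation of `1..n`.
#'
#' @param closeness numeric vector of finite closeness values.
#' @return Integer ranks, 1 = best.
#' @export
rank_by_closeness <- function(closeness) {
  closeness <- as.numeric(closeness)
  if (any(!is.finite(closeness))) stop("closeness values must be finite")
  as.integer(rank(-closeness, ties.method = "first"))
}

#' Entropy weights for a decision matrix
#'
#' Information-entropy weighting: columns whose values vary more across
#' alternatives carry more information and receive larger weights. The matrix
#' is min-max normalised column-wise (cost columns inverted), column shares
#' `p_ij = r_ij / sum_i r_ij` are formed, the entropy
#' `e_j = -(1/ln n) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`) is computed,
#' and weights are `w_j = (1 - e_j) / sum_k (1 - e_k)`. A constant column has
#' entropy 1 and weight 0.
#'
#' @param matrix a [decision_matrix].
#' @return Numeric weight vector summing to 1, named by indicator.
#' @export
entropy_weights <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  v <- matrix$values
  dir <- matrix$indicators$direction
  n <- nrow(v)
  e <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    cmin <- min(v[, j]); cmax <- max(v[, j])
    if (cmax == cmin) {
      e[j] <- 1 # constant column: no information
      next
    }
    r <- if (dir[j] == "cost") (cmax - v[, j]) / (cmax - cmin)
         else (v[, j] - cmin) / (cmax - cmin)
    s <- sum(r)
    if (s == 0) {
      e[j] <- 1
      next
    }
    p <- r / s
    plogp <- ifelse(p > 0, p * log(p), 0)
    e[j] <- -sum(plogp) / log(n)
  }
  d <- 1 - e
  if (all(d == 0)) {
    stop("entropy weights undefined: every column is constant")
  }
  w <- d / sum(d)
  names(w) <- matrix$indicators$name
  w
}

topsis_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("TOPSIS stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full TOPSIS evaluation
#'
#' Composes the whole comprehensive-evaluation chain: interval columns are
#' transformed to benefit via [transform_interval], the matrix is normalised,
#' indicator weights (normalised to sum to 1) are applied column-wise, the
#' positive and negative ideal solutions are located, Euclidean distances and
#' closeness coefficients are computed, and alternatives are ranked.
#'
#' Errors raised by any stage are re-signalled with the failing stage named.
#'
#' @param matrix a [decision_matrix] with directions, weights and (for
#'   interval indicators) optimum bounds.
#' @param normalize normalisation method, `"vector"` (default) or `"minmax"`.
#' @param weighting `"config"` (use the indicator weights, default),
#'   `"equal"`, or `"entropy"` ([entropy_weights] computed from the raw
#'   matrix).
#' @return A `topsis_result`: a data frame with columns `treatment`,
#'   `d_plus`, `d_minus`, `closeness`, `rank`, plus attributes `weights`,
#'   `normalization` and `interval_params`.
#' @examples
#' m <- decision_matrix(rbind(a = c(1, 1), b = c(2, 2), c = c(3, 3)),
#'                      indicator_set(c("x", "y")))
#' run_topsis(m)
#' @export
run_topsis <- function(matrix, normalize = c("vector", "minmax"),
                       weighting = c("config", "equal", "entropy")) {
  normalize <- match.arg(normalize)
  weighting <- match.arg(weighting)
  stopifnot(inherits(matrix, "decision_matrix"))

  w <- topsis_stage("weighting", switch(weighting,
    config = matrix$indicators$weight,
    equal = rep(1, ncol(matrix$values)),
    entropy = entropy_weights(matrix)
  ))
  if (sum(w) <= 0) {
    stop("TOPSIS stage 'weighting': weights must not all be zero",
         call. = FALSE)
  }
  w <- w / sum(w)
  names(w) <- matrix$indicators$name

  interval_params <- list()
  m <- matrix
  for (j in which(m$indicators$direction == "interval")) {
    tr <- topsis_stage("interval transform", transform_interval(
      m$values[, j],
      m$indicators$interval_low[j],
      m$indicators$interval_high[j]
    ))
    m$values[, j] <- tr$values
    m$indicators$direction[j] <- "benefit"
    interval_params[[m$indicators$name[j]]] <- tr$params
  }

  m <- topsis_stage("normalization", normalize_matrix(m, normalize))
  m$values <- sweep(m$values, 2L, w, "*")
  ideals <- topsis_stage("ideal solutions", ideal_solutions(m))
  d <- topsis_stage("distances",
                    topsis_distances(m, ideals$positive, ideals$negative))
  ci <- topsis_stage("closeness", closeness(d$d_plus, d$d_minus))
  rk <- topsis_stage("ranking", rank_by_closeness(ci))

  out <- data.frame(
    treatment = matrix$treatments,
    d_plus = unname(d$d_plus),
    d_minus = unname(d$d_minus),
    closeness = unname(ci),
    rank = rk,
    stringsAsFactors = FALSE
  )
  attr(out, "weights") <- w
  attr(out, "normalization") <- normalize
  attr(out, "interval_params") <- interval_params
  class(out) <- c("topsis_result", "data.frame")
  out
}

#' @export
print.topsis_result <- function(x, digits = 3, ...) {
  cat("TOPSIS comprehensive evaluation (", attr(x, "normalization"),
      " normalization)\n", sep = "")
  y <- as.data.frame(x)
  y$d_plus <- round(y$d_plus, digits)
  y$d_minus <- round(y$d_minus, digits)
  y$closeness <- round(y$closeness, digits)
  print(y[order(y$rank), ], row.names = FALSE, ...)
  invisible(x)
}
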