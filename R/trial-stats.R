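validate_trial_data <- function(data) {
  need <- c("region", "treatment", "replicate", "trait", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("trial data is missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(data$region, data$treatment, data$replicate, data$trait,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (region, treatment, replicate, trait) record(s)")
  }
  reg_per_trt <- tapply(data$region, data$treatment,
                        function(r) length(unique(r)))
  if (any(reg_per_trt > 1)) {
    stop("treatment(s) appear in more than one region: ",
         paste(names(reg_per_trt)[reg_per_trt > 1], collapse = ", "))
  }
  invisible(data)
}

# Component traits summed into each derived trait. Totals follow the
# pharmacopoeial definitions: total monoester / diester diterpenoid alkaloid
# contents are sums of three named compounds each.
derived_trait_parts <- list(
  "total underground" = c("CW", "FW"),
  "total MDA" = c("benzoylhypaconitine", "benzoylaconitine",
                  "benzoylmesaconitine"),
  "total DDA" = c("hypaconitine", "aconitine", "mesaconitine")
)

#' Add derived agronomic, quality and soil traits
#'
#' Augments a replicate-level long-format trial dataset with the standard
#' derived traits:
#' \itemize{
#'   \item `total underground` = Chuanwu weight (`CW`) + Fuzi weight (`FW`);
#'   \item `total biomass` = aboveground biomass (`AGB`) + total underground;
#'   \item `root/shoot ratio` = total underground / `AGB`;
#'   \item `total MDA` = benzoylhypaconitine + benzoylaconitine +
#'     benzoylmesaconitine (monoester diterpenoid alkaloids);
#'   \item `total DDA` = hypaconitine + aconitine + mesaconitine (diester
#'     diterpenoid alkaloids);
#'   \item `total alkaloids` = total MDA + total DDA;
#'   \item `organic carbon` = `organic matter` * `om_to_oc` (van Bemmelen
#'     factor by default) when organic carbon is not itself measured;
#'   \item `C/N ratio` = organic carbon / `total nitrogen`, for replicates
#'     where both are present.
#' }
#'
#' A derived trait is only computed for replicates carrying its components;
#' a replicate with some but not all components present is an error naming
#' the replicate and the missing trait.
#'
#' @param data long-format trial data with columns `region`, `treatment`,
#'   `replicate`, `trait`, `value`.
#' @param om_to_oc conversion factor from soil organic matter to organic
#'   carbon (default `1/1.724`, the van Bemmelen factor).
#' @return The input data with derived-trait records appended.
#' @export
derive_traits <- function(data, om_to_oc = 1 / 1.724) {
  validate_trial_data(data)
  traits <- unique(data$trait)
  keys <- unique(data[, c("region", "treatment", "replicate")])
  rownames(keys) <- NULL
  kid <- function(r, t, p) paste(r, t, p, sep = "\r")
  row_of <- match(kid(data$region, data$treatment, data$replicate),
                  kid(keys$region, keys$treatment, keys$replicate))
  wide <- matrix(NA_real_, nrow(keys), length(traits),
                 dimnames = list(NULL, traits))
  wide[cbind(row_of, match(data$trait, traits))] <- data$value

  get_col <- function(nm) {
    if (nm %in% colnames(wide)) wide[, nm] else rep(NA_real_, nrow(keys))
  }
  add_col <- function(nm, x) {
    wide <<- cbind(wide, matrix(x, ncol = 1, dimnames = list(NULL, nm)))
  }
  sum_parts <- function(new, parts) {
    if (!any(parts %in% colnames(wide))) return(invisible(NULL))
    absent <- setdiff(parts, colnames(wide))
    if (length(absent)) {
      stop(sprintf("cannot derive '%s': component trait '%s' is absent",
                   new, absent[1]))
    }
    have <- !is.na(wide[, parts, drop = FALSE])
    k <- rowSums(have)
    partial <- which(k > 0 & k < length(parts))
    if (length(partial)) {
      i <- partial[1]
      missing_part <- parts[!have[i, ]][1]
      stop(sprintf(
        "cannot derive '%s': replicate %s of %s (%s) is missing component trait '%s'",
        new, keys$replicate[i], keys$treatment[i], keys$region[i],
        missing_part))
    }
    x <- rowSums(wide[, parts, drop = FALSE])
    x[k == 0] <- NA_real_
    add_col(new, x)
  }

  for (nm in names(derived_trait_parts)) {
    sum_parts(nm, derived_trait_parts[[nm]])
  }
  if (!("organic carbon" %in% colnames(wide)) &&
      "organic matter" %in% colnames(wide)) {
    add_col("organic carbon", get_col("organic matter") * om_to_oc)
  }
  sum_parts("total biomass", c("AGB", "total underground"))
  if (all(c("AGB", "total underground") %in% colnames(wide))) {
    add_col("root/shoot ratio", get_col("total underground") / get_col("AGB"))
  }
  sum_parts("total alkaloids", c("total MDA", "total DDA"))
  if (all(c("organic carbon", "total nitrogen") %in% colnames(wide))) {
    add_col("C/N ratio", get_col("organic carbon") / get_col("total nitrogen"))
  }

  new_traits <- setdiff(colnames(wide), traits)
  if (!length(new_traits)) return(data)
  pieces <- lapply(new_traits, function(nm) {
    x <- wide[, nm]
    ok <- !is.na(x)
    if (!any(ok)) return(NULL)
    data.frame(region = keys$region[ok], treatment = keys$treatment[ok],
               replicate = keys$replicate[ok], trait = nm, value = x[ok],
               stringsAsFactors = FALSE)
  })
  out <- rbind(data[, c("region", "treatment", "replicate", "trait", "value")],
               do.call(rbind, pieces))
  rownames(out) <- NULL
  for (a in setdiff(names(attributes(data)), c("names", "row.names", "class"))) {
    attr(out, a) <- attr(data, a)
  }
  out
}

find_control <- function(data, region, controls = NULL) {
  trts <- unique(data$treatment[data$region == region])
  if (!is.null(controls)) {
    if (!region %in% names(controls)) {
      stop("no control treatment supplied for region ", region)
    }
    ctrl <- controls[[region]]
  } else {
    ctrl <- trts[grepl("control", trts, ignore.case = TRUE)]
  }
  if (length(ctrl) != 1L || !ctrl %in% trts) {
    stop("region ", region, " must have exactly one control treatment")
  }
  ctrl
}

stars_for_p <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Treatment-versus-control effect summary for one trait
#'
#' Computes the percent increment of a treatment over its region's control,
#' `100 * (treatment_mean - control_mean) / control_mean`, together with a
#' two-sided two-sample t-test p-value (Welch by default) and significance
#' stars at the 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param data long-format trial data (see [derive_traits]).
#' @param trait trait name.
#' @param treatment treatment label (must not be the control itself).
#' @param controls optional named character vector mapping region to its
#'   control treatment; by default the treatment whose label contains
#'   "control" is used.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return A one-row data frame: `region`, `treatment`, `trait`,
#'   `control_mean`, `treatment_mean`, `increment_pct`, `p_value`, `stars`.
#' @export
increment_vs_control <- function(data, trait, treatment, controls = NULL,
                                 var_equal = FALSE) {
  validate_trial_data(data)
  rows <- data$treatment == treatment & data$trait == trait
  if (!any(rows)) {
    stop("no records for treatment '", treatment, "', trait '", trait, "'")
  }
  region <- unique(data$region[rows])
  ctrl <- find_control(data, region, controls)
  if (identical(ctrl, treatment)) {
    stop("'", treatment, "' is the control of region ", region)
  }
  y <- data$value[rows]
  x <- data$value[data$treatment == ctrl & data$trait == trait]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 replicates in both the treatment and the control")
  }
  cm <- mean(x)
  tm <- mean(y)
  if (cm == 0) stop("control mean is zero: percent increment undefined")
  tt <- stats::t.test(y, x, var.equal = var_equal)
  p <- unname(tt$p.value)
  data.frame(
    region = region, treatment = treatment, trait = trait,
    control_mean = cm, treatment_mean = tm,
    increment_pct = 100 * (tm - cm) / cm,
    p_value = p, stars = stars_for_p(p),
    stringsAsFactors = FALSE
  )
}

#' Effect summaries for every treatment-by-trait combination
#'
#' Convenience wrapper looping [increment_vs_control] over all non-control
#' treatments and all (or selected) traits.
#'
#' @inheritParams increment_vs_control
#' @param traits optional subset of traits (default: all traits measured for
#'   at least one non-control treatment).
#' @return A data frame with one row per treatment-by-trait comparison.
#' @export
effect_summaries <- function(data, traits = NULL, controls = NULL,
                             var_equal = FALSE) {
  validate_trial_data(data)
  regions <- unique(data$region)
  ctrl_of <- vapply(regions, function(r) find_control(data, r, controls),
                    character(1))
  out <- list()
  for (r in regions) {
    sub <- data[data$region == r, ]
    for (trt in setdiff(unique(sub$treatment), ctrl_of[[r]])) {
      tr_all <- unique(sub$trait[sub$treatment == trt])
      tr_use <- if (is.null(traits)) tr_all else intersect(traits, tr_all)
      for (tr in tr_use) {
        out[[length(out) + 1L]] <- increment_vs_control(
          data, tr, trt, controls = controls, var_equal = var_equal)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Region-average percent increment of a trait
#'
#' Arithmetic mean of the treatment-versus-control percent increments over a
#' region's intercrop (non-control) treatments — e.g. the average soil-pH
#' gain of intercropping within one trial site.
#'
#' @inheritParams increment_vs_control
#' @param region region label.
#' @return A single percentage.
#' @export
region_average_increment <- function(data, trait, region, controls = NULL) {
  validate_trial_data(data)
  sub <- data[data$region == region, ]
  if (!nrow(sub)) stop("no records for region ", region)
  ctrl <- find_control(data, region, controls)
  trts <- setdiff(unique(sub$treatment[sub$trait == trait]), ctrl)
  if (!length(trts)) stop("region ", region, " has no non-control treatment")
  inc <- vapply(trts, function(trt) {
    increment_vs_control(data, trait, trt, controls = controls)$increment_pct
  }, numeric(1))
  mean(inc)
}

#' Weighted disease severity index
#'
#' The disease index is the weighted mean severity over graded plant counts,
#' expressed as a percentage of the maximum possible severity:
#' `DI = 100 * sum(n_s * s) / (N * s_max)`, where `n_s` is the number of
#' plants at severity grade `s` and `N` the total number of plants surveyed.
#'
#' @param counts non-negative integer plant counts per severity grade.
#' @param grades severity grade of each count (default `0, 1, ..., length-1`).
#' @param s_max maximum possible grade (default: `max(grades)`), must be
#'   at least 1.
#' @return Disease index in `[0, 100]`.
#' @examples
#' disease_index(c(2, 0, 2), grades = c(0, 1, 2), s_max = 4) # 25
#' @export
disease_index <- function(counts, grades = seq_along(counts) - 1L,
                          s_max = max(grades)) {
  counts <- as.numeric(counts)
  if (length(counts) != length(grades)) {
    stop("counts and grades must have the same length")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (s_max < 1) stop("s_max must be at least 1")
  if (any(grades < 0) || any(grades > s_max)) {
    stop("grades must lie in [0, s_max]")
  }
  N <- sum(counts)
  if (N == 0) stop("disease index undefined: no plants surveyed")
  100 * sum(counts * grades) / (N * s_max)
}

#' Pearson correlation screen with significance masking
#'
#' Computes Pearson correlations and two-sided p-values for every pair of
#' variables and masks (sets to `NA`) pairs whose p-value is not below
#' `alpha`. Pairs involving a constant variable, or with fewer than 3
#' complete observations, are masked with an explicit reason rather than
#' silently returning `NaN`.
#'
#' @param x numeric matrix or data frame, observations in rows and variables
#'   in columns.
#' @param alpha significance threshold (default 0.05).
#' @return A `correlation_screen` list: square matrices `r`, `p`, `retained`
#'   and `masked` (correlations with non-significant entries `NA`, unit
#'   diagonal), plus `edges`, a data frame with one row per variable pair
#'   (`var1`, `var2`, `r`, `p`, `retained`, `reason`).
#' @export
correlation_screen <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  nv <- ncol(x)
  if (nv < 2L) stop("need at least 2 variables")
  vn <- colnames(x)
  if (is.null(vn)) vn <- paste0("V", seq_len(nv))
  r <- p <- matrix(NA_real_, nv, nv, dimnames = list(vn, vn))
  retained <- matrix(FALSE, nv, nv, dimnames = list(vn, vn))
  diag(r) <- 1
  diag(p) <- 0
  edges <- list()
  is_const <- function(v) length(unique(v[!is.na(v)])) <= 1L
  for (i in seq_len(nv - 1L)) {
    for (j in seq(i + 1L, nv)) {
      ok <- stats::complete.cases(x[, c(i, j)])
      reason <- ""
      if (sum(ok) < 3L) {
        reason <- "fewer than 3 complete observations"
      } else if (is_const(x[ok, i]) || is_const(x[ok, j])) {
        reason <- "constant variable"
      } else {
        ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
        retained[i, j] <- retained[j, i] <- ct$p.value < alpha
      }
      edges[[length(edges) + 1L]] <- data.frame(
        var1 = vn[i], var2 = vn[j], r = r[i, j], p = p[i, j],
        retained = retained[i, j], reason = reason, stringsAsFactors = FALSE)
    }
  }
  masked <- r
  masked[!retained] <- NA_real_
  diag(masked) <- 1
  structure(
    list(r = r, p = p, retained = retained, masked = masked,
         edges = do.call(rbind, edges), alpha = alpha),
    class = "correlation_screen"
  )
}

#' @export
print.correlation_screen <- function(x, ...) {
  kept <- sum(x$retained[upper.tri(x$retained)])
  total <- sum(upper.tri(x$retained))
  cat(sprintf("Correlation screen: %d/%d pairs retained at alpha = %g\n",
              kept, total, x$alpha))
  print(round(x$masked, 3), ...)
  invisible(x)
}
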