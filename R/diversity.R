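# Community-diversity metrics over sample x taxon abundance tables.
# Computation is delegated to vegan (the field standard); Pielou evenness is
# derived from Shannon entropy and richness.

validate_taxon_table <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("abundance table must be numeric")
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("abundances must be finite and non-negative")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("sample labels must be unique")
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    stop("taxon labels must be unique")
  }
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    stop("sample(s) with non-positive total abundance: ",
         paste(rownames(x)[tot <= 0], collapse = ", "))
  }
  x
}

#' Per-sample alpha-diversity metrics
#'
#' Richness (number of taxa with positive abundance), Shannon entropy
#' `H = -sum(p log p)` (natural log; `0 log 0 := 0`), Gini–Simpson diversity
#' `1 - sum(p^2)`, and Pielou evenness `J = H / log(richness)`. Pielou is
#' undefined for a single-taxon sample and returned as `NA` (never 0); the
#' `pielou_defined` column flags this explicitly.
#'
#' @param x abundance matrix, samples in rows, taxa in columns; every sample
#'   must have positive total abundance. Counts or relative abundances both
#'   work — all metrics except richness depend only on relative abundances,
#'   and richness is unaffected by rescaling anyway.
#' @param base logarithm base for Shannon entropy (default `exp(1)`).
#' @return Data frame with columns `sample`, `richness`, `shannon`,
#'   `simpson`, `pielou`, `pielou_defined`.
#' @examples
#' alpha_diversity(rbind(even = c(1, 1, 1, 1)))[, c("shannon", "simpson")]
#' @export
alpha_diversity <- function(x, base = exp(1)) {
  x <- validate_taxon_table(x)
  richness <- vegan::specnumber(x)
  shannon <- vegan::diversity(x, index = "shannon", base = base)
  simpson <- vegan::diversity(x, index = "simpson")
  pielou <- ifelse(richness >= 2, shannon / log(richness, base = base),
                   NA_real_)
  data.frame(
    sample = rownames(x),
    richness = as.integer(richness),
    shannon = unname(shannon),
    simpson = unname(simpson),
    pielou = unname(pielou),
    pielou_defined = richness >= 2,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Pairwise Bray-Curtis dissimilarity
#'
#' `BC(a, b) = 1 - 2 sum(min(a_t, b_t)) / (sum(a_t) + sum(b_t))`: 0 for
#' identical samples, 1 for samples sharing no taxa.
#'
#' @param x abundance matrix, samples in rows (at least 2), taxa in columns.
#' @return Symmetric sample-by-sample dissimilarity matrix with zero
#'   diagonal, values in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  x <- validate_taxon_table(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  as.matrix(vegan::vegdist(x, method = "bray"))
}
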