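#' Tukey's trimean
#'
#' Robust location summary `(Q1 + 2*Q2 + Q3) / 4` with linear-interpolation
#' (type 7) quantiles. Used as the per-group expression summary in the
#' communication module so that group size cancels out of interaction
#' strengths.
#'
#' @param x Numeric vector.
#' @return A single number; `NA` for empty input.
#' @export
#' @examples
#' trimean(c(1, 2, 3, 4)) # 2.5
trimean <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  (q[1] + 2 * q[2] + q[3]) / 4
}

#' Geometric mean
#'
#' Used to summarize multi-subunit ligand/receptor complexes: a zero subunit
#' nullifies the complex, matching the biology of obligate complexes.
#'
#' @param x Nonnegative numeric vector.
#' @return Geometric mean of `x`.
#' @export
geomean <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Matthews correlation coefficient
#'
#' Binary-classification agreement between predicted and true labels, used to
#' quantify recovery of planted tumor-reactive labels.
#'
#' @param truth,pred Logical vectors of equal length.
#' @return MCC in `[-1, 1]`; 0 when any margin is empty.
#' @export
matthews_cc <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

# shared tissue vocabulary: metastatic intrahepatic tumor, surrounding hepatic
# tissue, primary CRC tumor, surrounding colonic tissue, blood, lymph node
TISSUES <- c("MT", "MN", "PT", "PN", "PBMC", "LN")
COARSE_TYPES <- c("CD8T", "macrophage", "monocyte", "NK", "Treg", "other")

# paired t with degenerate-case conventions: identical pairs give t = 0,
# p = 1; a constant nonzero shift gives |t| = Inf, p = 0
safe_paired_t <- function(a, b) {
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0))
  }
  ht <- t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# run code under a fixed seed without touching the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
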