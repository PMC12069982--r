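#' Fit triangular fuzzy term sets
#'
#' For each feature, three triangular membership functions anchored at
#' the training minimum, median and maximum:
#' `low = (min, min, median)`, `medium = (min, median, max)`,
#' `high = (median, max, max)`.  On `[min, max]` the three memberships
#' are non-negative and sum to 1 (partition of unity); out-of-range
#' values are clipped to the boundary membership.  Features with only
#' two distinct values fall back to a two-term low/high set, and
#' constant features to a single always-on `medium` term (which yields
#' no split candidates).
#'
#' Each term also carries the crisp threshold used to route samples at a
#' split: the value where its membership crosses 0.5 — `(min+median)/2`
#' for `low` and `(median+max)/2` for `high`.  `medium` crosses 0.5
#' twice (at exactly those two points), so its threshold is taken at its
#' peak, the training median, giving three distinct thresholds per
#' feature.
#'
#' @param train Data frame or matrix of numeric training features.
#' @return Tibble of class `fuzzy_termset` with columns `feature`,
#'   `term`, `left`, `peak`, `right`, `threshold`.
#' @export
#' @examples
#' fit_fuzzy_terms(data.frame(x = 0:10))
fit_fuzzy_terms <- function(train) {
  m <- as_feature_matrix(train, "training features")
  nm <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  out <- list_rbind(imap(seq_len(ncol(m)), function(j, i) {
    x <- m[, j]
    lo <- min(x); hi <- max(x); md <- median(x)
    nd <- length(unique(x))
    if (nd == 1L) {
      tibble(feature = nm[j], term = "medium",
             left = lo, peak = lo, right = lo, threshold = NA_real_)
    } else if (nd == 2L || md <= lo || md >= hi) {
      tibble(feature = nm[j], term = c("low", "high"),
             left = c(lo, lo), peak = c(lo, hi), right = c(hi, hi),
             threshold = rep((lo + hi) / 2, 2))
    } else {
      tibble(feature = nm[j],
             term = c("low", "medium", "high"),
             left = c(lo, lo, md), peak = c(lo, md, hi),
             right = c(md, hi, hi),
             threshold = c((lo + md) / 2, md, (md + hi) / 2))
    }
  }))
  class(out) <- c("fuzzy_termset", class(out))
  out
}

#' Triangular membership evaluation
#'
#' Membership of `values` in the triangle `(left, peak, right)`, with
#' degenerate shoulders (`left == peak` or `peak == right`) handled as
#' one-sided ramps and out-of-range values clipped into `[left, right]`.
#'
#' @param values Numeric vector.
#' @param left,peak,right Triangle breakpoints.
#' @return Numeric vector of memberships in `[0, 1]`.
#' @export
fuzzy_membership <- function(values, left, peak, right) {
  x <- pmin(right, pmax(left, values))
  up <- if (peak > left) (x - left) / (peak - left) else as.numeric(x >= peak)
  dn <- if (right > peak) (right - x) / (right - peak) else as.numeric(x <= peak)
  if (left == peak && peak == right) return(rep(1, length(values)))
  pmin(up, dn, 1)
}

# n x n_terms membership matrix for one feature's term set rows
term_membership_matrix <- function(values, terms) {
  vapply(seq_len(nrow(terms)),
         function(i) fuzzy_membership(values, terms$left[i], terms$peak[i],
                                      terms$right[i]),
         numeric(length(values)))
}

#' Fuzzy entropy of class membership masses
#'
#' For per-class fuzzy membership masses `|E_s|`, forms the proportions
#' `q_s = |E_s| / |E|` and returns the entropy `-sum(q_s log2 q_s)` (the
#' conventional sign, with `0 log 0 = 0`).  `sign = "as_printed"` returns
#' `+sum(q_s log2 q_s)`, preserving a variant in which the minus sign is
#' absorbed elsewhere; the conventional sign is the default because the
#' fuzzy gain otherwise ranks splits backwards.
#'
#' @param masses Non-negative numeric vector of per-class membership
#'   masses with positive total.
#' @param sign `"conventional"` or `"as_printed"`.
#' @return Scalar entropy in bits.
#' @export
#' @examples
#' fuzzy_entropy(c(3, 3))       # 1 bit
#' fuzzy_entropy(c(1, 1, 1, 1)) # 2 bits
fuzzy_entropy <- function(masses, sign = c("conventional", "as_printed")) {
  sign <- match.arg(sign)
  if (any(masses < 0)) abort("negative membership mass", class = "nutriclass_invalid_input")
  tot <- sum(masses)
  if (tot <= 0) abort("total membership mass must be positive",
                      class = "nutriclass_invalid_input")
  q <- masses / tot
  q <- q[q > 0]
  h <- -sum(q * log2(q))
  if (sign == "as_printed") -h else h
}

#' Fuzzy information gain of a partition
#'
#' `M = G(parent) - sum_k q_k G(branch_k)` with
#' `q_k = |branch_k| / sum_k |branch_k|` (branch total membership mass
#' over the partition total).  Branch masses must be additive: summed
#' over branches they reproduce the parent masses (the branches arise
#' from a partition of unity), checked to 1e-9.
#'
#' @param parent Non-negative per-class mass vector of the parent node.
#' @param branches List of per-class mass vectors, one per branch.
#' @param sign Entropy sign convention, see [fuzzy_entropy()].
#' @return Scalar gain in bits.
#' @export
#' @examples
#' fuzzy_gain(c(3, 3), list(c(3, 0), c(0, 3)))  # 1 bit
fuzzy_gain <- function(parent, branches,
                       sign = c("conventional", "as_printed")) {
  sign <- match.arg(sign)
  branch_sum <- Reduce(`+`, branches)
  if (any(abs(branch_sum - parent) > 1e-9)) {
    abort("branch masses are not additive to the parent masses",
          class = "nutriclass_invalid_input")
  }
  totals <- map_dbl(branches, sum)
  if (sum(totals) <= 0) abort("zero total branch mass",
                              class = "nutriclass_invalid_input")
  qk <- totals / sum(totals)
  child <- sum(map_dbl(seq_along(branches), function(k) {
    if (totals[k] <= 0) 0 else qk[k] * fuzzy_entropy(branches[[k]], sign)
  }))
  fuzzy_entropy(parent, sign) - child
}
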