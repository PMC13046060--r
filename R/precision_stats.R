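#' Relative difference between an SV-derived and a WKP-derived dose
#'
#' The precision statistic of the framework:
#' \code{RD = 100 * (sv - wkp) / wkp} (percent). Under the multiplicative
#' noise model the true dose cancels, so RD reflects measurement noise only.
#'
#' @param sv_value SV (or SV-mean) dose estimate, Gy.
#' @param wkp_value WKP reference dose, Gy, \code{> 0}.
#' @return Relative difference in percent (vectorized).
#' @export
relative_difference <- function(sv_value, wkp_value) {
  if (any(!is.finite(wkp_value)) || any(wkp_value <= 0))
    stop("reference WKP dose must be strictly positive")
  100 * (sv_value - wkp_value) / wkp_value
}

#' Normalization factor of the SV method
#'
#' The mean of all per-SV dose ratios \code{D_SV / D_WKP} pooled over
#' kidneys, with its standard error (sample sd of the ratios, denominator
#' n - 1, divided by sqrt(n)). The factor estimates the systematic
#' multiplicative SV bias; dividing SV doses by it removes the bias.
#'
#' @param records List of \code{\link{kidney_record}} objects.
#' @param by \code{"all"} pools every ratio in \code{records};
#'   \code{"stratum"} computes one factor per (SV volume, filter) condition.
#' @return For \code{by = "all"}, a list with \code{nf}, \code{sem} and
#'   \code{n}. For \code{by = "stratum"}, a data.frame with one row per
#'   condition and columns \code{sv_volume_ml}, \code{filter_sigma_mm},
#'   \code{nf}, \code{sem}, \code{n}.
#' @examples
#' recs <- list(kidney_record("p1", "left", 0, 2, 1.0, c(1.0, 1.1, 1.2)))
#' normalization_factor(recs)
#' @export
normalization_factor <- function(records, by = c("all", "stratum")) {
  by <- match.arg(by)
  stopifnot(is.list(records), length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "kidney_record")))
  if (by == "stratum") {
    strata <- split_records(records)
    out <- do.call(rbind, lapply(strata, function(recs) {
      nf <- normalization_factor(recs, by = "all")
      data.frame(sv_volume_ml = recs[[1L]]$sv_volume_ml,
                 filter_sigma_mm = recs[[1L]]$filter_sigma_mm,
                 nf = nf$nf, sem = nf$sem, n = nf$n)
    }))
    rownames(out) <- NULL
    return(out)
  }
  ratios <- unlist(lapply(records, function(r) r$sv_doses_gy / r$wkp_dose_gy))
  n <- length(ratios)
  if (n < 2L)
    stop("normalization factor needs at least 2 SV/WKP ratios")
  list(nf = mean(ratios), sem = stats::sd(ratios) / sqrt(n), n = n)
}

#' Divide SV doses by a normalization factor
#'
#' Returns the records with every SV dose divided by \code{nf}; WKP doses
#' are untouched. Recomputing the normalization factor on the returned
#' records gives exactly 1, which is why the post-normalization mean RD at
#' k = 1 is zero by construction.
#'
#' @param records List of \code{\link{kidney_record}} objects.
#' @param nf Normalization factor, \code{> 0}.
#' @return The normalized records.
#' @export
normalize_records <- function(records, nf) {
  stopifnot(is.numeric(nf), length(nf) == 1L)
  if (!is.finite(nf) || nf <= 0) stop("'nf' must be > 0")
  lapply(records, function(r) {
    r$sv_doses_gy <- r$sv_doses_gy / nf
    r
  })
}

#' Normalize each stratum by its own in-sample factor
#'
#' Convenience wrapper: computes the normalization factor per (SV volume,
#' filter) condition and divides that condition's SV doses by it.
#'
#' @param records List of \code{\link{kidney_record}} objects.
#' @return The normalized records, original order preserved.
#' @export
normalize_by_stratum <- function(records) {
  keys <- vapply(records, record_stratum, "")
  out <- records
  for (key in unique(keys)) {
    idx <- which(keys == key)
    nf <- normalization_factor(records[idx], by = "all")$nf
    out[idx] <- normalize_records(records[idx], nf)
  }
  out
}

# Subset index sets of size k for one record: all C(m, k) subsets in
# lexicographic order, or n_subsets sampled uniformly without replacement.
sv_subsets <- function(m, k, policy, n_subsets) {
  subs <- utils::combn(m, k)
  if (policy == "random") {
    if (is.null(n_subsets) || n_subsets <= 0)
      stop("'n_subsets' must be a positive count under the random policy")
    take <- sample.int(ncol(subs), min(n_subsets, ncol(subs)))
    subs <- subs[, sort(take), drop = FALSE]
  }
  subs
}

#' Pool relative differences over SV subsets of size k
#'
#' For each kidney, forms the mean over SV subsets of size \code{k} (all
#' \code{choose(m, k)} subsets by default) and computes the relative
#' difference of each subset mean against that kidney's WKP dose. Subset RDs
#' from all kidneys are pooled into one sample. Ordering is deterministic:
#' kidneys in input order, subsets in lexicographic order.
#'
#' Subsets within a kidney overlap, so pooled RDs are statistically
#' dependent; their standard deviation is still a valid dispersion estimate,
#' but the row count overstates the effective sample size.
#'
#' @param records List of \code{\link{kidney_record}} objects, each with at
#'   least \code{k} SV doses.
#' @param k Number of SVs averaged per subset.
#' @param subset_policy \code{"all"} enumerates every subset;
#'   \code{"random"} samples \code{n_subsets} subsets uniformly without
#'   replacement within each kidney (uses the global RNG stream).
#' @param n_subsets Number of subsets per kidney under the random policy.
#' @return A data.frame with columns \code{kidney_key}, \code{k},
#'   \code{subset_index} and \code{rd_percent}.
#' @export
rd_pool <- function(records, k, subset_policy = c("all", "random"),
                    n_subsets = NULL) {
  subset_policy <- match.arg(subset_policy)
  stopifnot(is.list(records), length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "kidney_record")),
            is.numeric(k), length(k) == 1L, k >= 1, k == round(k))
  k <- as.integer(k)
  m_min <- min(vapply(records, function(r) length(r$sv_doses_gy), 1L))
  if (k > m_min)
    stop(sprintf("k = %d exceeds the smallest SV count (%d)", k, m_min))
  keys <- sub_idx <- rds <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    subs <- sv_subsets(length(r$sv_doses_gy), k, subset_policy, n_subsets)
    means <- colMeans(matrix(r$sv_doses_gy[subs], nrow = k))
    keys[[i]] <- rep(sprintf("%s_%s_%s", r$patient_id, r$kidney_side,
                             record_stratum(r)), ncol(subs))
    sub_idx[[i]] <- seq_len(ncol(subs))
    rds[[i]] <- relative_difference(means, r$wkp_dose_gy)
  }
  data.frame(kidney_key = unlist(keys), k = k,
             subset_index = unlist(sub_idx), rd_percent = unlist(rds))
}

#' Empirical precision curve sd(RD(k))
#'
#' For each requested \code{k}, pools the subset relative differences of all
#' kidneys (see \code{\link{rd_pool}}) and takes their sample standard
#' deviation (denominator n - 1). The resulting U(k) in percent is the
#' empirical precision of a k-SV average relative to the WKP reference.
#'
#' @param records List of \code{\link{kidney_record}} objects from one
#'   (SV volume, filter) stratum.
#' @param k_values Counts of SVs to average; each \code{<=} the smallest SV
#'   count among the records.
#' @param subset_policy,n_subsets Passed to \code{\link{rd_pool}}.
#' @return An object of class \code{"precision_curve"}: a data.frame with
#'   columns \code{k}, \code{u_percent} and \code{n_samples}, plus a
#'   \code{condition} attribute \code{(sv_volume_ml, filter_sigma_mm)} when
#'   the records share one condition.
#' @examples
#' set.seed(7)
#' p <- noise_params(0.12, 0.07)
#' recs <- replicate(40, {
#'   sim <- simulate_kidney_measurement(4, p, 5)
#'   kidney_record("p", "left", 0, 2, sim$wkp_dose, sim$sv_doses)
#' }, simplify = FALSE)
#' precision_curve(recs, 1:5)
#' @export
precision_curve <- function(records, k_values,
                            subset_policy = c("all", "random"),
                            n_subsets = NULL) {
  subset_policy <- match.arg(subset_policy)
  stopifnot(is.numeric(k_values), length(k_values) >= 1L)
  k_values <- sort(unique(as.integer(k_values)))
  rows <- lapply(k_values, function(k) {
    rd <- rd_pool(records, k, subset_policy, n_subsets)
    if (nrow(rd) < 2L)
      stop(sprintf("fewer than 2 RD samples at k = %d", k))
    data.frame(k = k, u_percent = stats::sd(rd$rd_percent),
               n_samples = nrow(rd))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  strata <- unique(vapply(records, record_stratum, ""))
  cond <- if (length(strata) == 1L)
    c(sv_volume_ml = records[[1L]]$sv_volume_ml,
      filter_sigma_mm = records[[1L]]$filter_sigma_mm)
  attr(out, "condition") <- cond
  class(out) <- c("precision_curve", "data.frame")
  out
}

#' @export
print.precision_curve <- function(x, ...) {
  cond <- attr(x, "condition")
  if (!is.null(cond))
    cat(sprintf("Precision curve U(k), SV %g ml, GF %g mm:\n",
                cond[["sv_volume_ml"]], cond[["filter_sigma_mm"]]))
  else cat("Precision curve U(k):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Mean relative difference (empirical bias) at a given k
#'
#' The mean of the pooled subset RDs. On raw dose tables this estimates the
#' small positive ratio bias (\code{\link{analytic_rd_bias}}); after
#' in-sample normalization of the same stratum it is zero up to
#' floating-point roundoff.
#'
#' @inheritParams rd_pool
#' @return Mean RD in percent.
#' @export
rd_bias <- function(records, k = 1, subset_policy = c("all", "random"),
                    n_subsets = NULL) {
  mean(rd_pool(records, k, match.arg(subset_policy), n_subsets)$rd_percent)
}

# Exact two-sided rank-sum p-value via enumeration of all C(n1+n2, n1)
# group assignments, with midranks for ties. W is the rank sum of group a;
# two-sided p = P(|W - E[W]| >= |w_obs - E[W]|) under the permutation null.
ranksum_exact <- function(a, b) {
  n1 <- length(a)
  ranks <- rank(c(a, b))           # midranks
  w_obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(length(ranks), n1)
  w_all <- colSums(matrix(ranks[combos], nrow = n1))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Midrank normal approximation with tie-corrected variance (no continuity
# correction; used only above the enumeration cutoff).
ranksum_normal <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(ranks)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(1)
  min(1, 2 * stats::pnorm(-abs(w - mu) / sqrt(v)))
}

#' Compare two groups of precision estimates (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test on two groups of precision values (for example
#' the per-filter plateau precisions of the 2 ml and 0.6 ml SV methods).
#' Ties are handled by midranks. Small samples (all group assignments
#' enumerable, up to 200000 combinations) get an exact permutation p-value;
#' larger samples use the midrank normal approximation with tie-corrected
#' variance.
#'
#' @param rd_dispersions_a,rd_dispersions_b Numeric vectors of precision
#'   estimates (percent), each of length \code{>= 3}.
#' @return A list with \code{p_value}, \code{method} and the group sizes.
#' @examples
#' compare_precision(c(7.05, 7.27, 7.51), c(6.81, 6.92, 7.35))
#' @export
compare_precision <- function(rd_dispersions_a, rd_dispersions_b) {
  a <- as.numeric(rd_dispersions_a); b <- as.numeric(rd_dispersions_b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 precision values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("precision values must be finite")
  if (choose(length(a) + length(b), length(a)) <= 2e5) {
    list(p_value = ranksum_exact(a, b), method = "exact rank-sum (midranks)",
         n = c(length(a), length(b)))
  } else {
    list(p_value = ranksum_normal(a, b),
         method = "rank-sum normal approximation (midranks, tie-corrected)",
         n = c(length(a), length(b)))
  }
}
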