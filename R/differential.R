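## --- Audic-Claverie two-library count test ---------------------------------
##
## Given a feature observed x times among N1 reads in library 1, the
## posterior-predictive distribution of its count Y in a library of N2 reads
## is negative binomial:
##   p(y | x) = (N2/N1)^y (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )
## i.e. Y | x ~ NB(size = x + 1, prob = N1/(N1+N2)). Tail probabilities are
## computed by direct summation in log space (no normal or saddlepoint
## approximation). Because conditioning on either library is equally
## defensible and the two conditionals differ slightly for finite counts,
## each one-sided tail is the average of the two conditional formulations;
## this makes the two-sided p exactly invariant under swapping the
## libraries.

## log pmf of p(k | x) for the library pair (N1, N2), vectorized over k
ac_log_pmf <- function(k, x, N1, N2) {
  lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) +
    k * (log(N2) - log(N1 + N2)) + (x + 1) * (log(N1) - log(N1 + N2))
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

## P(Y <= y | x), exact summation
ac_tail_lower <- function(x, y, N1, N2) {
  if (y < 0) return(0)
  exp(logsumexp(ac_log_pmf(0:y, x, N1, N2)))
}

## P(Y >= y | x): direct upper summation when the tail is small, else
## complement of the lower tail (which is then small and exact).
ac_tail_upper <- function(x, y, N1, N2) {
  if (y <= 0) return(1)
  lower <- ac_tail_lower(x, y - 1, N1, N2)
  if (lower < 0.5) return(1 - lower)
  q <- N2 / (N1 + N2)
  total <- 0
  k0 <- y
  repeat {
    ks <- k0:(k0 + 999)
    terms <- exp(ac_log_pmf(ks, x, N1, N2))
    total <- total + sum(terms)
    last <- terms[length(terms)]
    r <- q * (x + ks[length(ks)] + 1) / (ks[length(ks)] + 1)
    r <- min(r, 0.999999)
    bound <- last * r / (1 - r)
    if (bound <= total * 1e-16 || last == 0) break
    k0 <- k0 + 1000
  }
  min(total, 1)
}

ac_p_scalar <- function(x, N1, y, N2) {
  ## "library 2 elevated": tail over y given x, and mirrored tail over x given y
  up <- (ac_tail_upper(x, y, N1, N2) + ac_tail_lower(y, x, N2, N1)) / 2
  dn <- (ac_tail_lower(x, y, N1, N2) + ac_tail_upper(y, x, N2, N1)) / 2
  min(1, 2 * min(up, dn))
}

#' Audic-Claverie test for a feature's counts in two libraries
#'
#' Bayesian comparison of one feature's read counts between two sequencing
#' libraries via the posterior-predictive (conditional negative binomial)
#' law of the second count given the first. Tails are computed by exact
#' log-space summation; the two-sided p-value doubles the smaller of the
#' two symmetrized one-sided tails and is exactly invariant under swapping
#' the libraries. Vectorized over `x` and `y`.
#'
#' @param x,y feature counts in libraries 1 and 2.
#' @param N1,N2 total (mapped) read counts of the libraries.
#' @param feature_id optional feature labels for the result table.
#' @return data.frame with columns `feature_id, x, y, N1, N2,
#'   log2_fold_change` (pseudocount 1 on both counts), `p_value`.
#' @examples
#' ac_test(5, 1e6, 50, 1e6)
#' @export
ac_test <- function(x, N1, y, N2, feature_id = NULL) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(N1 < 1) || any(N2 < 1)) stopf("library totals must be >= 1")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1v <- rep_len(N1, n); N2v <- rep_len(N2, n)
  p <- vapply(seq_len(n), function(i) ac_p_scalar(x[i], N1v[i], y[i], N2v[i]),
              numeric(1))
  lfc <- log2(((y + 1) / N2v) / ((x + 1) / N1v))
  data.frame(
    feature_id = if (is.null(feature_id)) paste0("f", seq_len(n)) else feature_id,
    x = x, y = y, N1 = N1v, N2 = N2v,
    log2_fold_change = lfc, p_value = p, stringsAsFactors = FALSE)
}

#' Differential miRNA expression screen between two libraries
#'
#' Runs the Audic-Claverie test per miRNA on the count of its most abundant
#' sequence variant, with the libraries' total assigned read counts as
#' totals, and flags features at `p < alpha`. A Benjamini-Hochberg column
#' is included for information; flagging uses the raw threshold.
#'
#' @param profiles1,profiles2 `profiles` tables from [profile_expression()]
#'   for the two conditions (shared miRNA universe).
#' @param alpha raw p-value threshold for flagging.
#' @param N1,N2 library totals; default is the sum of assigned counts of
#'   each profile table.
#' @param annotated_only restrict to named mature miRNAs (default TRUE).
#' @return data.frame `mirna_id, x, y, N1, N2, log2fc, p, p_bh, flagged`.
#' @export
de_screen <- function(profiles1, profiles2, alpha = 0.001,
                      N1 = NULL, N2 = NULL, annotated_only = TRUE) {
  if (nrow(profiles1) == 0L || nrow(profiles2) == 0L) {
    stopf("empty profile tables")
  }
  if (annotated_only) {
    profiles1 <- profiles1[profiles1$annotated, , drop = FALSE]
    profiles2 <- profiles2[profiles2$annotated, , drop = FALSE]
  }
  ids <- sort(union(profiles1$mirna_id, profiles2$mirna_id))
  x <- profiles1$top_variant_count[match(ids, profiles1$mirna_id)]
  y <- profiles2$top_variant_count[match(ids, profiles2$mirna_id)]
  x[is.na(x)] <- 0L; y[is.na(y)] <- 0L
  if (is.null(N1)) N1 <- max(sum(profiles1$total_count), 1)
  if (is.null(N2)) N2 <- max(sum(profiles2$total_count), 1)
  res <- ac_test(x, N1, y, N2, feature_id = ids)
  data.frame(mirna_id = ids, x = res$x, y = res$y, N1 = N1, N2 = N2,
             log2fc = res$log2_fold_change, p = res$p_value,
             p_bh = stats::p.adjust(res$p_value, "BH"),
             flagged = res$p_value < alpha, stringsAsFactors = FALSE)
}

#' Screen for isomiR pattern changes between two conditions
#'
#' Chi-square test (no continuity correction) on the 2 x 4 contingency
#' table of the four isomiR classes (canonical reads excluded from the
#' table, following the class definitions), per miRNA. A miRNA is flagged
#' when the test is significant at `alpha` AND its total count (canonical
#' included) reaches `min_total` in at least one condition AND some isomiR
#' class's share of the total shifts by at least `min_shift_pp` percentage
#' points. Classes absent from both conditions are dropped from the table
#' (with the degrees of freedom adjusted); miRNAs with all-zero isomiR
#' counts in both conditions are skipped.
#'
#' @param profiles1,profiles2 `profiles` tables from [profile_expression()].
#' @param min_total minimum total count in at least one condition.
#' @param min_shift_pp minimum share shift in percentage points.
#' @param alpha chi-square significance threshold.
#' @return data.frame per testable miRNA: `mirna_id, chi2, df, p,
#'   max_share_shift, total1, total2, warn_low_expected, flagged`.
#' @export
isomir_pattern_screen <- function(profiles1, profiles2, min_total = 1000L,
                                  min_shift_pp = 5, alpha = 0.05) {
  classes <- c("isomir_5p", "isomir_3p", "isomir_53p", "isomir_3e")
  ids <- intersect(profiles1$mirna_id, profiles2$mirna_id)
  i1 <- match(ids, profiles1$mirna_id); i2 <- match(ids, profiles2$mirna_id)
  rows <- lapply(seq_along(ids), function(k) {
    c1 <- as.numeric(profiles1[i1[k], classes])
    c2 <- as.numeric(profiles2[i2[k], classes])
    t1 <- profiles1$total_count[i1[k]]; t2 <- profiles2$total_count[i2[k]]
    if (sum(c1) + sum(c2) == 0) return(NULL)   # skipped, nothing to test
    keep <- (c1 + c2) > 0
    m <- rbind(c1[keep], c2[keep])
    if (sum(keep) < 2 || any(rowSums(m) == 0)) {
      chi2 <- 0; df <- 0L; p <- 1; warn <- FALSE
    } else {
      ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      chi2 <- unname(ct$statistic); df <- unname(ct$parameter)
      p <- unname(ct$p.value)
      warn <- any(ct$expected < 5)
    }
    share1 <- if (t1 > 0) 100 * c1 / t1 else rep(0, 4)
    share2 <- if (t2 > 0) 100 * c2 / t2 else rep(0, 4)
    shift <- max(abs(share2 - share1))
    data.frame(mirna_id = ids[k], chi2 = chi2, df = df, p = p,
               max_share_shift = shift, total1 = t1, total2 = t2,
               warn_low_expected = warn,
               flagged = is.finite(p) && p < alpha &&
                 max(t1, t2) >= min_total && shift >= min_shift_pp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(0), chi2 = numeric(0), df = integer(0),
                      p = numeric(0), max_share_shift = numeric(0),
                      total1 = integer(0), total2 = integer(0),
                      warn_low_expected = logical(0), flagged = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Scan for 5'/3' arm-ratio switches between two conditions
#'
#' Computes the pseudocount-1 ratio (count5p + 1)/(count3p + 1) per
#' precursor and condition and flags precursors whose ratio changes at
#' least `fold_cutoff`-fold in either direction (inclusive boundary).
#'
#' @param arm_counts1,arm_counts2 `arm_counts` tables from
#'   [profile_expression()] (same precursor universe).
#' @param fold_cutoff minimum ratio fold change flagged.
#' @param all return all precursors (default) or only the flagged subset.
#' @return data.frame `precursor_id, ratio1, ratio2, fold_change,
#'   direction, flagged` with `direction` `UP_5P` when the 5' arm share
#'   rises in condition 2.
#' @export
arm_switch_scan <- function(arm_counts1, arm_counts2, fold_cutoff = 1.5,
                            all = TRUE) {
  ids <- sort(intersect(arm_counts1$precursor_id, arm_counts2$precursor_id))
  i1 <- match(ids, arm_counts1$precursor_id)
  i2 <- match(ids, arm_counts2$precursor_id)
  r1 <- (arm_counts1$count5p[i1] + 1) / (arm_counts1$count3p[i1] + 1)
  r2 <- (arm_counts2$count5p[i2] + 1) / (arm_counts2$count3p[i2] + 1)
  fold <- pmax(r2 / r1, r1 / r2)
  out <- data.frame(precursor_id = ids, ratio1 = r1, ratio2 = r2,
                    fold_change = fold,
                    direction = ifelse(r2 > r1, "UP_5P", "DOWN_5P"),
                    flagged = fold >= fold_cutoff, stringsAsFactors = FALSE)
  if (!all) out <- out[out$flagged, , drop = FALSE]
  rownames(out) <- NULL
  out
}
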