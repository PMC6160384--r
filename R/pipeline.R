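#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; thin wrapper
#' around [stats::p.adjust()] kept as a named pipeline step.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Combine two p-values by normal inversion
#'
#' Each p-value is converted to an upper-tail standard-normal quantile;
#' the combined p is the upper-tail probability of their sum rescaled by
#' sqrt(2) (Stouffer's method for two tests). Inputs are clamped to
#' \[1e-16, 1 - 1e-16\] before inversion.
#'
#' @param p_de,p_enrich the two p-values (vectorized).
#' @return combined p-values.
#' @examples
#' combine_pvalues(0.05, 0.05)  # 0.0100
#' @export
combine_pvalues <- function(p_de, p_enrich) {
  cl <- function(p) pmin(pmax(p, 1e-16), 1 - 1e-16)
  z <- stats::qnorm(cl(p_de), lower.tail = FALSE) +
    stats::qnorm(cl(p_enrich), lower.tail = FALSE)
  stats::pnorm(z / sqrt(2), lower.tail = FALSE)
}

#' Signed adjusted rank of a transcript
#'
#' Ranking score combining abundance, fold change and significance: for a
#' base mean of 30 or less the score is log10(base mean) + |log2 fold
#' change|; above 30 the |log10 adjusted p| term is added. The score takes
#' the sign of the fold change (0 when the fold change is 0). Degenerate
#' inputs are clamped: base mean below 1 to 1, adjusted p below 1e-300 to
#' 1e-300.
#'
#' @param base_mean mean normalized count (vectorized).
#' @param log2fc signed log2 fold change.
#' @param adj_p BH-adjusted p-value.
#' @return signed rank values.
#' @examples
#' adjusted_rank(100, 1.5, 0.01)  # +5.5
#' @export
adjusted_rank <- function(base_mean, log2fc, adj_p) {
  bm <- pmax(base_mean, 1)
  ap <- pmax(adj_p, 1e-300)
  r <- log10(bm) + abs(log2fc) + ifelse(base_mean > 30, abs(log10(ap)), 0)
  r * sign(log2fc)
}

#' Rank transcripts of a differential-expression table
#'
#' Applies [adjusted_rank()] to a DE result table and returns the ranked
#' list used by [ranked_enrichment()], ordered most up-regulated first with
#' ties broken by transcript id.
#'
#' @param de data.frame with columns `id, base_mean, log2fc, p, adj_p`.
#' @return data.frame `transcript_id, adjusted_rank`, sorted.
#' @export
rank_transcripts <- function(de) {
  r <- adjusted_rank(de$base_mean, de$log2fc, de$adj_p)
  out <- data.frame(transcript_id = de$id, adjusted_rank = r,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$transcript_id), , drop = FALSE]
  out <- out[order(-out$adjusted_rank, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked-set enrichment of a target set
#'
#' Threshold-independent test for whether a target set concentrates at the
#' top (most up-regulated) or bottom (most down-regulated) of a ranked
#' transcript list. The list is cut at `n_partitions` rank quantiles; at
#' each cut a two-tailed Fisher exact test of set membership against list
#' side is run; the best (smallest) p is Bonferroni-corrected for the
#' number of cuts evaluated and capped at 1. The direction is taken from
#' the odds ratio at the best cut.
#'
#' @param ranked data.frame `transcript_id, adjusted_rank` (see
#'   [rank_transcripts()]); order-preserving transformations of the rank
#'   values do not change the result.
#' @param target_set character vector of transcript ids (duplicates
#'   removed; must intersect the ranked list).
#' @param n_partitions number of rank-quantile cut points.
#' @return one-row data.frame `direction, p_value, best_cut, odds_ratio`
#'   with `direction` in `TARGETS_UP`/`TARGETS_DOWN`.
#' @export
ranked_enrichment <- function(ranked, target_set, n_partitions = 30L) {
  target_set <- unique(target_set)
  if (length(target_set) == 0L) stopf("empty target set")
  ord <- ranked[order(-ranked$adjusted_rank, ranked$transcript_id), , drop = FALSE]
  ids <- ord$transcript_id[!duplicated(ord$transcript_id)]
  n <- length(ids)
  in_set <- ids %in% target_set
  K <- sum(in_set)
  if (K == 0L) stopf("target set does not intersect the ranked list")
  cum_in <- cumsum(in_set)
  cuts <- unique(pmin(pmax(round(seq_len(n_partitions) * n /
                                   (n_partitions + 1)), 1L), n - 1L))
  cuts <- cuts[cuts >= 1 & cuts <= n - 1]
  if (length(cuts) == 0L) cuts <- max(1L, floor(n / 2))
  best <- list(p = Inf, or = 1, cut = cuts[1])
  for (cc in cuts) {
    a <- cum_in[cc]; b <- cc - a
    c2 <- K - a; d <- n - cc - c2
    ft <- stats::fisher.test(matrix(c(a, b, c2, d), nrow = 2))
    if (ft$p.value < best$p) {
      best <- list(p = ft$p.value,
                   or = (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c2 + 0.5)),
                   cut = cc)
    }
  }
  data.frame(direction = if (best$or >= 1) "TARGETS_UP" else "TARGETS_DOWN",
             p_value = min(1, best$p * length(cuts)),
             best_cut = best$cut, odds_ratio = best$or,
             stringsAsFactors = FALSE)
}

#' Per-sample miRNA-target interaction prediction
#'
#' Default stand-in for a per-sample interaction-signature model: in each
#' sample, the interaction (miRNA i, transcript j) is active when the pair
#' has at least one predicted binding site and both features are expressed
#' at or above `expr_floor` counts in that sample. MiRNAs with fewer than
#' `min_targets` active interactions in a sample are dropped for that
#' sample. An externally computed per-sample probability matrix can be
#' supplied instead via `prob`; interactions with non-zero probability are
#' then counted as active (subject to the same `min_targets` rule).
#'
#' @param mirna_counts miRNA count matrix (miRNAs x samples).
#' @param transcript_counts transcript count matrix (transcripts x samples).
#' @param site_counts miRNA x transcript binding-site count matrix.
#' @param min_targets minimum active interactions per miRNA per sample.
#' @param expr_floor minimum count for a feature to be considered expressed.
#' @param prob optional list (one entry per sample) of miRNA x transcript
#'   probability matrices replacing the built-in rule.
#' @return named list (one element per sample) of named lists: miRNA id ->
#'   character vector of active target ids.
#' @export
predict_interactions <- function(mirna_counts, transcript_counts, site_counts,
                                 min_targets = 5L, expr_floor = 1,
                                 prob = NULL) {
  if (!identical(rownames(site_counts), rownames(mirna_counts)) ||
      !identical(colnames(site_counts), rownames(transcript_counts))) {
    stopf("site matrix dimensions must match the count matrices")
  }
  if (!identical(colnames(mirna_counts), colnames(transcript_counts))) {
    stopf("sample sets of the count matrices differ")
  }
  samples <- colnames(mirna_counts)
  has_site <- site_counts > 0
  out <- lapply(seq_along(samples), function(s) {
    act <- if (is.null(prob)) {
      has_site & outer(mirna_counts[, s] >= expr_floor,
                       transcript_counts[, s] >= expr_floor, `&`)
    } else {
      prob[[s]] > 0
    }
    sets <- lapply(rownames(act), function(m) colnames(act)[act[m, ]])
    names(sets) <- rownames(act)
    sets[lengths(sets) >= min_targets]
  })
  names(out) <- samples
  out
}

#' Consensus target sets across samples
#'
#' Per miRNA, the exact intersection of its per-sample active target sets;
#' a miRNA absent (dropped) in any sample has an empty consensus.
#'
#' @param per_sample output of [predict_interactions()].
#' @return named list: miRNA id -> character vector of consensus targets
#'   (miRNAs with empty consensus are omitted).
#' @export
consensus_targets <- function(per_sample) {
  if (length(per_sample) == 0L) stopf("need at least one sample")
  mirnas <- Reduce(intersect, lapply(per_sample, names))
  out <- lapply(mirnas, function(m) {
    Reduce(intersect, lapply(per_sample, function(s) s[[m]]))
  })
  names(out) <- mirnas
  out[lengths(out) > 0]
}

#' Pearson correlation of each miRNA with a regulator profile
#'
#' Two-sided t-based Pearson correlation of each miRNA row against the
#' regulator expression vector, BH-adjusted across miRNAs. Zero-variance
#' features get `r = NA`, `p = 1`.
#'
#' @param mirna_mat miRNA expression matrix (miRNAs x samples), any
#'   normalized scale.
#' @param regulator numeric vector of the regulator's expression in the
#'   same samples.
#' @return data.frame `mirna_id, r, p, adj_p`.
#' @export
correlate_with_regulator <- function(mirna_mat, regulator) {
  if (ncol(mirna_mat) < 3L) stopf("need >= 3 samples")
  if (length(regulator) != ncol(mirna_mat)) stopf("regulator length mismatch")
  res <- t(apply(mirna_mat, 1, function(v) {
    if (stats::sd(v) == 0 || stats::sd(regulator) == 0) return(c(NA_real_, 1))
    ct <- stats::cor.test(v, regulator, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }))
  data.frame(mirna_id = rownames(mirna_mat), r = res[, 1], p = res[, 2],
             adj_p = bh_adjust(res[, 2]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select candidate miRNAs
#'
#' Combines per-miRNA differential-expression and target-enrichment
#' adjusted p-values by normal inversion, BH-adjusts the combined p across
#' miRNAs, and applies three criteria: (A) DE FDR below `fdr_de`; (B) the
#' miRNA's targets change in the direction opposite to the miRNA; (C)
#' significant correlation with the regulator (FDR below `fdr_corr`). A
#' miRNA is selected when all three hold and the combined FDR is below
#' `fdr_combined`. MiRNAs missing from any input table are excluded.
#'
#' @param de_mirna data.frame `id, base_mean, log2fc, p, adj_p` for miRNAs.
#' @param enrich data.frame `mirna_id, direction, p_value, adj_p` from
#'   [ranked_enrichment()] applied per miRNA.
#' @param corr data.frame from [correlate_with_regulator()].
#' @param fdr_de,fdr_corr,fdr_combined the three FDR thresholds.
#' @return data.frame `mirna_id, log2fc, de_adj_p, enrich_direction,
#'   enrich_adj_p, combined_p, combined_adj_p, corr_r, corr_adj_p, crit_A,
#'   crit_B, crit_C, selected`.
#' @export
select_candidates <- function(de_mirna, enrich, corr,
                              fdr_de = 0.1, fdr_corr = 0.1,
                              fdr_combined = 0.05) {
  ids <- Reduce(intersect, list(de_mirna$id, enrich$mirna_id, corr$mirna_id))
  dropped <- setdiff(union(union(de_mirna$id, enrich$mirna_id), corr$mirna_id), ids)
  if (length(dropped)) {
    message(sprintf("select_candidates: %d miRNA(s) missing from some table, excluded",
                    length(dropped)))
  }
  d <- de_mirna[match(ids, de_mirna$id), ]
  e <- enrich[match(ids, enrich$mirna_id), ]
  cc <- corr[match(ids, corr$mirna_id), ]
  combined <- combine_pvalues(d$adj_p, e$adj_p)
  combined_adj <- bh_adjust(combined)
  crit_A <- d$adj_p < fdr_de
  crit_B <- (d$log2fc > 0 & e$direction == "TARGETS_DOWN") |
    (d$log2fc < 0 & e$direction == "TARGETS_UP")
  crit_C <- cc$adj_p < fdr_corr
  out <- data.frame(
    mirna_id = ids, log2fc = d$log2fc, de_adj_p = d$adj_p,
    enrich_direction = e$direction, enrich_adj_p = e$adj_p,
    combined_p = combined, combined_adj_p = combined_adj,
    corr_r = cc$r, corr_adj_p = cc$adj_p,
    crit_A = crit_A, crit_B = crit_B, crit_C = crit_C,
    selected = combined_adj < fdr_combined & crit_A & crit_B & crit_C,
    stringsAsFactors = FALSE)
  out[order(out$mirna_id), , drop = FALSE]
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= x) where X counts category members in a sample of `n` draws
#' without replacement from a universe of `N` items of which `K` belong to
#' the category. Computed in log space via [stats::phyper()].
#'
#' @param x observed overlap.
#' @param n sample size.
#' @param K category size in the universe.
#' @param N universe size.
#' @return the upper-tail probability (vectorized).
#' @examples
#' hypergeom_enrichment(4, 4, 40, 85)    # 0.045
#' @export
hypergeom_enrichment <- function(x, n, K, N) {
  if (any(x < 0 | x > pmin(n, K) | K > N | n > N)) {
    stopf("inconsistent hypergeometric arguments")
  }
  exp(stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Term over-representation in a gene set
#'
#' Generic two-tailed Fisher exact over-representation test of a gene set
#' against user-supplied gene-to-term annotations, BH-adjusted across
#' terms. Terms with no gene in the universe are skipped.
#'
#' @param gene_set character vector (must be a subset of `universe`).
#' @param universe character vector of all genes considered.
#' @param term_map data.frame with columns `gene, term`.
#' @return data.frame `term, overlap, set_size, term_size, universe_size,
#'   p, adj_p`, ordered by p.
#' @export
term_overrepresentation <- function(gene_set, universe, term_map) {
  if (length(universe) == 0L) stopf("empty universe")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) stopf("gene set must be a subset of the universe")
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  terms <- unique(tm$term)
  N <- length(unique(universe)); nset <- length(gene_set)
  rows <- lapply(terms, function(t) {
    tg <- unique(tm$gene[tm$term == t])
    a <- length(intersect(tg, gene_set))
    K <- length(tg)
    ft <- stats::fisher.test(matrix(c(a, nset - a, K - a, N - nset - (K - a)), 2))
    data.frame(term = t, overlap = a, set_size = nset, term_size = K,
               universe_size = N, p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), overlap = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      adj_p = numeric(0)))
  }
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the candidate network as node and edge tables
#'
#' Three-axis network: miRNA nodes (selected candidates), mRNA nodes
#' (their consensus targets), and term nodes (significant annotation
#' terms). Edges are selected miRNA-target interactions and target-term
#' annotations. Output ordering is deterministic.
#'
#' @param candidates table from [select_candidates()] (only `selected`
#'   rows are exported).
#' @param consensus named list from [consensus_targets()].
#' @param term_hits table from [term_overrepresentation()]; rows with
#'   `adj_p < term_fdr` become term nodes.
#' @param term_map data.frame `gene, term` used for target-term edges.
#' @param transcript_de optional DE table (`id, log2fc, adj_p`) to annotate
#'   mRNA nodes with signed log10 FDR and rank.
#' @param term_fdr FDR threshold for term nodes.
#' @param dir optional output directory; writes `nodes.tsv`, `edges.tsv`.
#' @return list with `nodes` (`id, axis, rank, signed_log10_fdr`) and
#'   `edges` (`from, to, kind`).
#' @export
export_network <- function(candidates, consensus, term_hits = NULL,
                           term_map = NULL, transcript_de = NULL,
                           term_fdr = 0.05, dir = NULL) {
  sel <- candidates[candidates$selected, , drop = FALSE]
  sel <- sel[order(sel$mirna_id), , drop = FALSE]
  slfdr <- function(p, s) ifelse(s >= 0, 1, -1) * -log10(pmax(p, 1e-300))
  mi_nodes <- data.frame(
    id = sel$mirna_id,
    axis = rep("miRNA", nrow(sel)),
    rank = sel$log2fc,
    signed_log10_fdr = slfdr(sel$de_adj_p, sel$log2fc),
    stringsAsFactors = FALSE)
  edges_mt <- do.call(rbind, lapply(sel$mirna_id, function(m) {
    tg <- sort(consensus[[m]])
    if (length(tg) == 0L) return(NULL)
    data.frame(from = m, to = tg, kind = "mirna-target", stringsAsFactors = FALSE)
  }))
  targets <- if (is.null(edges_mt)) character(0) else sort(unique(edges_mt$to))
  mr_nodes <- data.frame(id = targets, axis = rep("mRNA", length(targets)),
                         rank = numeric(length(targets)),
                         signed_log10_fdr = numeric(length(targets)),
                         stringsAsFactors = FALSE)
  if (!is.null(transcript_de) && nrow(mr_nodes) > 0) {
    j <- match(mr_nodes$id, transcript_de$id)
    ok <- !is.na(j)
    mr_nodes$rank[ok] <- adjusted_rank(transcript_de$base_mean[j[ok]],
                                       transcript_de$log2fc[j[ok]],
                                       transcript_de$adj_p[j[ok]])
    mr_nodes$signed_log10_fdr[ok] <- slfdr(transcript_de$adj_p[j[ok]],
                                           transcript_de$log2fc[j[ok]])
  }
  term_nodes <- NULL; edges_tt <- NULL
  if (!is.null(term_hits) && nrow(term_hits) > 0) {
    th <- term_hits[term_hits$adj_p < term_fdr, , drop = FALSE]
    th <- th[order(th$term), , drop = FALSE]
    if (nrow(th) > 0) {
      term_nodes <- data.frame(id = th$term, axis = "term", rank = th$overlap,
                               signed_log10_fdr = -log10(pmax(th$adj_p, 1e-300)),
                               stringsAsFactors = FALSE)
      if (!is.null(term_map)) {
        tm <- term_map[term_map$gene %in% targets & term_map$term %in% th$term, ,
                       drop = FALSE]
        if (nrow(tm) > 0) {
          tm <- tm[order(tm$gene, tm$term), , drop = FALSE]
          edges_tt <- data.frame(from = tm$gene, to = tm$term,
                                 kind = "target-term", stringsAsFactors = FALSE)
        }
      }
    }
  }
  nodes <- rbind(mi_nodes, mr_nodes, term_nodes)
  edges <- rbind(edges_mt, edges_tt)
  if (is.null(nodes)) nodes <- data.frame(id = character(0), axis = character(0),
                                          rank = numeric(0),
                                          signed_log10_fdr = numeric(0))
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0),
                                          kind = character(0))
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(nodes, file.path(dir, "nodes.tsv"))
    write_tsv(edges, file.path(dir, "edges.tsv"))
  }
  list(nodes = nodes, edges = edges)
}

#' Simple two-group differential expression for synthetic cohorts
#'
#' Welch t-test per feature on log2(CPM + 1), with the mean CPM as base
#' mean and the difference of group means of log2(CPM + 1) as log2 fold
#' change (group 2 minus group 1), BH-adjusted. This is a deliberately
#' simple built-in so synthetic cohort runs are self-contained; externally
#' produced DE tables in the same `id, base_mean, log2fc, p, adj_p` layout
#' can be used anywhere this output is consumed.
#'
#' @param counts feature x sample count matrix.
#' @param group factor or vector with two levels; the second level is the
#'   "tumor"/treatment group.
#' @return data.frame `id, base_mean, log2fc, p, adj_p`.
#' @export
simple_de <- function(counts, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stopf("group must have exactly 2 levels")
  cpm <- t(t(counts) / pmax(colSums(counts), 1)) * 1e6
  lg <- log2(cpm + 1)
  g2 <- group == levels(group)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- rowMeans(lg[, !g2, drop = FALSE]); m2 <- rowMeans(lg[, g2, drop = FALSE])
  v1 <- apply(lg[, !g2, drop = FALSE], 1, stats::var)
  v2 <- apply(lg[, g2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  data.frame(id = rownames(counts), base_mean = rowMeans(cpm),
             log2fc = m2 - m1, p = p, adj_p = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the candidate-selection pipeline on a cohort
#'
#' Orchestrates the full screen on matched miRNA/transcript count matrices:
#' two-group DE for both feature types ([simple_de()] by default),
#' per-sample interaction prediction and consensus target sets, ranked-set
#' enrichment per miRNA, correlation with the designated regulator
#' transcript, and criteria-based candidate selection.
#'
#' @param mirna_counts,transcript_counts feature x sample count matrices
#'   (shared samples).
#' @param site_counts miRNA x transcript binding-site count matrix.
#' @param group two-level group vector over samples (second level = tumor).
#' @param regulator id of the regulator transcript (row of
#'   `transcript_counts`).
#' @param de_mirna,de_transcript optional externally computed DE tables
#'   (`id, base_mean, log2fc, p, adj_p`); [simple_de()] is used when NULL.
#' @param min_targets,expr_floor see [predict_interactions()].
#' @param n_partitions see [ranked_enrichment()].
#' @param fdr_de,fdr_corr,fdr_combined see [select_candidates()].
#' @return list with `candidates`, `de_mirna`, `de_transcript`, `ranked`,
#'   `enrichment`, `correlation`, `consensus`.
#' @export
run_candidate_pipeline <- function(mirna_counts, transcript_counts, site_counts,
                                   group, regulator,
                                   de_mirna = NULL, de_transcript = NULL,
                                   min_targets = 5L, expr_floor = 1,
                                   n_partitions = 30L,
                                   fdr_de = 0.1, fdr_corr = 0.1,
                                   fdr_combined = 0.05) {
  if (!regulator %in% rownames(transcript_counts)) {
    stopf("regulator '%s' not in transcript matrix", regulator)
  }
  if (is.null(de_mirna)) de_mirna <- simple_de(mirna_counts, group)
  if (is.null(de_transcript)) de_transcript <- simple_de(transcript_counts, group)
  ranked <- rank_transcripts(de_transcript)
  per_sample <- predict_interactions(mirna_counts, transcript_counts, site_counts,
                                     min_targets = min_targets,
                                     expr_floor = expr_floor)
  consensus <- consensus_targets(per_sample)
  enr <- do.call(rbind, lapply(names(consensus), function(m) {
    tg <- intersect(consensus[[m]], ranked$transcript_id)
    if (length(tg) == 0L) return(NULL)
    e <- ranked_enrichment(ranked, tg, n_partitions = n_partitions)
    data.frame(mirna_id = m, direction = e$direction, p_value = e$p_value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(enr)) {
    enr <- data.frame(mirna_id = character(0), direction = character(0),
                      p_value = numeric(0))
  }
  enr$adj_p <- bh_adjust(enr$p_value)
  ## correlation with the regulator is assessed within the tumor samples
  ## (second group level), so that tumor-vs-control shifts cannot inject
  ## spurious correlation
  tum <- group == levels(as.factor(group))[2]
  lg <- log2(mirna_counts[, tum, drop = FALSE] + 1)
  reg_lg <- log2(transcript_counts[regulator, tum] + 1)
  corr <- correlate_with_regulator(lg, reg_lg)
  cand <- select_candidates(de_mirna, enr, corr, fdr_de = fdr_de,
                            fdr_corr = fdr_corr, fdr_combined = fdr_combined)
  list(candidates = cand, de_mirna = de_mirna, de_transcript = de_transcript,
       ranked = ranked, enrichment = enr, correlation = corr,
       consensus = consensus)
}
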