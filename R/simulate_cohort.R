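#' Parameters for the tumor/control cohort simulators
#'
#' @param n_tumor,n_control sample counts per group.
#' @param n_mirna,n_transcript feature counts.
#' @param site_count_sparsity fraction of miRNA-transcript pairs carrying
#'   at least one predicted binding site.
#' @param planted_suppressors named list, miRNA id -> `list(targets =
#'   <transcript ids>, strength = <log2 repression per log2 unit of miRNA
#'   change>)`. Planted pairs are guaranteed a binding site.
#' @param mirna_log2fc named numeric, miRNA id -> tumor-vs-control log2
#'   fold change (unnamed miRNAs are null).
#' @param regulator_corr named numeric in \[-1,1\], miRNA id -> latent
#'   Pearson correlation with the designated regulator transcript.
#' @param regulator id of the regulator transcript row.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param bio_sdlog biological log-normal variability of per-sample
#'   expected expression (log scale).
#' @param survival_beta named numeric, feature id -> log-hazard coefficient
#'   per standard deviation of expression, for [simulate_survival_cohort()].
#' @param censor_rate expected fraction of samples censored (in \[0,1)).
#' @param seed RNG seed.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(n_tumor = 60L, n_control = 30L,
                          n_mirna = 50L, n_transcript = 400L,
                          site_count_sparsity = 0.05,
                          planted_suppressors = list(),
                          mirna_log2fc = numeric(0),
                          regulator_corr = numeric(0),
                          regulator = "REGULATOR",
                          dispersion = 0.02,
                          bio_sdlog = 0.8,
                          survival_beta = numeric(0),
                          censor_rate = 0.3,
                          seed = 1L) {
  if (any(abs(regulator_corr) > 1)) stopf("|regulator_corr| must be <= 1")
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must lie in [0,1)")
  if (any(!is.finite(survival_beta))) stopf("survival_beta must be finite")
  structure(list(
    n_tumor = as.integer(n_tumor), n_control = as.integer(n_control),
    n_mirna = as.integer(n_mirna), n_transcript = as.integer(n_transcript),
    site_count_sparsity = site_count_sparsity,
    planted_suppressors = planted_suppressors,
    mirna_log2fc = mirna_log2fc, regulator_corr = regulator_corr,
    regulator = regulator, dispersion = dispersion, bio_sdlog = bio_sdlog,
    survival_beta = survival_beta, censor_rate = censor_rate,
    seed = as.integer(seed)), class = "cohort_params")
}

#' Simulate a tumor/control expression cohort
#'
#' Generates matched miRNA and transcript count matrices with
#' negative-binomial noise around log-normal baseline means, a binding-site
#' count matrix, and planted structure: per-miRNA tumor fold changes;
#' suppressed targets whose tumor means drop by the planted log2
#' repression strength times the miRNA's log2 change; and a designated
#' regulator transcript whose per-sample latent factor is shared (at the
#' requested correlation) with chosen miRNAs.
#'
#' @param params a `cohort_params` object.
#' @param dir optional output directory; writes `mirna_counts.tsv`,
#'   `transcript_counts.tsv`, `site_counts.tsv`, `truth_*.tsv`.
#' @return list with `mirna_counts`, `transcript_counts` (feature x
#'   sample), `site_counts` (miRNA x transcript), `group` (factor
#'   control/tumor), and `truth` (list of planted values).
#' @export
simulate_expression_cohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    p <- params
    mirnas <- sprintf("miR-sim-%02d", seq_len(p$n_mirna))
    ## planted suppressors may use their own ids; honor them
    extra <- setdiff(names(p$planted_suppressors), mirnas)
    if (length(extra)) mirnas[seq_along(extra)] <- extra
    extra2 <- setdiff(names(p$mirna_log2fc), mirnas)
    if (length(extra2)) stopf("mirna_log2fc key not simulated: %s", extra2[1])
    transcripts <- sprintf("TX%04d", seq_len(p$n_transcript))
    if (!p$regulator %in% transcripts) transcripts[p$n_transcript] <- p$regulator
    for (m in names(p$planted_suppressors)) {
      bad <- setdiff(p$planted_suppressors[[m]]$targets, transcripts)
      if (length(bad)) stopf("planted target not in transcript universe: %s", bad[1])
    }
    samples <- c(sprintf("C%03d", seq_len(p$n_control)),
                 sprintf("T%03d", seq_len(p$n_tumor)))
    group <- factor(rep(c("control", "tumor"), c(p$n_control, p$n_tumor)),
                    levels = c("control", "tumor"))
    nS <- length(samples)

    ## binding sites: sparse Poisson counts, planted pairs forced >= 1
    sites <- matrix(0L, p$n_mirna, p$n_transcript,
                    dimnames = list(mirnas, transcripts))
    nz <- which(stats::runif(length(sites)) < p$site_count_sparsity)
    sites[nz] <- 1L + stats::rpois(length(nz), 0.5)
    for (m in names(p$planted_suppressors)) {
      tg <- p$planted_suppressors[[m]]$targets
      sites[m, tg] <- pmax(sites[m, tg], 1L)
    }

    ## baseline means; planted features kept well expressed so they pass
    ## expression floors in every sample
    mu_mi <- stats::rlnorm(p$n_mirna, log(500), 1)
    names(mu_mi) <- mirnas
    mu_mi[names(p$planted_suppressors)] <- pmax(mu_mi[names(p$planted_suppressors)], 500)
    mu_tx <- stats::rlnorm(p$n_transcript, log(300), 1)
    names(mu_tx) <- transcripts
    planted_tg <- unique(unlist(lapply(p$planted_suppressors, `[[`, "targets")))
    mu_tx[planted_tg] <- pmax(mu_tx[planted_tg], 300)
    mu_tx[p$regulator] <- max(mu_tx[p$regulator], 1000)

    ## tumor log2 shifts
    lfc_mi <- setNames(numeric(p$n_mirna), mirnas)
    lfc_mi[names(p$mirna_log2fc)] <- p$mirna_log2fc
    lfc_tx <- setNames(numeric(p$n_transcript), transcripts)
    for (m in names(p$planted_suppressors)) {
      ps <- p$planted_suppressors[[m]]
      lfc_tx[ps$targets] <- lfc_tx[ps$targets] - ps$strength * lfc_mi[m]
    }

    tumor <- as.integer(group == "tumor")
    ## latent per-sample biological factors; the regulator's factor is
    ## shared with chosen miRNAs at the requested correlation
    z_reg <- stats::rnorm(nS)
    z_mi <- matrix(stats::rnorm(p$n_mirna * nS), p$n_mirna, nS,
                   dimnames = list(mirnas, samples))
    for (m in names(p$regulator_corr)) {
      r <- p$regulator_corr[[m]]
      z_mi[m, ] <- r * z_reg + sqrt(1 - r^2) * z_mi[m, ]
    }
    z_tx <- matrix(stats::rnorm(p$n_transcript * nS), p$n_transcript, nS,
                   dimnames = list(transcripts, samples))
    z_tx[p$regulator, ] <- z_reg

    size <- 1 / p$dispersion
    mean_mi <- mu_mi * 2^(outer(lfc_mi, tumor)) * exp(p$bio_sdlog * z_mi)
    mean_tx <- mu_tx * 2^(outer(lfc_tx, tumor)) * exp(p$bio_sdlog * z_tx)
    counts_mi <- matrix(stats::rnbinom(length(mean_mi), mu = mean_mi, size = size),
                        p$n_mirna, nS, dimnames = list(mirnas, samples))
    counts_tx <- matrix(stats::rnbinom(length(mean_tx), mu = mean_tx, size = size),
                        p$n_transcript, nS, dimnames = list(transcripts, samples))

    truth <- list(mirna_log2fc = lfc_mi, transcript_log2fc = lfc_tx,
                  suppressors = p$planted_suppressors,
                  regulator = p$regulator, regulator_corr = p$regulator_corr)
    out <- list(mirna_counts = counts_mi, transcript_counts = counts_tx,
                site_counts = sites, group = group, samples = samples,
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_matrix_tsv(counts_mi, file.path(dir, "mirna_counts.tsv"))
      write_matrix_tsv(counts_tx, file.path(dir, "transcript_counts.tsv"))
      write_matrix_tsv(sites, file.path(dir, "site_counts.tsv"))
      write_tsv(data.frame(sample = samples, group = as.character(group)),
                file.path(dir, "samples.tsv"))
      write_tsv(data.frame(feature = names(lfc_mi), log2fc = lfc_mi),
                file.path(dir, "truth_mirna_log2fc.tsv"))
    }
    out
  })
}

#' Simulate a survival cohort with expression-linked hazards
#'
#' Draws per-sample expression for a set of features (log-normal with
#' negative-binomial-like noise), standardizes each feature, and samples
#' survival times from an exponential distribution with hazard
#' `h0 * exp(sum(beta * z))`. Censoring is independent exponential with its
#' rate chosen so the expected censored fraction equals `censor_rate`
#' under the baseline hazard.
#'
#' @param params a `cohort_params` object (`survival_beta` names the
#'   informative features; `censor_rate` the censoring level).
#' @param n number of samples (defaults to tumor + control counts).
#' @param n_features total features simulated; features beyond
#'   `survival_beta` are null.
#' @param h0 baseline hazard per day.
#' @param dir optional output directory; writes `clinical.tsv` and
#'   `survival_expression.tsv`.
#' @return list with `clinical` (data.frame `sample_id, time, event`),
#'   `expression` (feature x sample matrix), and `truth` (betas and the
#'   realized event fraction).
#' @export
simulate_survival_cohort <- function(params, n = NULL, n_features = NULL,
                                     h0 = 1 / 1000, dir = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$censor_rate >= 1) stopf("censor_rate = 1 leaves no events")
  with_seed(params$seed + 1L, {
    p <- params
    if (is.null(n)) n <- p$n_tumor + p$n_control
    betas <- p$survival_beta
    feats <- names(betas)
    if (is.null(n_features)) n_features <- max(length(feats), 1L)
    if (n_features > length(feats)) {
      feats <- c(feats, sprintf("null-feat-%02d", seq_len(n_features - length(feats))))
      betas <- c(betas, setNames(numeric(n_features - length(betas)),
                                 setdiff(feats, names(betas))))
    }
    samples <- sprintf("S%04d", seq_len(n))
    expr <- matrix(stats::rlnorm(length(feats) * n, log(500), 0.8),
                   length(feats), n, dimnames = list(feats, samples))
    z <- t(scale(t(log(expr))))
    lp <- as.numeric(crossprod(z, betas[feats]))   # sum over features
    times <- stats::rexp(n, rate = h0 * exp(lp))
    if (p$censor_rate > 0) {
      cens <- stats::rexp(n, rate = h0 * p$censor_rate / (1 - p$censor_rate))
      event <- as.integer(times <= cens)
      time <- pmin(times, cens)
    } else {
      event <- rep(1L, n)
      time <- times
    }
    time <- pmax(time, 1e-6)
    clinical <- data.frame(sample_id = samples, time = time, event = event,
                           stringsAsFactors = FALSE)
    out <- list(clinical = clinical, expression = expr,
                truth = list(beta = betas, event_fraction = mean(event)))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(clinical, file.path(dir, "clinical.tsv"))
      write_matrix_tsv(expr, file.path(dir, "survival_expression.tsv"))
    }
    out
  })
}
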