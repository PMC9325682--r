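## Five-gene pro-apoptotic NF-kB signature: per-sample score, median split,
## Kaplan-Meier curves, log-rank test and stage-wise comparisons.

#' Default signature gene set
#' @export
nfkb_signature_genes <- c("FAS", "FASLG", "TNFSF10", "TRAF1", "TRAF2")

#' Per-sample signature score
#'
#' Each gene's expression is z-scored across samples (sample sd); the
#' signature score is the mean of the per-gene z-scores.
#'
#' @param cohort data.frame with one column per signature gene.
#' @param genes signature gene names (default the five-gene NF-kB set).
#' @return named numeric score per sample.
#' @export
signature_score <- function(cohort, genes = nfkb_signature_genes) {
  missing <- setdiff(genes, names(cohort))
  if (length(missing) > 0L)
    stop("cohort lacks gene column(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(cohort[, genes])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ", paste(genes[sds == 0], collapse = ", "))
  z <- scale(x)
  sc <- rowMeans(z)
  names(sc) <- if ("sample_id" %in% names(cohort)) cohort$sample_id
               else rownames(cohort)
  sc
}

#' Median split into high/low signature groups
#'
#' High iff score >= median (inclusive); the median is the standard
#' midpoint for even n. A degenerate split (all scores equal) is flagged
#' with a warning.
#'
#' @param scores numeric score per sample.
#' @return factor with levels low, high.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2L)
  med <- stats::median(scores)
  if (all(scores == scores[1L]))
    warning("all scores identical; degenerate split (everyone high)")
  factor(ifelse(scores >= med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times survival/censoring times (> 0).
#' @param events event indicator (1 = death, 0 = censored).
#' @return data.frame: time (distinct event times), n_risk, n_event,
#'   surv (product-limit estimate).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) >= 1L, all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], surv = fit$surv[keep])
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared statistic on 1 degree of freedom; the
#' p-value is the upper tail of the chi-squared distribution. A zero
#' hypergeometric variance (no comparable event times) yields p = 1 with a
#' warning.
#'
#' @param times survival times.
#' @param events event indicators (1 = death).
#' @param groups two-level grouping factor.
#' @return list: chisq, df, p.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two nonempty groups required")
  sd0 <- tryCatch(
    survival::survdiff(survival::Surv(times, events) ~ groups),
    error = function(e) NULL)
  if (is.null(sd0) || !is.finite(sd0$chisq)) {
    warning("zero log-rank variance; p = 1")
    return(list(chisq = 0, df = 1L, p = 1))
  }
  list(chisq = unname(sd0$chisq), df = 1L,
       p = chisq_pvalue(sd0$chisq, 1L))
}

#' Upper-tail chi-squared p-value
#'
#' The routine used to turn a log-rank chi-squared statistic into its
#' p-value.
#'
#' @param chisq chi-squared statistic.
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
#' @examples
#' round(chisq_pvalue(6.6), 2)  # 0.01
#' round(chisq_pvalue(4.3), 2)  # 0.04
chisq_pvalue <- function(chisq, df = 1L) {
  stats::pchisq(chisq, df = df, lower.tail = FALSE)
}

#' Signature survival stratification
#'
#' End-to-end readout: score, median split, per-group Kaplan-Meier curves
#' and the two-group log-rank test.
#'
#' @param cohort data.frame with signature gene columns plus `os_time` and
#'   `os_event`.
#' @param genes signature gene names.
#' @return object of class `signature_result`: list with `score`, `group`,
#'   `km` (named list of KM data.frames), `logrank` (chisq, df, p).
#' @export
signature_survival <- function(cohort, genes = nfkb_signature_genes) {
  sc <- signature_score(cohort, genes)
  grp <- median_split(sc)
  km <- lapply(split(seq_len(nrow(cohort)), grp), function(ii)
    km_estimate(cohort$os_time[ii], cohort$os_event[ii]))
  lr <- logrank_test(cohort$os_time, cohort$os_event, grp)
  structure(list(score = sc, group = grp, km = km, logrank = lr),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("signature_result:", length(x$score), "samples;",
      sum(x$group == "high"), "high /", sum(x$group == "low"), "low\n")
  cat(sprintf("log-rank chi-squared = %.3g on %d df, p = %.3g\n",
              x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}

#' Stage-wise signature comparison
#'
#' Kruskal-Wallis global test (with tie correction) across disease stages
#' plus two-sided pairwise Wilcoxon rank-sum tests, Holm-Sidak adjusted.
#' Stages with fewer than 2 samples are excluded with a warning.
#'
#' @param scores numeric signature scores.
#' @param stages stage labels aligned to `scores`.
#' @return list: `global_p` (Kruskal-Wallis), `pairwise` (data.frame
#'   stage_a, stage_b, p, p_adj).
#' @export
stage_comparison <- function(scores, stages) {
  stages <- as.factor(stages)
  sizes <- table(stages)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("stage(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
    keep <- !(stages %in% small)
    scores <- scores[keep]; stages <- droplevels(stages[keep])
  }
  if (nlevels(stages) < 2L) stop("need >= 2 stages with >= 2 samples")
  kw <- stats::kruskal.test(scores, stages)
  pairs <- utils::combn(levels(stages), 2L)
  praw <- apply(pairs, 2L, function(pp)
    suppressWarnings(stats::wilcox.test(scores[stages == pp[1L]],
                                        scores[stages == pp[2L]])$p.value))
  list(global_p = kw$p.value,
       pairwise = data.frame(stage_a = pairs[1L, ], stage_b = pairs[2L, ],
                             p = praw, p_adj = holm_sidak(praw),
                             stringsAsFactors = FALSE))
}
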