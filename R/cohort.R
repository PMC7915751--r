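# Cohort-level statistics: distribution diagnostics of the MitoTracker-low
# proportion, deterministic 1-D k-means stratification into two clusters,
# and association statistics (Pearson correlations with TNF secretion,
# per-cluster mean +/- SEM with two-sample t-tests).

#' Shapiro-Wilk normality test of the proportion distribution
#'
#' @param x Numeric vector (`n >= 3`).
#' @return List: `statistic` (W), `p`, `degenerate` (TRUE for constant
#'   input, where W/p are `NA`).
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 values")
  if (sd(x) == 0) {
    warning("constant input: normality test degenerate")
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  s <- shapiro.test(x)
  list(statistic = unname(s$statistic), p = s$p.value, degenerate = FALSE)
}

#' Deterministic 1-D k-means with k = 2
#'
#' For one-dimensional data the optimal 2-means partition is a contiguous
#' split of the sorted values, so the global optimum is found by exhaustive
#' search over all n - 1 splits — no random initialization. Clusters are
#' numbered so that center 1 < center 2.
#'
#' @param x Numeric vector with `n >= 2` and at least two distinct values.
#' @return List: `cluster` (1/2 per input value, original order), `centers`
#'   (sorted), `withinss` (per cluster), `tot_withinss`.
#' @export
kmeans2 <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  if (length(unique(x)) < 2L) stop("all values identical: no 2-cluster split")
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ss_tot <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    s1 <- cs[k]; s2 <- cs[n] - cs[k]
    q1 <- cs2[k]; q2 <- cs2[n] - cs2[k]
    ss_tot[k] <- (q1 - s1^2 / k) + (q2 - s2^2 / (n - k))
  }
  k <- which.min(ss_tot)
  cl_sorted <- rep(c(1L, 2L), times = c(k, n - k))
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  centers <- c(mean(xs[1:k]), mean(xs[(k + 1L):n]))
  wss <- c(sum((xs[1:k] - centers[1])^2), sum((xs[(k + 1L):n] - centers[2])^2))
  list(cluster = cluster, centers = centers, withinss = wss,
       tot_withinss = ss_tot[k])
}

#' Pearson correlation with two-tailed p-value
#'
#' Sample Pearson r with significance from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3`), nonzero variance.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Independent-samples Student t-test (pooled variance)
#'
#' Two-sample t with the pooled-variance estimator on `n_a + n_b - 2`
#' degrees of freedom; `welch = TRUE` switches to the Welch statistic.
#'
#' @param a,b Numeric vectors, each with `n >= 2`.
#' @param welch Use the Welch (unequal-variance) form.
#' @return List: `t`, `p` (two-tailed), `df`.
#' @export
ttest_ind <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  if (welch) {
    va <- var(a) / na; vb <- var(b) / nb
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  p <- if (is.nan(t)) 1 else 2 * pt(-abs(t), df = df)
  if (is.nan(t)) t <- 0
  list(t = t, p = p, df = df)
}

#' Mean and standard error of the mean
#' @param x Numeric vector.
#' @return List: `mean`, `sem` (`sd/sqrt(n)`), `n`.
#' @export
summarize_mean_sem <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
}

#' TNF activation metrics
#'
#' Increase = LPS-induced minus basal secretion (pg/mL); fold = ratio,
#' defined only for positive basal secretion.
#'
#' @param tnf_basal,tnf_lps Secretion (pg/mL).
#' @return Data frame with `increase` and `fold`.
#' @export
tnf_metrics <- function(tnf_basal, tnf_lps) {
  data.frame(increase = tnf_lps - tnf_basal,
             fold = ifelse(tnf_basal > 0, tnf_lps / tnf_basal, NA_real_))
}

#' Cohort association report
#'
#' Given the subject-level covariate table (including the estimated
#' MitoTracker-low proportion), computes: Pearson correlations of the
#' proportion with basal and LPS-induced TNF; the deterministic 2-cluster
#' stratification of the proportion; and, per cluster, mean +/- SEM with
#' pooled-variance t-tests for IMT, plaque score, basal TNF, LPS-induced
#' TNF, TNF increase and TNF fold change. Holm-adjusted p-values are
#' reported alongside the raw ones. Cluster 1 is the low-proportion cluster.
#'
#' @param covariates Data frame with columns `subject_id`, `prop_low`,
#'   `imt`, `plaque_score`, `tnf_basal`, `tnf_lps`.
#' @param normality Also run [normality_test()] on `prop_low`.
#' @return List: `correlations` (data frame), `clusters` (subject_id,
#'   prop_low, cluster), `centers`, `comparison` (per-covariate cluster
#'   means, SEMs, t, p, p_holm), `normality`, `fig_density` (KDE of the
#'   proportion distribution), `n_dropped`.
#' @export
cohort_report <- function(covariates, normality = TRUE) {
  need <- c("subject_id", "prop_low", "imt", "plaque_score", "tnf_basal",
            "tnf_lps")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  num_cols <- setdiff(need, "subject_id")
  complete <- Reduce(`&`, lapply(covariates[num_cols],
                                 function(v) is.finite(as.numeric(v))))
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    warning(sprintf("dropping %d subject(s) with incomplete covariates",
                    n_dropped))
  cov <- covariates[complete, , drop = FALSE]
  if (nrow(cov) < 4L) stop("need at least 4 subjects with complete covariates")

  tm <- tnf_metrics(cov$tnf_basal, cov$tnf_lps)
  cov$tnf_increase <- tm$increase
  cov$tnf_fold <- tm$fold

  corr <- do.call(rbind, lapply(
    c(tnf_basal = "tnf_basal", tnf_lps = "tnf_lps"), function(v) {
      ct <- pearson_cor(cov$prop_low, cov[[v]])
      data.frame(variable = v, r = ct$r, p = ct$p, n = ct$n,
                 stringsAsFactors = FALSE)
    }))
  rownames(corr) <- NULL

  km <- kmeans2(cov$prop_low)
  clusters <- data.frame(subject_id = cov$subject_id, prop_low = cov$prop_low,
                         cluster = km$cluster, stringsAsFactors = FALSE)

  comp_vars <- c(imt = "imt", plaque_score = "plaque_score",
                 tnf_basal = "tnf_basal", tnf_lps = "tnf_lps",
                 tnf_increase = "tnf_increase", tnf_fold = "tnf_fold")
  comparison <- do.call(rbind, lapply(comp_vars, function(v) {
    a <- cov[[v]][km$cluster == 1L]
    b <- cov[[v]][km$cluster == 2L]
    sa <- summarize_mean_sem(a); sb <- summarize_mean_sem(b)
    tt <- if (sa$n >= 2L && sb$n >= 2L) ttest_ind(a, b)
          else list(t = NA_real_, p = NA_real_, df = NA_real_)
    data.frame(variable = v, mean_1 = sa$mean, sem_1 = sa$sem, n_1 = sa$n,
               mean_2 = sb$mean, sem_2 = sb$sem, n_2 = sb$n,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL
  comparison$p_holm <- p.adjust(comparison$p, method = "holm")

  dens <- density(cov$prop_low, bw = "nrd0")
  list(correlations = corr, clusters = clusters, centers = km$centers,
       comparison = comparison,
       normality = if (normality) normality_test(cov$prop_low) else NULL,
       fig_density = data.frame(grid = dens$x, density = dens$y),
       n_dropped = n_dropped)
}

#' Presentation rounding for report tables
#'
#' Rounds numeric report cells to the conventional precision (integers for
#' TNF in pg/mL, one decimal for scores and millimetre-scale measures)
#' without touching the stored full-precision values.
#'
#' @param comparison The `comparison` element of [cohort_report()].
#' @return Data frame with rounded display columns.
#' @export
format_comparison <- function(comparison) {
  digits <- c(imt = 2, plaque_score = 1, tnf_basal = 0, tnf_lps = 0,
              tnf_increase = 0, tnf_fold = 1)
  out <- comparison
  for (i in seq_len(nrow(out))) {
    d <- digits[[out$variable[i]]]
    for (cn in c("mean_1", "sem_1", "mean_2", "sem_2"))
      out[[cn]][i] <- round(out[[cn]][i], d)
  }
  out$p <- signif(out$p, 3)
  out$p_holm <- signif(out$p_holm, 3)
  out
}
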