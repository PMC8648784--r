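# Age-of-onset screen: per-gene median expression split, logrank test on
# age at diagnosis (every age an observed event; no censoring), and
# Kaplan-Meier summaries.

#' Split samples at a gene's median expression
#'
#' Samples strictly above the median go to `high`; samples at or below it
#' (including ties at the median, and the middle sample at odd n) go to
#' `low`.
#'
#' @param values Named numeric expression vector.
#' @return List (high, low, split_value) or NULL with a warning when the
#'   split is degenerate (one side empty).
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop2("need >= 4 samples to split")
  med <- stats::median(values)
  high <- names(values)[values > med]
  low <- names(values)[values <= med]
  if (!length(high) || !length(low)) {
    warning("degenerate split (constant or near-constant expression)",
            call. = FALSE)
    return(NULL)
  }
  list(high = high, low = low, split_value = med)
}

#' Logrank test on event times
#'
#' Standard logrank statistic over the distinct event times: at each time
#' the observed group-1 events are compared with the hypergeometric
#' expectation given the risk sets, `chi2 = (sum(O1 - E1))^2 / sum(V)`,
#' referred to a chi-square with 1 df. All times are treated as observed
#' events (no censoring), as appropriate when the "event" is diagnosis at
#' a given age.
#'
#' @param times1,times2 Event times (ages at diagnosis) in the two groups.
#' @return List (chi2, p, observed1, expected1).
#' @export
logrank_test <- function(times1, times2) {
  times1 <- times1[!is.na(times1)]; times2 <- times2[!is.na(times2)]
  if (!length(times1) || !length(times2)) stop2("a group is empty")
  times <- sort(unique(c(times1, times2)))
  o1 <- e1 <- v <- 0
  for (tj in times) {
    n1 <- sum(times1 >= tj); n2 <- sum(times2 >= tj); n <- n1 + n2
    d1 <- sum(times1 == tj); d <- d1 + sum(times2 == tj)
    if (n < 2) next
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(list(chi2 = 0, p = 1, observed1 = o1, expected1 = e1))
  chi2 <- (o1 - e1)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       observed1 = o1, expected1 = e1)
}

#' Per-gene median-split logrank screen of age at diagnosis
#'
#' For every gene: split the scanned samples at its median expression,
#' logrank-test age at diagnosis between the high and low halves, rank by
#' ascending p with BH adjustment. Genes with a degenerate split or with
#' more than `max_missing_age` of their samples lacking age are skipped.
#'
#' @param expr An `expr_matrix` or logcpm matrix.
#' @param clinical Clinical data.frame (sample_id, age_at_diagnosis).
#' @param samples Samples to scan (typically the APCmut- group).
#' @param max_missing_age Maximum tolerated fraction of missing ages.
#' @return data.frame (gene, split_value, n_high, n_low, chi2, p, p_adj)
#'   sorted by ascending p.
#' @export
onset_scan <- function(expr, clinical, samples,
                       max_missing_age = 0.2) {
  mat <- if (inherits(expr, "expr_matrix")) expr$logcpm else expr
  samples <- intersect(samples, colnames(mat))
  age <- stats::setNames(clinical$age_at_diagnosis, clinical$sample_id)
  age <- age[samples]
  if (mean(is.na(age)) > max_missing_age)
    stop2("too many samples without age at diagnosis")
  ok <- samples[!is.na(age)]
  if (length(ok) < 4) stop2("need >= 4 samples with age")
  rows <- lapply(rownames(mat), function(g) {
    sp <- withCallingHandlers(
      median_split(mat[g, ok]),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(sp)) return(NULL)
    lr <- logrank_test(age[sp$high], age[sp$low])
    data.frame(gene = g, split_value = sp$split_value,
               n_high = length(sp$high), n_low = length(sp$low),
               chi2 = lr$chi2, p = lr$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop2("no gene produced a usable split")
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier curves of age at diagnosis by group
#'
#' With every age an observed event the Kaplan-Meier estimator reduces to
#' one minus the empirical CDF; curves and per-group median onset ages are
#' returned as step-function tables.
#'
#' @param ages Named list of numeric age vectors, one per group.
#' @return List with `curves` (data.frame group, time, surv, n_risk,
#'   n_event) and `medians` (named vector of median onset ages).
#' @export
km_curves <- function(ages) {
  stopifnot(is.list(ages), !is.null(names(ages)))
  rows <- lapply(names(ages), function(g) {
    a <- sort(ages[[g]][!is.na(ages[[g]])])
    if (!length(a)) return(NULL)
    times <- unique(a)
    n <- length(a)
    n_event <- as.integer(table(factor(a, levels = times)))
    n_risk <- n - cumsum(c(0, utils::head(n_event, -1)))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(group = g, time = times, surv = surv, n_risk = n_risk,
               n_event = n_event, stringsAsFactors = FALSE)
  })
  medians <- vapply(ages, function(a) stats::median(a, na.rm = TRUE),
                    numeric(1))
  list(curves = do.call(rbind, rows), medians = medians)
}
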