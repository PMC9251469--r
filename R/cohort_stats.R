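# Cohort-level statistics: gene-frequency tables, exact and rank tests,
# Kaplan-Meier survival with the log-rank test, and molecular-vs-pathology
# concordance.

#' 2x2 gene-frequency table for a cohort
#'
#' Cross-tabulates per-sample mutation flags against the IM/MO group label.
#' Counting is per sample (each lesion once), matching per-lesion reporting
#' denominators.
#'
#' @param labels character vector of group labels (`"IM"`/`"MO"`).
#' @param mutated logical vector: is the gene mutated in that sample?
#' @return 2x2 integer matrix, rows `mutated`/`wildtype`, columns `IM`/`MO`.
#' @export
gene_frequency_table <- function(labels, mutated) {
  if (length(labels) != length(mutated)) stop("length mismatch")
  if (any(is.na(labels)) || any(!labels %in% c("IM", "MO"))) {
    stop("every sample needs an IM/MO label")
  }
  if (any(is.na(mutated))) stop("every sample needs a mutation flag")
  tab <- matrix(0L, 2, 2, dimnames = list(c("mutated", "wildtype"),
                                          c("IM", "MO")))
  for (g in c("IM", "MO")) {
    tab["mutated", g] <- sum(labels == g & mutated)
    tab["wildtype", g] <- sum(labels == g & !mutated)
  }
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric enumeration: the probabilities
#' of all tables with the observed margins are computed and those no more
#' probable than the observed table are summed. The odds ratio is the
#' sample cross-product `(ad)/(bc)`, reported as `Inf` when `bc = 0`.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  n <- a + b + cc + d
  if (n == 0) stop("all-zero table")
  m1 <- a + b            # row-1 margin
  k1 <- a + cc           # column-1 margin
  xs <- max(0, k1 - (n - m1)):min(m1, k1)
  probs <- dhyper(xs, m1, n - m1, k1)
  p_obs <- dhyper(a, m1, n - m1, k1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * cc)
  }
  list(odds_ratio = or, p_value = p)
}

mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (`n_a + n_b <= 12`) the
#' p-value is computed by exact enumeration of all group assignments
#' (valid under ties); otherwise by the normal approximation with the tie
#' correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `U` (statistic for group `a`) and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  na <- length(a)
  nb <- length(b)
  u <- mw_u_statistic(a, b)
  mu <- na * nb / 2
  if (na + nb <= 12) {
    pool <- c(a, b)
    combs <- combn(na + nb, na)
    us <- apply(combs, 2, function(idx)
      mw_u_statistic(pool[idx], pool[-idx]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    n <- na + nb
    ties <- table(c(a, b))
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
  }
  list(U = u, p_value = min(1, p))
}

#' Welch two-sample t-test
#'
#' @param a,b numeric vectors with at least two values each.
#' @return list with `t` and `p_value` (two-sided, unequal variances).
#' @export
student_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(t = 0, p_value = 1))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value)
}

#' Kaplan-Meier curves and the log-rank test
#'
#' Product-limit survival estimate per group plus the log-rank chi-square
#' (1 degree of freedom for two groups). With a single group only the
#' curve is returned and the test fields are `NA`.
#'
#' @param times non-negative follow-up times.
#' @param events logical (TRUE = event observed, FALSE = censored).
#' @param groups group labels (1 or 2 levels).
#' @return list with `curves` (data frame: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `p_value`.
#' @export
km_logrank <- function(times, events, groups = rep("all", length(times))) {
  if (any(times < 0)) stop("negative survival time")
  if (is.factor(groups) && any(table(groups) == 0)) stop("empty group")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) == 0) stop("empty group")
  df <- data.frame(time = times, event = as.integer(events), group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = FALSE)
  grp <- if (is.null(sm$strata)) rep(names(tab)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       stringsAsFactors = FALSE)
  if (length(tab) < 2) {
    return(list(curves = curves, chisq = NA_real_, p_value = NA_real_))
  }
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(lr$n) - 1
  list(curves = curves, chisq = unname(lr$chisq),
       p_value = pchisq(lr$chisq, dfree, lower.tail = FALSE))
}

#' Molecular-vs-pathology concordance
#'
#' Percent agreement between the molecular MO/IM calls and the
#' pathologist's calls over the patients where pathology committed to a
#' call (`"unknown"`/`NA` pathology entries are excluded from both
#' counts). Symmetric in its two arguments.
#'
#' @param molecular,pathology character label vectors over the same
#'   patients, in the same order.
#' @return object of class `concordance_result`: list with `n_total`
#'   (compared patients), `n_agree`, `percent_agreement` (exact).
#' @export
concordance <- function(molecular, pathology) {
  if (length(molecular) != length(pathology)) stop("length mismatch")
  keep <- !is.na(molecular) & !is.na(pathology) &
    molecular != "unknown" & pathology != "unknown"
  if (!any(keep)) stop("no comparable patients")
  m <- molecular[keep]
  p <- pathology[keep]
  n_agree <- sum(m == p)
  structure(list(n_total = length(m), n_agree = n_agree,
                 percent_agreement = 100 * n_agree / length(m)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> %d/%d agree (%.1f%%)\n",
              x$n_agree, x$n_total, x$percent_agreement))
  invisible(x)
}

#' Group comparison of a continuous variable between MO and IM
#'
#' @param values numeric vector.
#' @param labels `"IM"`/`"MO"` labels.
#' @param test `"mann_whitney"` (default) or `"t"`.
#' @param variable name recorded in the output.
#' @return one-row data frame: variable, per-group n and mean, test name,
#'   statistic, p-value.
#' @export
group_comparison <- function(values, labels, test = c("mann_whitney", "t"),
                             variable = "value") {
  test <- match.arg(test)
  a <- values[labels == "IM"]
  b <- values[labels == "MO"]
  res <- if (test == "mann_whitney") {
    r <- mann_whitney(a, b)
    list(stat = r$U, p = r$p_value, name = "Mann-Whitney U")
  } else {
    r <- student_t(a, b)
    list(stat = r$t, p = r$p_value, name = "Welch t")
  }
  data.frame(variable = variable, n_im = length(a), n_mo = length(b),
             mean_im = mean(a), mean_mo = mean(b), test = res$name,
             statistic = res$stat, p_value = res$p, stringsAsFactors = FALSE)
}
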