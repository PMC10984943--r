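#' Stratify cohort samples by ECT-fraction profiles
#'
#' Hierarchical clustering of samples on 1 - Pearson correlation between their
#' ECT-fraction vectors, Ward.D2 linkage, cut at `k`; subgroup ids are ordered
#' by size (1 = largest). Constant rows (correlation undefined) are excluded
#' from the tree and assigned post hoc to the subgroup with the nearest
#' Euclidean centroid, with a warning.
#'
#' @param ect_fractions samples x ECT matrix (e.g. from [ect_fractions()]).
#' @param k number of subgroups (>= 2), default 4.
#' @return list: `labels` (integer subgroup per sample), `hclust` (tree over
#'   the non-constant samples).
#' @export
stratify_patients <- function(ect_fractions, k = 4L) {
  x <- as.matrix(ect_fractions)
  if (k < 2L) stop2("k must be >= 2")
  if (nrow(x) < k) stop2("need at least k samples")
  const <- apply(x, 1L, sd) == 0
  if (all(!const)) {
    core <- x
  } else {
    warning(sum(const), " constant sample row(s) assigned post hoc",
            call. = FALSE)
    core <- x[!const, , drop = FALSE]
    if (nrow(core) < k) stop2("fewer than k non-constant samples")
  }
  dd <- as.dist(1 - cor(t(core)))
  hc <- hclust(dd, method = "ward.D2")
  lab_core <- cutree(hc, k = k)
  labels <- integer(nrow(x))
  labels[!const] <- lab_core
  if (any(const)) {
    cent <- rowsum(core, lab_core) / as.vector(table(lab_core))
    for (i in which(const)) {
      d2 <- rowSums(sweep(cent, 2L, x[i, ])^2)
      labels[i] <- as.integer(rownames(cent)[which.min(d2)])
    }
  }
  labels <- renumber_by_size(labels)
  list(labels = labels, hclust = hc)
}

#' Kaplan-Meier curves and k-sample log-rank test
#'
#' Product-limit survival estimate per group, and the k-sample log-rank
#' chi-square computed directly from the observed-minus-expected event counts
#' with the hypergeometric variance-covariance at each distinct event time
#' (k - 1 degrees of freedom). With no events anywhere the test is undefined
#' and a `no_events` result is returned.
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @param group group label per subject (>= 2 non-empty groups).
#' @return list: `curves` (data.frame: group, time, n_risk, n_event, surv),
#'   `observed`, `expected` (per group), `chisq`, `df`, `p_value`,
#'   `no_events` flag.
#' @export
km_logrank <- function(time, event, group) {
  if (any(time < 0)) stop2("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop2("event must be 0/1")
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2L) stop2("need at least 2 groups")
  if (any(tab == 0L)) stop2("empty group")
  groups <- names(tab)

  curves <- do.call(rbind, lapply(groups, function(g) {
    tg <- time[group == g]; eg <- event[group == g]
    tu <- sort(unique(tg[eg == 1]))
    if (!length(tu))
      return(data.frame(group = character(0), time = numeric(0),
                        n_risk = integer(0), n_event = integer(0),
                        surv = numeric(0)))
    n_risk <- vapply(tu, function(t) sum(tg >= t), 1L)
    n_event <- vapply(tu, function(t) sum(tg == t & eg == 1), 1L)
    data.frame(group = g, time = tu, n_risk = n_risk, n_event = n_event,
               surv = cumprod(1 - n_event / n_risk))
  }))

  if (sum(event) == 0)
    return(list(curves = curves, observed = setNames(rep(0, length(groups)), groups),
                expected = setNames(rep(0, length(groups)), groups),
                chisq = NA_real_, df = length(groups) - 1L,
                p_value = NA_real_, no_events = TRUE))

  k <- length(groups)
  event_times <- sort(unique(time[event == 1]))
  O <- E <- setNames(numeric(k), groups)
  V <- matrix(0, k, k, dimnames = list(groups, groups))
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    ng <- vapply(groups, function(g) sum(at_risk & group == g), 1)
    dg <- vapply(groups, function(g) sum(time == t & event == 1 & group == g), 1)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      c1 <- d * (n - d) / (n - 1)
      V <- V + c1 * (diag(ng * n, k) - outer(ng, ng)) / n^2
    }
  }
  x <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(drop(t(x) %*% solve(Vk, x)),
                    error = function(e) drop(t(x) %*% MASS_ginv(Vk) %*% x))
  p <- pchisq(chisq, df = k - 1L, lower.tail = FALSE)
  list(curves = curves, observed = O, expected = E,
       chisq = chisq, df = k - 1L, p_value = p, no_events = FALSE)
}

# Moore-Penrose pseudoinverse via SVD (for singular log-rank variance, e.g.
# groups with identical event histories).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Median stratification into high/low groups
#'
#' `low` = value < median, `high` = value >= median (samples tied at the
#' median are "high"; with odd n the median sample is "high").
#'
#' @param values numeric vector (>= 2 samples, not all identical).
#' @return factor with levels `low`, `high`.
#' @export
median_stratify <- function(values) {
  if (length(values) < 2L) stop2("need at least 2 samples")
  if (length(unique(values)) < 2L)
    stop2("all values identical; median stratification impossible")
  factor(ifelse(values >= median(values), "high", "low"),
         levels = c("low", "high"))
}

#' Two-marker risk groups
#'
#' `low` risk = protective marker at or above its median AND adverse marker
#' below its median; all other samples are `high` risk. Used for the combined
#' Detox-iCAF-high / TGFβ-myCAF-low stratification.
#'
#' @param protective,adverse aligned numeric fraction vectors.
#' @return factor with levels `low`, `high` (risk).
#' @export
risk_groups <- function(protective, adverse) {
  if (length(protective) != length(adverse))
    stop2("fraction vectors must be aligned on samples")
  if (length(unique(protective)) < 2L || length(unique(adverse)) < 2L)
    stop2("degenerate median (all values identical)")
  low <- protective >= median(protective) & adverse < median(adverse)
  factor(ifelse(low, "low", "high"), levels = c("low", "high"))
}

#' Multivariate Cox proportional hazards model
#'
#' Partial-likelihood estimation with Efron tie handling (delegated to the
#' standard survival routine); per-covariate hazard ratio, Wald 95% CI and p.
#'
#' @param time,event survival outcome (event 0/1).
#' @param covariates data.frame of covariates (factors or numeric).
#' @return data.frame: term, coef, hr, ci_low, ci_high, se, p_value.
#' @export
cox_multivariate <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if ((is.factor(v) || is.character(v)) && length(unique(v)) < 2L)
      stop2("covariate with a single level: ", nm)
    if (is.numeric(v) && length(unique(v)) < 2L)
      stop2("constant covariate: ", nm)
  }
  df <- data.frame(.time = time, .event = event, covariates,
                   check.names = TRUE)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ .,
    data = df, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop2("Cox model did not converge")
  sm <- summary(fit)
  co <- sm$coefficients
  data.frame(term = rownames(co),
             coef = co[, "coef"],
             hr = exp(co[, "coef"]),
             ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             se = co[, "se(coef)"],
             p_value = co[, "Pr(>|z|)"],
             row.names = NULL)
}
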