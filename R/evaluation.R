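#' Risk dichotomies
#'
#' Three-level TdP risk labels are evaluated through two binary splits:
#' `low_vs_rest` (positives = intermediate + high) and `high_vs_rest`
#' (positives = high). No ordinal three-class statistic is computed.
#'
#' @param name `"low_vs_rest"` or `"high_vs_rest"`.
#' @return list with `name` and `positive_classes`.
#' @export
risk_dichotomy <- function(name = c("low_vs_rest", "high_vs_rest")) {
  name <- match.arg(name)
  list(name = name,
       positive_classes = if (name == "low_vs_rest")
         c("intermediate", "high") else "high")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
    return(as.integer(labels))
  }
  stop("labels must be logical or 0/1", call. = FALSE)
}

#' ROC area under the curve (Mann-Whitney, midrank ties)
#'
#' The AUC is computed as the Mann-Whitney probability that a randomly
#' chosen positive outranks a randomly chosen negative, with ties
#' counted half: `P(s_pos > s_neg) + 0.5 P(s_pos = s_neg)`, via midranks.
#' If the metric is oriented the other way (lower = riskier, as for a
#' torsade-metric-score-like reference), pass
#' `higher_is_positive = FALSE`; scores are negated internally and
#' `orientation_applied` is set. The function never guesses direction
#' from the data.
#'
#' @param scores numeric metric values.
#' @param labels binary labels (logical or 0/1), same length.
#' @param higher_is_positive logical; `TRUE` when larger scores should
#'   indicate the positive class.
#' @return object of class `roc_result`: `auc`, `n_pos`, `n_neg`,
#'   `orientation_applied`.
#' @examples
#' roc_auc(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, higher_is_positive = TRUE) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must not contain NA", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 1L || n_neg < 1L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  orientation_applied <- !isTRUE(higher_is_positive)
  if (orientation_applied) scores <- -scores
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg,
                 orientation_applied = orientation_applied),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (n_pos = %d, n_neg = %d%s)\n",
              x$auc, x$n_pos, x$n_neg,
              if (x$orientation_applied) ", metric negated" else ""))
  invisible(x)
}

# log-likelihood of a univariable logistic model at (a, b)
logistic_loglik <- function(a, b, scores, y) {
  eta <- a + b * scores
  # log(p) and log(1-p) in a numerically safe form: -log1p(exp(-|eta|)) ...
  sum(ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

#' Univariable logistic regression by maximum likelihood
#'
#' Fits `logit P(y = 1) = a + b * score` by Newton iteration (iterative
#' reweighting) on an internally standardised score, stopping when the
#' gradient max-norm on the standardised problem falls below `1e-8`.
#' Reports the likelihood-ratio statistic against the intercept-only
#' null, `chi2 = 2 (LL_model - LL_null)`.
#'
#' Complete or quasi-complete separation (the score ranges of the two
#' classes touch or do not overlap, so the ML slope diverges) is
#' detected geometrically before fitting; the fit then stops at a capped
#' number of iterations, `separation_detected = TRUE`,
#' `converged = FALSE`, and `chi2` is reported from the last stable
#' iterate (it approaches `2 * (-LL_null)` from below). Constant scores
#' yield `slope = 0`, `chi2 = 0`.
#'
#' @param scores numeric metric values.
#' @param labels binary labels (logical or 0/1), same length, both
#'   classes present.
#' @param max_iter iteration cap (default 25).
#' @return object of class `logistic_fit`: `intercept`, `slope` (on the
#'   original score scale), `loglik_model`, `loglik_null`, `chi2`,
#'   `converged`, `separation_detected`, `n_iter`.
#' @export
logistic_fit <- function(scores, labels, max_iter = 25L) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels must have equal length", call. = FALSE)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("degenerate fit: both classes must be present", call. = FALSE)
  n <- length(y)
  pbar <- n1 / n
  loglik_null <- n1 * log(pbar) + n0 * log(1 - pbar)

  s_sd <- stats::sd(scores)
  if (!is.finite(s_sd) || s_sd == 0) {
    # metric carries no information
    return(structure(list(intercept = stats::qlogis(pbar), slope = 0,
                          loglik_model = loglik_null,
                          loglik_null = loglik_null, chi2 = 0,
                          converged = TRUE, separation_detected = FALSE,
                          n_iter = 0L),
                     class = "logistic_fit"))
  }
  s_mu <- mean(scores)
  z <- (scores - s_mu) / s_sd
  # ML slope is finite iff the class score ranges strictly overlap
  separation <- min(z[y == 1L]) >= max(z[y == 0L]) ||
    min(z[y == 0L]) >= max(z[y == 1L])

  beta <- c(stats::qlogis(pbar), 0)
  X <- cbind(1, z)
  ll <- logistic_loglik(beta[1], beta[2], z, y)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, y - p))
    if (max(abs(grad)) < 1e-8) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X)
    step <- solve(H, grad)
    # halve the step until the likelihood does not decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_cand <- logistic_loglik(cand[1], cand[2], z, y)
      if (ll_cand >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll <- ll_cand
  }
  if (separation) converged <- FALSE
  structure(list(intercept = unname(beta[1] - beta[2] * s_mu / s_sd),
                 slope = unname(beta[2] / s_sd),
                 loglik_model = ll, loglik_null = loglik_null,
                 chi2 = max(0, 2 * (ll - loglik_null)),
                 converged = converged,
                 separation_detected = separation,
                 n_iter = iter),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> logit(p) = %.4g + %.4g * score; chi2(1) = %.4f%s%s\n",
    x$intercept, x$slope, x$chi2,
    if (!x$converged) " [not converged]" else "",
    if (x$separation_detected) " [separation]" else ""))
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return the square of the Pearson product-moment correlation, in
#'   `[0, 1]` (sign-blind).
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain NA", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y)^2
}

#' Two-sample t-test
#'
#' Welch's unequal-variance statistic with Welch-Satterthwaite degrees
#' of freedom by default (`var_equal = TRUE` gives the pooled Student
#' form). Two-sided p-value.
#'
#' @param a,b numeric vectors, each of length >= 2 with finite variance.
#' @param var_equal logical; pooled-variance Student's t if `TRUE`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("inputs must not contain NA", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Ranking-performance report for one or more metrics
#'
#' For each named metric column this computes, against the three-level
#' risk labels: the ROC AUC on both dichotomies (low vs intermediate +
#' high, and low + intermediate vs high), a univariable logistic
#' likelihood-ratio chi-square (on the low-vs-rest split by default),
#' the squared Pearson correlation with a reference metric when one is
#' named, and a two-sample t-test of low-risk versus the rest. Metric
#' orientation is declared, never inferred: net-block-style metrics are
#' higher-is-riskier, a torsade-metric-score-like reference is
#' lower-is-riskier.
#'
#' @param scores data.frame with a `risk` column
#'   (`low`/`intermediate`/`high`) and one numeric column per metric.
#'   Rows without a risk label are dropped.
#' @param metrics character vector of metric column names to evaluate.
#' @param reference_metric optional name of the column to correlate each
#'   metric against (`r2_vs_reference`); `NA` is reported for the
#'   reference against itself.
#' @param higher_is_riskier named logical vector giving the orientation
#'   of each metric (and of the reference); metrics not named default to
#'   `TRUE`.
#' @param logistic_dichotomy which split the logistic model is fitted on
#'   (default `"low_vs_rest"`).
#' @return object of class `evaluation_report`: list with `table` (one
#'   row per metric: `metric`, `roc_auc_low_vs_rest`,
#'   `roc_auc_high_vs_rest`, `r2_vs_reference`, `chi2`, `t`, `df`, `p`,
#'   `higher_is_riskier`), `fits` (the `logistic_fit` objects),
#'   `n_drugs`, `reference_metric`, `logistic_dichotomy`.
#' @export
evaluate_metrics <- function(scores, metrics, reference_metric = NULL,
                             higher_is_riskier = logical(0),
                             logistic_dichotomy = c("low_vs_rest",
                                                    "high_vs_rest")) {
  logistic_dichotomy <- match.arg(logistic_dichotomy)
  stopifnot(is.data.frame(scores))
  if (!"risk" %in% names(scores))
    stop("scores must contain a 'risk' column", call. = FALSE)
  keep <- !is.na(scores$risk) & scores$risk %in% RISK_LEVELS
  scores <- scores[keep, , drop = FALSE]
  if (!nrow(scores))
    stop("no drugs with risk labels; nothing to evaluate", call. = FALSE)
  missing_cols <- setdiff(c(metrics, reference_metric), names(scores))
  if (length(missing_cols))
    stop("metric column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  orient <- function(m) {
    if (m %in% names(higher_is_riskier)) isTRUE(higher_is_riskier[[m]])
    else TRUE
  }
  lab <- function(d) as.integer(scores$risk %in% risk_dichotomy(d)$positive_classes)
  ref_vals <- if (!is.null(reference_metric)) scores[[reference_metric]]

  rows <- list()
  fits <- list()
  for (m in metrics) {
    v <- scores[[m]]
    if (anyNA(v))
      stop("metric '", m, "' has missing values for risk-labeled drugs",
           call. = FALSE)
    hi <- orient(m)
    auc_low <- roc_auc(v, lab("low_vs_rest"), higher_is_positive = hi)
    auc_high <- roc_auc(v, lab("high_vs_rest"), higher_is_positive = hi)
    fit <- logistic_fit(if (hi) v else -v, lab(logistic_dichotomy))
    fits[[m]] <- fit
    r2 <- NA_real_
    if (!is.null(reference_metric) && m != reference_metric) {
      both <- !is.na(v) & !is.na(ref_vals)
      if (sum(both) >= 3L) r2 <- pearson_r2(v[both], ref_vals[both])
    }
    tl <- two_sample_t(v[scores$risk == "low"], v[scores$risk != "low"])
    rows[[m]] <- data.frame(
      metric = m,
      roc_auc_low_vs_rest = auc_low$auc,
      roc_auc_high_vs_rest = auc_high$auc,
      r2_vs_reference = r2,
      chi2 = fit$chi2,
      t = tl$t, df = tl$df, p = tl$p,
      higher_is_riskier = hi,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, n_drugs = nrow(scores),
                 reference_metric = reference_metric,
                 logistic_dichotomy = logistic_dichotomy),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d risk-labeled drugs; logistic on %s\n",
              x$n_drugs, x$logistic_dichotomy))
  print(x$table, digits = 4)
  invisible(x)
}

#' Serialise an evaluation report
#'
#' Writes the report as JSON (stable key order, full precision) and
#' optionally as a flat CSV with one row per metric and the columns
#' `metric, roc_auc_low_vs_rest, roc_auc_high_vs_rest, r2_vs_reference,
#' chi2`. Output is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report an [evaluate_metrics()] result.
#' @param json_path output JSON path, or `NULL` to skip.
#' @param csv_path output CSV path, or `NULL` to skip.
#' @return invisibly, the list serialised to JSON.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  tab <- report$table
  metrics <- stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
    fit <- report$fits[[tab$metric[i]]]
    list(roc_auc_low_vs_rest = tab$roc_auc_low_vs_rest[i],
         roc_auc_high_vs_rest = tab$roc_auc_high_vs_rest[i],
         r2_vs_reference = tab$r2_vs_reference[i],
         chi2 = tab$chi2[i],
         logistic = list(intercept = fit$intercept, slope = fit$slope,
                         converged = fit$converged,
                         separation_detected = fit$separation_detected),
         t_test = list(t = tab$t[i], df = tab$df[i], p = tab$p[i]),
         higher_is_riskier = tab$higher_is_riskier[i])
  }), tab$metric)
  out <- list(n_drugs = report$n_drugs,
              logistic_dichotomy = report$logistic_dichotomy,
              reference_metric = report$reference_metric,
              metrics = metrics)
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(tab[, c("metric", "roc_auc_low_vs_rest",
                             "roc_auc_high_vs_rest", "r2_vs_reference",
                             "chi2")],
                     csv_path, row.names = FALSE)
  invisible(out)
}
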