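#' Topic prevalence by group
#'
#' For each topic, the number and fraction of each group's documents in which
#' the topic is present (binary coding), plus the prevalence ratio
#' frac_b / frac_a. Ratios with a zero reference fraction are reported as NA
#' ("undefined") rather than continuity-corrected, and are excluded (with a
#' count) from downstream correlation.
#'
#' @param presence Docs x K 0/1 matrix with doc_id rownames (e.g. from
#'   [corpus_topics()]).
#' @param metadata data.frame with `doc_id` and the grouping variable.
#' @param group_var Name of the grouping column.
#' @param group_levels Length-2 character vector (reference level first);
#'   defaults to the sorted unique values, which must number exactly two.
#' @return data.frame: topic_id, n_a, n_b, frac_a, frac_b, ratio.
#' @export
prevalence <- function(presence, metadata, group_var = "group",
                       group_levels = NULL) {
  if (!group_var %in% names(metadata)) {
    stop("prevalence: metadata lacks column '", group_var, "'")
  }
  ids <- rownames(presence)
  mrow <- match(ids, metadata$doc_id)
  if (anyNA(mrow)) {
    stop("prevalence: metadata missing for doc_id(s): ",
         paste(head(ids[is.na(mrow)], 5), collapse = ", "))
  }
  g <- as.character(metadata[[group_var]][mrow])
  if (is.null(group_levels)) group_levels <- sort(unique(g))
  if (length(group_levels) != 2) {
    stop("prevalence: need exactly two group levels, got ",
         length(group_levels))
  }
  if (!all(g %in% group_levels)) {
    stop("prevalence: unknown group level(s): ",
         paste(setdiff(unique(g), group_levels), collapse = ", "))
  }
  in_a <- g == group_levels[1]
  in_b <- g == group_levels[2]
  n_a <- colSums(presence[in_a, , drop = FALSE])
  n_b <- colSums(presence[in_b, , drop = FALSE])
  frac_a <- n_a / sum(in_a)
  frac_b <- n_b / sum(in_b)
  ratio <- ifelse(frac_a > 0, frac_b / frac_a, NA_real_)
  data.frame(topic_id = seq_len(ncol(presence)), n_a = n_a, n_b = n_b,
             frac_a = frac_a, frac_b = frac_b, ratio = ratio,
             row.names = NULL)
}

# Average ranks (midranks) of a numeric vector; the building block of the
# Spearman statistic, kept separate so tests can oracle it.
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman correlation between topic loadings and prevalence ratios
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value from
#' the standard large-sample t approximation on n - 2 degrees of freedom.
#' Pairs with an undefined (NA or non-finite) ratio are dropped and counted;
#' at least three usable pairs are required. Because Spearman is invariant to
#' monotone transforms, raw and log ratios give the same statistic.
#'
#' @param loadings Per-topic loadings on a semantic dimension.
#' @param ratios Per-topic prevalence ratios (NAs allowed).
#' @return list: rho, p, n_used, n_dropped.
#' @export
loading_prevalence_correlation <- function(loadings, ratios) {
  if (length(loadings) != length(ratios)) {
    stop("loading_prevalence_correlation: length mismatch")
  }
  ok <- is.finite(loadings) & is.finite(ratios)
  n <- sum(ok)
  if (n < 3) stop("loading_prevalence_correlation: fewer than 3 usable pairs")
  rx <- midrank(loadings[ok])
  ry <- midrank(ratios[ok])
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n_used = n, n_dropped = sum(!ok))
}

#' Logistic regression of binary topic presence on covariates
#'
#' Describes correlates of a topic: fits presence ~ covariates by maximum
#' likelihood (IRLS via [stats::glm()]) and reports adjusted odds ratios
#' exp(coefficient) with Wald 95% confidence intervals. Reference levels for
#' factor covariates can be set explicitly (they default to the first sorted
#' level). Degenerate outcomes (all zero or all one) are an error;
#' non-convergence or separation (inflated standard errors) flags the result
#' instead of returning it silently.
#'
#' @param presence Docs x K 0/1 matrix with doc_id rownames.
#' @param metadata data.frame with `doc_id` and the covariate columns.
#' @param topic_id Topic (column) to model.
#' @param covariates Character vector of metadata column names.
#' @param ref_levels Optional named list, covariate -> reference level.
#' @param conf_level Wald confidence level (default 0.95).
#' @return list: `table` (term, estimate, se, aor, ci_lo, ci_hi, p),
#'   `n`, `converged`, `flagged` (TRUE on separation/convergence trouble).
#' @export
topic_logit <- function(presence, metadata, topic_id, covariates,
                        ref_levels = NULL, conf_level = 0.95) {
  ids <- rownames(presence)
  mrow <- match(ids, metadata$doc_id)
  if (anyNA(mrow)) stop("topic_logit: metadata missing for some documents")
  missing_cov <- setdiff(covariates, names(metadata))
  if (length(missing_cov)) {
    stop("topic_logit: unknown covariate(s): ",
         paste(missing_cov, collapse = ", "))
  }
  y <- presence[, topic_id]
  if (all(y == 0) || all(y == 1)) {
    stop("topic_logit: degenerate outcome (presence all ",
         if (all(y == 0)) "zero" else "one", ") for topic ", topic_id)
  }
  df <- metadata[mrow, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.character(df[[v]]) || is.factor(df[[v]])) {
      lev <- sort(unique(as.character(df[[v]])))
      ref <- ref_levels[[v]] %||% lev[1]
      if (!ref %in% lev) stop("topic_logit: reference level '", ref,
                              "' absent from covariate '", v, "'")
      df[[v]] <- factor(as.character(df[[v]]),
                        levels = c(ref, setdiff(lev, ref)))
    }
  }
  df$.y <- y
  fit <- glm(.y ~ ., data = df, family = binomial())
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    aor = exp(unname(est)),
    ci_lo = exp(unname(est) - z * unname(se)),
    ci_hi = exp(unname(est) + z * unname(se)),
    p = 2 * pnorm(-abs(unname(est) / unname(se))),
    stringsAsFactors = FALSE
  )
  flagged <- !fit$converged || any(!is.finite(se)) || any(se > 50) ||
    any(abs(est) > 20)
  if (flagged) {
    warning("topic_logit: fit flagged (separation or non-convergence) for topic ",
            topic_id)
  }
  list(table = tab, n = nrow(df), converged = fit$converged,
       flagged = flagged)
}
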