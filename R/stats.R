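#' Fit the per-bin differential linear model
#'
#' Ordinary least squares of log2 peak area (or log2 lesioned/intact ratio)
#' on treatment group and analysis run, the per-bin model used for the
#' imaging data: `log2_value ~ group + run` with dummy-coded groups (lesion
#' control `LC` as reference when present) and the duplicate-run batch as a
#' covariate. Returns the t-test on the treatment contrast of interest.
#'
#' @param design Data frame with columns `group`, `run`, `bin` and `value`
#'   (log2 scale), one row per observation (animal x run).
#' @param bin Bin (m/z) to test; must match `design$bin`.
#' @param contrast Group level tested against the reference (default
#'   `"HD"`).
#' @return A one-row data frame with `mz`, `effect` (log2), `se`, `t`, `p`.
#' @export
fit_linear_model <- function(design, bin, contrast = "HD") {
  stopifnot(is.data.frame(design),
            all(c("group", "run", "bin", "value") %in% names(design)))
  d <- design[design$bin == bin, , drop = FALSE]
  if (nrow(d) == 0L) stop("bin not present in design", call. = FALSE)
  d$group <- droplevels(factor(d$group))
  if ("LC" %in% levels(d$group)) d$group <- stats::relevel(d$group, "LC")
  d$run <- factor(d$run)
  if (nlevels(d$group) < 2L) {
    stop("need at least 2 treatment groups", call. = FALSE)
  }
  form <- if (nlevels(d$run) > 1L) value ~ group + run else value ~ group
  mm <- stats::model.matrix(form, d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    confounded <- colnames(mm)[qrm$pivot[(qrm$rank + 1L):ncol(mm)]]
    stop(sprintf("rank-deficient design; confounded columns: %s",
                 paste(confounded, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(form, data = d)
  # exact fits trip summary.lm's "essentially perfect fit" warning; the
  # degenerate case is handled explicitly below
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  term <- paste0("group", contrast)
  if (!term %in% rownames(co)) {
    stop(sprintf("contrast level '%s' not in design", contrast),
         call. = FALSE)
  }
  est <- co[term, 1L]; se <- co[term, 2L]
  tv <- co[term, 3L]; p <- co[term, 4L]
  # exact fits make the t ratio numerically meaningless
  scale <- max(abs(d$value), 1)
  if (sm$sigma <= 1e-10 * scale) {
    if (abs(est) <= 1e-10 * scale) {
      est <- 0; tv <- 0; p <- 1
    } else {
      tv <- sign(est) * Inf; p <- 0
    }
  }
  data.frame(mz = bin, effect = est, se = se, t = tv, p = p)
}

#' Fit the per-bin model across all bins and adjust for multiple testing
#'
#' @inheritParams fit_linear_model
#' @param catalog Optional peptide catalog for annotation of bin centers
#'   (tolerance 0.3 Da); `NULL` skips annotation.
#' @return Data frame with one row per bin: `mz`, `effect`, `se`, `t`, `p`,
#'   `p_adj` (Benjamini-Hochberg) and `annotation`.
#' @export
fit_all_bins <- function(design, contrast = "HD", catalog = NULL) {
  bins <- sort(unique(design$bin))
  res <- do.call(rbind, lapply(bins, function(b) {
    fit_linear_model(design, b, contrast = contrast)
  }))
  res$p_adj <- adjust_bh(res$p)
  res$annotation <- ""
  if (!is.null(catalog)) {
    ann <- annotate_peaks(res$mz, catalog, tolerance = 0.3)
    if (nrow(ann) > 0L) {
      first <- ann[!duplicated(ann$observed_mz), ]
      idx <- match(res$mz, first$observed_mz)
      res$annotation <- ifelse(is.na(idx), "", first$peptide_name[idx])
    }
  }
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false discovery rate across m/z bins; an adjusted p below
#' 0.05 is the package's significance convention. Validates the input and
#' applies the classical step-up procedure with monotonicity enforcement;
#' output order matches input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson correlation of ROI peak areas with dyskinesia severity
#'
#' Pearson's correlation (with two-sided t-based p-value) assesses the
#' relationship between per-animal peak areas and cumulative dyskinesia
#' scores; the least-squares regression line is returned alongside as the
#' representative value.
#'
#' @param x,y Numeric vectors, length >= 3, neither constant.
#' @return A list with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate_with_behavior <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 animals", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(x))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Classical one-factor ANOVA F-test for comparisons of more than two
#' groups, followed by Tukey's honestly-significant-difference pairwise
#' comparisons based on the studentized-range distribution.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return A list with `F`, `df`, `p` (omnibus) and `tukey` (data frame of
#'   pairwise differences and adjusted p-values).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1L]]
  Fv <- tab[1L, "F value"]; p <- tab[1L, "Pr(>F)"]
  if (!is.finite(Fv)) { Fv <- 0; p <- 1 }  # all groups identical
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = Fv, df = tab[, "Df"], p = p, tukey = tukey)
}

#' Repeated-measures ANOVA of dyskinesia scores
#'
#' Two-way mixed ANOVA of the session-score matrix (between factor = group,
#' within factor = session) via the classical split-plot sums of squares.
#' Within-subject effects (session and the group-by-session interaction)
#' are Greenhouse-Geisser corrected: repeated scores from one animal are
#' correlated (e.g. animals follow individual trajectories), which violates
#' sphericity and would otherwise inflate the within-effect F tests.
#' Post hoc: per-session two-sample t-tests with Bonferroni correction
#' (factor = number of sessions) when exactly two groups are compared.
#'
#' @param scores Complete numeric matrix, animals x sessions (no missing
#'   cells).
#' @param groups Factor or character vector of group labels, one per animal.
#' @return A list with `p_group`, `p_time`, `p_interaction`, `F_interaction`
#'   and `posthoc` (per-session data frame with Bonferroni-adjusted p, or
#'   `NULL` when more than two groups).
#' @export
repeated_measures_anova <- function(scores, groups) {
  stopifnot(is.matrix(scores), nrow(scores) == length(groups))
  if (anyNA(scores)) {
    stop("missing cells: imputation out of scope", call. = FALSE)
  }
  n_animal <- nrow(scores); n_sess <- ncol(scores)
  d <- data.frame(
    score = as.vector(scores),
    animal = factor(rep(seq_len(n_animal), times = n_sess)),
    session = factor(rep(seq_len(n_sess), each = n_animal)),
    group = factor(rep(groups, times = n_sess))
  )
  fit <- stats::aov(score ~ group * session + Error(animal), data = d)
  sm <- summary(fit)
  between <- sm[["Error: animal"]][[1L]]
  within <- sm[["Error: Within"]][[1L]]
  # Greenhouse-Geisser epsilon from the pooled within-group covariance of
  # the session columns
  gg_epsilon <- function(scores, groups) {
    k <- ncol(scores)
    grp <- split(seq_len(nrow(scores)), groups)
    S <- Reduce(`+`, lapply(grp, function(ix) {
      stats::cov(scores[ix, , drop = FALSE]) * (length(ix) - 1L)
    })) / (nrow(scores) - length(grp))
    if (!all(is.finite(S)) || sum(S^2) == 0) return(1)
    cm <- diag(k) - 1 / k
    D <- cm %*% S %*% cm
    eps <- sum(diag(D))^2 / ((k - 1) * sum(D^2))
    min(1, max(eps, 1 / (k - 1)))
  }
  eps <- gg_epsilon(scores, groups)

  ss_total <- sum((scores - mean(scores))^2)
  get_p <- function(tab, term, gg = FALSE) {
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tab)))
    # an effect whose sum of squares is numerically zero is no effect
    if (!is.finite(tab[i, "Pr(>F)"]) ||
        tab[i, "Sum Sq"] <= 1e-10 * max(ss_total, 1)) {
      return(c(F = 0, p = 1))
    }
    Fv <- tab[i, "F value"]
    df1 <- tab[i, "Df"]
    df2 <- tab[nrow(tab), "Df"]
    p <- if (gg) {
      stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    } else {
      tab[i, "Pr(>F)"]
    }
    c(F = Fv, p = p)
  }
  g <- get_p(between, "group")
  t_ <- get_p(within, "session", gg = TRUE)
  gx <- get_p(within, "group:session", gg = TRUE)

  posthoc <- NULL
  if (nlevels(factor(groups)) == 2L) {
    lev <- levels(factor(groups))
    posthoc <- do.call(rbind, lapply(seq_len(n_sess), function(j) {
      a <- scores[groups == lev[1L], j]; b <- scores[groups == lev[2L], j]
      p <- if (stats::sd(c(a, b)) == 0) 1 else
        stats::t.test(a, b, var.equal = TRUE)$p.value
      data.frame(session = j, diff = mean(b) - mean(a), p = p,
                 p_bonf = min(1, p * n_sess))
    }))
  }
  list(p_group = g[["p"]], p_time = t_[["p"]], p_interaction = gx[["p"]],
       F_interaction = gx[["F"]], posthoc = posthoc)
}
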