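#' Median split into a binary group
#'
#' Values at or below the median go to group 0 ("low"), values above to
#' group 1 ("high"); ties at the median go low, which keeps the split
#' deterministic.
#'
#' @param variate numeric vector with at least two distinct values.
#' @return integer vector of 0/1 group codes.
#' @export
medianSplit <- function(variate) {
  if (length(unique(variate)) < 2) stop("constant variate cannot be split")
  as.integer(variate > median(variate))
}

#' Square-root outcome residualized for its earlier assessment
#'
#' Takes the square root of the later and earlier psychopathology totals and
#' returns the residuals of the later on the earlier (plus intercept), i.e.
#' the change in global psychopathology not explained by its prior level.
#'
#' @param psychopathology_t3 later-wave totals (>= 0).
#' @param psychopathology_t2 earlier-wave totals (>= 0).
#' @return residual vector.
#' @export
prepareOutcome <- function(psychopathology_t3, psychopathology_t2) {
  if (any(psychopathology_t3 < 0) || any(psychopathology_t2 < 0))
    stop("psychopathology totals must be nonnegative")
  y <- sqrt(psychopathology_t3)
  x <- sqrt(psychopathology_t2)
  if (sd(x) < .Machine$double.eps) return(y - mean(y))
  resid(lm(y ~ x))
}

# OLS via .lm.fit returning coefficients only; NULL on singular fit
fast_ols <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)
  fit$coefficients
}

#' Fit a moderated mediation model (moderation of the mediator-outcome path)
#'
#' Two OLS models: mediator `M ~ X + covariates` and outcome
#' `Y ~ X + M + W + M:W + covariates`, with the binary moderator W acting on
#' the mediator-to-outcome path.  Coefficient tests use a
#' heteroscedasticity-consistent covariance (default HC3).  Percentile
#' bootstrap over observations (both models refit per draw) yields CIs for
#' the conditional indirect effects `a x (b + b3 W)` at each moderator level
#' and for the index of moderated mediation `a x b3`; bootstrap draws with a
#' singular fit are redrawn and counted.
#'
#' @param data data.frame containing all model columns.
#' @param predictor,mediator,outcome,moderator column names; the moderator
#'   must be binary 0/1.
#' @param covariates character vector of covariate column names (optional).
#' @param n_boot bootstrap draws (>= 1000 recommended).
#' @param seed RNG seed.
#' @param hc_type heteroscedasticity-consistent estimator type, "HC0" to
#'   "HC4", or "none" for classical SEs.
#' @param ci_level confidence level (default 0.95).
#' @return a [MediationResult-class].
#' @export
fitModeratedMediation <- function(data, predictor, mediator, outcome,
                                  moderator, covariates = character(0),
                                  n_boot = 5000, seed = 1, hc_type = "HC3",
                                  ci_level = 0.95) {
  cols <- c(predictor, mediator, outcome, moderator, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[complete.cases(data[, cols]), cols, drop = FALSE]
  W <- d[[moderator]]
  if (!all(W %in% c(0, 1))) stop("moderator must be dummy-coded 0/1")
  if (length(unique(W)) < 2) stop("moderator has a single level")
  for (v in c(predictor, mediator, outcome))
    if (sd(d[[v]]) < .Machine$double.eps)
      stop("constant column: ", v)

  # drop collinear / constant covariates once, with a log
  dropped <- character(0)
  if (length(covariates)) {
    Cm <- as.matrix(d[, covariates, drop = FALSE])
    keep <- apply(Cm, 2, sd) > .Machine$double.eps
    qrC <- qr(cbind(1, Cm[, keep, drop = FALSE]))
    if (qrC$rank < ncol(Cm[, keep, drop = FALSE]) + 1) {
      piv <- qrC$pivot[seq_len(qrC$rank)]
      keep_idx <- piv[piv > 1] - 1
      keep[keep][-keep_idx] <- FALSE
    }
    dropped <- covariates[!keep]
    if (length(dropped))
      warning("dropping collinear/constant covariate(s): ",
              paste(dropped, collapse = ", "))
    covariates <- covariates[keep]
  }

  f_med <- stats::reformulate(c(predictor, covariates), response = mediator)
  f_out <- stats::reformulate(
    c(predictor, mediator, moderator,
      paste(mediator, moderator, sep = ":"), covariates),
    response = outcome)
  m_med <- lm(f_med, data = d)
  m_out <- lm(f_out, data = d)
  a <- unname(coef(m_med)[predictor])
  b <- unname(coef(m_out)[mediator])
  int_name <- paste(mediator, moderator, sep = ":")
  if (!int_name %in% names(coef(m_out)))
    int_name <- paste(moderator, mediator, sep = ":")
  b3 <- unname(coef(m_out)[int_name])
  if (anyNA(coef(m_out)) || anyNA(coef(m_med)))
    stop("rank-deficient model: aliased coefficient(s) ",
         paste(names(coef(m_out))[is.na(coef(m_out))], collapse = ", "))

  V <- if (identical(hc_type, "none")) stats::vcov(m_out) else
    sandwich::vcovHC(m_out, type = hc_type)
  se_b3 <- sqrt(V[int_name, int_name])
  t_b3 <- b3 / se_b3
  df_out <- df.residual(m_out)
  p_b3 <- 2 * pt(-abs(t_b3), df_out)

  # bootstrap
  Xm <- stats::model.matrix(m_med)
  Xo <- stats::model.matrix(m_out)
  ym <- d[[mediator]]; yo <- d[[outcome]]
  a_col <- match(predictor, colnames(Xm))
  b_col <- match(mediator, colnames(Xo))
  i_col <- match(int_name, colnames(Xo))
  n <- nrow(d)
  set.seed(seed)
  ind0 <- numeric(n_boot); ind1 <- numeric(n_boot); idxm <- numeric(n_boot)
  n_failed <- 0L
  b_drawn <- 0L
  while (b_drawn < n_boot) {
    idx <- sample.int(n, replace = TRUE)
    cm <- fast_ols(Xm[idx, , drop = FALSE], ym[idx])
    co <- fast_ols(Xo[idx, , drop = FALSE], yo[idx])
    if (is.null(cm) || is.null(co)) {
      n_failed <- n_failed + 1L
      if (n_failed > 100 * n_boot) stop("bootstrap cannot obtain full-rank fits")
      next
    }
    b_drawn <- b_drawn + 1L
    ab <- cm[a_col] * co[b_col]
    ab3 <- cm[a_col] * co[i_col]
    ind0[b_drawn] <- ab
    ind1[b_drawn] <- ab + ab3
    idxm[b_drawn] <- ab3
  }
  ci0 <- percentile_ci(ind0, ci_level)
  ci1 <- percentile_ci(ind1, ci_level)
  cii <- percentile_ci(idxm, ci_level)

  cov_coefs <- coef(m_out)[covariates]
  if (!length(covariates)) cov_coefs <- numeric(0)

  new("MediationResult",
      a_path = a, b_path = b, b_interaction = b3,
      interaction_t = t_b3, interaction_df = df_out, interaction_p = p_b3,
      conditional_indirect = data.frame(
        moderator_level = c(0, 1),
        effect = c(a * b, a * (b + b3)),
        lower = c(ci0["lower"], ci1["lower"]),
        upper = c(ci0["upper"], ci1["upper"])),
      index_modmed = a * b3, index_se = sd(idxm),
      index_lower = unname(cii["lower"]), index_upper = unname(cii["upper"]),
      covariate_coefs = if (length(cov_coefs)) cov_coefs else numeric(0),
      n_boot_failed = as.numeric(n_failed))
}
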