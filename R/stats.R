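#' Assemble a balanced long table
#'
#' Canonical input of the group-level statistics: one value per
#' subject x factor-A level x factor-B level. Replicated cells (e.g. the two
#' repetition blocks of a session) can be averaged with
#' `aggregate = TRUE`; otherwise replication is an error.
#'
#' @param subject,factor_a,factor_b,value equal-length vectors.
#' @param aggregate average replicated cells instead of failing.
#' @return data.frame with columns `subject`, `factor_a`, `factor_b`,
#'   `value`, checked for balance.
#' @export
long_table <- function(subject, factor_a, factor_b, value,
                       aggregate = FALSE) {
  df <- data.frame(subject = as.character(subject),
                   factor_a = as.character(factor_a),
                   factor_b = as.character(factor_b),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  counts <- table(df$subject, df$factor_a, df$factor_b)
  if (any(counts > 1)) {
    if (!aggregate) stop("replicated cells; set aggregate = TRUE to average")
    df <- stats::aggregate(value ~ subject + factor_a + factor_b, df, mean)
    counts <- table(df$subject, df$factor_a, df$factor_b)
  }
  if (any(counts == 0)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    lab <- apply(miss, 1, function(r)
      paste(dimnames(counts)[[1]][r[1]], dimnames(counts)[[2]][r[2]],
            dimnames(counts)[[3]][r[3]], sep = ":"))
    stop("unbalanced design; missing cells: ",
         paste(head(lab, 5), collapse = ", "),
         if (length(lab) > 5) " ...")
  }
  df
}

# n x a x b cell array from a long table
cell_array <- function(data) {
  tapply(data$value,
         list(factor(data$subject), factor(data$factor_a),
              factor(data$factor_b)),
         mean)
}

# orthonormal contrast matrix, (k-1) x k, rows orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k) # k x (k-1), orthogonal columns
  t(sweep(h, 2, sqrt(colSums(h^2)), "/"))
}

# per-subject contrast scores of one effect; columns are contrast dimensions
effect_scores <- function(Y, effect) {
  switch(effect,
         factor_a = {
           m <- apply(Y, c(1, 2), mean)
           m %*% t(orthonormal_contrasts(ncol(m)))
         },
         factor_b = {
           m <- apply(Y, c(1, 3), mean)
           m %*% t(orthonormal_contrasts(ncol(m)))
         },
         interaction = {
           a <- dim(Y)[2]; b <- dim(Y)[3]
           flat <- matrix(Y, nrow = dim(Y)[1]) # cells in (i, j) column order
           C <- kronecker(orthonormal_contrasts(b),
                          orthonormal_contrasts(a))
           # flat columns vary i fastest, matching kronecker(Cb, Ca)
           flat %*% t(C)
         },
         stop("unknown effect: ", effect))
}

#' Mauchly's sphericity test
#'
#' Tests sphericity of a within-subject effect through the covariance of its
#' orthonormal contrast scores: `W = det(S) / (tr(S)/p)^p` with the usual
#' chi-square approximation. Effects with fewer than 3 levels are spherical
#' by construction (`W = 1`, `p = 1`).
#'
#' @param data a balanced [long_table()] data.frame.
#' @param effect `"factor_a"`, `"factor_b"`, or `"interaction"`.
#' @return list with `W`, `p_value`, `df`.
#' @export
mauchly_sphericity <- function(data, effect = "factor_a") {
  Y <- cell_array(data)
  scores <- effect_scores(Y, effect)
  p <- ncol(scores)
  n <- nrow(scores)
  if (p < 2L) return(list(W = 1, p_value = 1, df = 0))
  if (n <= p)
    stop("too few subjects (", n, ") for a non-singular ", p,
         "-dimensional contrast covariance")
  S <- stats::cov(scores)
  W <- det(S) / (sum(diag(S)) / p)^p
  df <- p * (p + 1) / 2 - 1
  # Box's asymptotic expansion (first- plus second-order term)
  nq <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nq)
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p + 2) /
    (288 * (nq * p * rho)^2)
  z <- -nq * rho * log(max(W, .Machine$double.xmin))
  pr1 <- pchisq(z, df, lower.tail = FALSE)
  pr2 <- pchisq(z, df + 4, lower.tail = FALSE)
  pval <- min(max(pr1 + w2 * (pr2 - pr1), 0), 1)
  list(W = W, p_value = pval, df = df)
}

#' Greenhouse-Geisser epsilon
#'
#' Degrees-of-freedom deflation factor of a within-subject effect, computed
#' from the eigenstructure of the orthonormal-contrast covariance:
#' `epsilon = tr(S)^2 / (p * tr(S^2))`, bounded in `[1/p, 1]`.
#'
#' @inheritParams mauchly_sphericity
#' @return epsilon (scalar).
#' @export
gg_epsilon <- function(data, effect = "factor_a") {
  Y <- cell_array(data)
  scores <- effect_scores(Y, effect)
  p <- ncol(scores)
  if (p < 2L) return(1)
  S <- stats::cov(scores)
  eps <- sum(diag(S))^2 / (p * sum(S * S))
  min(max(eps, 1 / p), 1)
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject two-way ANOVA on a balanced long table: each effect (A, B,
#' and A x B) is tested against its own subject-interaction error term.
#' Sphericity is assessed per effect with Mauchly's test, the
#' Greenhouse-Geisser-corrected p-value is always reported, and
#' `gg_applied` records whether the correction is deemed necessary
#' (Mauchly p below `sphericity_alpha`).
#'
#' @param data a balanced [long_table()] data.frame (or arguments accepted by
#'   [long_table()] when given as such).
#' @param sphericity_alpha Mauchly p-value threshold that triggers the
#'   Greenhouse-Geisser correction.
#' @return data.frame with one row per testable effect and columns `effect`,
#'   `F`, `df_num`, `df_den`, `p_uncorrected`, `sphericity_W`,
#'   `sphericity_p`, `gg_epsilon`, `df_num_gg`, `df_den_gg`, `p_gg`,
#'   `gg_applied`, `p_reported`.
#' @export
rm_anova_2way <- function(data, sphericity_alpha = 0.05) {
  data <- long_table(data$subject, data$factor_a, data$factor_b, data$value)
  Y <- cell_array(data)
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  if (n < 2) stop("need at least 2 subjects")
  G <- mean(Y)
  m_s <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean)
  m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)
  ss <- function(x) sum(x^2)
  SS_A <- n * b * ss(m_a - G)
  SS_B <- n * a * ss(m_b - G)
  SS_AB <- n * ss(sweep(sweep(m_ab, 1, m_a), 2, m_b) + G)
  SS_AS <- b * ss(sweep(sweep(m_sa, 1, m_s), 2, m_a) + G)
  SS_BS <- a * ss(sweep(sweep(m_sb, 1, m_s), 2, m_b) + G)
  resid <- Y
  for (s in seq_len(n)) resid[s, , ] <- Y[s, , ] - m_sa[s, ] %o% rep(1, b) -
    rep(1, a) %o% m_sb[s, ] - m_ab + m_s[s] + rep(m_a, times = b) +
    rep(m_b, each = a) - G
  SS_ABS <- ss(resid)
  tol <- 1e-12 * max(1, ss(Y - G))
  effects <- list(
    factor_a = list(ss = SS_A, df = a - 1, ss_err = SS_AS,
                    df_err = (a - 1) * (n - 1)),
    factor_b = list(ss = SS_B, df = b - 1, ss_err = SS_BS,
                    df_err = (b - 1) * (n - 1)),
    interaction = list(ss = SS_AB, df = (a - 1) * (b - 1), ss_err = SS_ABS,
                       df_err = (a - 1) * (b - 1) * (n - 1))
  )
  rows <- lapply(names(effects), function(e) {
    x <- effects[[e]]
    if (x$df < 1) return(NULL)
    Fval <- if (x$ss <= tol && x$ss_err <= tol) 0 else
      (x$ss / x$df) / (x$ss_err / x$df_err)
    p <- if (Fval == 0) 1 else pf(Fval, x$df, x$df_err, lower.tail = FALSE)
    # with n <= p subjects the contrast covariance is singular and the
    # sphericity test undefined; report NA and fall back to uncorrected p
    mau <- tryCatch(mauchly_sphericity(data, e),
                    error = function(e) list(W = NA_real_,
                                             p_value = NA_real_, df = NA))
    eps <- gg_epsilon(data, e)
    p_gg <- if (Fval == 0) 1 else
      pf(Fval, eps * x$df, eps * x$df_err, lower.tail = FALSE)
    applied <- isTRUE(mau$p_value < sphericity_alpha)
    data.frame(effect = e, F = Fval, df_num = x$df, df_den = x$df_err,
               p_uncorrected = p, sphericity_W = mau$W,
               sphericity_p = mau$p_value, gg_epsilon = eps,
               df_num_gg = eps * x$df, df_den_gg = eps * x$df_err,
               p_gg = p_gg, gg_applied = applied,
               p_reported = if (applied) p_gg else p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' All pairwise paired t-tests between the levels of one within-subject
#' factor (each subject's values averaged over the other factor first), with
#' the Bonferroni correction `p_adj = min(1, m * p_raw)` over the
#' `m = k(k-1)/2` comparisons of the family.
#'
#' @inheritParams mauchly_sphericity
#' @return data.frame with `level_1`, `level_2`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `p_adj`, `m`.
#' @export
bonferroni_posthoc <- function(data, effect = "factor_a") {
  Y <- cell_array(data)
  m_lvl <- switch(effect,
                  factor_a = apply(Y, c(1, 2), mean),
                  factor_b = apply(Y, c(1, 3), mean),
                  stop("post-hoc comparisons apply to factor_a or factor_b"))
  lv <- colnames(m_lvl)
  k <- length(lv)
  if (k < 2) stop("effect has fewer than 2 levels")
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  n <- nrow(m_lvl)
  rows <- lapply(seq_len(m), function(j) {
    d <- m_lvl[, pairs[1, j]] - m_lvl[, pairs[2, j]]
    tt <- mean(d) / (sd(d) / sqrt(n))
    p <- 2 * pt(abs(tt), n - 1, lower.tail = FALSE)
    data.frame(level_1 = lv[pairs[1, j]], level_2 = lv[pairs[2, j]],
               mean_diff = mean(d), t = tt, df = n - 1, p_raw = p,
               p_adj = min(1, m * p), m = m, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
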