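# Inferential layer: paired t with Cohen's d, one- and two-factor
# repeated-measures ANOVA with Mauchly's test and Greenhouse-Geisser
# correction, Bonferroni pairwise comparisons, eta-squared effect sizes and
# their f transform, and a-priori power via the noncentral F distribution.

new_effect_result <- function(effect, statistic, stat_name, df, p,
                              effect_sizes = list(), ci = NULL,
                              sphericity = NULL, corrected = FALSE,
                              degenerate = FALSE) {
  structure(
    list(effect = effect, statistic = statistic, stat_name = stat_name,
         df = df, p = p, effect_sizes = effect_sizes, ci = ci,
         sphericity = sphericity, corrected = corrected,
         degenerate = degenerate),
    class = "effect_result"
  )
}

#' @export
print.effect_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  es <- if (length(x$effect_sizes)) {
    paste(sprintf("%s = %.3f", names(x$effect_sizes),
                  unlist(x$effect_sizes)), collapse = ", ")
  } else ""
  cat(sprintf("%s: %s(%s) = %.3f, p = %.4g%s%s\n",
              x$effect, x$stat_name, dfs, x$statistic, x$p,
              if (nzchar(es)) paste0("; ", es) else "",
              if (x$corrected) " [GG-corrected]" else ""))
  invisible(x)
}

#' Paired-samples t test
#'
#' Two-tailed paired t on the within-participant differences, with Cohen's
#' d for paired designs (`mean(d) / sd(d)`) and the 95% CI of the mean
#' difference. Zero variance of the differences is flagged as degenerate
#' rather than raised as an error.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return An `effect_result`.
#' @export
paired_t <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  abort_if(length(x) < 2, "need at least two pairs")
  d <- x - y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    degenerate <- TRUE
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    cohens_d <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    ci <- c(mean(d), mean(d))
  } else {
    degenerate <- FALSE
    tt <- stats::t.test(x, y, paired = TRUE)
    tval <- unname(tt$statistic)
    p <- tt$p.value
    cohens_d <- mean(d) / sd_d
    ci <- unname(tt$conf.int)
  }
  new_effect_result(
    effect = "paired difference", statistic = tval, stat_name = "t",
    df = n - 1L, p = p,
    effect_sizes = list(cohens_d = cohens_d, mean_diff = mean(d)),
    ci = ci, degenerate = degenerate
  )
}

# Orthonormal contrast matrix for k repeated levels (k x (k-1)).
orthonormal_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  qr.Q(qr(cm))
}

#' Mauchly's sphericity test and Greenhouse-Geisser epsilon
#'
#' Mauchly's W is computed from the covariance of the orthonormalized
#' contrasts of the repeated measures, with the usual chi-squared
#' approximation; the Greenhouse-Geisser epsilon comes from the eigenvalues
#' of the same contrast covariance, clamped to its theoretical range
#' `[1/(k-1), 1]`. With k = 2 there is a single contrast and sphericity
#' holds trivially.
#'
#' @param Y numeric matrix, subjects x k repeated levels (n > k).
#' @return A list: `W`, `chisq`, `df`, `p`, `epsilon`.
#' @export
mauchly_gg <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  abort_if(k < 2, "need at least two repeated levels")
  if (k == 2) {
    return(list(W = 1, chisq = 0, df = 0, p = 1, epsilon = 1))
  }
  abort_if(n <= k, "Mauchly's test needs more subjects than levels")
  C <- orthonormal_contrasts(k)
  S <- stats::cov(Y %*% C)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  abort_if(any(ev <= 0), "singular contrast covariance")
  p_ <- k - 1
  W <- prod(ev) / (sum(ev) / p_)^p_
  dfr <- n - 1
  # Box's series approximation to the null distribution (to second order,
  # matching the standard implementation)
  rho <- 1 - (2 * p_^2 + p_ + 2) / (6 * p_ * dfr)
  w2 <- (p_ + 2) * (p_ - 1) * (p_ - 2) * (2 * p_^3 + 6 * p_^2 + 3 * p_ + 2) /
    (288 * (dfr * p_ * rho)^2)
  chisq <- -dfr * rho * log(W)
  df <- p_ * (p_ + 1) / 2 - 1
  p <- stats::pchisq(chisq, df, lower.tail = FALSE) +
    w2 * (stats::pchisq(chisq, df + 4, lower.tail = FALSE) -
            stats::pchisq(chisq, df, lower.tail = FALSE))
  eps <- sum(ev)^2 / (p_ * sum(ev^2))
  eps <- min(1, max(1 / p_, eps))
  list(W = W, chisq = chisq, df = df, p = p, epsilon = eps)
}

# One-way within-subject sums of squares on a wide matrix (subjects x k).
rm_anova_ss1 <- function(Y) {
  n <- nrow(Y)
  k <- ncol(Y)
  grand <- mean(Y)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  list(n = n, k = k, ss_subject = ss_subj, ss_effect = ss_cond,
       ss_error = ss_err)
}

rm_anova_oneway <- function(Y, gg_rule = c("mauchly", "always", "never"),
                            effect = "condition") {
  gg_rule <- match.arg(gg_rule)
  ss <- rm_anova_ss1(Y)
  df1 <- ss$k - 1
  df2 <- (ss$n - 1) * (ss$k - 1)
  ms_eff <- ss$ss_effect / df1
  ms_err <- ss$ss_error / df2
  Fval <- ms_eff / ms_err
  sph <- if (ss$k > 2 && ss$n > ss$k) {
    mauchly_gg(Y)
  } else if (ss$k == 2) {
    list(W = 1, chisq = 0, df = 0, p = 1, epsilon = 1)
  } else {
    # too few subjects to assess sphericity; no correction possible
    list(W = NA_real_, chisq = NA_real_, df = NA_real_, p = NA_real_,
         epsilon = 1)
  }
  corrected <- switch(gg_rule,
                      mauchly = isTRUE(sph$p < 0.05),
                      always = TRUE,
                      never = FALSE)
  eps <- if (corrected) sph$epsilon else 1
  p <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  etap <- ss$ss_effect / (ss$ss_effect + ss$ss_error)
  etag <- ss$ss_effect / (ss$ss_effect + ss$ss_subject + ss$ss_error)
  # 95% CIs of condition means from the within-subject error term
  tcrit <- stats::qt(0.975, df2)
  half <- tcrit * sqrt(ms_err / ss$n)
  means <- colMeans(Y)
  ci <- cbind(lower = means - half, upper = means + half)
  new_effect_result(
    effect = effect, statistic = Fval, stat_name = "F",
    df = c(df1 * eps, df2 * eps), p = p,
    effect_sizes = list(eta_p2 = etap, eta_g2 = etag),
    ci = ci, sphericity = sph, corrected = corrected
  )
}

rm_anova_twoway <- function(arr, gg_rule = c("mauchly", "always", "never"),
                            names_ab = c("A", "B")) {
  gg_rule <- match.arg(gg_rule)
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  grand <- mean(arr)
  m_s <- apply(arr, 1, mean)
  m_a <- apply(arr, 2, mean)
  m_b <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(1, 2), mean)
  m_sb <- apply(arr, c(1, 3), mean)
  m_ab <- apply(arr, c(2, 3), mean)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_tot <- sum((arr - grand)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_sa - ss_sb - ss_ab
  ss_err_all <- ss_sa + ss_sb + ss_sab
  denom_g <- ss_s + ss_err_all

  wide_a <- m_sa                       # subjects x a (collapsed over b)
  wide_b <- m_sb                       # subjects x b
  one <- function(effect, ss_eff, df1, ss_err, df2, Ywide) {
    Fval <- (ss_eff / df1) / (ss_err / df2)
    sph <- if (!is.null(Ywide) && ncol(Ywide) > 2 &&
                 nrow(Ywide) > ncol(Ywide)) {
      mauchly_gg(Ywide)
    } else if (!is.null(Ywide) && ncol(Ywide) == 2) {
      list(W = 1, chisq = 0, df = 0, p = 1, epsilon = 1)
    } else {
      NULL
    }
    corrected <- !is.null(sph) && switch(gg_rule,
                                         mauchly = isTRUE(sph$p < 0.05),
                                         always = TRUE, never = FALSE)
    eps <- if (corrected) sph$epsilon else 1
    p <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
    new_effect_result(
      effect = effect, statistic = Fval, stat_name = "F",
      df = c(df1 * eps, df2 * eps), p = p,
      effect_sizes = list(
        eta_p2 = ss_eff / (ss_eff + ss_err),
        eta_g2 = ss_eff / (ss_eff + denom_g)
      ),
      sphericity = sph, corrected = corrected
    )
  }
  list(
    one(names_ab[1], ss_a, a - 1, ss_sa, (n - 1) * (a - 1), wide_a),
    one(names_ab[2], ss_b, b - 1, ss_sb, (n - 1) * (b - 1), wide_b),
    one(paste(names_ab, collapse = ":"), ss_ab, (a - 1) * (b - 1),
        ss_sab, (n - 1) * (a - 1) * (b - 1), NULL)
  )
}

#' Repeated-measures ANOVA
#'
#' Within-subject analysis of variance for one or two fully crossed
#' within-subject factors on a complete balanced design. Each effect is
#' tested against its own subject-by-effect error stratum. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`; generalized eta squared
#' places all subject-related variance in the denominator. When Mauchly's
#' test rejects sphericity at .05 (and the factor has more than two
#' levels), the Greenhouse-Geisser correction is applied to the degrees of
#' freedom.
#'
#' @param data long-format data frame, or (for the one-factor case) a wide
#'   numeric matrix subjects x levels.
#' @param dv,subject,within column names of the response, the subject
#'   identifier, and one or two within-subject factors (ignored for matrix
#'   input).
#' @param gg_rule when to apply the Greenhouse-Geisser correction:
#'   `"mauchly"` (when Mauchly p < .05, the default), `"always"`, or
#'   `"never"`.
#' @return A list of `effect_result` objects (one per main effect, plus
#'   the interaction for two factors).
#' @export
rm_anova <- function(data, dv = "value", subject = "participant_id",
                     within = "condition", gg_rule = "mauchly") {
  if (is.matrix(data)) {
    return(list(rm_anova_oneway(data, gg_rule = gg_rule)))
  }
  abort_if(length(within) < 1 || length(within) > 2,
           "one or two within-subject factors are supported")
  abort_if(any(is.na(data[[dv]])), "missing responses in the design")
  cells <- table(data[[subject]],
                 do.call(interaction, as.list(data[, within, drop = FALSE])))
  abort_if(any(cells != 1),
           "design must be complete and balanced (one observation per subject x cell)")
  if (length(within) == 1) {
    levs <- unique(data[[within]])
    subj <- unique(data[[subject]])
    Y <- matrix(NA_real_, length(subj), length(levs),
                dimnames = list(subj, levs))
    idx <- cbind(match(data[[subject]], subj), match(data[[within]], levs))
    Y[idx] <- data[[dv]]
    list(rm_anova_oneway(Y, gg_rule = gg_rule, effect = within))
  } else {
    la <- unique(data[[within[1]]])
    lb <- unique(data[[within[2]]])
    subj <- unique(data[[subject]])
    arr <- array(NA_real_, c(length(subj), length(la), length(lb)))
    idx <- cbind(match(data[[subject]], subj),
                 match(data[[within[1]]], la),
                 match(data[[within[2]]], lb))
    arr[idx] <- data[[dv]]
    dimnames(arr) <- list(subj, la, lb)
    rm_anova_twoway(arr, gg_rule = gg_rule, names_ab = within)
  }
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All `C(k, 2)` paired t tests between the columns of a subjects-by-levels
#' matrix, with `p_adj = min(1, p * C(k, 2))`.
#'
#' @param Y numeric matrix, subjects x k condition levels (k >= 2).
#' @return A tibble: `level_1`, `level_2`, `mean_diff`, `t`, `df`, `p`,
#'   `p_adj`, `cohens_d`.
#' @export
bonferroni_pairwise <- function(Y) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  abort_if(k < 2, "need at least two conditions")
  levs <- colnames(Y) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res <- paired_t(Y[, i1], Y[, i2])
    rows[[j]] <- tibble::tibble(
      level_1 = levs[i1], level_2 = levs[i2],
      mean_diff = mean(Y[, i1] - Y[, i2]),
      t = res$statistic, df = res$df, p = res$p,
      cohens_d = res$effect_sizes$cohens_d
    )
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' Convert between eta squared and Cohen's f
#'
#' `f = sqrt(eta2 / (1 - eta2))`; the inverse is
#' `eta2 = f^2 / (1 + f^2)`.
#'
#' @param eta2 eta squared in `[0, 1)`.
#' @param f Cohen's f (>= 0).
#' @return The converted effect size.
#' @export
eta_to_f <- function(eta2) {
  abort_if(any(eta2 < 0 | eta2 >= 1), "eta squared must lie in [0, 1)")
  sqrt(eta2 / (1 - eta2))
}

#' @rdname eta_to_f
#' @export
f_to_eta <- function(f) {
  abort_if(any(f < 0), "f must be non-negative")
  f^2 / (1 + f^2)
}

#' Power of a repeated-measures ANOVA
#'
#' A-priori power for a one-group repeated-measures design in the
#' convention of the standard power tool for this analysis: noncentrality
#' `lambda = n * m * f^2 / (1 - rho) * epsilon`, numerator df
#' `(m - 1) * epsilon`, denominator df `(n - 1) * (m - 1) * epsilon`, and
#' power the upper tail of the noncentral F beyond the central-F critical
#' value.
#'
#' @param f Cohen's f effect size (>= 0).
#' @param n sample size (>= 2).
#' @param m number of repeated measurements (>= 2).
#' @param rho assumed correlation among repeated measures, in `[0, 1)`.
#' @param epsilon nonsphericity correction, in `(1/(m-1), 1]`.
#' @param alpha significance level.
#' @return Power in `[0, 1]`; equals `alpha` when `f = 0`.
#' @export
rm_power <- function(f, n, m = 4, rho = 0.5, epsilon = 1, alpha = 0.05) {
  abort_if(f < 0, "f must be non-negative")
  abort_if(n < 2, "n must be at least 2")
  abort_if(m < 2, "m must be at least 2")
  abort_if(rho < 0 || rho >= 1, "rho must lie in [0, 1)")
  lambda <- n * m * f^2 / (1 - rho) * epsilon
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' @rdname rm_power
#' @param target_power required power.
#' @param n_max search ceiling.
#' @return `required_n()`: the smallest integer n with power >= target.
#' @export
required_n <- function(f, target_power = 0.80, m = 4, rho = 0.5,
                       epsilon = 1, alpha = 0.05, n_max = 1e6) {
  n <- 2
  while (n <= n_max) {
    if (rm_power(f, n, m = m, rho = rho, epsilon = epsilon,
                 alpha = alpha) >= target_power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop("target power unreachable within n <= n_max", call. = FALSE)
}
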