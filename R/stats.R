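#' Paired t-test
#'
#' Thin, contract-checked wrapper around [stats::t.test()] for paired
#' samples, reporting the statistic, degrees of freedom (n - 1) and the
#' one- or two-tailed p-value.
#'
#' @param sample_a,sample_b paired numeric vectors of equal length >= 2.
#' @param tails `"two"` (default), or `"greater"` / `"less"` for
#'   one-tailed alternatives on `mean(sample_a - sample_b)`.
#' @return A one-row [tibble][tibble::tibble] (`test`, `statistic`, `df`,
#'   `p`, `tails`).
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_t <- function(sample_a, sample_b, tails = c("two", "greater", "less")) {
  tails <- match.arg(tails)
  if (length(sample_a) != length(sample_b)) stop("samples must have equal length")
  if (length(sample_a) < 2) stop("need at least 2 pairs")
  d <- sample_a - sample_b
  if (isTRUE(all.equal(var(d), 0)))
    stop("zero variance of paired differences: t statistic undefined")
  alt <- switch(tails, two = "two.sided", greater = "greater", less = "less")
  tt <- t.test(sample_a, sample_b, paired = TRUE, alternative = alt)
  tibble::tibble(test = "paired_t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, tails = tails)
}

#' Two-by-three repeated-measures ANOVA with sphericity correction
#'
#' Balanced within-subject ANOVA for the 2 (group: A, B) x 3 (reward
#' condition: Pre-reward, Rewarded, Unrewarded) design: closed-form sums
#' of squares for both main effects and the interaction, Mauchly's test of
#' sphericity on each multi-level within-subject effect (via orthonormal
#' contrasts of the condition covariance), the Greenhouse-Geisser epsilon,
#' and -- whenever Mauchly rejects at the `alpha` level -- epsilon-corrected
#' degrees of freedom and p-values. Bonferroni-corrected pairwise paired
#' t-tests on the reward levels (collapsed across group) are returned as
#' post hocs.
#'
#' @param data long-format data.frame with columns `subject`, `group` (2
#'   levels), `reward` (3 levels), `value`; exactly one value per cell.
#' @param alpha significance level for the sphericity decision.
#' @return A list with `anova` (tibble: effect, F, df1, df2, p,
#'   correction, epsilon, p_corrected), `mauchly` (tibble: effect, W,
#'   chisq, df, p), and `posthoc` (pairwise comparisons with raw and
#'   Bonferroni p-values).
#' @export
rm_anova_2x3 <- function(data, alpha = 0.05) {
  req <- c("subject", "group", "reward", "value")
  if (!all(req %in% names(data))) stop("data must have columns ", paste(req, collapse = ", "))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$reward <- factor(data$reward)
  if (nlevels(data$group) != 2 || nlevels(data$reward) != 3)
    stop("design must be 2 (group) x 3 (reward)")
  tab <- table(data$subject, data$group, data$reward)
  if (any(tab != 1)) stop("unbalanced design: need exactly one value per cell")
  n <- nlevels(data$subject)

  Y <- array(NA_real_, dim = c(n, 2, 3))
  Y[cbind(as.integer(data$subject), as.integer(data$group), as.integer(data$reward))] <- data$value
  M <- mean(Y)
  m_s <- apply(Y, 1, mean); m_g <- apply(Y, 2, mean); m_r <- apply(Y, 3, mean)
  m_sg <- apply(Y, c(1, 2), mean); m_sr <- apply(Y, c(1, 3), mean)
  m_gr <- apply(Y, c(2, 3), mean)

  ss_g  <- 3 * n * sum((m_g - M)^2)
  ss_gs <- 3 * sum((m_sg - outer(m_s, rep(1, 2)) - outer(rep(1, n), m_g) + M)^2)
  ss_r  <- 2 * n * sum((m_r - M)^2)
  ss_rs <- 2 * sum((m_sr - outer(m_s, rep(1, 3)) - outer(rep(1, n), m_r) + M)^2)
  ss_gr <- n * sum((m_gr - outer(m_g, rep(1, 3)) - outer(rep(1, 2), m_r) + M)^2)
  resid <- Y
  for (s in seq_len(n)) for (g in 1:2) for (r in 1:3)
    resid[s, g, r] <- Y[s, g, r] - m_sg[s, g] - m_sr[s, r] - m_gr[g, r] +
      m_s[s] + m_g[g] + m_r[r] - M
  ss_grs <- sum(resid^2)

  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= .Machine$double.eps * max(1, abs(ss_eff))) {
      if (ss_eff <= .Machine$double.eps) return(c(F = 0, p = 1))
      return(c(F = Inf, p = 0))
    }
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    c(F = F, p = pf(F, df_eff, df_err, lower.tail = FALSE))
  }
  fg <- f_of(ss_g, 1, ss_gs, n - 1)
  fr <- f_of(ss_r, 2, ss_rs, 2 * (n - 1))
  fi <- f_of(ss_gr, 2, ss_grs, 2 * (n - 1))

  # sphericity machinery: orthonormal contrasts on the 6 condition columns
  Y6 <- matrix(NA_real_, n, 6)  # column order: (g, r) = (1,1),(1,2),(1,3),(2,1),(2,2),(2,3)
  k <- 0
  for (g in 1:2) for (r in 1:3) { k <- k + 1; Y6[, k] <- Y[, g, r] }
  c_r <- cbind(c(-1, 1, 0) / sqrt(2), c(-1, -1, 2) / sqrt(6))
  m_reward <- rbind(c_r / 2, c_r / 2)                      # averaged over group
  m_inter  <- rbind(c_r / sqrt(2), -c_r / sqrt(2))         # group contrast x reward
  sph <- function(Mc) {
    Tm <- Y6 %*% Mc
    S <- stats::cov(Tm)
    k <- ncol(S)
    tr <- sum(diag(S)); tr2 <- sum(S * S)
    eps <- if (tr2 > 0) tr^2 / (k * tr2) else 1
    dets <- det(S)
    if (tr <= 0 || dets <= 0) {
      return(list(W = NA_real_, chisq = NA_real_, df = k * (k + 1) / 2 - 1,
                  p = NA_real_, eps = eps))
    }
    W <- dets / (tr / k)^k
    f <- (2 * k^2 + k + 2) / (6 * k)
    chisq <- -(n - 1 - f) * log(W)
    list(W = W, chisq = chisq, df = k * (k + 1) / 2 - 1,
         p = pchisq(chisq, k * (k + 1) / 2 - 1, lower.tail = FALSE), eps = eps)
  }
  sph_r <- sph(m_reward)
  sph_i <- sph(m_inter)

  correct <- function(f, df1, df2, sphres) {
    p_gg <- if (is.finite(f[["F"]]))
      pf(f[["F"]], df1 * sphres$eps, df2 * sphres$eps, lower.tail = FALSE)
    else f[["p"]]
    violated <- !is.na(sphres$p) && sphres$p < alpha
    list(correction = if (violated) "Greenhouse-Geisser" else "none",
         p_gg = p_gg,
         p_corrected = if (violated) p_gg else f[["p"]])
  }
  cr <- correct(fr, 2, 2 * (n - 1), sph_r)
  ci <- correct(fi, 2, 2 * (n - 1), sph_i)

  anova <- tibble::tibble(
    effect = c("group", "reward", "group:reward"),
    F = c(fg[["F"]], fr[["F"]], fi[["F"]]),
    df1 = c(1, 2, 2),
    df2 = c(n - 1, 2 * (n - 1), 2 * (n - 1)),
    p = c(fg[["p"]], fr[["p"]], fi[["p"]]),
    correction = c("none", cr$correction, ci$correction),
    epsilon = c(NA, sph_r$eps, sph_i$eps),
    p_gg = c(fg[["p"]], cr$p_gg, ci$p_gg),
    p_corrected = c(fg[["p"]], cr$p_corrected, ci$p_corrected))

  mauchly <- tibble::tibble(
    effect = c("reward", "group:reward"),
    W = c(sph_r$W, sph_i$W),
    chisq = c(sph_r$chisq, sph_i$chisq),
    df = c(sph_r$df, sph_i$df),
    p = c(sph_r$p, sph_i$p))

  # Bonferroni post hocs on reward levels, collapsed across group
  lev <- levels(data$reward)
  coll <- (Y[, 1, ] + Y[, 2, ]) / 2
  pairs <- utils::combn(3, 2)
  ph <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- coll[, i1] - coll[, i2]
    if (isTRUE(all.equal(var(d), 0))) {
      tibble::tibble(contrast = paste(lev[i1], "-", lev[i2]),
                     statistic = 0, df = n - 1, p_raw = 1)
    } else {
      tt <- t.test(coll[, i1], coll[, i2], paired = TRUE)
      tibble::tibble(contrast = paste(lev[i1], "-", lev[i2]),
                     statistic = unname(tt$statistic), df = n - 1, p_raw = tt$p.value)
    }
  })
  posthoc <- dplyr::bind_rows(ph)
  posthoc$p_bonferroni <- pmin(1, posthoc$p_raw * nrow(posthoc))

  list(anova = anova, mauchly = mauchly, posthoc = posthoc)
}
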