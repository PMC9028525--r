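#' Unbiased hit rate from a confusion table
#'
#' Wagner's bias-corrected recognition index: for stimulus category s,
#' `H_u(s) = n(s, s)^2 / (row_total(s) * column_total(s))`, i.e. the hit
#' rate multiplied by the proportion of correct responses among trials on
#' which the category was chosen.  A category never chosen as a response
#' has `H_u = 0`.  `H_u` equals raw accuracy for a diagonal table and is
#' strictly below it whenever the response receives off-diagonal mass.
#'
#' @param table square numeric matrix of counts, rows = stimulus
#'   categories, columns = response categories (same order).
#' @return named numeric vector of per-category unbiased hit rates.
#' @export
unbiased_hit_rate <- function(table) {
  table <- as.matrix(table)
  stop_if_not(nrow(table) == ncol(table),
              "confusion table must be square (same categories)")
  stop_if_not(all(table >= 0), "counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0))
    stop("no presentations for category: ",
         paste(rownames(table)[rs == 0], collapse = ", "), call. = FALSE)
  hu <- ifelse(cs == 0, 0, diag(table)^2 / (rs * cs))
  names(hu) <- rownames(table)
  hu
}

# Orthonormal contrast rows spanning the deviation space of a k-level
# factor (rows orthogonal to the unit vector, mutually orthonormal).
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- t(C) / sqrt(colSums(C^2))
  C
}

# Greenhouse-Geisser epsilon for one within-subject effect, from the
# sample covariance of the condition vectors and the effect's orthonormal
# contrast matrix.
gg_epsilon <- function(Sigma, C) {
  S <- C %*% Sigma %*% t(C)
  q <- nrow(C)
  sum(diag(S))^2 / (q * sum(S * S))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classic univariate within-subject ANOVA for a balanced complete
#' two-factor design: main effects and interaction F tests against their
#' subject-interaction error terms, Greenhouse-Geisser epsilon per effect
#' (from the pooled covariance of the condition scores), corrected degrees
#' of freedom and p-values, partial eta squared, and Bonferroni-adjusted
#' pairwise contrasts on each factor's marginal means.
#'
#' @param data data frame in long format.
#' @param dv name of the value column.
#' @param subject name of the subject id column.
#' @param factors character vector naming the two within-subject factor
#'   columns.
#' @return object of class `anova_rm`: `effects` (data frame with SS, df,
#'   F, epsilon, uncorrected and GG-corrected p, partial eta squared) and
#'   `pairwise` (per factor, Bonferroni-adjusted paired comparisons).
#' @export
rm_anova_gg <- function(data, dv = "value", subject = "subject",
                        factors = c("expression", "body_part")) {
  stop_if_not(length(factors) == 2, "exactly two within-subject factors")
  f1 <- factor(data[[factors[1]]]); f2 <- factor(data[[factors[2]]])
  s <- factor(data[[subject]])
  y <- data[[dv]]
  a <- nlevels(f1); b <- nlevels(f2); n <- nlevels(s)
  stop_if_not(n >= 3, "need at least 3 subjects")
  counts <- table(s, f1, f2)
  stop_if_not(all(counts == 1),
              "design must be balanced and complete (one value per cell)")
  # n x (a*b) matrix of condition scores, factor 1 slow, factor 2 fast
  Y <- matrix(0, n, a * b)
  Y[cbind(as.integer(s), (as.integer(f1) - 1L) * b + as.integer(f2))] <- y
  m <- mean(Y)
  mS <- rowMeans(Y)
  mAB <- matrix(colMeans(Y), b, a)           # b x a cell means
  mA <- colMeans(mAB)
  mB <- rowMeans(mAB)
  mSA <- t(sapply(seq_len(n), function(i) colMeans(matrix(Y[i, ], b, a))))
  mSB <- t(sapply(seq_len(n), function(i) rowMeans(matrix(Y[i, ], b, a))))
  ss_A <- n * b * sum((mA - m)^2)
  ss_B <- n * a * sum((mB - m)^2)
  ss_AB <- n * sum((t(mAB) - outer(mA, mB, `+`) + m)^2)
  # subject x factor interaction sums of squares (error terms)
  ss_AS <- b * sum(sweep(sweep(mSA, 1, mS - m), 2, mA)^2)
  ss_BS <- a * sum(sweep(sweep(mSB, 1, mS - m), 2, mB)^2)
  ss_tot <- sum((Y - m)^2)
  ss_S <- a * b * sum((mS - m)^2)
  ss_ABS <- ss_tot - ss_A - ss_B - ss_AB - ss_S - ss_AS - ss_BS
  df <- list(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1))
  dfe <- list(A = (a - 1) * (n - 1), B = (b - 1) * (n - 1),
              AB = (a - 1) * (b - 1) * (n - 1))
  sse <- list(A = ss_AS, B = ss_BS, AB = ss_ABS)
  ssx <- list(A = ss_A, B = ss_B, AB = ss_AB)
  Sigma <- stats::cov(Y)
  CA <- orthonormal_contrasts(a); CB <- orthonormal_contrasts(b)
  ones <- function(k) matrix(1 / sqrt(k), 1, k)
  Ceff <- list(A = kronecker(CA, ones(b)),
               B = kronecker(ones(a), CB),
               AB = kronecker(CA, CB))
  eff <- do.call(rbind, lapply(names(ssx), function(e) {
    Fv <- (ssx[[e]] / df[[e]]) / (sse[[e]] / dfe[[e]])
    eps <- gg_epsilon(Sigma, Ceff[[e]])
    data.frame(effect = c(A = factors[1], B = factors[2],
                          AB = paste(factors, collapse = ":"))[[e]],
               ss = ssx[[e]], df1 = df[[e]], df2 = dfe[[e]], F = Fv,
               p = stats::pf(Fv, df[[e]], dfe[[e]], lower.tail = FALSE),
               epsilon = eps,
               df1_gg = df[[e]] * eps, df2_gg = dfe[[e]] * eps,
               p_gg = stats::pf(Fv, df[[e]] * eps, dfe[[e]] * eps,
                                lower.tail = FALSE),
               pes = ssx[[e]] / (ssx[[e]] + sse[[e]]))
  }))
  rownames(eff) <- NULL
  pairwise <- list(
    pairwise_paired(mSA, levels(f1), factors[1]),
    pairwise_paired(mSB, levels(f2), factors[2]))
  names(pairwise) <- factors
  structure(list(effects = eff, pairwise = pairwise,
                 factors = factors, n_subjects = n),
            class = "anova_rm")
}

# Bonferroni-adjusted paired t-tests over all level pairs of one factor
# (columns of `M` are subject-level marginal means).
pairwise_paired <- function(M, levels, factor_name) {
  pairs <- utils::combn(ncol(M), 2)
  out <- data.frame(
    factor = factor_name,
    level1 = levels[pairs[1, ]], level2 = levels[pairs[2, ]],
    difference = apply(pairs, 2, function(ij) mean(M[, ij[1]] - M[, ij[2]])),
    t = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    tt <- stats::t.test(M[, pairs[1, j]], M[, pairs[2, j]], paired = TRUE)
    out$t[j] <- unname(tt$statistic); out$p[j] <- tt$p.value
  }
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' @param Y n_subjects x k matrix of condition scores.
#' @param levels optional level labels.
#' @return data frame with F, df, epsilon, uncorrected and corrected p.
#' @export
rm_anova1 <- function(Y, levels = colnames(Y)) {
  n <- nrow(Y); k <- ncol(Y)
  stop_if_not(n >= 2 && k >= 2, "need at least 2 subjects and 2 levels")
  m <- mean(Y); mC <- colMeans(Y); mS <- rowMeans(Y)
  ss_C <- n * sum((mC - m)^2)
  ss_CS <- sum(sweep(sweep(Y, 1, mS - m), 2, mC)^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_C / df1) / (ss_CS / df2)
  eps <- if (k == 2) 1 else gg_epsilon(stats::cov(Y), orthonormal_contrasts(k))
  data.frame(df1 = df1, df2 = df2, F = Fv,
             p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
             epsilon = eps,
             p_gg = stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
             pes = ss_C / (ss_C + ss_CS))
}

#' Simple-effect analyses after an interaction
#'
#' At each level of `at`, runs a one-way repeated-measures ANOVA (with
#' Greenhouse-Geisser correction) over the levels of `within`, followed by
#' Bonferroni-adjusted pairwise paired comparisons within that level.
#'
#' @inheritParams rm_anova_gg
#' @param within factor analyzed within each level.
#' @param at factor whose levels stratify the analyses.
#' @return named list (one entry per level of `at`) with `anova` and
#'   `pairwise` components.
#' @export
simple_effects <- function(data, dv = "value", subject = "subject",
                           within, at) {
  f_at <- factor(data[[at]])
  out <- lapply(levels(f_at), function(lv) {
    d <- data[f_at == lv, ]
    fw <- factor(d[[within]]); s <- factor(d[[subject]])
    Y <- matrix(0, nlevels(s), nlevels(fw))
    Y[cbind(as.integer(s), as.integer(fw))] <- d[[dv]]
    colnames(Y) <- levels(fw)
    list(anova = rm_anova1(Y),
         pairwise = pairwise_paired(Y, levels(fw), within))
  })
  names(out) <- levels(f_at)
  out
}

#' @export
print.anova_rm <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$n_subjects, " subjects)\n", sep = "")
  eff <- x$effects
  eff$F <- round(eff$F, 3); eff$epsilon <- round(eff$epsilon, 3)
  print(eff[, c("effect", "df1", "df2", "F", "epsilon", "p_gg", "pes")],
        row.names = FALSE)
  invisible(x)
}
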