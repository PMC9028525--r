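#' Condition labels of the 3 x 4 expression-by-body-part design
#'
#' @param expressions expression labels.
#' @param parts body-part labels.
#' @return character vector `"<expression>_<part>"`, part varying slowest.
#' @export
design_conditions <- function(expressions = c("anger", "fear", "neutral"),
                              parts = c("whole_body", "torso_with_arms",
                                        "legs", "head")) {
  as.vector(t(outer(parts, expressions,
                    function(p, e) paste(e, p, sep = "_"))))
}

# Split condition labels into emotion (first token) and part (rest).
parse_conditions <- function(labels) {
  sp <- strsplit(labels, "_", fixed = TRUE)
  data.frame(
    condition = labels,
    emotion = vapply(sp, `[`, character(1), 1),
    part = vapply(sp, function(x) paste(x[-1], collapse = "_"), character(1)))
}

#' True representational dissimilarity matrix
#'
#' Pairwise dissimilarity 1 - Pearson correlation between condition
#' response patterns.
#'
#' @param patterns numeric matrix, rows = conditions (rownames taken as
#'   condition labels), columns = ROI units (voxels).
#' @return symmetric matrix with zero diagonal, entries in \[0, 2\],
#'   class `rdm` with `kind = "true"`.
#' @export
true_rdm <- function(patterns) {
  stop_if_not(is.matrix(patterns) && nrow(patterns) >= 2 &&
                ncol(patterns) >= 2,
              "patterns must be a conditions x units matrix (>= 2 each)")
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds < 1e-12))
    stop("zero-variance pattern for condition: ",
         paste(rownames(patterns)[sds < 1e-12], collapse = ", "),
         call. = FALSE)
  d <- 1 - stats::cor(t(patterns))
  diag(d) <- 0
  structure(d, class = c("rdm", "matrix"), kind = "true")
}

#' Group-average RDM
#'
#' Entrywise mean of per-subject RDMs sharing one condition ordering.
#'
#' @param rdms list of RDM matrices with identical dimnames.
#' @return the mean RDM.
#' @export
group_rdm <- function(rdms) {
  stop_if_not(length(rdms) >= 1, "need at least one RDM")
  ord <- rownames(rdms[[1]])
  for (r in rdms)
    stop_if_not(identical(rownames(r), ord) && identical(colnames(r), ord),
                "condition ordering differs across RDMs")
  out <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  structure(out, class = c("rdm", "matrix"), kind = "true")
}

#' Candidate model RDMs for the expression-by-body-part design
#'
#' Builds the seven candidate dissimilarity models over the 12 conditions
#' (3 expressions x 4 body parts):
#' \describe{
#'   \item{body_separate}{categorical; each body part its own category.}
#'   \item{body_pattern1}{categorical; whole body and torso-with-arms
#'     merged into one category.}
#'   \item{emotion_separate}{categorical; each emotion its own category.}
#'   \item{emotion_pattern1}{categorical; emotions distinguished only
#'     among whole-body / torso-with-arms conditions, all other pairs
#'     maximally dissimilar.}
#'   \item{body_pattern2}{ranked; within a part 0, torso-with-arms vs
#'     whole body and vs legs rank 1, legs vs whole body / head vs
#'     torso-with-arms / head vs legs rank 2, whole body vs head rank 3.}
#'   \item{emotion_pattern2}{body_pattern2 refined: pairs within the
#'     whole-body / torso-with-arms block take ranks 0--5 increasing with
#'     emotional dissimilarity (same emotion < anger-fear < emotion-
#'     neutral) and body-type mismatch, torso-with-arms vs legs rank 6,
#'     then ranks 7 and 8 reproduce body_pattern2's two remaining tiers.}
#'   \item{random}{symmetric uniform(0, 1) entries, seeded.}
#' }
#' All rank models are normalized to \[0, 1\]; every candidate is
#' symmetric with a zero diagonal.
#'
#' @param condition_order condition labels enumerating the full 3 x 4
#'   design (see [design_conditions()]).
#' @param seed seed for the random model.
#' @return named list of 7 `rdm` matrices with `kind = "candidate"`.
#' @export
candidate_rdms <- function(condition_order = design_conditions(), seed = 0) {
  info <- parse_conditions(condition_order)
  emos <- unique(info$emotion); parts <- unique(info$part)
  stop_if_not(length(emos) == 3 && length(parts) == 4 &&
                nrow(info) == 12 && !anyDuplicated(info$condition),
              "condition order must enumerate the full 3 x 4 design")
  stop_if_not(all(c("whole_body", "torso_with_arms") %in% parts) &&
                "neutral" %in% emos,
              "design must include whole_body, torso_with_arms and neutral")
  n <- nrow(info)
  wbta <- info$part %in% c("whole_body", "torso_with_arms")
  same_part <- outer(info$part, info$part, `==`)
  same_emo <- outer(info$emotion, info$emotion, `==`)
  in_block <- outer(wbta, wbta, `&`)
  neutral <- info$emotion == "neutral"

  mk <- function(m, normalize = 1) {
    m <- m / normalize
    diag(m) <- 0
    dimnames(m) <- list(info$condition, info$condition)
    structure(m, class = c("rdm", "matrix"), kind = "candidate")
  }

  merged <- ifelse(wbta, "wb_ta", info$part)
  body_separate <- mk(1 * !same_part)
  body_pattern1 <- mk(1 * outer(merged, merged, `!=`))
  emotion_separate <- mk(1 * !same_emo)
  emotion_pattern1 <- mk(ifelse(in_block, 1 * !same_emo, 1))

  # body_pattern2 tier lookup over part pairs
  tier <- matrix(0, 4, 4, dimnames = list(parts, parts))
  tier["torso_with_arms", "whole_body"] <- 1
  tier["torso_with_arms", "legs"] <- 1
  tier["legs", "whole_body"] <- 2
  tier["head", "torso_with_arms"] <- 2
  tier["head", "legs"] <- 2
  tier["whole_body", "head"] <- 3
  tier <- pmax(tier, t(tier))
  bp2 <- tier[cbind(match(info$part, parts)[row(same_part)],
                    match(info$part, parts)[col(same_part)])]
  bp2 <- matrix(bp2, n, n)
  body_pattern2 <- mk(bp2, normalize = 3)

  # emotion_pattern2: emotion-graded ranks inside the WB/TA block,
  # then body_pattern2's remaining tiers shifted to 7 and 8
  emo_dist <- ifelse(same_emo, 0, ifelse(outer(neutral, neutral, `|`), 2, 1))
  ep2 <- matrix(0, n, n)
  ep2[in_block] <- (2 * emo_dist + !same_part)[in_block]
  ta_legs <- outer(info$part == "torso_with_arms", info$part == "legs") |
    outer(info$part == "legs", info$part == "torso_with_arms")
  ep2[ta_legs] <- 6
  ep2[!in_block & !ta_legs & bp2 == 2] <- 7
  ep2[!in_block & bp2 == 3] <- 8
  emotion_pattern2 <- mk(ep2, normalize = 8)

  rnd <- local_seed(seed, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
    m + t(m)
  })
  random <- mk(rnd)

  list(body_separate = body_separate, body_pattern1 = body_pattern1,
       body_pattern2 = body_pattern2, emotion_separate = emotion_separate,
       emotion_pattern1 = emotion_pattern1,
       emotion_pattern2 = emotion_pattern2, random = random)
}

#' Lower-triangle vector of an RDM
#'
#' @param rdm square matrix.
#' @return numeric vector of the strictly-lower-triangle entries.
#' @export
lower_tri <- function(rdm) rdm[lower.tri(rdm)]

#' Kendall's tau-a rank correlation
#'
#' (concordant - discordant) / (n (n - 1) / 2): ties are never counted as
#' concordant or discordant but remain in the denominator (no tie
#' correction), the convention recommended when candidate models predict
#' tied ranks.
#'
#' @param x,y numeric vectors of equal length (>= 2), e.g. the
#'   lower-triangle entries of two RDMs.
#' @return tau_a in \[-1, 1\].
#' @export
kendall_tau_a <- function(x, y) {
  stop_if_not(length(x) == length(y), "vectors must have equal length")
  n <- length(x)
  stop_if_not(n >= 2, "need at least 2 entries")
  sx <- sign(outer(x, x, `-`)); sy <- sign(outer(y, y, `-`))
  ut <- upper.tri(sx)
  sum(sx[ut] * sy[ut]) / (n * (n - 1) / 2)
}

#' Exact Wilcoxon signed-rank p-value
#'
#' Signed-rank test against zero shift.  Zeros are dropped; the null
#' distribution is exact (via the standard signed-rank distribution when
#' the absolute values are untied, or complete sign-flip enumeration for
#' tied samples up to n = 16) and a tie-corrected normal approximation
#' beyond that.  All-zero input gives the degenerate p = 1.
#'
#' @param x numeric vector of paired differences (or per-subject values
#'   tested against zero).
#' @param alternative `"greater"` (one-sided) or `"two.sided"`.
#' @return the p-value.
#' @export
signed_rank_p <- function(x, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- x[x != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties) {
    p_ge <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p_le <- stats::psignrank(W, n)
  } else if (n <= 16) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.vector(signs %*% r)
    p_ge <- mean(Wnull >= W)
    p_le <- mean(Wnull <= W)
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48)
    p_ge <- stats::pnorm((W - 0.5 - mu) / sig, lower.tail = FALSE)
    p_le <- stats::pnorm((W + 0.5 - mu) / sig)
  }
  if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
}

#' Model-relatedness test
#'
#' Tests whether a candidate model's per-subject tau_a correlations with
#' the true RDMs are positive: one-sided signed-rank test against zero
#' (default) or a t-test.
#'
#' @param taus per-subject tau_a values for one model.
#' @param test `"signed-rank"` or `"t"`.
#' @return the p-value.
#' @export
relatedness_test <- function(taus, test = c("signed-rank", "t")) {
  test <- match.arg(test)
  if (all(taus == 0)) return(1)
  if (test == "signed-rank") signed_rank_p(taus, "greater")
  else stats::t.test(taus, mu = 0)$p.value
}

#' Pairwise model-comparison test
#'
#' Two-sided signed-rank (default) or paired t-test on the per-subject
#' difference in tau_a between two candidate models.
#'
#' @param taus_a,taus_b per-subject tau_a values of the two models,
#'   paired by subject.
#' @param test `"signed-rank"` or `"t"`.
#' @return the p-value.
#' @export
pairwise_model_test <- function(taus_a, taus_b,
                                test = c("signed-rank", "t")) {
  test <- match.arg(test)
  stop_if_not(length(taus_a) == length(taus_b),
              "tau vectors must be paired by subject")
  d <- taus_a - taus_b
  if (all(d == 0)) return(1)
  if (test == "signed-rank") signed_rank_p(d, "two.sided")
  else stats::t.test(d, mu = 0)$p.value
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control over one family of p-values, evaluated at one or
#' more q levels.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q FDR level(s).
#' @return list with `adjusted` (BH-adjusted p-values), `significant`
#'   (logical matrix, one column per q), and `thresholds` (the largest
#'   rejected raw p per q, 0 when none).
#' @export
fdr_correct <- function(p_values, q = c(0.05, 0.01)) {
  stop_if_not(all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  sig <- vapply(q, function(qq) adj <= qq, logical(length(p_values)))
  sig <- matrix(sig, ncol = length(q),
                dimnames = list(names(p_values), paste0("q", q)))
  thr <- vapply(q, function(qq) {
    rej <- p_values[adj <= qq]
    if (length(rej)) max(rej) else 0
  }, numeric(1))
  list(adjusted = adj, significant = sig,
       thresholds = stats::setNames(thr, paste0("q", q)))
}

#' Compare candidate models against per-subject true RDMs
#'
#' Computes each subject's tau_a between the true RDM and every candidate
#' model, tests each model's relatedness (one-sided) and every model pair
#' (two-sided), and applies Benjamini-Hochberg FDR within the two
#' families (models; model pairs).
#'
#' @param true_rdms list of per-subject RDMs (shared condition order).
#' @param models named list of candidate RDMs (see [candidate_rdms()]).
#' @param q FDR level(s).
#' @param test `"signed-rank"` or `"t"` (applies to both inference steps).
#' @return object of class `model_comparison`: `taus` (subjects x models),
#'   `relatedness` (data frame with mean tau, p, FDR flags), `pairwise`
#'   (data frame per model pair), and the parameters.
#' @export
rsa_compare <- function(true_rdms, models, q = c(0.05, 0.01),
                        test = c("signed-rank", "t")) {
  test <- match.arg(test)
  stop_if_not(length(true_rdms) >= 5, "need at least 5 subjects")
  taus <- vapply(models, function(m) {
    mv <- lower_tri(m)
    vapply(true_rdms, function(r) kendall_tau_a(lower_tri(r), mv),
           numeric(1))
  }, numeric(length(true_rdms)))
  rel_p <- apply(taus, 2, relatedness_test, test = test)
  rel_fdr <- fdr_correct(rel_p, q)
  relatedness <- data.frame(model = colnames(taus),
                            mean_tau = colMeans(taus), p = rel_p,
                            rel_fdr$significant, row.names = NULL,
                            check.names = FALSE)
  pairs <- utils::combn(colnames(taus), 2)
  pw_p <- apply(pairs, 2, function(mm)
    pairwise_model_test(taus[, mm[1]], taus[, mm[2]], test = test))
  pw_fdr <- fdr_correct(pw_p, q)
  pairwise <- data.frame(model1 = pairs[1, ], model2 = pairs[2, ],
                         mean_diff = apply(pairs, 2, function(mm)
                           mean(taus[, mm[1]] - taus[, mm[2]])),
                         p = pw_p, pw_fdr$significant, row.names = NULL,
                         check.names = FALSE)
  structure(list(taus = taus, relatedness = relatedness,
                 pairwise = pairwise, q = q, test = test),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("RSA model comparison (", nrow(x$taus), " subjects, ",
      ncol(x$taus), " models, ", x$test, " test)\n", sep = "")
  rel <- x$relatedness
  rel$mean_tau <- round(rel$mean_tau, 3)
  rel$p <- signif(rel$p, 3)
  print(rel[order(-rel$mean_tau), ], row.names = FALSE)
  invisible(x)
}

#' Classical 2-D multidimensional scaling of an RDM
#'
#' Torgerson double-centering with the top two eigen-dimensions; each
#' coordinate axis is sign-fixed so that its first non-zero loading is
#' non-negative.
#'
#' @param rdm square dissimilarity matrix.
#' @return list with `coords` (conditions x 2) and `eig` (eigenvalues).
#' @export
mds_2d <- function(rdm) {
  n <- nrow(rdm)
  if (n < 3) warning("fewer than 3 conditions: embedding is degenerate")
  cm <- stats::cmdscale(stats::as.dist(rdm), k = min(2, n - 1), eig = TRUE)
  coords <- cm$points
  if (ncol(coords) < 2)
    coords <- cbind(coords, matrix(0, n, 2 - ncol(coords)))
  for (j in 1:2) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(rdm)
  list(coords = coords, eig = cm$eig)
}

#' Single-linkage dendrogram of an RDM
#'
#' Nearest-neighbor agglomerative clustering of the conditions.
#'
#' @param rdm square dissimilarity matrix.
#' @return an [stats::hclust] tree.
#' @export
rdm_dendrogram <- function(rdm) {
  stats::hclust(stats::as.dist(rdm), method = "single")
}

#' Sorensen-Dice overlap of two binary maps
#'
#' `R = 2 * V_overlap / (V1 + V2)` with V1, V2 the set sizes and
#' V_overlap the intersection size; two empty maps give R = 0.
#'
#' @param map_a,map_b logical (or 0/1) arrays on the same grid.
#' @return object of class `overlap_result` with `v1`, `v2`, `v_overlap`
#'   and `r_overlap`.
#' @export
dice_overlap <- function(map_a, map_b) {
  stop_if_not(identical(dim(map_a), dim(map_b)),
              "maps must share the same grid")
  a <- as.logical(map_a); b <- as.logical(map_b)
  v1 <- sum(a); v2 <- sum(b); vo <- sum(a & b)
  structure(list(v1 = v1, v2 = v2, v_overlap = vo,
                 r_overlap = if (v1 + v2 == 0) 0 else 2 * vo / (v1 + v2)),
            class = "overlap_result")
}
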