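# Cohort-level statistics: ellipsoid tumor volume, the normality-gated
# two-group comparison, and Kruskal-Wallis with Dunn's post-hoc test.

#' Ellipsoid tumor volume from caliper axes
#'
#' V = (pi / 6) a b c for the three orthogonal tumor axes in mm; symmetric
#' in its arguments and vectorised.
#'
#' @param a,b,c orthogonal axes in mm (>= 0).
#' @return volume in mm^3.
#' @examples
#' ellipsoidVolume(1, 1, 1)  # pi/6
#' @export
ellipsoidVolume <- function(a, b, c) {
  stopIfNot(all(is.finite(c(a, b, c))) && all(c(a, b, c) >= 0),
            "axes must be finite and non-negative")
  pi / 6 * a * b * c
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K2 omnibus test combining transformed sample skewness and kurtosis
#' (D'Agostino, Belanger & D'Agostino 1990); K2 is referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires n >= 8; the kurtosis
#' transformation is unreliable below that.
#'
#' @param x numeric sample (n >= 8).
#' @return list with \code{statistic} (K2), \code{p}, \code{skewZ},
#'   \code{kurtZ}.
#' @export
dagostinoPearsonTest <- function(x) {
  n <- length(x)
  stopIfNot(n >= 8L, "D'Agostino-Pearson needs n >= 8")
  stopIfNot(stats::sd(x) > 0, "constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3

  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
          ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Zg1^2 + Zg2^2
  list(statistic = K2, p = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       skewZ = Zg1, kurtZ = Zg2)
}

#' Two-group comparison with a normality gate
#'
#' Applies the D'Agostino-Pearson omnibus test to each group; if both are
#' compatible with normality (p > alpha) an unpaired t-test is used,
#' otherwise the Mann-Whitney test. Groups smaller than 8 default to the
#' rank test, since the gate statistic is unreliable there. The rank path
#' uses the normal approximation with mid-ranks and no continuity
#' correction, so exactly tied groups give p = 1.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alpha normality-gate level.
#' @param gate \code{"auto"} (the normality gate), or force
#'   \code{"normal"} / \code{"rank"}.
#' @param varEqual classic equal-variance t-test (TRUE, the conventional
#'   unpaired t-test) or Welch.
#' @param labels group labels for reporting.
#' @return a \code{\linkS4class{StatResult}}; the statistic is t or the
#'   Mann-Whitney U of the first group.
#' @export
compareTwoGroups <- function(x, y, alpha = 0.05,
                             gate = c("auto", "normal", "rank"),
                             varEqual = TRUE,
                             labels = c("group1", "group2")) {
  gate <- match.arg(gate)
  stopIfNot(length(x) >= 3L && length(y) >= 3L,
            "each group needs at least 3 values")
  normP <- c(NA_real_, NA_real_)
  if (gate == "auto") {
    if (length(x) >= 8L && length(y) >= 8L) {
      normP <- c(dagostinoPearsonTest(x)$p, dagostinoPearsonTest(y)$p)
      path <- if (all(normP > alpha)) "normal" else "rank"
      why <- sprintf(
        "D'Agostino-Pearson gate: p = %.3g, %.3g -> %s path",
        normP[1L], normP[2L], if (path == "normal") "t-test"
        else "Mann-Whitney")
    } else {
      path <- "rank"
      why <- "group n < 8: normality gate not evaluable, rank test used"
    }
  } else {
    path <- gate
    why <- sprintf("gate forced to %s path", gate)
  }
  if (path == "normal") {
    tt <- stats::t.test(x, y, var.equal = varEqual)
    new("StatResult", test = "unpaired t-test", groups = labels,
        statistic = unname(tt$statistic), p = tt$p.value,
        normality = normP, gate = why)
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    new("StatResult", test = "Mann-Whitney", groups = labels,
        statistic = unname(wt$statistic), p = wt$p.value,
        normality = normP, gate = why)
  }
}

# Dunn's z post-hoc comparisons on pooled mid-ranks, with tie correction
.dunnPosthoc <- function(values, g, padjust) {
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tieT <- sum(ties^3 - ties)
  lev <- levels(g)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  prs <- utils::combn(seq_along(lev), 2L)
  z <- p <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1L, k]; j <- prs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tieT / (12 * (N - 1))) *
               (1 / ni[i] + 1 / ni[j]))
    z[k] <- (rbar[i] - rbar[j]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = lev[prs[1L, ]], group2 = lev[prs[2L, ]],
             z = z, p = p, p_adj = stats::p.adjust(p, method = padjust),
             stringsAsFactors = FALSE)
}

#' Multi-group comparison: Kruskal-Wallis with Dunn's post-hoc test
#'
#' Kruskal-Wallis across k >= 3 groups; when the omnibus p falls below
#' alpha, Dunn's pairwise z comparisons on the pooled ranks follow, with a
#' Bonferroni-family multiplicity adjustment (configurable via
#' \code{padjust}). Adjusted p-values are never smaller than the raw ones.
#'
#' @param groups named list of numeric vectors (k >= 3, each n >= 3).
#' @param alpha omnibus level gating the post-hoc step.
#' @param padjust p-adjustment method for \code{\link[stats]{p.adjust}}.
#' @return a \code{\linkS4class{StatResult}} with the H statistic, omnibus
#'   p, and the post-hoc table (empty when the omnibus is not significant).
#' @export
compareKGroups <- function(groups, alpha = 0.05, padjust = "bonferroni") {
  stopIfNot(is.list(groups) && length(groups) >= 3L,
            "need at least 3 groups (use compareTwoGroups for two)")
  stopIfNot(all(vapply(groups, length, integer(1L)) >= 3L),
            "each group needs at least 3 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1L))),
              levels = names(groups))
  kw <- stats::kruskal.test(values, g)
  posthoc <- if (is.finite(kw$p.value) && kw$p.value < alpha)
    .dunnPosthoc(values, g, padjust) else data.frame()
  new("StatResult", test = "Kruskal-Wallis", groups = names(groups),
      statistic = unname(kw$statistic), p = kw$p.value, posthoc = posthoc,
      gate = if (nrow(posthoc)) "omnibus significant: Dunn post-hoc run"
             else "omnibus not significant: no post-hoc")
}

#' Mean and standard error of the mean
#'
#' @param x numeric vector.
#' @return data.frame (n, mean, sem).
#' @export
meanSem <- function(x) {
  data.frame(n = length(x), mean = mean(x),
             sem = stats::sd(x) / sqrt(length(x)))
}
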