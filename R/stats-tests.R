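# Statistical primitives not available in the installed stack: the
# D'Agostino-Pearson omnibus normality test and Dunn's rank-based post hoc
# test. Standard published formulas; validated in the test suite against
# independent references.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into the K2 statistic, chi-squared with 2 df
#' under normality. Requires n >= 8.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant sample: normality test undefined", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino's Z1
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn's Z2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  denom <- 1 + xx * sqrt(2 / (a - 4))
  if (denom == 0) stop("degenerate kurtosis transform", call. = FALSE)
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Dunn's multiple-comparison test
#'
#' Rank-based pairwise z tests after a Kruskal-Wallis test, with the
#' standard tie correction; two-sided p-values adjusted by Bonferroni over
#' all pairs (the convention of common analysis software).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return tibble with `contrast`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(groups, p_adjust = "bonferroni") {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  tibble::tibble(contrast = paste(pairs[1, ], pairs[2, ], sep = " - "),
                 z = z, p_raw = p_raw,
                 p_adj = pmin(1, stats::p.adjust(p_raw, method = p_adjust)))
}
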