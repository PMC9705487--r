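# Treatment-comparison statistics: assumption checks, one-way ANOVA,
# step-down Holm-Sidak pairwise multiple comparisons with letter codes,
# and Welch t-tests.

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and Brown-Forsythe (median-centred Levene) across
#' groups, flagged at the supplied significance level. Groups too small (or
#' constant) for the normality test are skipped with a flag rather than
#' failing the pipeline.
#'
#' @param groups A named list of numeric vectors, one per treatment group.
#' @param alpha Significance level for the flags (default 0.05).
#' @return A list of class `assumption_checks` with `shapiro` (data frame:
#'   group, n, p, skipped), `brown_forsythe_p`, `normality_ok`,
#'   `variance_ok`.
#' @export
assumption_checks <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  sw <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]][!is.na(groups[[g]])]
    skipped <- length(x) < 3L || sd(x) == 0
    p <- if (skipped) NA_real_ else shapiro.test(x)$p.value
    data.frame(group = g, n = length(x), p = p, skipped = skipped,
               stringsAsFactors = FALSE)
  }))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, 1L)))
  bf <- tryCatch(
    car::leveneTest(values ~ fac, center = stats::median)[1, "Pr(>F)"],
    error = function(e) NA_real_
  )
  structure(list(shapiro = sw, brown_forsythe_p = bf,
                 normality_ok = all(sw$p > alpha, na.rm = TRUE),
                 variance_ok = is.na(bf) || bf > alpha,
                 alpha = alpha),
            class = "assumption_checks")
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way F test across treatment groups.
#'
#' @param groups A named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A list of class `oneway_anova` with `f`, `p`, `df1`, `df2` and
#'   the underlying `aov` fit.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, function(x) sum(!is.na(x)), 1L)
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, 1L)))
  if (sd(values, na.rm = TRUE) == 0)
    stop("degenerate data: zero total variance", call. = FALSE)
  fit <- aov(values ~ fac)
  tab <- anova(fit)
  structure(list(f = tab[1, "F value"], p = tab[1, "Pr(>F)"],
                 df1 = tab[1, "Df"], df2 = tab[2, "Df"],
                 ms_error = tab[2, "Mean Sq"], fit = fit),
            class = "oneway_anova")
}

#' Step-down Holm-Sidak adjustment of a set of p-values
#'
#' Sorts the raw p-values ascending, sets
#' adjusted_(i) = 1 - (1 - p_(i))^(m - i + 1), enforces monotone
#' non-decrease down the ordering, caps at 1, and restores the input order.
#' Controls the family-wise error rate at the nominal level.
#'
#' @param raw_p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04, 0.03))  # 0.0297, 0.0591, 0.0591
#' @export
holm_sidak_adjust <- function(raw_p) {
  if (!is.numeric(raw_p) || any(!is.finite(raw_p)) || any(raw_p < 0 | raw_p > 1))
    stop("invalid p-values: need finite values in [0, 1]", call. = FALSE)
  m <- length(raw_p)
  if (m == 0L) return(numeric(0))
  ord <- order(raw_p)
  p_sorted <- raw_p[ord]
  adj <- 1 - (1 - p_sorted)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' All-pairs multiple comparisons with Holm-Sidak adjustment
#'
#' Pairwise t statistics use the pooled ANOVA error mean square and its
#' degrees of freedom (the classical post-hoc construction); the resulting
#' raw p-values are adjusted with [holm_sidak_adjust()] and translated into
#' compact letter codes at level `alpha` (groups sharing a letter are not
#' significantly different).
#'
#' @param groups A named list of numeric vectors.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list of class `pairwise_comparisons` with `comparisons` (data
#'   frame: group_a, group_b, t, raw_p, adj_p, significant) and `letters`
#'   (named character vector of letter codes).
#' @export
pairwise_holm_sidak <- function(groups, alpha = 0.05) {
  an <- oneway_anova(groups)
  means <- vapply(groups, function(x) mean(x, na.rm = TRUE), 1)
  ns <- vapply(groups, function(x) sum(!is.na(x)), 1L)
  g <- names(groups)
  pairs <- utils::combn(g, 2L)
  t_stat <- raw_p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(an$ms_error * (1 / ns[[a]] + 1 / ns[[b]]))
    t_stat[k] <- (means[[a]] - means[[b]]) / se
    raw_p[k] <- 2 * stats::pt(-abs(t_stat[k]), df = an$df2)
  }
  adj <- holm_sidak_adjust(raw_p)
  cmp <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    t = t_stat, raw_p = raw_p, adj_p = adj,
                    significant = adj <= alpha, stringsAsFactors = FALSE)
  structure(list(comparisons = cmp, anova = an,
                 letters = letter_codes(cmp, g[order(-means)], alpha)),
            class = "pairwise_comparisons")
}

#' Compact letter display from an adjusted-p comparison table
#'
#' Deterministic function of the adjusted-p matrix: every maximal clique of
#' the "not significantly different at alpha" graph receives one letter, so
#' two groups share a letter exactly when they are not significantly
#' different. Cliques are enumerated exhaustively (treatment counts in this
#' design are small) and lettered in the supplied group order
#' (conventionally by descending mean).
#'
#' @param comparisons Data frame with columns `group_a`, `group_b`, `adj_p`.
#' @param group_order Character vector giving the lettering order of all
#'   group names.
#' @param alpha Significance level.
#' @return Named character vector of letter codes, one per group.
#' @export
letter_codes <- function(comparisons, group_order, alpha = 0.05) {
  k <- length(group_order)
  if (k > 16L) stop("letter display supported for <= 16 groups", call. = FALSE)
  compat <- matrix(TRUE, k, k, dimnames = list(group_order, group_order))
  for (r in seq_len(nrow(comparisons))) {
    a <- comparisons$group_a[r]; b <- comparisons$group_b[r]
    if (comparisons$adj_p[r] <= alpha)
      compat[a, b] <- compat[b, a] <- FALSE
  }
  # enumerate all cliques of the compatibility graph, keep the maximal ones
  cliques <- list()
  for (mask in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    sub <- compat[members, members, drop = FALSE]
    if (all(sub)) cliques[[length(cliques) + 1L]] <- members
  }
  is_max <- vapply(cliques, function(ci) {
    !any(vapply(cliques, function(cj)
      length(cj) > length(ci) && all(ci %in% cj), logical(1)))
  }, logical(1))
  cliques <- cliques[is_max]
  # deterministic letter order: by earliest member in group_order
  cliques <- cliques[order(vapply(cliques, min, 1L),
                           vapply(cliques, function(x) -length(x), -1L))]
  out <- setNames(rep("", k), group_order)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out
}

#' Two-sample Welch t-test
#'
#' Two-sided t-test with Welch-Satterthwaite degrees of freedom (default) or
#' pooled variance.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @param pooled Use the pooled-variance (Student) form instead of Welch.
#' @return A list of class `welch_t` with `t`, `p`, `df`.
#' @export
welch_t_test <- function(group_a, group_b, pooled = FALSE) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    stop("degenerate data: zero variance in both groups with equal means",
         call. = FALSE)
  fit <- t.test(a, b, var.equal = pooled)
  structure(list(t = unname(fit$statistic), p = fit$p.value,
                 df = unname(fit$parameter)),
            class = "welch_t")
}
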