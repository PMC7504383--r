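#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard routine with explicit guards: sample
#' size must be in 3..5000 and the input must not be constant.
#'
#' @param values Numeric vector.
#' @return List with elements `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant input: normality test undefined")
  t <- stats::shapiro.test(values)
  list(W = unname(t$statistic), p_value = t$p.value)
}

#' Classical one-way (between-subjects) analysis of variance
#'
#' F = MS_between / MS_within with degrees of freedom (g - 1, N - g);
#' p from the F distribution. Sums of squares are computed directly.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups of >= 2 samples each).
#' @return A list of class `anova_result`: `f_value`, `p_value`,
#'   `df_between`, `df_within`, and a `groups` data frame of per-group n,
#'   mean, and sd.
#' @export
one_way_anova <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  g <- length(sizes)
  if (g < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("singleton group(s)")
  N <- length(values)
  gm <- tapply(values, groups, mean)
  ss_between <- sum(sizes * (gm - mean(values))^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- g - 1L; df_w <- N - g
  ms_w <- ss_within / df_w
  if (ms_w < .Machine$double.eps * max(1, ss_between)) {
    stop("zero within-group variance: F undefined (infinite)")
  }
  f <- (ss_between / df_b) / ms_w
  structure(list(
    f_value = f,
    p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
    df_between = df_b, df_within = df_w,
    ms_within = ms_w,
    groups = data.frame(group = names(sizes), n = as.integer(sizes),
                        mean = as.numeric(gm),
                        sd = as.numeric(tapply(values, groups, stats::sd)),
                        stringsAsFactors = FALSE)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_value, x$p_value))
  invisible(x)
}

# Compact letter display: each maximal clique of the non-significance graph
# gets a letter; a group's letters are the cliques containing it. Brute
# force over subsets is fine for the handful of groups used here.
compact_letters <- function(group_names, nonsig) {
  g <- length(group_names)
  if (g > 15L) stop("compact letter display supports at most 15 groups")
  is_clique <- function(members) {
    if (length(members) <= 1L) return(TRUE)
    pairs <- utils::combn(members, 2)
    all(nonsig[cbind(pairs[1, ], pairs[2, ])])
  }
  cliques <- list()
  for (mask in seq_len(2^g - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(g) - 1L)) > 0L)
    if (is_clique(members)) cliques[[length(cliques) + 1L]] <- members
  }
  # keep maximal cliques only
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  cliques <- cliques[keep]
  # order cliques by their best (smallest-index) member for stable letters
  cliques <- cliques[order(vapply(cliques, min, integer(1)))]
  letters_out <- rep("", g)
  for (k in seq_along(cliques)) {
    letters_out[cliques[[k]]] <- paste0(letters_out[cliques[[k]]], letters[k])
  }
  stats::setNames(letters_out, group_names)
}

#' Tukey's honestly-significant-difference post-hoc test
#'
#' Pairwise comparisons based on the studentized range distribution using
#' the Tukey-Kramer standard error for unequal group sizes, followed by a
#' compact letter display (groups sharing a letter do not differ at `alpha`).
#' Groups are lettered in decreasing order of mean.
#'
#' @param values,groups As in [one_way_anova()].
#' @param alpha Significance level for the letter display.
#' @return A list of class `tukey_result`: `pairs` (data frame of pairwise
#'   differences and adjusted p-values), `letters` (data frame: group, n,
#'   mean, sd, letter), `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  av <- one_way_anova(values, groups)
  gi <- av$groups
  gi <- gi[order(-gi$mean), , drop = FALSE]
  g <- nrow(gi)
  pairs <- utils::combn(seq_len(g), 2)
  pd <- data.frame(
    group1 = gi$group[pairs[1, ]], group2 = gi$group[pairs[2, ]],
    diff = gi$mean[pairs[1, ]] - gi$mean[pairs[2, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(av$ms_within / 2 *
               (1 / gi$n[pairs[1, ]] + 1 / gi$n[pairs[2, ]]))
  q_obs <- abs(pd$diff) / se
  pd$p_adj <- stats::ptukey(q_obs, nmeans = g, df = av$df_within,
                            lower.tail = FALSE)
  nonsig <- matrix(TRUE, g, g)
  for (k in seq_len(ncol(pairs))) {
    s <- pd$p_adj[k] < alpha
    nonsig[pairs[1, k], pairs[2, k]] <- !s
    nonsig[pairs[2, k], pairs[1, k]] <- !s
  }
  gi$letter <- unname(compact_letters(gi$group, nonsig))
  structure(list(pairs = pd, letters = gi, alpha = alpha,
                 anova = av), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD (alpha = %g):\n", x$alpha))
  print(x$letters, row.names = FALSE)
  invisible(x)
}

#' Treatment-effect tests for a table of spectra-derived traits
#'
#' Runs, per trait column: a Shapiro-Wilk normality check, a one-way ANOVA
#' of the treatment effect, and Tukey's post-hoc letters.
#'
#' @param traits Data frame of numeric trait columns (and optionally
#'   `sample_id`).
#' @param groups Treatment labels, one per row.
#' @param alpha Significance level.
#' @return A list with `anova` (data frame: trait, shapiro_p, f, p) and
#'   `tukey` (data frame: trait, group, n, mean, sd, letter).
#' @export
trait_treatment_tests <- function(traits, groups, alpha = 0.05) {
  traits <- as.data.frame(traits)
  traits$sample_id <- NULL
  anova_rows <- list(); tukey_rows <- list()
  for (tr in names(traits)) {
    v <- traits[[tr]]
    if (!is.numeric(v)) next
    sw <- tryCatch(shapiro_wilk(v)$p_value, error = function(e) NA_real_)
    tk <- tukey_hsd(v, groups, alpha = alpha)
    anova_rows[[tr]] <- data.frame(trait = tr, shapiro_p = sw,
                                   f_value = tk$anova$f_value,
                                   p_value = tk$anova$p_value,
                                   stringsAsFactors = FALSE)
    lt <- tk$letters
    lt$trait <- tr
    tukey_rows[[tr]] <- lt[, c("trait", "group", "n", "mean", "sd", "letter")]
  }
  list(anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
       tukey = do.call(rbind, c(tukey_rows, list(make.row.names = FALSE))))
}
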