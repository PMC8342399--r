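#' Shapiro-Wilk normality test with a large-sample policy
#'
#' Thin wrapper around [stats::shapiro.test()]. The test is undefined below
#' n = 3; above `max_n` observations a fixed-seed subsample of `max_n` is
#' tested (the base implementation is limited to 5000), which keeps the result
#' deterministic and documented. Constant input is reported as degenerate
#' rather than an error.
#'
#' @param values numeric vector, n >= 3.
#' @param max_n subsampling threshold (default 5000).
#' @param subsample_seed fixed seed for the subsample.
#' @return List: `W`, `p`, `n`, `n_used`, `degenerate`.
#' @export
shapiro_wilk <- function(values, max_n = 5000L, subsample_seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("Shapiro-Wilk requires at least 3 observations")
  if (diff(range(values)) == 0)
    return(list(W = NA_real_, p = NA_real_, n = n, n_used = n, degenerate = TRUE))
  used <- values
  if (n > max_n)
    used <- local_seed(subsample_seed, sample(values, max_n))
  ht <- shapiro.test(used)
  list(W = unname(ht$statistic), p = ht$p.value, n = n,
       n_used = length(used), degenerate = FALSE)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) stop("`groups` must be a list of numeric vectors")
  groups <- lapply(groups, function(g) {
    v <- as.numeric(g)
    if (any(!is.finite(v))) stop("group values must be finite")
    v
  })
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs n >= 2")
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA on a list of group samples:
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)`. The regular path
#' delegates to [stats::oneway.test()] with `var.equal = TRUE`; degenerate
#' inputs are resolved from the sums of squares directly (all groups
#' identical: `F = 0`, `p = 1`; zero within-group variance with unequal
#' means: `F = Inf`, `p = 0`, flagged).
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @return List: `F`, `df_between`, `df_within`, `p`, `flag` (`"ok"` or
#'   `"zero_within_variance"`).
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  ns <- vapply(groups, length, 0L)
  N <- sum(ns)
  means <- vapply(groups, mean, 0)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- k - 1L
  df_w <- N - k
  if (ssw <= 0) {
    if (ssb <= 0)
      return(list(F = 0, df_between = df_b, df_within = df_w, p = 1, flag = "ok"))
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0,
                flag = "zero_within_variance"))
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), ns), levels = names(groups))
  ht <- oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ht$statistic), df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]), p = ht$p.value, flag = "ok")
}

#' Tamhane's T2 post hoc pairwise comparisons
#'
#' All-pairs comparison for unequal variances: for each pair the Welch
#' statistic `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value, adjusted
#' for the `m = k(k-1)/2` comparisons with the Sidak-type correction
#' `1 - (1 - p)^m` (the classical T2 definition; a Bonferroni option is
#' provided). A pair with zero variance in both groups and equal means is
#' reported as `t = 0`, `p = 1`.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param alpha familywise significance level.
#' @param adjust `"sidak"` (default) or `"bonferroni"`.
#' @return A list of class `posthoc_table`: `pairs` (data frame `group1`,
#'   `group2`, `mean_difference`, `welch_t`, `welch_df`, `raw_p`,
#'   `adjusted_p`, `significant`), `letters` (per-group compact letter
#'   display), `alpha`, `adjust`.
#' @export
tamhane_t2 <- function(groups, alpha = 0.05, adjust = c("sidak", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- as_group_list(groups)
  k <- length(groups)
  labs <- names(groups)
  m <- k * (k - 1) / 2
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  vars <- vapply(groups, var, 0)

  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      vi <- vars[i] / ns[i]
      vj <- vars[j] / ns[j]
      diff_ <- means[i] - means[j]
      if (vi + vj <= 0) {
        tt <- if (diff_ == 0) 0 else Inf * sign(diff_)
        df <- NA_real_
        p <- if (diff_ == 0) 1 else 0
      } else {
        tt <- diff_ / sqrt(vi + vj)
        df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
        p <- 2 * pt(-abs(tt), df)
      }
      adj <- switch(adjust,
                    sidak = -expm1(m * log1p(-p)),
                    bonferroni = min(1, m * p))
      adj <- min(1, max(adj, p))
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = labs[i], group2 = labs[j], mean_difference = diff_,
        welch_t = tt, welch_df = df, raw_p = p, adjusted_p = adj,
        significant = adj < alpha)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 letters = letters_from_pairs(pairs, labs),
                 alpha = alpha, adjust = adjust),
            class = "posthoc_table")
}

#' @export
print.posthoc_table <- function(x, ...) {
  cat(sprintf("<posthoc_table> Tamhane T2 (%s adjustment), alpha = %g\n",
              x$adjust, x$alpha))
  print(x$pairs, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Compact letter display from pairwise significance
#'
#' Insert-and-absorb algorithm: groups share at least one letter if and only
#' if they are not significantly different in the pairwise table.
#'
#' @param pairs data frame with columns `group1`, `group2`, `significant`
#'   (complete all-pairs table).
#' @param groups optional character vector fixing group order.
#' @return Named character vector of letter strings, one per group.
#' @export
letters_from_pairs <- function(pairs, groups = NULL) {
  if (inherits(pairs, "posthoc_table")) pairs <- pairs$pairs
  groups <- groups %||% sort(unique(c(pairs$group1, pairs$group2)))
  cols <- list(groups)  # each column: set of groups sharing a letter
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    a <- sig$group1[r]; b <- sig$group2[r]
    newcols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) {
      for (j in seq_along(newcols)) {
        if (i != j && keep[j] &&
            all(newcols[[i]] %in% newcols[[j]]) &&
            (length(newcols[[i]]) < length(newcols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- newcols[keep]
    cols <- cols[vapply(cols, length, 0L) > 0]
  }
  out <- setNames(character(length(groups)), groups)
  for (ci in seq_along(cols)) {
    lt <- make_letter(ci)
    for (g in cols[[ci]]) out[g] <- paste0(out[g], lt)
  }
  out[out == ""] <- make_letter(length(cols) + seq_len(sum(out == "")))
  out
}

make_letter <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0) {
      s <- paste0(letters[(n - 1) %% 26 + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

#' @importFrom stats var setNames
NULL
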