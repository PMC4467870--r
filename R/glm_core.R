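# Factorial GLM core: Type-III F-tests with sum-to-zero contrasts (the
# convention of mainstream GLM software for unbalanced factorials),
# explained variance as unadjusted R-squared, and Bonferroni homogeneous
# subsets of factor levels.

# All interaction terms (hierarchical) over a set of factor names,
# main effects first, then two-way, then three-way.
#' @noRd
all_factorial_terms <- function(fnames) {
  unlist(lapply(seq_along(fnames), function(k) {
    apply(utils::combn(fnames, k), 2, paste, collapse = ":")
  }))
}

#' Fit a factorial GLM to one chemical parameter
#'
#' Least-squares fit of a full-factorial linear model with sum-to-zero level
#' coding; term significance by Type-III (marginal) F-tests; explained
#' variance as the model R-squared in percent. Terms whose design columns
#' are aliased in the given subset (common in small tree nodes of an
#' unbalanced design) are dropped with a warning and reported as absent.
#'
#' @param values numeric response vector.
#' @param factors data frame of categorical columns (each with >= 2 levels
#'   present in the subset).
#' @param terms character vector of term labels (factor names joined by
#'   `:`); defaults to the full factorial over `factors`.
#' @param parameter response name carried into the result.
#' @return A `glm_result`: list with `parameter`, `p_values` (named by
#'   term, absent terms dropped), `explained_variance_pct`, `n`,
#'   `terms_tested`, `dropped_terms`.
#' @export
fit_factorial_glm <- function(values, factors, terms = NULL, parameter = "y") {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  fnames <- names(factors)
  for (f in fnames) factors[[f]] <- droplevels(as.factor(factors[[f]]))
  if (any(vapply(factors, nlevels, integer(1)) < 2))
    stop("every included factor needs >= 2 levels in the subset")
  if (length(values) != nrow(factors)) stop("length mismatch")
  if (is.null(terms)) terms <- all_factorial_terms(fnames)
  # order hierarchically: by interaction order, then given order
  terms <- terms[order(lengths(strsplit(terms, ":", fixed = TRUE)))]

  dat <- cbind(data.frame(.y = values), factors)
  in_terms <- fnames[vapply(fnames, function(f)
    f %in% unlist(strsplit(terms, ":", fixed = TRUE)), logical(1))]
  contr <- setNames(lapply(in_terms, function(f) "contr.sum"), in_terms)
  form <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  mm <- model.matrix(form, dat, contrasts.arg = contr)
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(form), "term.labels")

  # greedy estimability: keep a term only if its full column block adds
  # exactly its own rank on top of what is already in the model
  keep <- logical(length(labels))
  cols <- mm[, asgn == 0, drop = FALSE]  # intercept
  rank0 <- qr(cols)$rank
  for (t in seq_along(labels)) {
    block <- mm[, asgn == t, drop = FALSE]
    cand <- cbind(cols, block)
    r <- qr(cand)$rank
    if (r - rank0 == ncol(block)) {
      keep[t] <- TRUE
      cols <- cand
      rank0 <- r
    }
  }
  dropped <- labels[!keep]
  if (length(dropped))
    warning("dropping inestimable term(s): ", paste(dropped, collapse = ", "))
  kept <- labels[keep]
  if (!length(kept)) stop("no estimable terms")
  n <- nrow(dat)
  if (n - rank0 <= 0)
    stop("zero residual degrees of freedom: model is saturated")

  form2 <- as.formula(paste(".y ~", paste(kept, collapse = " + ")))
  used <- fnames[vapply(fnames, function(f)
    any(f == unlist(strsplit(kept, ":", fixed = TRUE))), logical(1))]
  fit <- lm(form2, dat, contrasts = contr[used])
  an <- car::Anova(fit, type = 3)
  p <- setNames(an[kept, "Pr(>F)"], kept)
  r2 <- summary(fit)$r.squared

  structure(
    list(parameter = parameter, p_values = p,
         explained_variance_pct = 100 * r2, n = n,
         terms_tested = terms, dropped_terms = dropped),
    class = "glm_result"
  )
}

#' @export
print.glm_result <- function(x, ...) {
  cat("GLM result for", x$parameter, "(n =", x$n, ")\n")
  print(round(x$p_values, 4))
  cat(sprintf("explained variance: %.1f%%\n", x$explained_variance_pct))
  invisible(x)
}

#' Explained variance in percent
#'
#' `100 * (1 - SS_residual / SS_total)`, the full model R-squared on a
#' percentage scale.
#'
#' @param ss_residual residual sum of squares.
#' @param ss_total total sum of squares (> 0).
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' explained_variance(0, 10)   # 100
#' explained_variance(10, 10)  # 0
explained_variance <- function(ss_residual, ss_total) {
  if (ss_total <= 0) stop("constant response: total sum of squares is zero")
  if (ss_residual < 0 || ss_residual > ss_total)
    stop("ss_residual must lie in [0, ss_total]")
  100 * (1 - ss_residual / ss_total)
}

#' Bonferroni homogeneous subsets of factor levels
#'
#' All pairwise level comparisons by t statistics on the pooled within-group
#' mean square (one-way ANOVA MSE), with the Bonferroni family-wise
#' threshold `alpha / m` for `m = L(L-1)/2` pairs. Levels are ordered by
#' mean and grouped into maximal runs in which no pair differs
#' significantly; each maximal run is one homogeneous subset (compact
#' letter display), which makes the partition deterministic even when
#' pairwise non-significance is non-transitive.
#'
#' @param values numeric response.
#' @param factor_labels categorical vector (>= 2 levels present, each with
#'   >= 2 samples; a single-sample level signals the tree's stop condition
#'   and raises a `tomauth_singleton_level` error).
#' @param alpha family-wise significance level.
#' @return A `subset_partition`: levels in mean order with `means`, `sds`,
#'   `ns`, the `subsets` (list of level-name vectors with letter labels),
#'   the Bonferroni-adjusted `pairwise_p` matrix, `alpha`, `df`, `mse`.
#' @export
bonferroni_subsets <- function(values, factor_labels, alpha = 0.05) {
  g <- droplevels(as.factor(factor_labels))
  L <- nlevels(g)
  if (L < 2) stop("need >= 2 levels")
  ns <- tapply(values, g, length)
  if (any(ns < 2)) {
    bad <- names(ns)[ns < 2]
    stop(structure(
      list(message = paste0("level(s) with a single sample: ",
                            paste(bad, collapse = ", "),
                            " - mean values cannot be compared"),
           call = NULL),
      class = c("tomauth_singleton_level", "error", "condition")
    ))
  }
  means <- tapply(values, g, mean)
  vars <- tapply(values, g, var)
  N <- length(values)
  df <- N - L
  mse <- sum((ns - 1) * vars) / df

  ord <- order(means)
  lev <- levels(g)[ord]
  means <- means[ord]; vars <- vars[ord]; ns <- ns[ord]
  m <- L * (L - 1) / 2
  padj <- matrix(1, L, L, dimnames = list(lev, lev))
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      dmean <- means[j] - means[i]
      if (mse == 0) {
        p <- if (dmean == 0) 1 else 0
      } else {
        tt <- dmean / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
        p <- min(1, 2 * pt(-abs(tt), df) * m)
      }
      padj[i, j] <- padj[j, i] <- p
    }
  }
  nonsig <- padj >= alpha

  subsets <- list()
  for (i in seq_len(L)) {
    j <- i
    while (j < L && all(nonsig[i:(j + 1), i:(j + 1)])) j <- j + 1
    run <- lev[i:j]
    contained <- any(vapply(subsets, function(s) all(run %in% s), logical(1)))
    if (!contained) subsets[[length(subsets) + 1]] <- run
  }
  names(subsets) <- LETTERS[seq_along(subsets)]

  structure(
    list(factor = NULL, levels = lev, means = means,
         sds = sqrt(vars), ns = as.integer(ns), subsets = subsets,
         alpha = alpha, pairwise_p = padj, df = df, mse = mse),
    class = "subset_partition"
  )
}

#' @export
print.subset_partition <- function(x, ...) {
  cat("Bonferroni homogeneous subsets (alpha =", x$alpha, ")\n")
  for (nm in names(x$subsets))
    cat(" ", nm, ":", paste(x$subsets[[nm]], collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate GLM results in the survey's layout
#'
#' One row per parameter, one column per term p-value plus the explained
#' variance, mirroring the published characterization table.
#'
#' @param results list of `glm_result` objects.
#' @return Data frame.
#' @export
glm_results_table <- function(results) {
  terms <- unname(term_label_map())
  rows <- lapply(results, function(r) {
    p <- setNames(rep(NA_real_, length(terms)), terms)
    p[names(r$p_values)] <- r$p_values
    cbind(data.frame(parameter = r$parameter, n = r$n),
          as.data.frame(as.list(p), check.names = FALSE),
          data.frame(explained_variance = r$explained_variance_pct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
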