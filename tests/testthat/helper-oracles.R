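# Independent oracles and shared fixtures, built in code.

# Closed-form one-way ANOVA p-value from group means/variances.
oneway_p_oracle <- function(values, groups) {
  g <- as.factor(groups)
  k <- nlevels(g)
  n <- tapply(values, g, length)
  m <- tapply(values, g, mean)
  v <- tapply(values, g, var)
  grand <- mean(values)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * v)
  df1 <- k - 1
  df2 <- length(values) - k
  f <- (ssb / df1) / (ssw / df2)
  pf(f, df1, df2, lower.tail = FALSE)
}

# Closed-form balanced two-way ANOVA (a x b, r replicates): p-values for
# A, B and A:B from cell means only.
twoway_p_oracle <- function(values, fa, fb) {
  fa <- as.factor(fa); fb <- as.factor(fb)
  a <- nlevels(fa); b <- nlevels(fb)
  r <- length(values) / (a * b)
  stopifnot(r == round(r), r >= 2)
  grand <- mean(values)
  ma <- tapply(values, fa, mean)
  mb <- tapply(values, fb, mean)
  mab <- tapply(values, list(fa, fb), mean)
  ssa <- b * r * sum((ma - grand)^2)
  ssb <- a * r * sum((mb - grand)^2)
  ssab <- r * sum((mab - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + grand)^2)
  sse <- sum((values - mab[cbind(fa, fb)])^2)
  dfe <- a * b * (r - 1)
  p <- function(ss, df) pf((ss / df) / (sse / dfe), df, dfe, lower.tail = FALSE)
  c(A = p(ssa, a - 1), B = p(ssb, b - 1), AB = p(ssab, (a - 1) * (b - 1)))
}

# Central finite-difference gradient of the total network error with
# respect to every weight and bias.
finite_diff_gradient <- function(net, x, d, eps = 1e-5) {
  total_error <- function(nn) {
    y <- net_forward(nn, x)$output
    sum(vapply(seq_len(nrow(y)), function(i) sse_error(d[i, ], y[i, ]),
               numeric(1)))
  }
  num <- list()
  for (fld in c("W1", "b1", "W2", "b2")) {
    g <- net[[fld]]
    g[] <- NA_real_
    for (k in seq_along(net[[fld]])) {
      up <- net; up[[fld]][k] <- up[[fld]][k] + eps
      dn <- net; dn[[fld]][k] <- dn[[fld]][k] - eps
      g[k] <- (total_error(up) - total_error(dn)) / (2 * eps)
    }
    num[[fld]] <- g
  }
  num
}

# Balanced two-factor toy cohort (single harvest level, so only practice
# and cultivar are active): parameter A separates practices, B separates
# the two cultivars, C is pure noise.
make_toy_cohort <- function(seed = 42, reps = 6, b_effect = 3) {
  grid <- expand.grid(cultivar = c("Dorothy", "Boludo"),
                      practice = c("conventional", "organic", "no-soil"),
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  n <- nrow(grid)
  withr::with_seed(seed, {
    data.frame(
      sample_id = sprintf("T%03d", seq_len(n)),
      cultivar = factor(grid$cultivar, levels = factor_levels()$cultivar[1:2]),
      practice = factor(grid$practice, levels = factor_levels()$practice),
      harvest = factor("October", levels = factor_levels()$harvest),
      A = 5 * (grid$practice == "organic") - 5 * (grid$practice == "no-soil") +
        rnorm(n),
      B = b_effect * (grid$cultivar == "Boludo") + rnorm(n),
      C = rnorm(n),
      stringsAsFactors = FALSE
    )
  })
}

# Brute-force re-implementation of the tree rule for two-factor balanced
# data, written independently of the package internals: sequential ANOVA
# (equal to marginal tests under balance), candidate rule, pairwise
# Bonferroni grouping by graph components over mean-consecutive levels.
oracle_tree <- function(cohort, alpha = 0.05) {
  pars <- setdiff(names(cohort), c("sample_id", "cultivar", "practice", "harvest"))
  grow <- function(ids) {
    sub <- cohort[cohort$sample_id %in% ids, , drop = FALSE]
    fac <- c("cultivar", "practice", "harvest")
    fac <- fac[vapply(fac, function(f)
      length(unique(as.character(sub[[f]]))) >= 2, logical(1))]
    if (!length(fac)) return(list(ids = ids, leaf = TRUE))
    cand <- NULL
    for (p in pars) {
      ff <- lapply(sub[fac], function(f) droplevels(as.factor(f)))
      fit <- lm(sub[[p]] ~ ., data = as.data.frame(ff))
      an <- anova(fit)
      pv <- an[["Pr(>F)"]]
      names(pv) <- rownames(an)
      pv <- pv[names(pv) != "Residuals"]
      sig <- pv[pv < alpha]
      if (length(sig) == 1 && !grepl(":", names(sig))) {
        cand <- rbind(cand, data.frame(
          p = p, f = names(sig), pv = unname(sig),
          ev = summary(fit)$r.squared, stringsAsFactors = FALSE))
      }
    }
    if (is.null(cand)) return(list(ids = ids, leaf = TRUE))
    cand <- cand[order(cand$pv, -cand$ev), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      p <- cand$p[k]; f <- cand$f[k]
      g <- droplevels(as.factor(sub[[f]]))
      if (any(table(g) < 2)) return(list(ids = ids, leaf = TRUE))
      means <- sort(tapply(sub[[p]], g, mean))
      lev <- names(means)
      L <- length(lev)
      m <- L * (L - 1) / 2
      # pooled-SD pairwise t tests via stats::pairwise.t.test
      pw <- stats::pairwise.t.test(sub[[p]], g, p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)$p.value
      sig_pair <- function(l1, l2) {
        if (l1 %in% rownames(pw) && l2 %in% colnames(pw) && !is.na(pw[l1, l2]))
          return(pw[l1, l2] < alpha)
        pw[l2, l1] < alpha
      }
      # group mean-ordered levels: break wherever the full prefix run would
      # contain a significant pair
      groups <- list(lev[1])
      for (i in 2:L) {
        cur <- groups[[length(groups)]]
        if (any(vapply(cur, function(l) sig_pair(l, lev[i]), logical(1)))) {
          groups[[length(groups) + 1]] <- lev[i]
        } else {
          groups[[length(groups)]] <- c(cur, lev[i])
        }
      }
      if (length(groups) < 2) next
      kids <- lapply(groups, function(gl)
        grow(sub$sample_id[as.character(sub[[f]]) %in% gl]))
      return(list(ids = ids, leaf = FALSE, parameter = p, factor = f,
                  children = kids))
    }
    list(ids = ids, leaf = TRUE)
  }
  grow(cohort$sample_id)
}

# Printed model catalog of the motivating survey (Table-2-style), reduced
# 10-input models only (the survey's final proposal), in long form.
survey_catalog_reduced <- function() {
  rows <- list(
    list(1L, "ANN_3", "10-13-3", 200000L, "harvest", 87.4, 68.8, 85.6),
    list(1L, "ANN_3", "10-13-3", 200000L, "practice", 90.1, 68.8, 88.0),
    list(1L, "ANN_3", "10-13-3", 200000L, "cultivar", 82.8, 43.8, 79.0),
    list(2L, "ANN_3", "10-10-3", 200000L, "harvest", 88.7, 93.8, 89.2),
    list(2L, "ANN_3", "10-10-3", 200000L, "practice", 85.4, 56.3, 82.6),
    list(2L, "ANN_3", "10-10-3", 200000L, "cultivar", 64.9, 31.3, 61.7),
    list(3L, "ANN_3", "10-9-3", 400000L, "harvest", 68.2, 75.0, 68.9),
    list(3L, "ANN_3", "10-9-3", 400000L, "practice", 84.1, 93.8, 85.0),
    list(3L, "ANN_3", "10-9-3", 400000L, "cultivar", 46.4, 18.8, 43.7),
    list(4L, "ANN_4", "10-18-1", 1000L, "harvest", 98.7, 100.0, 98.8),
    list(5L, "ANN_4", "10-8-1", 64000L, "practice", 93.4, 81.3, 92.2),
    list(6L, "ANN_4", "10-18-1", 32000L, "cultivar", 61.6, 31.3, 58.7)
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(model_id = r[[1]], type = r[[2]], topology = r[[3]],
               cycles = r[[4]], output = r[[5]], aps_training = r[[6]],
               aps_validation = r[[7]], aps_average = r[[8]],
               stringsAsFactors = FALSE)))
}

# Shared expensive fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

default_cohort_fixture <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(default_config(seed = 1))
  .fixture_env$cohort
}

default_tree_fixture <- function() {
  if (is.null(.fixture_env$tree))
    .fixture_env$tree <- build_tree(default_cohort_fixture(), 0.05)
  .fixture_env$tree
}
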