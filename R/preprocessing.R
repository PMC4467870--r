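# Preprocessing: z-score standardization for the GLM-AID stage, min-max
# scaling and equal-spaced target codes for the neural networks, and the
# seeded 151/16 train/validation split.

#' Standardize the chemical parameters of a cohort
#'
#' Transforms every parameter column to `z = (x - mean) / sd` using the
#' sample standard deviation (n - 1 denominator), so each column has mean 0
#' and unit variance and every parameter enters the statistical analysis
#' with equal weight. The fitted per-column statistics are returned so
#' held-out data can be transformed with training statistics.
#'
#' @param cohort cohort data frame.
#' @param stats optional list with `center` and `scale` named vectors from a
#'   previous call, to transform new data with fitted statistics.
#' @return List with `table` (standardized cohort, provenance attribute
#'   `"standardized"`), `center` and `scale`.
#' @export
standardize <- function(cohort, stats = NULL) {
  pars <- parameter_names(cohort)
  if (is.null(stats)) {
    center <- vapply(cohort[pars], mean, numeric(1))
    scale <- vapply(cohort[pars], sd, numeric(1))
    zero <- names(scale)[scale == 0]
    if (length(zero))
      stop("standardization undefined: constant column(s) ",
           paste(zero, collapse = ", "))
  } else {
    center <- stats$center[pars]
    scale <- stats$scale[pars]
  }
  out <- cohort
  for (p in pars) out[[p]] <- (cohort[[p]] - center[p]) / scale[p]
  attr(out, "provenance") <- "standardized"
  list(table = out, center = center, scale = scale)
}

#' Invert a standardization
#'
#' @param standardized standardized cohort data frame.
#' @param stats list with `center` and `scale` (from [standardize()]).
#' @return Cohort on the original measurement scale.
#' @export
unstandardize <- function(standardized, stats) {
  pars <- parameter_names(standardized)
  out <- standardized
  for (p in pars) out[[p]] <- standardized[[p]] * stats$scale[p] + stats$center[p]
  attr(out, "provenance") <- "raw"
  out
}

#' Min-max scale parameter columns to [0, 1]
#'
#' Sigmoid-friendly input scaling for the neural networks, fitted on
#' training ranges; held-out data may fall slightly outside [0, 1].
#'
#' @param x data frame or matrix of numeric inputs.
#' @param ranges optional list with `min` and `max` named vectors from a
#'   previous call.
#' @return List with `x` (numeric matrix), `min`, `max`.
#' @export
scale_minmax <- function(x, ranges = NULL) {
  m <- as.matrix(x)
  if (is.null(ranges)) {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
    flat <- hi - lo == 0
    if (any(flat))
      stop("min-max scaling undefined: constant column(s) ",
           paste(colnames(m)[flat], collapse = ", "))
  } else {
    lo <- ranges$min[colnames(m)]
    hi <- ranges$max[colnames(m)]
  }
  list(x = sweep(sweep(m, 2, lo), 2, hi - lo, "/"), min = lo, max = hi)
}

#' Equal-spaced codes for a categorical target
#'
#' Each neural network output neuron carries one categorical variable, so a
#' K-level factor is coded on a single [0, 1] axis: level k (0-based) maps
#' to `k / (K - 1)`.
#'
#' @param labels factor or character vector.
#' @param levels ordered level names (K >= 2).
#' @return Numeric vector in [0, 1].
#' @export
#' @examples
#' encode_target(c("October", "April"), factor_levels()$harvest)  # 0, 1
encode_target <- function(labels, levels) {
  K <- length(levels)
  if (K < 2) stop("need at least 2 levels")
  idx <- match(as.character(labels), levels)
  if (anyNA(idx))
    stop("unknown label(s): ",
         paste(unique(as.character(labels)[is.na(idx)]), collapse = ", "))
  (idx - 1) / (K - 1)
}

#' Decode predicted values to the nearest target code
#'
#' Maps each predicted value to the nearest equal-spaced code; exact ties go
#' to the lower level index.
#'
#' @param values numeric vector of network outputs.
#' @param levels ordered level names (K >= 2).
#' @return Character vector of level names.
#' @export
decode_target <- function(values, levels) {
  K <- length(levels)
  if (K < 2) stop("need at least 2 levels")
  codes <- (seq_len(K) - 1) / (K - 1)
  idx <- vapply(values, function(v) {
    d <- abs(v - codes)
    which(d <= min(d) + 1e-12)[1]  # exact ties go to the lower index
  }, integer(1))
  levels[idx]
}

#' Split a cohort into training and validation sets
#'
#' Deterministic given the seed. In stratified mode (default) the validation
#' cases are spread over the harvest x practice cells as evenly as
#' possible: each of the 12 cells contributes `floor(n_validation / 12)`
#' cases plus at most one extra, the extras going to a seeded sample of
#' cells.
#'
#' @param cohort cohort data frame.
#' @param n_validation number of held-out samples (default 16, as in the
#'   151/16 protocol of the motivating survey).
#' @param seed split seed.
#' @param stratified logical.
#' @return List with `train`, `validation` (cohort subsets) and `spec`
#'   (train/validation sample ids, seed, stratified flag).
#' @export
split_train_validation <- function(cohort, n_validation = 16L, seed = 1L,
                                   stratified = TRUE) {
  n <- nrow(cohort)
  if (n_validation > n)
    stop("requested validation size (", n_validation, ") exceeds cohort (", n, ")")
  val_idx <- withr_seed(seed, {
    if (!stratified) {
      sample.int(n, n_validation)
    } else {
      cells <- interaction(cohort$harvest, cohort$practice, drop = FALSE)
      cell_names <- levels(cells)
      base <- n_validation %/% length(cell_names)
      extra <- n_validation %% length(cell_names)
      quota <- setNames(rep(base, length(cell_names)), cell_names)
      if (extra > 0) {
        bump <- sample(cell_names, extra)
        quota[bump] <- quota[bump] + 1
      }
      idx <- integer(0)
      for (cn in cell_names) {
        members <- which(cells == cn)
        take <- min(quota[cn], length(members))
        if (take > 0) idx <- c(idx, members[sample.int(length(members), take)])
      }
      # top up from the remainder if some cells were too small
      if (length(idx) < n_validation) {
        pool <- setdiff(seq_len(n), idx)
        idx <- c(idx, pool[sample.int(length(pool), n_validation - length(idx))])
      }
      idx
    }
  })
  val_idx <- sort(val_idx)
  spec <- list(train_ids = cohort$sample_id[-val_idx],
               validation_ids = cohort$sample_id[val_idx],
               seed = as.integer(seed), stratified = stratified)
  list(train = cohort[-val_idx, , drop = FALSE],
       validation = cohort[val_idx, , drop = FALSE],
       spec = spec)
}

#' Write a split as a two-column CSV
#'
#' @param split result of [split_train_validation()].
#' @param path file path.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    sample_id = c(split$spec$train_ids, split$spec$validation_ids),
    partition = c(rep("train", length(split$spec$train_ids)),
                  rep("validation", length(split$spec$validation_ids)))
  )
  write.csv(df[order(df$sample_id), ], path, row.names = FALSE)
  invisible(path)
}
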