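# Evaluation and orchestration: Average Percentage of Success (APS),
# weight-sum input importance, variable reduction, model selection by
# validation APS, and the end-to-end pipeline.

#' Average Percentage of Success
#'
#' `APS = 100 * successes / n`, the fraction of cases whose predicted
#' category matches the real one.
#'
#' @param successes number of correct classifications (0..n).
#' @param n number of cases (> 0).
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' aps(14, 16)  # 87.5
aps <- function(successes, n) {
  if (n <= 0) stop("n must be > 0")
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  100 * successes / n
}

#' Weight-sum input importance
#'
#' The importance of input neuron `n` is the sum of absolute values of all
#' weights between that input neuron and the intermediate neurons,
#' normalized to a percent share over inputs. Scaling all input-to-hidden
#' weights by a positive constant scales raw importances but leaves the
#' shares unchanged.
#'
#' @param net an `mlp_net` (trained or raw).
#' @return An `importance_table` data frame with columns `input`, `raw`,
#'   `percent`, ordered as the network's inputs.
#' @export
input_importance <- function(net) {
  raw <- rowSums(abs(net$W1))
  if (sum(raw) == 0) stop("all input-to-hidden weights are zero; shares undefined")
  nm <- rownames(net$W1) %||% paste0("x", seq_along(raw))
  structure(
    data.frame(input = nm, raw = unname(raw),
               percent = unname(100 * raw / sum(raw)),
               stringsAsFactors = FALSE),
    class = c("importance_table", "data.frame")
  )
}

#' Reduce the input variable set by averaged importance
#'
#' Averages the percent shares across the supplied importance tables and
#' keeps the top `k` variables; ties are broken by the variable order of
#' the first table (the survey's column order).
#'
#' @param importances list of `importance_table`s over the same variables.
#' @param k number of variables to keep (default 10).
#' @return Character vector of selected variable names, by descending
#'   average share.
#' @export
reduce_inputs <- function(importances, k = 10L) {
  if (!length(importances)) stop("need at least one importance table")
  vars <- importances[[1]]$input
  for (imp in importances) {
    if (!setequal(imp$input, vars))
      stop("importance tables cover different variable sets")
  }
  if (k > length(vars)) stop("k exceeds the number of inputs")
  shares <- vapply(importances,
                   function(imp) imp$percent[match(vars, imp$input)],
                   numeric(length(vars)))
  avg <- rowMeans(matrix(shares, nrow = length(vars)))
  ord <- order(-avg, seq_along(vars))
  vars[ord][seq_len(k)]
}

#' Evaluate a trained network on a train/validation split
#'
#' Computes, per output variable, the APS of the training and validation
#' phases and their pooled average (successes over both phases together;
#' a plain mean of the two phase values is available via
#' `average = "plain"`), plus per-class success percentages pooled over
#' both phases and the confusion tallies.
#'
#' @param net an `mlp_net`.
#' @param train_x,val_x input matrices (already scaled).
#' @param train_labels,val_labels data frames of true labels, one column
#'   per output variable (named as `codebooks`).
#' @param codebooks named list of ordered level vectors, one per output
#'   neuron, in output-column order.
#' @param average `"pooled"` (sample-weighted, default) or `"plain"`.
#' @return An `aps_report`: list with `aps` (data frame output x phase),
#'   `per_class` (data frame), `confusion` (named list of tables).
#' @export
evaluate_network <- function(net, train_x, train_labels, val_x, val_labels,
                             codebooks, average = c("pooled", "plain")) {
  average <- match.arg(average)
  outs <- names(codebooks)
  for (v in outs) {
    for (labs in list(train_labels[[v]], val_labels[[v]])) {
      bad <- setdiff(unique(as.character(labs)), codebooks[[v]])
      if (length(bad))
        stop("unseen ", v, " level(s): ", paste(bad, collapse = ", "))
    }
  }
  pred_tr <- predict_classes(net, train_x, codebooks)
  pred_va <- predict_classes(net, val_x, codebooks)

  aps_rows <- list(); cls_rows <- list(); confusion <- list()
  for (v in outs) {
    tr_true <- as.character(train_labels[[v]]); va_true <- as.character(val_labels[[v]])
    tr_ok <- pred_tr[[v]] == tr_true; va_ok <- pred_va[[v]] == va_true
    a_tr <- aps(sum(tr_ok), length(tr_ok))
    a_va <- aps(sum(va_ok), length(va_ok))
    a_av <- if (average == "pooled")
      aps(sum(tr_ok) + sum(va_ok), length(tr_ok) + length(va_ok))
    else (a_tr + a_va) / 2
    aps_rows[[v]] <- data.frame(output = v, training = a_tr,
                                validation = a_va, average = a_av,
                                stringsAsFactors = FALSE)
    all_true <- c(tr_true, va_true); all_ok <- c(tr_ok, va_ok)
    for (cl in codebooks[[v]]) {
      idx <- all_true == cl
      cls_rows[[paste(v, cl)]] <- data.frame(
        output = v, class = cl, n = sum(idx),
        success_pct = if (any(idx)) aps(sum(all_ok[idx]), sum(idx)) else NA_real_,
        stringsAsFactors = FALSE)
    }
    confusion[[v]] <- table(
      true = factor(all_true, levels = codebooks[[v]]),
      predicted = factor(c(pred_tr[[v]], pred_va[[v]]), levels = codebooks[[v]])
    )
  }
  structure(
    list(aps = do.call(rbind, c(aps_rows, list(make.row.names = FALSE))),
         per_class = do.call(rbind, c(cls_rows, list(make.row.names = FALSE))),
         confusion = confusion),
    class = "aps_report"
  )
}

#' Select the best model per output variable
#'
#' For each output variable, picks the catalog entry with the highest
#' validation APS; ties go to the higher pooled-average APS, then to the
#' smaller intermediate layer. The result does not depend on catalog row
#' order.
#'
#' @param catalog data frame in long form with columns `model_id`, `type`,
#'   `topology`, `cycles`, `output`, `aps_training`, `aps_validation`,
#'   `aps_average`.
#' @return Named list (one entry per output) of single catalog rows.
#' @export
select_models <- function(catalog) {
  if (!nrow(catalog)) stop("empty catalog")
  out <- list()
  for (v in unique(catalog$output)) {
    rows <- catalog[catalog$output == v & !is.na(catalog$aps_validation), ,
                    drop = FALSE]
    if (!nrow(rows)) stop("no catalog entries for output '", v, "'")
    hid <- vapply(rows$topology,
                  function(t) parse_topology(t)$n_intermediate, integer(1))
    ord <- order(-rows$aps_validation, -rows$aps_average, hid,
                 rows$model_id)
    out[[v]] <- rows[ord[1], , drop = FALSE]
  }
  out
}

#' Train with a plateau rule
#'
#' Trains in chunks of `chunk` cycles up to `max_cycles`, monitoring the
#' training-phase APS of one output variable; stops early when that APS
#' reaches 100 or has not improved for `patience` consecutive chunks.
#' Used for the long-cycle reduced-input models.
#'
#' @param net an `mlp_net`.
#' @param inputs,targets training matrices.
#' @param monitor function(net) returning the quantity to monitor.
#' @param chunk cycles per chunk.
#' @param max_cycles cycle budget.
#' @param patience chunks without improvement tolerated.
#' @param ... passed to [train_network()].
#' @return Trained net with attribute `"cycles_run"`.
#' @export
train_until_plateau <- function(net, inputs, targets, monitor,
                                chunk = 1000L, max_cycles = 400000L,
                                patience = 10L, ...) {
  best <- -Inf; stall <- 0L; run <- 0L
  dots <- list(...)
  seed0 <- dots$seed %||% net$seed
  dots$seed <- NULL
  while (run < max_cycles) {
    net <- do.call(train_network,
                   c(list(net, inputs, targets, cycles = chunk,
                          seed = (seed0 + run) %% 2147483647), dots))
    run <- run + chunk
    cur <- monitor(net)
    if (cur >= 100) break
    if (cur > best + 1e-9) { best <- cur; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break
  }
  attr(net, "cycles_run") <- run
  net
}

#' @noRd
catalog_rows <- function(model_id, type, topology, cycles, report) {
  a <- report$aps
  data.frame(model_id = model_id, type = type, topology = topology,
             cycles = cycles, output = a$output,
             aps_training = a$training, aps_validation = a$validation,
             aps_average = a$average, stringsAsFactors = FALSE)
}

# Train one model and evaluate it; internal workhorse for the sweep.
#' @noRd
fit_and_score <- function(topology, targets, train_x, train_labels,
                          val_x, val_labels, cycles, seed,
                          learning_rate = 0.6, momentum = 0.8,
                          plateau = FALSE, max_cycles = cycles) {
  lv <- factor_levels()
  codebooks <- lv[targets]
  ttr <- vapply(targets, function(v)
    encode_target(train_labels[[v]], codebooks[[v]]), numeric(nrow(train_x)))
  ttr <- matrix(ttr, nrow = nrow(train_x),
                dimnames = list(NULL, targets))
  net <- init_network(topology, seed)
  rownames(net$W1) <- colnames(train_x)
  if (plateau) {
    monitor <- function(nn) {
      pr <- predict_classes(nn, train_x, codebooks)
      mean(vapply(targets, function(v)
        aps(sum(pr[[v]] == as.character(train_labels[[v]])), nrow(train_x)),
        numeric(1)))
    }
    net <- train_until_plateau(net, train_x, ttr, monitor,
                               chunk = cycles, max_cycles = max_cycles,
                               learning_rate = learning_rate,
                               momentum = momentum, seed = seed)
  } else {
    net <- train_network(net, train_x, ttr, cycles,
                         learning_rate = learning_rate, momentum = momentum,
                         seed = seed)
  }
  report <- evaluate_network(net, train_x, train_labels[, targets, drop = FALSE],
                             val_x, val_labels[, targets, drop = FALSE],
                             codebooks)
  list(net = net, report = report, codebooks = codebooks)
}

#' Run the full characterization + authentication pipeline
#'
#' Simulate (or accept) a cohort, split it, build the GLM-AID tree, train
#' the 25-input networks, reduce to the top-10 inputs by averaged weight-sum
#' importance, train the reduced-input networks, select the best model per
#' output variable by validation APS, and write all artifacts. Fully seeded
#' and deterministic.
#'
#' @param config a `generator_config`, or `NULL` when `cohort` is given.
#' @param cohort optional pre-built cohort data frame.
#' @param out_dir output directory (created if needed).
#' @param seed master seed for split and training.
#' @param alpha GLM-AID significance level.
#' @param skip_ann build only the tree stage.
#' @param full_cycles training cycles for the 25-input models.
#' @param reduced_chunk,reduced_max plateau chunk size and cycle budget for
#'   the three-output reduced models.
#' @param single_cycles cycles for the single-output reduced models.
#' @return Invisible list with `cohort`, `tree`, `purity`, `catalog`,
#'   `selected`, `reduced_inputs`, `reports`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL,
                         out_dir = "results", seed = 1L, alpha = 0.05,
                         skip_ann = FALSE, full_cycles = 2000L,
                         reduced_chunk = 1000L, reduced_max = 50000L,
                         single_cycles = 1000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  cohort <- stage("simulate", {
    if (is.null(cohort)) cohort <- generate_cohort(config, seed)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    cohort
  })
  tree <- stage("characterize", {
    tree <- build_tree(cohort, alpha)
    tree_to_json(tree, file.path(out_dir, "tree.json"))
    writeLines(tree_to_dot(tree), file.path(out_dir, "tree.dot"))
    writeLines(tree_to_text(tree), file.path(out_dir, "tree.txt"))
    tree
  })
  purity <- tree_level1_purity(tree, cohort)
  if (skip_ann) {
    writeLines(sprintf("GLM-AID tree: %d nodes; level-1 harvest purity %.1f%%",
                       tree$n_nodes, purity),
               file.path(out_dir, "summary.txt"))
    return(invisible(list(cohort = cohort, tree = tree, purity = purity)))
  }

  res <- stage("authenticate", {
    split <- split_train_validation(cohort, seed = seed)
    write_split(split, file.path(out_dir, "split.csv"))
    pars <- parameter_names(cohort)
    sc <- scale_minmax(split$train[pars])
    train_x <- sc$x
    val_x <- scale_minmax(split$validation[pars], sc)$x
    targets3 <- c("harvest", "practice", "cultivar")

    catalog <- list(); reports <- list(); nets <- list(); model_id <- 0L
    add <- function(type, topology, cycles, fit) {
      model_id <<- model_id + 1L
      catalog[[model_id]] <<- catalog_rows(model_id, type, topology, cycles,
                                           fit$report)
      reports[[model_id]] <<- fit$report
      nets[[model_id]] <<- fit$net
      model_id
    }

    # 25-input models
    np <- length(pars)
    fit1 <- fit_and_score(sprintf("%d-41-3", np), targets3, train_x,
                          split$train, val_x, split$validation,
                          full_cycles, seed + 11)
    id1 <- add("ANN_1", sprintf("%d-41-3", np), full_cycles, fit1)
    imps <- list(input_importance(fit1$net))
    single_topo <- c(harvest = 13L, practice = 28L, cultivar = 44L)
    for (v in names(single_topo)) {
      f <- fit_and_score(sprintf("%d-%d-1", np, single_topo[[v]]), v, train_x,
                         split$train, val_x, split$validation,
                         full_cycles, seed + 20 + single_topo[[v]])
      add("ANN_2", sprintf("%d-%d-1", np, single_topo[[v]]), full_cycles, f)
      imps[[length(imps) + 1]] <- input_importance(f$net)
    }
    keep <- reduce_inputs(imps, 10L)
    utils::write.csv(
      data.frame(input = imps[[1]]$input,
                 mean_percent = rowMeans(vapply(imps, function(im)
                   im$percent[match(imps[[1]]$input, im$input)],
                   numeric(np)))),
      file.path(out_dir, "importance.csv"), row.names = FALSE)

    rtrain <- train_x[, keep, drop = FALSE]
    rval <- val_x[, keep, drop = FALSE]

    # reduced-input models
    for (topo_h in c(13L, 10L, 9L)) {
      f <- fit_and_score(sprintf("10-%d-3", topo_h), targets3, rtrain,
                         split$train, rval, split$validation,
                         reduced_chunk, seed + 40 + topo_h,
                         plateau = TRUE, max_cycles = reduced_max)
      add("ANN_3", sprintf("10-%d-3", topo_h),
          attr(f$net, "cycles_run") %||% reduced_max, f)
    }
    single4 <- c(harvest = 18L, practice = 8L, cultivar = 20L)
    for (v in names(single4)) {
      f <- fit_and_score(sprintf("10-%d-1", single4[[v]]), v, rtrain,
                         split$train, rval, split$validation,
                         single_cycles, seed + 60 + single4[[v]])
      id <- add("ANN_4", sprintf("10-%d-1", single4[[v]]), single_cycles, f)
      write_network(f$net, file.path(out_dir, sprintf("model_%02d.json", id)),
                    scaling = list(min = sc$min[keep], max = sc$max[keep]),
                    codebooks = f$codebooks)
    }
    catalog <- do.call(rbind, catalog)
    # the proposal restricts to reduced-input (10-variable) models
    selected <- select_models(catalog[catalog$type %in% c("ANN_3", "ANN_4"), ])
    utils::write.csv(catalog, file.path(out_dir, "aps.csv"), row.names = FALSE)
    per_class <- do.call(rbind, lapply(seq_along(reports), function(i)
      cbind(model_id = i, reports[[i]]$per_class)))
    utils::write.csv(per_class, file.path(out_dir, "per_class.csv"),
                     row.names = FALSE)
    list(catalog = catalog, selected = selected, reduced_inputs = keep,
         reports = reports, split = split)
  })

  sel_lines <- vapply(names(res$selected), function(v) {
    r <- res$selected[[v]]
    sprintf("%s: %s %s (validation APS %.1f%%)", v, r$type, r$topology,
            round_half_up(r$aps_validation, 1))
  }, character(1))
  writeLines(c(
    sprintf("GLM-AID tree: %d nodes; level-1 harvest purity %.1f%%",
            tree$n_nodes, purity),
    sprintf("reduced inputs: %s", paste(res$reduced_inputs, collapse = ", ")),
    "selected models:", paste(" ", sel_lines)),
    file.path(out_dir, "summary.txt"))

  invisible(c(list(cohort = cohort, tree = tree, purity = purity), res))
}
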