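# GLM-AID: recursive characterization tree. At each node a factorial GLM is
# fitted for every chemical parameter over the factors still active in the
# node; the parameter that depends on exactly one factor (a single
# significant main effect) with the lowest p-value (ties broken by explained
# variance) defines the split, carried out by Bonferroni homogeneous subsets
# of that factor's levels. Recursion stops when no such predictor exists,
# when subsets cannot be formed, or when factors are exhausted.

#' Select the split predictor from a set of GLM results
#'
#' Candidates are the parameters whose significant terms (p < alpha) are
#' exactly one single-factor main effect. They are ranked by that term's
#' p-value (ascending), ties broken by explained variance (descending),
#' then by input order. Returns `NULL` when no candidate exists, which the
#' tree interprets as a stop.
#'
#' @param results list of `glm_result` objects computed on the same subset.
#' @param alpha significance level.
#' @return A `predictor_selection` (list with `parameter`, `factor`,
#'   `p_value`, `explained_variance_pct`, `alternates` data frame of all
#'   ranked candidates) or `NULL`.
#' @export
#' @examples
#' sel <- select_predictor(reference_glm_results(), alpha = 0.05)
#' sel$parameter                 # "p-Coumaric acid"
#' sel$explained_variance_pct    # 73.6
select_predictor <- function(results, alpha = 0.05) {
  cand <- list()
  for (k in seq_along(results)) {
    r <- results[[k]]
    sig <- r$p_values[r$p_values < alpha]
    if (length(sig) != 1) next
    term <- names(sig)
    if (grepl(":", term, fixed = TRUE)) next
    cand[[length(cand) + 1]] <- data.frame(
      parameter = r$parameter, factor = term, p_value = unname(sig),
      explained_variance_pct = r$explained_variance_pct,
      input_order = k, stringsAsFactors = FALSE
    )
  }
  if (!length(cand)) return(NULL)
  tab <- do.call(rbind, cand)
  tab <- tab[order(tab$p_value, -tab$explained_variance_pct, tab$input_order), ,
             drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(parameter = tab$parameter[1], factor = tab$factor[1],
         p_value = tab$p_value[1],
         explained_variance_pct = tab$explained_variance_pct[1],
         alternates = tab),
    class = "predictor_selection"
  )
}

#' @noRd
new_aid_node <- function(id, sample_ids, levels, depth, path_factors) {
  list(id = id, sample_ids = sample_ids, levels = levels, depth = depth,
       path_factors = path_factors, selection = NULL, partition = NULL,
       stop_reason = NULL, children = list())
}

#' Attempt to split one tree node
#'
#' Fits the factorial GLM (restricted to the node's active factors) for
#' every chemical parameter, selects a predictor, and partitions the node
#' by Bonferroni subsets of the selected factor. If the partition collapses
#' to a single subset the next-ranked candidate is tried. A leaf records a
#' machine-readable `stop_reason`: `no-candidate`, `no-significance`,
#' `singleton-level`, `factors-exhausted` or `no-split`.
#'
#' @param node an AID node (internal structure; see [build_tree()]).
#' @param cohort raw-scale cohort (for reported node means).
#' @param zcohort globally standardized cohort used for fitting.
#' @param alpha significance level.
#' @return The node, with either `children` populated or `stop_reason` set.
#' @export
split_node <- function(node, cohort, zcohort, alpha = 0.05) {
  sub <- cohort[match(node$sample_ids, cohort$sample_id), , drop = FALSE]
  zsub <- zcohort[match(node$sample_ids, zcohort$sample_id), , drop = FALSE]
  active <- character(0)
  for (f in FACTOR_NAMES) {
    if (length(unique(as.character(sub[[f]]))) >= 2) active <- c(active, f)
  }
  if (!length(active)) {
    node$stop_reason <- "factors-exhausted"
    return(node)
  }
  pars <- parameter_names(cohort)
  results <- list()
  for (p in pars) {
    r <- tryCatch(
      suppressWarnings(fit_factorial_glm(zsub[[p]], zsub[active],
                                         parameter = p)),
      error = function(e) NULL
    )
    if (!is.null(r)) results[[length(results) + 1]] <- r
  }
  if (!length(results)) {
    node$stop_reason <- "no-significance"
    return(node)
  }
  sel <- select_predictor(results, alpha)
  if (is.null(sel)) {
    node$stop_reason <- "no-candidate"
    return(node)
  }
  for (k in seq_len(nrow(sel$alternates))) {
    cand <- sel$alternates[k, ]
    part <- tryCatch(
      bonferroni_subsets(zsub[[cand$parameter]], sub[[cand$factor]], alpha),
      tomauth_singleton_level = function(e) "singleton-level"
    )
    if (identical(part, "singleton-level")) {
      node$stop_reason <- "singleton-level"
      return(node)
    }
    if (length(part$subsets) < 2) next  # try next-ranked candidate
    part$factor <- cand$factor
    # letter-display subsets may overlap (non-transitive pairwise tests);
    # children need a partition, so each level joins the first (lowest-mean)
    # subset that contains it
    assigned <- character(0)
    groups <- list()
    for (s in part$subsets) {
      g <- setdiff(s, assigned)
      if (length(g)) {
        groups[[length(groups) + 1]] <- g
        assigned <- c(assigned, g)
      }
    }
    names(groups) <- LETTERS[seq_along(groups)]
    part$groups <- groups
    raw <- sub[[cand$parameter]]
    part$level_stats <- data.frame(
      level = part$levels,
      n = part$ns,
      mean = as.numeric(tapply(raw, factor(as.character(sub[[cand$factor]]),
                                           levels = part$levels), mean)),
      sd = as.numeric(tapply(raw, factor(as.character(sub[[cand$factor]]),
                                         levels = part$levels), sd)),
      stringsAsFactors = FALSE
    )
    node$selection <- structure(
      list(parameter = cand$parameter, factor = cand$factor,
           p_value = cand$p_value,
           explained_variance_pct = cand$explained_variance_pct,
           alternates = sel$alternates),
      class = "predictor_selection"
    )
    node$partition <- part
    return(node)
  }
  node$stop_reason <- "no-split"
  node
}

#' Build the GLM-AID characterization tree
#'
#' Parameters are standardized once, globally, before any fitting (F-tests
#' are unaffected by the affine transform; node summaries report raw-scale
#' means and SDs). Nodes are processed breadth-first and numbered in
#' creation order. A factor can be re-split further down a path while more
#' than one of its levels remains in the node.
#'
#' @param cohort raw cohort data frame.
#' @param alpha significance level for both predictor selection and the
#'   Bonferroni subsets.
#' @return An `aid_tree`: list with `root` (recursive node structure),
#'   `alpha`, `standardization` (per-column center/scale), `depth` (maximum
#'   number of distinct factors split along any path), `n_samples`,
#'   `n_nodes`.
#' @export
build_tree <- function(cohort, alpha = 0.05) {
  if (!nrow(cohort)) stop("empty cohort")
  std <- standardize(cohort)
  lv <- lapply(cohort[FACTOR_NAMES],
               function(f) unique(as.character(f)))
  root <- new_aid_node(1L, cohort$sample_id, lv, 0L, character(0))

  nodes <- list(root)   # flat store; children linked by id
  children_of <- list()
  queue <- 1L
  next_id <- 2L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    node <- split_node(nodes[[i]], cohort, std$table, alpha)
    if (is.null(node$partition)) {
      nodes[[i]] <- node
      next
    }
    kid_ids <- integer(0)
    for (s in node$partition$groups) {
      sub_ids <- node$sample_ids[
        as.character(cohort[[node$partition$factor]][
          match(node$sample_ids, cohort$sample_id)]) %in% s]
      child_lv <- node$levels
      child_lv[[node$partition$factor]] <- s
      child <- new_aid_node(next_id, sub_ids, child_lv, node$depth + 1L,
                            union(node$path_factors, node$partition$factor))
      nodes[[next_id]] <- child
      kid_ids <- c(kid_ids, next_id)
      queue <- c(queue, next_id)
      next_id <- next_id + 1L
    }
    children_of[[as.character(node$id)]] <- kid_ids
    nodes[[i]] <- node
  }

  assemble <- function(id) {
    node <- nodes[[id]]
    kids <- children_of[[as.character(id)]]
    node$children <- lapply(kids, assemble)
    node
  }
  root <- assemble(1L)
  depth <- max(vapply(nodes, function(nd) length(nd$path_factors), integer(1)))
  structure(
    list(root = root, alpha = alpha,
         standardization = list(center = std$center, scale = std$scale),
         depth = depth, n_samples = nrow(cohort), n_nodes = next_id - 1L),
    class = "aid_tree"
  )
}

#' Flatten a tree into a list of nodes
#'
#' @param tree an `aid_tree`.
#' @return List of nodes in depth-first order.
#' @export
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' Purity of the first-level partition with respect to a factor
#'
#' Percentage of samples lying in a first-level node all of whose members
#' share that sample's level of `factor` (100 when the first split isolates
#' each level of the factor).
#'
#' @param tree an `aid_tree`.
#' @param cohort the cohort the tree was built on.
#' @param factor factor name (default `"harvest"`).
#' @return Percentage in [0, 100].
#' @export
tree_level1_purity <- function(tree, cohort, factor = "harvest") {
  kids <- tree$root$children
  if (!length(kids)) return(0)
  pure <- 0
  for (ch in kids) {
    labs <- cohort[[factor]][match(ch$sample_ids, cohort$sample_id)]
    if (length(unique(as.character(labs))) == 1) pure <- pure + length(ch$sample_ids)
  }
  100 * pure / tree$n_samples
}

# ---- rendering ----------------------------------------------------------

#' @noRd
node_to_list <- function(node) {
  out <- list(
    id = node$id, sample_ids = node$sample_ids, levels = node$levels,
    depth = node$depth, path_factors = node$path_factors
  )
  if (!is.null(node$selection)) {
    out$selection <- list(
      parameter = node$selection$parameter, factor = node$selection$factor,
      p_value = node$selection$p_value,
      explained_variance_pct = node$selection$explained_variance_pct
    )
  }
  if (!is.null(node$partition)) {
    out$partition <- list(
      factor = node$partition$factor,
      subsets = node$partition$subsets,
      groups = node$partition$groups,
      level_stats = node$partition$level_stats,
      alpha = node$partition$alpha
    )
  }
  if (!is.null(node$stop_reason)) out$stop_reason <- node$stop_reason
  out$children <- lapply(node$children, node_to_list)
  out
}

#' Serialize a tree to JSON
#'
#' The JSON form (schema version 1) round-trips losslessly through
#' [tree_from_json()].
#'
#' @param tree an `aid_tree`.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(
    schema = "tomauth-aid-tree/1", alpha = tree$alpha,
    standardization = list(center = as.list(tree$standardization$center),
                           scale = as.list(tree$standardization$scale)),
    depth = tree$depth, n_samples = tree$n_samples, n_nodes = tree$n_nodes,
    root = node_to_list(tree$root)
  )
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tree_to_json
#' @param json a path to a JSON file or a JSON string.
#' @export
tree_from_json <- function(json) {
  obj2 <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(obj2$schema, "tomauth-aid-tree/1"))
    stop("unrecognized tree schema")
  rebuild2 <- function(nd) {
    node <- new_aid_node(
      as.integer(nd$id),
      vapply(nd$sample_ids, as.character, character(1)),
      lapply(nd$levels, function(l) vapply(l, as.character, character(1))),
      as.integer(nd$depth),
      vapply(nd$path_factors, as.character, character(1))
    )
    if (!is.null(nd$selection))
      node$selection <- structure(
        list(parameter = nd$selection$parameter, factor = nd$selection$factor,
             p_value = as.numeric(nd$selection$p_value),
             explained_variance_pct = as.numeric(nd$selection$explained_variance_pct)),
        class = "predictor_selection")
    if (!is.null(nd$partition)) {
      rows <- nd$partition$level_stats  # serialized row-wise by jsonlite
      node$partition <- list(
        factor = nd$partition$factor,
        subsets = lapply(nd$partition$subsets,
                         function(s) vapply(s, as.character, character(1))),
        groups = lapply(nd$partition$groups,
                        function(s) vapply(s, as.character, character(1))),
        level_stats = data.frame(
          level = vapply(rows, function(r) as.character(r$level), character(1)),
          n = vapply(rows, function(r) as.integer(r$n), integer(1)),
          mean = vapply(rows, function(r) as.numeric(r$mean), numeric(1)),
          sd = vapply(rows, function(r) as.numeric(r$sd %||% NA_real_),
                      numeric(1)),
          stringsAsFactors = FALSE
        ),
        alpha = as.numeric(nd$partition$alpha)
      )
    }
    if (!is.null(nd$stop_reason)) node$stop_reason <- nd$stop_reason
    node$children <- lapply(nd$children, rebuild2)
    node
  }
  o <- obj2
  structure(
    list(root = rebuild2(o$root), alpha = as.numeric(o$alpha),
         standardization = list(
           center = unlist(o$standardization$center),
           scale = unlist(o$standardization$scale)),
         depth = as.integer(o$depth), n_samples = as.integer(o$n_samples),
         n_nodes = as.integer(o$n_nodes)),
    class = "aid_tree"
  )
}

#' Render a tree in DOT format
#'
#' Nodes are labelled with the split parameter and factor (internal nodes)
#' or the subset levels with the parent split parameter's mean and SD
#' (children), consumable by standard graph renderers.
#'
#' @param tree an `aid_tree`.
#' @return A DOT string.
#' @export
tree_to_dot <- function(tree) {
  lines <- c("digraph aid_tree {", "  node [shape=box, fontsize=10];")
  walk <- function(node, parent_part = NULL, subset_name = NULL) {
    label <- sprintf("node %d\\nn = %d", node$id, length(node$sample_ids))
    if (!is.null(parent_part) && !is.null(subset_name)) {
      levs <- parent_part$groups[[subset_name]]
      st <- parent_part$level_stats
      st <- st[st$level %in% levs, , drop = FALSE]
      mu <- sum(st$mean * st$n) / sum(st$n)
      label <- sprintf("%s\\n%s = %s\\n%.3g ± %.3g", label,
                       parent_part$factor, paste(levs, collapse = ", "),
                       mu, mean(st$sd))
    }
    if (!is.null(node$selection)) {
      label <- sprintf("%s\\nsplit: %s (%s)", label,
                       node$selection$parameter, node$selection$factor)
    } else if (!is.null(node$stop_reason)) {
      label <- sprintf("%s\\nleaf: %s", label, node$stop_reason)
    }
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", node$id, label))
    if (length(node$children)) {
      sn <- names(node$partition$groups)
      for (k in seq_along(node$children)) {
        ch <- node$children[[k]]
        lines <<- c(lines, sprintf("  n%d -> n%d;", node$id, ch$id))
        walk(ch, node$partition, sn[k])
      }
    }
  }
  walk(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}

#' Render a tree as an indented text outline
#'
#' @param tree an `aid_tree`.
#' @return Character string.
#' @export
tree_to_text <- function(tree) {
  out <- character(0)
  walk <- function(node, indent) {
    head <- sprintf("%snode %d (n=%d)", strrep("  ", indent), node$id,
                    length(node$sample_ids))
    if (!is.null(node$selection)) {
      head <- sprintf("%s split on %s by %s (p=%.3g, EV=%.1f%%)", head,
                      node$selection$factor, node$selection$parameter,
                      node$selection$p_value,
                      node$selection$explained_variance_pct)
    } else if (!is.null(node$stop_reason)) {
      head <- sprintf("%s [%s]", head, node$stop_reason)
    }
    out <<- c(out, head)
    for (ch in node$children) walk(ch, indent + 1)
  }
  walk(tree$root, 0)
  paste(out, collapse = "\n")
}

#' @export
print.aid_tree <- function(x, ...) {
  cat("GLM-AID tree:", x$n_nodes, "nodes,", x$n_samples, "samples, depth",
      x$depth, "\n")
  cat(tree_to_text(x), "\n")
  invisible(x)
}
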