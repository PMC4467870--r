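# GLM-AID tree: predictor selection rule, node splitting, full-tree
# structure, and rendering.

test_that("predictor selection on the survey matrix picks p-coumaric acid", {
  sel <- select_predictor(reference_glm_results(), alpha = 0.05)
  expect_identical(sel$parameter, "p-Coumaric acid")
  expect_identical(sel$factor, "harvest")
  expect_equal(sel$explained_variance_pct, 73.6)
  # the tie at printed p = 0.000 is with caffeic acid and lycopene,
  # broken by explained variance
  top3 <- sel$alternates$parameter[1:3]
  expect_setequal(top3, c("p-Coumaric acid", "Caffeic acid", "Lycopene"))
  expect_identical(top3[1], "p-Coumaric acid")
})

test_that("with the strongest rows removed, fumaric acid beats oxalic acid", {
  sel <- select_predictor(
    reference_glm_results(drop = c("p-Coumaric acid", "Caffeic acid",
                                   "Lycopene")), alpha = 0.05)
  expect_identical(sel$parameter, "Fumaric acid")
  expect_identical(sel$factor, "harvest")
  expect_equal(sel$explained_variance_pct, 36.0)
  expect_equal(sel$p_value, 0.009)
})

test_that("parameters depending on several terms are never candidates", {
  fake <- function(name, p) {
    structure(list(parameter = name, p_values = p,
                   explained_variance_pct = 50, n = 60,
                   terms_tested = names(p)), class = "glm_result")
  }
  rs <- list(
    fake("two-mains", c(harvest = 0.001, practice = 0.002)),
    fake("interaction-only", c(`cultivar:practice` = 0.0001)),
    fake("nothing", c(harvest = 0.5))
  )
  expect_null(select_predictor(rs, 0.05))
  rs[[4]] <- fake("good", c(practice = 0.01))
  expect_identical(select_predictor(rs, 0.05)$parameter, "good")
})

test_that("split_node selects a planted single-factor effect", {
  toy <- make_toy_cohort(seed = 1)
  std <- standardize(toy)
  node <- tomauth:::new_aid_node(1L, toy$sample_id,
                                 lapply(toy[c("cultivar", "practice", "harvest")],
                                        function(f) unique(as.character(f))),
                                 0L, character(0))
  out <- split_node(node, toy, std$table, 0.05)
  expect_identical(out$selection$parameter, "A")
  expect_identical(out$selection$factor, "practice")
  expect_gt(length(out$partition$subsets), 1)
})

test_that("a pure-noise node becomes a no-candidate leaf", {
  toy <- make_toy_cohort(seed = 2)
  withr::with_seed(902, {
    toy$A <- rnorm(nrow(toy)); toy$B <- rnorm(nrow(toy)); toy$C <- rnorm(nrow(toy))
  })
  tree <- build_tree(toy, 0.05)
  expect_length(tree$root$children, 0)
  expect_identical(tree$root$stop_reason, "no-candidate")
  expect_equal(tree$n_nodes, 1L)
})

test_that("the tree equals an independent brute-force implementation on a toy", {
  toy <- make_toy_cohort(seed = 8)
  tree <- build_tree(toy, 0.05)
  oracle <- oracle_tree(toy, 0.05)
  compare <- function(node, onode) {
    expect_setequal(node$sample_ids, onode$ids)
    if (isTRUE(onode$leaf)) {
      expect_length(node$children, 0)
      return(invisible())
    }
    expect_identical(node$selection$parameter, onode$parameter)
    expect_identical(node$selection$factor, onode$factor)
    expect_length(node$children, length(onode$children))
    # match children by sample sets
    osets <- lapply(onode$children, function(k) sort(k$ids))
    for (ch in node$children) {
      hit <- which(vapply(osets, function(s)
        identical(s, sort(ch$sample_ids)), logical(1)))
      expect_length(hit, 1)
      compare(ch, onode$children[[hit]])
    }
  }
  compare(tree$root, oracle)
})

test_that("the default-cohort tree separates harvest dates completely", {
  coh <- default_cohort_fixture()
  tree <- default_tree_fixture()
  expect_identical(tree$root$selection$factor, "harvest")
  # the split parameter is one of the harvest-only survey parameters
  expect_true(tree$root$selection$parameter %in%
                c("p-Coumaric acid", "Caffeic acid", "Lycopene", "Fumaric acid"))
  expect_length(tree$root$children, 4)
  expect_equal(tree_level1_purity(tree, coh), 100)
  expect_lte(tree$depth, 3)
})

test_that("every split conserves samples and is significant", {
  tree <- default_tree_fixture()
  for (node in tree_nodes(tree)) {
    if (length(node$children)) {
      kids <- unlist(lapply(node$children, `[[`, "sample_ids"))
      expect_setequal(kids, node$sample_ids)
      expect_equal(length(kids), length(node$sample_ids))  # no duplication
      expect_lt(node$selection$p_value, tree$alpha)
      expect_null(node$stop_reason)
    } else {
      expect_true(!is.null(node$stop_reason) || is.null(node$partition))
      if (!is.null(node$stop_reason))
        expect_true(node$stop_reason %in%
                      c("no-candidate", "no-significance", "singleton-level",
                        "factors-exhausted", "no-split"))
    }
  }
})

test_that("a single-month cohort roots its split on a remaining factor", {
  coh <- default_cohort_fixture()
  oct <- coh[coh$harvest == "October", , drop = FALSE]
  tree <- build_tree(oct, 0.05)
  expect_true(tree$root$selection$factor %in% c("practice", "cultivar"))
})

test_that("tree JSON round-trips losslessly", {
  tree <- default_tree_fixture()
  json <- tree_to_json(tree)
  back <- tree_from_json(json)
  expect_equal(back$alpha, tree$alpha)
  expect_equal(back$n_nodes, tree$n_nodes)
  expect_equal(back$standardization$center, tree$standardization$center)
  a <- tree_nodes(tree); b <- tree_nodes(back)
  expect_length(b, length(a))
  for (k in seq_along(a)) {
    expect_identical(b[[k]]$id, a[[k]]$id)
    expect_identical(b[[k]]$sample_ids, a[[k]]$sample_ids)
    expect_identical(b[[k]]$stop_reason, a[[k]]$stop_reason)
    if (!is.null(a[[k]]$selection)) {
      expect_identical(b[[k]]$selection$parameter, a[[k]]$selection$parameter)
      expect_equal(b[[k]]$selection$p_value, a[[k]]$selection$p_value)
      expect_equal(b[[k]]$partition$level_stats$mean,
                   a[[k]]$partition$level_stats$mean)
    }
  }
  # file round trip too
  f <- tempfile(fileext = ".json")
  tree_to_json(tree, f)
  expect_equal(tree_from_json(f)$n_nodes, tree$n_nodes)
})

test_that("DOT and text renderings reflect the tree structure", {
  tree <- default_tree_fixture()
  dot <- tree_to_dot(tree)
  expect_match(dot, "digraph aid_tree")
  for (ch in tree$root$children)
    expect_match(dot, sprintf("n1 -> n%d;", ch$id))
  txt <- tree_to_text(tree)
  expect_match(txt, "node 1 \\(n=167\\)")

  toy <- make_toy_cohort(seed = 3)
  withr::with_seed(903, {
    toy$A <- rnorm(nrow(toy)); toy$B <- rnorm(nrow(toy)); toy$C <- rnorm(nrow(toy))
  })
  single <- build_tree(toy, 0.05)
  expect_length(strsplit(tree_to_text(single), "\n")[[1]], 1)
})

test_that("an empty cohort is rejected", {
  coh <- default_cohort_fixture()
  expect_error(build_tree(coh[0, ]), "empty")
})
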