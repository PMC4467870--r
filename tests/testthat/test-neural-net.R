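# Sigmoid MLP: topology notation, initialization, forward/error math,
# gradient correctness, online training, decoding, serialization.

test_that("topology strings parse and re-render identically", {
  for (txt in c("25-41-3", "10-18-1", "2-2-1")) {
    topo <- parse_topology(txt)
    expect_identical(format_topology(topo), txt)
  }
  t1 <- parse_topology("25-41-3")
  expect_equal(c(t1$n_input, t1$n_intermediate, t1$n_output), c(25, 41, 3))
  expect_error(parse_topology("10-0-3"), "positive")
  expect_error(parse_topology("10-3"), "malformed")
  expect_error(parse_topology("a-b-c"), "malformed")
})

test_that("initialization is seeded, bounded, and correctly shaped", {
  n1 <- init_network("2-2-1", seed = 9)
  n2 <- init_network("2-2-1", seed = 9)
  expect_identical(n1, n2)
  n3 <- init_network("2-2-1", seed = 10)
  expect_false(identical(n1$W1, n3$W1))
  # 2x2 + 2 + 2x1 + 1 = 9 free values
  expect_equal(length(n1$W1) + length(n1$b1) + length(n1$W2) + length(n1$b2), 9)
  big <- init_network("25-41-3", seed = 1)
  w <- c(big$W1, big$b1, big$W2, big$b2)
  expect_true(all(w >= -0.5 & w <= 0.5))
  expect_equal(dim(big$W1), c(25, 41))
  expect_equal(dim(big$W2), c(41, 3))
})

test_that("forward propagation follows the propagation/activation equations", {
  z <- init_network("3-4-2", seed = 1)
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  out <- net_forward(z, c(0.3, 0.9, 0.1))
  expect_equal(as.numeric(out$output), c(0.5, 0.5))  # sigma(0) = 1/2

  one <- init_network("1-1-1", seed = 1)
  one$W1[] <- 1; one$b1[] <- 0; one$W2[] <- 1; one$b2[] <- 0
  fw <- net_forward(one, 0)
  expect_equal(as.numeric(fw$hidden), 0.5)
  expect_equal(as.numeric(fw$output), 1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(as.numeric(fw$output), 0.62246, tolerance = 1e-4)

  r <- init_network("5-7-2", seed = 3)
  y <- net_forward(r, matrix(runif(50), 10, 5))$output
  expect_true(all(y > 0 & y < 1))
  expect_error(net_forward(r, c(1, 2)), "n_input")
})

test_that("the network error is half the squared deviation", {
  expect_equal(sse_error(c(1), c(1)), 0)
  expect_equal(sse_error(c(1), c(0)), 0.5)
  expect_equal(sse_error(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_error(sse_error(c(1, 0), c(1)), "length")
})

test_that("analytic gradients match central finite differences", {
  worst <- 0
  for (s in 1:50) {
    net <- init_network("3-4-2", seed = s)
    x <- withr::with_seed(1000 + s, matrix(runif(6), 2, 3))
    d <- withr::with_seed(2000 + s, matrix(runif(4), 2, 2))
    ana <- net_gradient(net, x, d)
    num <- finite_diff_gradient(net, x, d)
    for (fld in c("W1", "b1", "W2", "b2"))
      worst <- max(worst, max(abs(ana[[fld]] - num[[fld]])))
  }
  expect_lt(worst, 1e-6)
})

test_that("one compiled online step equals the analytic gradient step", {
  net <- init_network("4-3-2", seed = 5)
  x <- matrix(runif(4), 1, 4)
  d <- matrix(c(0.2, 0.9), 1, 2)
  lr <- 0.37
  trained <- train_network(net, x, d, cycles = 1, learning_rate = lr,
                           momentum = 0, shuffle = FALSE)
  g <- net_gradient(net, x, d)
  expect_equal(trained$W1, net$W1 - lr * g$W1, tolerance = 1e-12)
  expect_equal(trained$b1, net$b1 - lr * g$b1, tolerance = 1e-12)
  expect_equal(trained$W2, net$W2 - lr * g$W2, tolerance = 1e-12)
  expect_equal(trained$b2, net$b2 - lr * g$b2, tolerance = 1e-12)
  expect_equal(attr(trained, "trace"),
               sse_error(d, net_forward(net, x)$output), tolerance = 1e-12)
})

test_that("hidden and output layers share the same layer math", {
  # a 1-1-1 net exercised at both layers: swapping which layer carries the
  # non-trivial weight must give symmetric results through the same sigmoid
  a <- init_network("1-1-1", seed = 1)
  a$W1[] <- 2; a$b1[] <- -1; a$W2[] <- 0; a$b2[] <- 0
  b <- init_network("1-1-1", seed = 1)
  b$W1[] <- 0; b$b1[] <- 0; b$W2[] <- 2; b$b2[] <- -1
  x <- 0.7
  ha <- net_forward(a, x)$hidden[1]
  expect_equal(ha, 1 / (1 + exp(-(2 * x - 1))), tolerance = 1e-12)
  yb <- net_forward(b, x)$output[1]
  expect_equal(yb, 1 / (1 + exp(-(2 * 0.5 - 1))), tolerance = 1e-12)
})

test_that("training is deterministic, trains the separable toy, and reduces error", {
  set.seed(4)
  x <- rbind(matrix(runif(100, 0, 0.35), 10, 10),
             matrix(runif(100, 0.65, 1), 10, 10))
  d <- matrix(c(rep(0, 10), rep(1, 10)), 20, 1)
  net <- init_network("10-5-1", seed = 2)
  t1 <- train_network(net, x, d, cycles = 2000)
  t2 <- train_network(net, x, d, cycles = 2000)
  expect_identical(t1$W1, t2$W1)
  expect_identical(t1$b2, t2$b2)
  pred <- decode_target(net_forward(t1, x)$output[, 1], c("lo", "hi"))
  expect_identical(pred, c(rep("lo", 10), rep("hi", 10)))  # training APS 100
  trace <- attr(t1, "trace")
  expect_lt(trace[length(trace)], trace[1])
  # zero cycles change nothing
  t0 <- train_network(net, x, d, cycles = 0)
  expect_identical(t0$W1, net$W1)
})

test_that("training input contracts are enforced", {
  net <- init_network("2-2-1", seed = 1)
  x <- matrix(runif(10), 5, 2)
  expect_error(train_network(net, x, matrix(2, 5, 1), 10), "\\[0, 1\\]")
  expect_error(train_network(net, x, matrix(0.5, 4, 1), 10), "row counts")
  expect_error(train_network(net, matrix(1, 5, 3), matrix(0.5, 5, 1), 10),
               "width")
})

test_that("predicted outputs decode to nearest codes", {
  net <- init_network("2-2-1", seed = 1)
  net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2[] <- -50
  # output ~ 0 -> first level regardless of codebook size
  p <- predict_classes(net, matrix(0.5, 3, 2),
                       list(harvest = factor_levels()$harvest))
  expect_identical(p$harvest, rep("October", 3))
  expect_identical(decode_target(0.02, factor_levels()$harvest), "October")
  expect_identical(decode_target(0.5, c("a", "b", "c")), "b")
  expect_error(predict_classes(net, matrix(0.5, 1, 2),
                               list(a = c("x", "y"), b = c("u", "v"))),
               "one codebook")
})

test_that("a saved network reloads to identical behaviour", {
  net <- init_network("4-3-2", seed = 12)
  rownames(net$W1) <- c("Glucose", "Lycopene", "P", "Na")
  x <- matrix(runif(20), 5, 4)
  d <- matrix(runif(10), 5, 2)
  net <- train_network(net, x, d, cycles = 50)
  f <- tempfile(fileext = ".json")
  write_network(net, f,
                scaling = list(min = c(a = 0, b = 0, c = 0, d = 0),
                               max = c(a = 1, b = 1, c = 1, d = 1)),
                codebooks = list(practice = factor_levels()$practice,
                                 harvest = factor_levels()$harvest[1:2]))
  back <- read_network(f)
  expect_equal(back$W1, net$W1, tolerance = 1e-12)
  expect_equal(net_forward(back, x)$output, net_forward(net, x)$output,
               tolerance = 1e-12)
  expect_identical(attr(back, "codebooks")$practice, factor_levels()$practice)
})
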