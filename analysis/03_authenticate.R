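#!/usr/bin/env Rscript
# Stage 3 — train the authentication networks.
#
# 151/16 stratified split, min-max input scaling on training ranges,
# then four model families as in the survey's protocol:
#   ANN_1  25 inputs, three outputs (harvest, practice, cultivar)
#   ANN_2  25 inputs, one output each
#   ANN_3  10 inputs (importance-reduced), three outputs
#   ANN_4  10 inputs, one output each
# The 25 -> 10 reduction averages the weight-sum importance shares of the
# ANN_1 net and the three ANN_2 nets. Writes the APS catalog, importance
# table, per-class success table and the reduced-model JSONs.

suppressPackageStartupMessages(library(tomauth))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
cohort <- read_cohort("results/cohort.csv")
targets3 <- c("harvest", "practice", "cultivar")
lv <- factor_levels()

split <- split_train_validation(cohort, n_validation = 16L, seed = seed)
write_split(split, "results/split.csv")
pars <- parameter_names(cohort)
sc <- scale_minmax(split$train[pars])
trx <- sc$x
vax <- scale_minmax(split$validation[pars], sc)$x

fit_one <- function(topology, targets, x_tr, x_va, cycles, seed,
                    plateau = FALSE, max_cycles = cycles) {
  codebooks <- lv[targets]
  ttr <- matrix(vapply(targets, function(v)
    encode_target(split$train[[v]], codebooks[[v]]), numeric(nrow(x_tr))),
    nrow = nrow(x_tr), dimnames = list(NULL, targets))
  net <- init_network(topology, seed)
  rownames(net$W1) <- colnames(x_tr)
  if (plateau) {
    monitor <- function(nn) {
      pr <- predict_classes(nn, x_tr, codebooks)
      mean(vapply(targets, function(v)
        aps(sum(pr[[v]] == as.character(split$train[[v]])), nrow(x_tr)),
        numeric(1)))
    }
    net <- train_until_plateau(net, x_tr, ttr, monitor, chunk = cycles,
                               max_cycles = max_cycles, seed = seed)
  } else {
    net <- train_network(net, x_tr, ttr, cycles, seed = seed)
  }
  rep <- evaluate_network(net, x_tr, split$train[, targets, drop = FALSE],
                          x_va, split$validation[, targets, drop = FALSE],
                          codebooks)
  list(net = net, report = rep, codebooks = codebooks)
}

catalog <- list(); per_class <- list(); id <- 0L
add <- function(type, topology, cycles, fit) {
  id <<- id + 1L
  a <- fit$report$aps
  catalog[[id]] <<- data.frame(model_id = id, type = type,
                               topology = topology, cycles = cycles,
                               output = a$output, aps_training = a$training,
                               aps_validation = a$validation,
                               aps_average = a$average)
  per_class[[id]] <<- cbind(model_id = id, fit$report$per_class)
  id
}

cat("training 25-input models...\n")
f1 <- fit_one("25-41-3", targets3, trx, vax, 2000L, seed + 11)
add("ANN_1", "25-41-3", 2000L, f1)
imps <- list(input_importance(f1$net))
topo2 <- c(harvest = "25-13-1", practice = "25-28-1", cultivar = "25-44-1")
for (v in targets3) {
  f <- fit_one(topo2[[v]], v, trx, vax, 2000L, seed + 20 + match(v, targets3))
  add("ANN_2", topo2[[v]], 2000L, f)
  imps[[length(imps) + 1]] <- input_importance(f$net)
}

keep <- reduce_inputs(imps, 10L)
cat("reduced inputs:", paste(keep, collapse = ", "), "\n")
avg_imp <- data.frame(
  input = imps[[1]]$input,
  mean_percent = rowMeans(vapply(imps, function(im)
    im$percent[match(imps[[1]]$input, im$input)], numeric(length(pars)))))
write.csv(avg_imp[order(-avg_imp$mean_percent), ],
          "results/importance.csv", row.names = FALSE)

rtr <- trx[, keep, drop = FALSE]
rva <- vax[, keep, drop = FALSE]

cat("training 10-input models...\n")
for (h in c(13L, 10L, 9L)) {
  f <- fit_one(sprintf("10-%d-3", h), targets3, rtr, rva, 1000L,
               seed + 40 + h, plateau = TRUE, max_cycles = 60000L)
  add("ANN_3", sprintf("10-%d-3", h), attr(f$net, "cycles_run"), f)
}
topo4 <- c(harvest = "10-18-1", practice = "10-8-1", cultivar = "10-20-1")
for (v in targets3) {
  f <- fit_one(topo4[[v]], v, rtr, rva, 1000L, seed + 60 + match(v, targets3))
  mid <- add("ANN_4", topo4[[v]], 1000L, f)
  write_network(f$net, sprintf("results/model_%02d.json", mid),
                scaling = list(min = sc$min[keep], max = sc$max[keep]),
                codebooks = f$codebooks)
}

catalog <- do.call(rbind, catalog)
write.csv(catalog, "results/aps.csv", row.names = FALSE)
write.csv(do.call(rbind, per_class), "results/per_class.csv",
          row.names = FALSE)
cat("catalog (validation APS):\n")
print(catalog[, c("type", "topology", "cycles", "output", "aps_validation")],
      row.names = FALSE)
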