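# Published summary of the motivating tomato survey: grand mean and SD of
# each chemical parameter (fresh-weight units), the p-value of every
# significant term of the three-way factorial GLM (blank = not significant,
# stored as NA), and the model's explained variance in percent. Term columns
# use the survey's shorthand: c = cultivar, h = harvest date, p = practice;
# interactions are colon-joined. A printed "0.000" means < 0.0005 and is
# stored as 0.

.survey_rows <- list(
  #    name                         unit          mean    sd     c      h      p      c:h    c:p    p:h    c:p:h   ev
  list("Fructose",                  "%",          1.28,   0.41,  NA,    0.012, 0.001, NA,    NA,    NA,    0.030,  47.6),
  list("Glucose",                   "%",          1.29,   0.41,  NA,    0.000, 0.000, 0.004, 0.033, NA,    NA,     56.7),
  list("Total fiber",               "%",          1.81,   0.56,  NA,    0.006, 0.008, 0.001, 0.027, 0.000, 0.003,  57.3),
  list("Protein",                   "%",          0.80,   0.15,  NA,    0.005, 0.018, NA,    NA,    NA,    NA,     36.2),
  list("Phenolic compound",         "mg/100g",   20.41,   4.30,  NA,    0.020, NA,    0.005, NA,    NA,    NA,     38.3),
  list("Lycopene",                  "mg/100g",    2.31,   0.72,  NA,    0.000, NA,    NA,    NA,    NA,    NA,     53.9),
  list("P",                         "mg/kg",    246,     61,     NA,    NA,    0.000, NA,    NA,    NA,    0.034,  50.3),
  list("Na",                        "mg/kg",     92.4,   63.4,   0.004, NA,    0.000, NA,    0.004, 0.018, NA,     58.8),
  list("K",                         "mg/kg",   2522,    512,     NA,    0.000, 0.015, NA,    NA,    NA,    NA,     52.2),
  list("Ca",                        "mg/kg",     67.5,   18.6,   0.010, 0.001, 0.000, 0.002, 0.000, 0.009, NA,     59.3),
  list("Mg",                        "mg/kg",    115,     22,     NA,    0.000, 0.000, NA,    NA,    NA,    0.038,  59.3),
  list("Fe",                        "mg/kg",      1.92,   0.05,  0.000, 0.020, NA,    0.040, 0.002, 0.000, NA,     53.3),
  list("Cu",                        "mg/kg",      0.30,   0.15,  NA,    0.000, 0.022, 0.017, NA,    NA,    NA,     50.4),
  list("Zn",                        "mg/kg",      0.77,   0.21,  NA,    0.045, 0.000, NA,    0.024, NA,    NA,     49.9),
  list("Mn",                        "mg/kg",      0.60,   0.21,  0.000, 0.008, 0.000, NA,    0.000, 0.032, NA,     69.8),
  list("Ascorbic acid",             "mg/100g",   15.3,    4.48,  NA,    NA,    NA,    NA,    0.035, NA,    NA,     37.8),
  list("Oxalic acid",               "mg/100g",   25.6,    9.3,   NA,    NA,    0.011, NA,    NA,    NA,    NA,     37.5),
  list("Pyruvic acid",              "mg/100g",    1.37,   0.77,  0.031, 0.001, NA,    0.000, 0.028, NA,    0.004,  59.8),
  list("Malic acid",                "mg/100g",   78.3,   40.2,   0.000, 0.000, 0.000, 0.001, 0.000, 0.002, 0.000,  75.0),
  list("Citric acid",               "mg/100g",  354,    121,     NA,    0.000, 0.043, 0.037, 0.013, NA,    NA,     48.2),
  list("Fumaric acid",              "mg/100g",    2.77,   1.22,  NA,    0.009, NA,    NA,    NA,    NA,    NA,     36.0),
  list("Chlorogenic acid",          "mg/100g",    0.59,   0.05,  NA,    0.000, NA,    0.027, NA,    0.030, NA,     50.7),
  list("Caffeic acid",              "mg/100g",    0.04,   0.01,  NA,    0.000, NA,    NA,    NA,    NA,    NA,     53.9),
  list("Ferulic acid",              "mg/100g",    0.09,   0.04,  0.032, 0.000, NA,    NA,    0.001, 0.022, NA,     57.2),
  list("p-Coumaric acid",           "mg/100g",    0.02,   0.03,  NA,    0.000, NA,    NA,    NA,    NA,    NA,     73.6)
)

#' Reference GLM summary of the motivating tomato survey
#'
#' Per-parameter grand mean and standard deviation on fresh weight, the
#' p-value of each significant term of the three-way factorial model
#' (cultivar, practice, harvest date and their interactions; `NA` where the
#' term was not significant at 0.05), and the explained variance of the full
#' model in percent. This matrix drives two things: the packaged defaults of
#' the synthetic cohort generator, and the worked predictor-selection example
#' for the GLM-AID tree (see [select_predictor()]).
#'
#' @return A data frame with 25 rows and columns `parameter`, `unit`,
#'   `mean`, `sd`, the seven term columns `c`, `h`, `p`, `c:h`, `c:p`,
#'   `p:h`, `c:p:h`, and `explained_variance`.
#' @export
#' @examples
#' ref <- reference_survey()
#' ref[ref$parameter == "p-Coumaric acid", c("h", "explained_variance")]
reference_survey <- function() {
  df <- do.call(rbind, lapply(.survey_rows, function(r) {
    data.frame(
      parameter = r[[1]], unit = r[[2]], mean = r[[3]], sd = r[[4]],
      c = r[[5]], h = r[[6]], p = r[[7]],
      `c:h` = r[[8]], `c:p` = r[[9]], `p:h` = r[[10]], `c:p:h` = r[[11]],
      explained_variance = r[[12]],
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }))
  rownames(df) <- NULL
  df
}

# Map between the survey's shorthand term labels and the factor-name labels
# used by the model-fitting code.
#' @noRd
term_label_map <- function() {
  c(
    "c" = "cultivar", "p" = "practice", "h" = "harvest",
    "c:p" = "cultivar:practice", "c:h" = "cultivar:harvest",
    "p:h" = "practice:harvest", "c:p:h" = "cultivar:practice:harvest"
  )
}

#' Reference survey as a list of GLM results
#'
#' Converts [reference_survey()] into the `glm_result` list format consumed
#' by [select_predictor()], so the tree's predictor-selection rule can be
#' exercised against the published term-significance matrix.
#'
#' @param drop character vector of parameter names to omit.
#' @return A list of `glm_result` objects in survey row order.
#' @export
reference_glm_results <- function(drop = character()) {
  ref <- reference_survey()
  ref <- ref[!ref$parameter %in% drop, , drop = FALSE]
  map <- term_label_map()
  lapply(seq_len(nrow(ref)), function(i) {
    row <- ref[i, ]
    p <- unlist(row[names(map)])
    names(p) <- unname(map)
    structure(
      list(
        parameter = row$parameter,
        p_values = p[!is.na(p)],
        explained_variance_pct = row$explained_variance,
        n = NA_integer_,
        terms_tested = unname(map)
      ),
      class = "glm_result"
    )
  })
}
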