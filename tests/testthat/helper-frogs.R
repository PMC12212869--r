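# canonical suite seed: fixed once for every stochastic fixture
SUITE_SEED <- 1L

# small hand-built cohort data frame; deliberately includes rows that the
# inclusion rules must reject
tiny_cohort_df <- function() {
  data.frame(
    id = paste0("r", 1:10),
    ga_days = c(280L, 275L, 268L, 150L, 290L, 259L, 245L, 280L, 266L, 281L),
    sex = c("male", "female", "male", "male", "female", "male", "female",
            NA, "male", "female"),
    birthweight_g = c(3500, 3200, 50, 3100, 9000, 3000, 2400, 3300, 2900, 3600),
    stillbirth = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                   FALSE, FALSE),
    neonatal_death = FALSE,
    stringsAsFactors = FALSE
  )
}

# deterministic bracket table covering weeks 38-40, male/female, labels 3..97
toy_bracket_table <- function() {
  grid <- expand.grid(week = 38:40, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    base <- 2500 + 100 * (grid$week[i] - 38) + ifelse(grid$sex[i] == "male", 50, 0)
    data.frame(week = grid$week[i], sex = grid$sex[i],
               centile_label = c(3, 10, 25, 50, 75, 90, 97),
               threshold_g = base + c(0, 150, 330, 530, 740, 930, 1100),
               stringsAsFactors = FALSE)
  }))
  bracket_table(rows)
}

# a null calibration cohort shared by the distribution tests (weights drawn
# exactly from the chart model, outcomes independent of size)
null_cohort <- local({
  cache <- NULL
  function(n = 50000L, seed = SUITE_SEED) {
    key <- paste(n, seed)
    if (is.null(cache) || attr(cache, "key") != key) {
      co <- generate_cohort(null_simulation_params(n, seed = seed))
      attr(co, "key") <- key
      cache <<- co
    }
    cache
  }
})
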