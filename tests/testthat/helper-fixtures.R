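# small in-code fixtures shared across test files

# tiny mixed-type table with known statistics
tiny_dataset <- function() {
  values <- data.frame(
    age = c(10, 20, 30, 40, NA, 60),
    hb  = c(1, 2, 3, NA, 5, 6),
    htn = c("yes", "yes", "no", NA, "yes", "no"),
    rbc = c("normal", "abnormal", "normal", "normal", NA, "abnormal"),
    stringsAsFactors = FALSE)
  col_meta <- data.frame(name = names(values),
                         kind = c("numeric", "numeric", "nominal", "nominal"),
                         stringsAsFactors = FALSE)
  col_meta$levels <- list(NULL, NULL, c("yes", "no"),
                          c("normal", "abnormal"))
  tabular_dataset(values, col_meta, labels = c(1, 1, 0, 1, 0, 0))
}

# m-column numeric-only dataset with controllable per-row missing counts
wide_dataset <- function(n = 4, m = 24, missing_per_row = rep(0, n)) {
  values <- as.data.frame(matrix(1, n, m))
  names(values) <- sprintf("f%02d", seq_len(m))
  for (i in seq_len(n))
    if (missing_per_row[i] > 0)
      values[i, seq_len(missing_per_row[i])] <- NA
  col_meta <- data.frame(name = names(values), kind = "numeric",
                         stringsAsFactors = FALSE)
  col_meta$levels <- vector("list", m)
  tabular_dataset(values, col_meta, labels = rep(c(0, 1), length.out = n))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# reduced-size nested-CV configuration used by pipeline-level tests
fast_pipeline_config <- function(seed = 1, tune = FALSE) {
  pipeline_config(
    fs = fs_config(n_agents = 8, max_iter = 15, seed = seed),
    eho = eho_config(n_clans = 2, clan_size = 3, max_iter = 2, seed = seed),
    train = train_config(epochs = 10, finetune_epochs = 60, patience = 10,
                         learning_rate = 0.05, seed = seed),
    tune_train = train_config(epochs = 5, finetune_epochs = 40,
                              patience = 8, seed = seed),
    tune = tune)
}
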