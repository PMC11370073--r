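# Shared fixtures, built once per test run.

# Small labelled corpus and a forest trained on it: 6 children, 5-minute
# sessions (120 windows).
small_corpus <- simulate_annotated_corpus(
  n_subjects = 6, session_s = 300, seed = 11
)
small_model <- train_activity_model(small_corpus, n_trees = 150, seed = 11)

# Feature rows for windows simulated from a given class.
class_feature_rows <- function(class_label, n, seed_base = 500,
                               params = default_class_params()) {
  purrr::map_dfr(seq_len(n), function(i) {
    d <- simulate_window_signal(params[[class_label]], 15, 30, seed = seed_base + i)
    tibble::as_tibble(as.list(window_features(vector_magnitude(d), 30)))
  })
}
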