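# Shared fixtures for the test suite. The desk-scale benchmark (dataset,
# region split, trained models) is expensive, so everything is memoised in a
# session-level environment: each artifact is built once, on first use, and
# reused by later tests. All seeds are fixed, so the artifacts are
# reproducible.

.bench <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (is.null(.bench[[key]])) .bench[[key]] <- force(value)
  .bench[[key]]
}

bench_dataset <- function() memo("dataset", build_dataset(profile = "desk", seed = 1))

bench_split <- function() {
  memo("split", split_rois(unique(bench_dataset()$manifest$roi_id),
                           n_test = 2, n_val = 2, seed = 1))
}

# desk-scale training runs shared across tests; `key` selects the variant
bench_model <- function(key = c("two_path", "five_path", "five_path_aux",
                                "five_path_te")) {
  key <- match.arg(key)
  memo(paste0("model_", key), {
    ds <- bench_dataset()
    sp <- bench_split()
    tc <- desk_train_config(seed = 11)
    switch(key,
      two_path = train_model(
        build_model("two_path_3d", desk_model_config(), seed = 11),
        ds, sp, tc, augment = random_flip_sequence),
      five_path = train_model(
        build_model("five_path_4d", desk_model_config(), seed = 11),
        ds, sp, tc, augment = random_flip_sequence),
      five_path_aux = train_model(
        build_model("five_path_4d", desk_model_config(aux_outputs = TRUE),
                    seed = 11),
        ds, sp, tc, w_n1 = 0.75, w_n2 = 0.75,
        augment = random_flip_sequence),
      five_path_te = train_model(
        build_model("five_path_4d", desk_model_config(), seed = 11),
        ds, sp, tc,
        augment = function(s) random_flip_sequence(distort_sequence(s, 0.5, 2L))))
  })
}

bench_report <- function(key = c("two_path", "five_path")) {
  key <- match.arg(key)
  memo(paste0("report_", key),
       evaluate_model(bench_model(key), bench_dataset(), bench_split()$test))
}

# a tiny phantom + a handful of sequences for fast unit tests
tiny_dataset <- function() memo("tiny_dataset",
                                build_dataset(n_rois = 3, n_patterns = 2, seed = 7))

tiny_config <- function(aux_outputs = FALSE) {
  model_config(initial_channels = c(2L, 2L, 4L), growth_rate = 2L,
               path_pool = 2L, aux_outputs = aux_outputs)
}
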