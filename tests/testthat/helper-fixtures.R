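# Small shared pipeline fixture, built once per test run: six template
# phantoms, the library cropped from them, and a trained classifier.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tds <- sample_phantom_dataset(c(normal = 2, mild = 2, moderate = 2),
                                    seed = 501)
      lib <- build_templates(tds$phantoms)
      clf <- train_poi_classifier(dataset_landmarks(tds),
                                  lapply(tds$phantoms, `[[`, "image"))
      cache <<- list(tds = tds, lib = lib, clf = clf)
    }
    cache
  }
})

# a 100x100 patch with smooth structure (deterministic)
structured_patch <- function(phase = 0) {
  g <- outer(seq_len(100), seq_len(100),
             function(y, x) 120 + 60 * sin(x / 9 + phase) * cos(y / 13))
  pmin(pmax(g, 0), 255)
}
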