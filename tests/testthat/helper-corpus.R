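# Memoized shared fixtures: built once per test run, in code.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small labeled population + trained classifier shared by the classifier
# module tests (the acceptance test builds its own full-size corpus)
small_trained <- function() {
  fixture("small_trained", function() {
    pop_tr <- simulate_population(synthetic_config(n_larvae = 40, duration = 60,
                                                   seed = 101))
    pop_te <- simulate_population(synthetic_config(n_larvae = 12, duration = 60,
                                                   seed = 202))
    ctr <- labeled_corpus(pop_tr)
    cte <- labeled_corpus(pop_te)
    models <- suppressWarnings(train_pipeline(ctr, classifier_config(seed = 5)))
    list(train = ctr, test = cte, models = models)
  })
}
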