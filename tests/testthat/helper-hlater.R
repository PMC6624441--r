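# Shared builders for small fitted objects. Heavy fits are cached per
# test run so several test files can reuse them.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fit_cache)
  get(key, envir = .fit_cache, inherits = FALSE)
}

# hand-built trial table on a full 2x2 design
toy_trials <- function(n_per_cell = 3, persons = c("A", "B"),
                       rt = 0.3) {
  grid <- expand.grid(person_id = persons,
                      session = c("smoke_as_usual", "abstinent"),
                      trial_type = c("neutral", "reward"),
                      rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  grid$rt <- rep_len(rt, nrow(grid))
  grid[c("person_id", "session", "trial_type", "rt")]
}

quick_sampler <- function(chains = 3L, iter = 500L, warmup = 250L,
                          seed = 1L, ...) {
  later_sampler(chains = chains, iter = iter, warmup = warmup,
                seed = seed, ...)
}

# small exact-model (unwindowed) study and fit shared across files
small_study <- function() {
  cached("small_study",
         simulate_study(seed = 42, design = study_design(
           n_persons = 6, runs_per_session = 1), window = FALSE))
}

small_fit <- function() {
  cached("small_fit",
         later_fit(small_study()$data,
                   sampler = quick_sampler(chains = 3, iter = 600,
                                           warmup = 300, seed = 9)))
}

# minimal later_fit wrapper around a bare draw array, for summary tests
fake_fit <- function(draws_by_chain, parameter = "x") {
  k <- length(draws_by_chain[[1L]])
  arr <- array(unlist(draws_by_chain), c(k, length(draws_by_chain), 1L),
               dimnames = list(NULL, NULL, parameter))
  structure(list(draws = arr, model = later_model()), class = "later_fit")
}
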