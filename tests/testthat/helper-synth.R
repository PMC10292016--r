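# shared fixtures, built once per test run

# small noisy benchmark reused across pipeline tests
small_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_benchmark(n_subjects = 6, seed = 42)
    cache
  }
})

# one clean record per morphology case
clean_record <- local({
  cache <- list()
  function(case) {
    if (is.null(cache[[case]]))
      cache[[case]] <<- simulate_record(params = case_params(case))
    cache[[case]]
  }
})

expect_ppg_error <- function(expr, class) {
  expect_error(expr, class = class)
}
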