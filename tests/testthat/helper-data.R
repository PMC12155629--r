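# default synthetic dataset, generated once per test run
.default_data_cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (!exists("d", envir = .default_data_cache)) {
    assign("d", generate_synth_data(synth_config(seed = 1)),
           envir = .default_data_cache)
  }
  get("d", envir = .default_data_cache)
}
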