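# shared fixture builders

demo_path <- function(file) {
  system.file("extdata", file, package = "psdrisk", mustWork = TRUE)
}

demo_compounds <- function() {
  read_compound_table(demo_path("demo_compounds_synthetic.csv"))
}

demo_measurements <- function() {
  read_measurements(demo_path("demo_measurements_synthetic.csv"))
}

# minimal hand-built measurement tibble
make_measurements <- function(compound_id, matrix, value,
                              timepoint = "2021-07", replicate = 1L,
                              censor = "quantified") {
  validate_measurements(tibble::tibble(
    compound_id = compound_id, matrix = matrix, timepoint = timepoint,
    replicate = as.integer(replicate), value = value, censor = censor
  ))
}
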