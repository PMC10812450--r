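# Small in-code fixtures shared across tests.

# Minimal conditions frame covering every factor, built programmatically.
tiny_conditions <- function(n = 8L) {
  data.frame(
    sample_id = sprintf("T-%02d", seq_len(n)),
    area = rep(c("Guariba", "Valparaiso"), length.out = n),
    collection_date = as.Date("2020-06-04") + rep(c(0, 40, 80, 120),
                                                  length.out = n),
    variety = rep(c("CTC4", "CU0618", "RB966928", "SP813250"),
                  length.out = n),
    infection_class = rep(c("high", "low"), length.out = n),
    infection_level = rep(c(7.5, 2.0), length.out = n),
    harvest_number = rep(c(1L, 3L, 5L, 7L), length.out = n),
    stringsAsFactors = FALSE
  )
}

with_seed_noise <- function(seed, n) strawpoly:::with_seed(seed, rnorm(n))

# Study data loaded once per test file run.
study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- strawpoly::load_study_data()
    cache
  }
})
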