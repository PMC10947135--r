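# shared objects; built once per test run
CO <- dgp_coefficients()

# moderate complete panel reused by several tests
P2E4 <- generate_complete_panel(scenario_spec("monotone", "low", n = 20000),
                                CO, seed = 424242)

# a coefficient set with all treatment-assignment slopes zeroed
# (treatment effectively randomized; unweighted analysis unbiased)
co_unconfounded <- function() {
  co <- CO
  co$a$lag <- 0; co$a$x <- 0; co$a$y_lag <- 0; co$a$b_bin <- 0; co$a$b_cont <- 0
  co
}

# a coefficient set with zero treatment effect everywhere
co_null_effect <- function() {
  co <- CO
  co$y$a <- 0; co$y$a_lag <- 0; co$x$a_lag <- 0
  co
}

# build a treatment_models stub with constant probabilities
stub_treatment_models <- function(p_den, p_num, visits = 1:4) {
  structure(list(den = c(logit(p_den), rep(0, 5 + length(visits) - 1)),
                 num = c(logit(p_num), rep(0, 3 + length(visits) - 1)),
                 bz_center = 0, bz_scale = 1, visits = visits),
            class = "treatment_models")
}

logit <- function(p) log(p / (1 - p))
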