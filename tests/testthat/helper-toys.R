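# Small validation systems built through the documented extension point.

# dX*/dt = k1 s(t) - k2 X*, X*(0) = 0: output integral is exactly linear
# in k1, and has a closed form in k2 under constant signal.
toy_linear_model <- function(k1 = 2, k2 = 0.1) {
  define_hub_model("toy", "Xa", 0, list(
    list(label = "prod", type = "zero_order_signal", to = "Xa",
         k_name = "k1", k_value = k1),
    list(label = "deg", type = "mass_action", from = "Xa",
         substrate = "Xa", k_name = "k2", k_value = k2)),
    output = "Xa")
}

# Ornstein-Uhlenbeck: dX = -k X dt + sigma dW, realised as a signed linear
# drift reaction (noise off) plus a diffusion-only reaction with
# propensity sigma^2 (drift off), so sqrt(a) dW = sigma dW.
ou_model <- function(k = 0.2, sigma = 0.5, x0 = 3) {
  define_hub_model("OU", "X", x0, list(
    list(label = "decay", type = "linear", from = "X", substrate = "X",
         k_name = "k", k_value = k, noise = FALSE),
    list(label = "noise", type = "zero_order", to = "X",
         k_name = "s2", k_value = sigma^2, drift = FALSE)),
    output = "X")
}

# an M1 parameter set (log coordinates) with a near-zero Michaelis constant
# whose stiffness exhausts moderate solver step budgets
failing_m1_logp <- c(1.372902807779610, -13.346467353403568,
                     -12.582168448716402)

# small shared M1 control ensemble for unit tests (built once per session)
unit_control_m1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_control_data(hub_model("M1"), n_replicates = 50,
                                      seed = 7)
    cache
  }
})

# hand-made sensitivity table for the trend statistics unit tests
synthetic_sens_table <- function(df, model_id = "TEST") {
  structure(df, class = c("sensitivity_table", "data.frame"),
            model_id = model_id, reactions = unique(df$reaction))
}
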