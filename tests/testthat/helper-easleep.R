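# Shared fixtures: the model's standard parameter sets and the worked
# rate sets printed in the supplementary Poincare-map panels.

std_params <- function(...) ea_params(...)

wake_params <- function() {
  # continuous wakefulness, all four rates 0.5
  ea_params(TST_h = 0, r_Ww = 0.5, r_Bw = 0.5, r_Ws = 0.5, r_Bs = 0.5)
}

# supplementary panel parameter lists (TST = 8 h, r_Ww = 0.5 throughout)
s2_rates <- list(
  B = list(r_Bw = 0,       r_Ws = 0.21,    r_Bs = 0.14),    # no fixed point
  C = list(r_Bw = 0.20079, r_Ws = 0.15378, r_Bs = 0.33678), # cycle onset
  D = list(r_Bw = 0.3,     r_Ws = 0.126,   r_Bs = 0.434)    # two fixed points
)

s2_params <- function(panel) {
  r <- s2_rates[[panel]]
  ea_params(TST_h = 8, r_Ww = 0.5, r_Bw = r$r_Bw, r_Ws = r$r_Ws, r_Bs = r$r_Bs)
}

# random valid parameter set for property-style loops
random_params <- function() {
  m_C <- runif(1, 2, 7)
  ea_params(
    p_W = runif(1, 0.5, 2), p_B1 = runif(1, 0.2, 1.5),
    m_C = m_C, A = runif(1, 0, 0.9) * m_C,
    TST_h = runif(1, 0, 16),
    r_Ww = runif(1, 0.2, 1), r_Bw = runif(1, 0.2, 1),
    r_Ws = runif(1, 0.05, 1), r_Bs = runif(1, 0.05, 1)
  )
}
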