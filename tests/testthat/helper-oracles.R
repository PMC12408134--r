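# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# weighted least squares by explicit 2x2 normal equations:
# minimize sum w_i (y_i - a - b x_i)^2
wls_normal_equations <- function(x, y, w) {
  sw <- sum(w)
  sx <- sum(w * x)
  sy <- sum(w * y)
  sxx <- sum(w * x^2)
  sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  b <- (sw * sxy - sx * sy) / det
  a <- (sy * sxx - sx * sxy) / det
  c(intercept = a, slope = b)
}

# amount bookkeeping: total amount in the insert divided by the plasma
# volume equals the original total plasma concentration
amount_bookkeeping_total <- function(c_plasma, c_buffer, vp = 200, vb = 333) {
  (c_plasma * vp + c_buffer * vb) / vp
}

# closed-form free/total concentration ratio (per original plasma volume)
# for linear binding at dialysis equilibrium
free_total_ratio_closed_form <- function(fu, vp = 200, vb = 333) {
  f <- vp * fu / (vp + fu * vb)       # buffer conc per unit total
  f * (vp + vb) / vp                  # free per original plasma volume
}
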