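# Shared fixtures: the published profile/muscle constants and small oracles.

paper_profile <- function() acsa_profile(d_offset = 23, b_width = 0.48,
                                         c_peak = 7.3)

bic <- function() muscle_preset("BIC")
bra <- function() muscle_preset("BRA")

# independent central finite-difference derivative
fd_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# 2-decimal rounding as used for published table cells
round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
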