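# shared fixtures: the cavity case-study configuration and small helpers

table1_light <- function(L = 0.02) light_field(L = L, Ot = 8 * log(2), u_av = 1)

# closed-form steady activated fraction (leading order in q5)
yA_ss <- function(u, q2 = 0.3) (u / q2) / (u^2 + u / q2 + 1)
yB_ss <- function(u, q2 = 0.3) u^2 / (u^2 + u / q2 + 1)

# depth-averaged steady yA for a light field, by fine quadrature of the
# closed forms (the unmixed-culture performance oracle)
unmixed_steady_J <- function(light, q2 = 0.3, n = 8001) {
  z <- seq(0, light$L, length.out = n)
  u <- irradiance_at(light, z)
  w <- rep(1, n); w[c(1, n)] <- 0.5          # trapezoid
  sum(w * yA_ss(u, q2)) / sum(w)
}

# square-wave normalized-irradiance signal (light:dark cycling)
square_signal <- function(u_light, u_dark, period, duty = 0.5) {
  function(t) ifelse((t %% period) < duty * period, u_light, u_dark)
}

make_history <- function(t, u) {
  structure(data.frame(t = t, u = u),
            class = c("irradiance_history", "data.frame"))
}

zero_flow <- function(grid) solve_cavity(0, grid)
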