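# shared helpers: grids and independent quadrature oracles

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

fine_log_grid <- function(lo = 0.5, hi = 15, n = 90)
  exp(seq(log(lo), log(hi), length.out = n))

# printed low-energy grid of the recommended table (below the
# pseudo-resonance cutoff region)
coarse_low_grid <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 1.0, 1.5, 2.0,
                     3.0, 4.0, 5.0, 7.0, 10)

# independent solid-angle quadrature of a DCS over [th_lo, th_hi] degrees
quad_dcs <- function(dcs, th_lo = 0, th_hi = 180, ...) {
  2 * pi * stats::integrate(function(th) dcs(th * 180 / pi) * sin(th),
                            th_lo * pi / 180, th_hi * pi / 180,
                            rel.tol = 1e-11, ...)$value
}
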