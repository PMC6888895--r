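# shared fixtures and independent oracles

# cylinder lake: constant area A down to zmax
cylinder_hypsometry <- function(area = 1e6, zmax = 20) {
  data.frame(depth_m = 0:zmax, area_m2 = rep(area, zmax + 1))
}

# independent explicit diffusion oracle (constant area, plain FTCS with
# insulated boundaries); deliberately distinct from the package's
# conservative simulator
ftcs_diffuse <- function(temp, kz, dz, dt_s, n_steps) {
  n <- length(temp)
  for (s in seq_len(n_steps)) {
    lap <- c(temp[2] - temp[1],
             temp[-c(1, 2)] - 2 * temp[-c(1, n)] + temp[-c(n - 1, n)],
             temp[n - 1] - temp[n])
    temp <- temp + kz * dt_s / dz^2 * lap
  }
  temp
}

# per-volume closure written independently of the package internals
pnet_by_hand <- function(fs, fl, fz, alpha) (fs - fl - fz) / (1 - alpha)
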