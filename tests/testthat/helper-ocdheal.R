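# shared fixtures: everything is generated in code at test time

default_geom <- function() build_condyle_geometry()

small_grid <- function(mode = "marrow_invasion", fs = matrix(0, 40, 40)) {
  initialize_grid(mode, fs = fs, source = lattice_source_mask())
}

# independent explicit finite-difference diffusion oracle on the cell lattice
# (cell-centred 5-point stencil, harmonic face diffusivities, no-flux edges)
fd_diffuse <- function(N, D, h = 0.125, dt = 1, nsub = 2000) {
  dts <- dt / nsub
  nz <- nrow(N); nr <- ncol(N)
  harm <- function(a, b) 2 * a * b / pmax(a + b, 1e-300)
  for (s in seq_len(nsub)) {
    fz <- matrix(0, nz + 1, nr)   # fluxes across horizontal faces
    Df <- harm(D[-1, ], D[-nz, ])
    fz[2:nz, ] <- -Df * (N[-1, ] - N[-nz, ]) / h
    fr <- matrix(0, nz, nr + 1)
    Dfr <- harm(D[, -1], D[, -nr])
    fr[, 2:nr] <- -Dfr * (N[, -1] - N[, -nr]) / h
    N <- N - dts / h * (fz[-1, ] - fz[-(nz + 1), ] + fr[, -1] - fr[, -(nr + 1)])
  }
  N
}

# closed-form one-day recursion for a single cell under a constant fate,
# mirroring the documented intra-day ordering (no diffusion, non-source cell)
cell_recursion <- function(msc, ph, days, cap = 100,
                           diff = 0.05, mit = 0.05, prol = 0.15) {
  for (d in seq_len(days)) {
    dn <- diff * msc
    msc <- msc - dn; ph <- ph + dn
    ph <- min(ph * (1 + mit), cap)
    msc <- min(msc * (1 + prol), max(cap - ph, 0))
  }
  c(msc = msc, ph = ph)
}

terzaghi_series <- function(zH, Tv, nterm = 200) {
  s <- 0
  for (m in 0:nterm) {
    M <- pi * (2 * m + 1) / 2
    s <- s + 2 / M * sin(M * zH) * exp(-M^2 * Tv)
  }
  s
}
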