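# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_phantom <- function() fixture("phantom48", function() {
  make_phantom(c(48, 48, 48))
})

small_fields <- function() fixture("fields48", function() {
  make_fields(c(48, 48, 48), amplitude = 0.2, smoothness_mm = 40, seed = 7,
              mask = small_phantom()$brain_mask)
})

flat_fields <- function() fixture("flat48", function() {
  make_fields(c(48, 48, 48), amplitude = 0)
})

# Noiseless acquisition with inhomogeneous fields.
noiseless_acq <- function() fixture("acq0", function() {
  simulate_protocol(small_phantom(), small_fields(),
                    default_protocol(noise_sd = 0), seed = 1)
})

# SNR-50 acquisition (default study noise).
noisy_acq <- function() fixture("acq_snr50", function() {
  simulate_protocol(small_phantom(), small_fields(),
                    default_protocol(noise_sd = 0.02), seed = 21)
})

noiseless_chain <- function() fixture("chain0", function() {
  map_water(noiseless_acq(), small_phantom()$ventricle_mask)
})

noisy_chain <- function() fixture("chain_snr50", function() {
  map_water(noisy_acq(), small_phantom()$ventricle_mask)
})

# Independent oracle: spoiled-GRE saturation factor, written out directly.
oracle_sat <- function(tr, fa_deg, t1) {
  a <- fa_deg * pi / 180
  e1 <- exp(-tr / t1)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# Independent oracle for the B1+ fit: 1-D minimization of the residual sum
# of squares over b with the amplitude profiled out by lm().
oracle_b1_fit <- function(signal, angles_deg, interval = c(0.3, 1.7)) {
  rss <- function(b) {
    x <- sin(b * angles_deg * pi / 180)
    sum(resid(lm(signal ~ x + 0))^2)
  }
  optimize(rss, interval, tol = 1e-10)$minimum
}

# Independent oracle for the exact Wilcoxon rank-sum p-value: enumerate all
# group assignments of the pooled sample.
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- nx * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
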