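# shared fixtures: protocol TIs and a one-call noiseless subject simulator

PROTOCOL_TIS <- c(0.2, 0.75, 1.5, 2.75, 4.0, 6.5)

sim_subject <- function(f = 24, cbf = 283, ventricle_volume = 3.75,
                        noise_sd = 0, seed = 1L, alpha = 1,
                        spec_args = list()) {
  sp <- do.call(phantom_spec, c(list(f_bcsfb_true = f, cbf_true = cbf,
                                     ventricle_volume = ventricle_volume),
                                spec_args))
  ph <- make_phantom(sp, seed = seed)
  list(
    phantom = ph,
    bbb = simulate_acquisition(ph, asl_protocol(noise_sd = noise_sd,
                                                alpha = alpha), seed = seed),
    bcsfb = simulate_acquisition(ph, bcsfb_protocol(noise_sd = noise_sd,
                                                    alpha = alpha),
                                 seed = seed + 1L),
    rois = phantom_rois(ph)
  )
}

quantify_sim <- function(s, ...) {
  quantify_subject(s$bbb, s$bcsfb, s$rois$cortex, s$rois$ventricle, ...)
}

# random valid kinetic parameter draw for property tests
random_kinetic <- function() {
  kinetic_params(
    f = stats::runif(1, 1e-4, 0.05),
    delta = stats::runif(1, 0, 2),
    tau = stats::runif(1, 0.5, 6),
    alpha = stats::runif(1, 0.3, 1),
    phi = stats::runif(1, 0.8, 1.2),
    r1app = stats::runif(1, 0.1, 1.2),
    r1a = stats::runif(1, 0.2, 0.8),
    m0 = stats::runif(1, 0.5, 200)
  )
}
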