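# Small parameter sets used across tests; sizes chosen so whole-suite
# runtime stays modest while statistics remain meaningful.

# decoupled network: zero means, optional gain/noise
decoupled_params <- function(N_E = 60, N_I = 40, g = 0, sigma = 0.8,
                             eta_E = 0, eta_I = 0,
                             transfer = transfer_spec("atan")) {
  ei_params(N_E = N_E, N_I = N_I, m_EE = 0, m_EI = 0, m_IE = 0, m_II = 0,
            g = g, eta_E = eta_E, eta_I = eta_I, sigma = sigma,
            transfer = transfer)
}

# baseline preset scaled down but preserving N_E eta_E = N_I eta_I
small_fig2a <- function(...) ei_preset("fig2a", N_E = 600, N_I = 400, ...)

small_fig3b <- function(...) ei_preset("fig3b", N_E = 600, N_I = 400, ...)
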