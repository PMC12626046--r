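# Shared fixtures: default grids, presets, and small builders used
# across the suite. Everything is generated in code; no stored data.

default_geom <- probe_geometry()
default_spec <- forward_model_spec()
p785_healthy <- healthy_muscle_preset(785)

# noiseless Gaussian IRF on the default grid
fixture_irf <- gaussian_irf(default_spec, noise = FALSE)

# a vot_trace data.frame from raw channel vectors
make_trace <- function(t, sto2, bfi = sto2 * 1e-10, cuff = NULL,
                       markers = NULL) {
  tr <- data.frame(t = t, sto2 = sto2, bfi = bfi)
  if (!is.null(cuff)) tr$cuff_pressure <- cuff
  if (!is.null(markers)) attr(tr, "markers") <- markers
  class(tr) <- c("vot_trace", "data.frame")
  tr
}

# noiseless QP table with one segment per laser-state combo at the
# given mean levels (constant within segments; 10 s each)
make_qp <- function(dcs_dark = 1, dcs_signal = 50, dcs_crosstalk = 1.5,
                    td_signal = 1e6, td_dark = 1e4, td_crosstalk = 1.5e4,
                    oxi_valid = TRUE, segment_s = 10) {
  combos <- data.frame(dcs = c("off", "on", "off", "on"),
                       td = c("off", "off", "on", "on"))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    dcs <- combos$dcs[i]; td <- combos$td[i]
    dcs_level <- if (dcs == "on") dcs_signal else
      if (td == "on") dcs_crosstalk else dcs_dark
    td_level <- if (td == "on") td_signal else
      if (dcs == "on") td_crosstalk else td_dark
    data.frame(timestamp = (i - 1) * segment_s + seq_len(segment_s) - 1,
               segment = i, dcs_laser = dcs, tdnirs_laser = td,
               dcs_khz = dcs_level, tdnirs_685_cps = td_level,
               tdnirs_828_cps = td_level, oxi_valid = oxi_valid)
  })
  do.call(rbind, rows)
}
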