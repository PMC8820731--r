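# shared fixtures: representative parameter sets and small builders

p_second <- representative_params("second_order")
p_first <- representative_params("first_order")

# a plain single-cell design for targeted simulations
flat_design <- function(n, delay_ms, noise) {
  tibble::tibble(participant = "S01", block = 1L, trial = seq_len(n),
                 noise = noise, delay_ms = delay_ms, joa = NA_integer_,
                 rt_s = NA_real_, error_flag = FALSE)
}

# interior boundaries (finite gammas) for one noise condition
interior <- function(params, noise, ...) {
  pos <- place_criteria(params, noise, ...)$position_s
  pos[is.finite(pos)]
}
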