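# Shared fixtures: reference parameter records as lists keyed by
# adsorbent/temperature, built from the package's embedded tables.

ref_params_list <- function() {
  ref <- ref_slmrg_params()
  out <- lapply(seq_len(nrow(ref)), function(i)
    list(adsorbent = ref$adsorbent[i], temperature = ref$temperature[i],
         params = slmrg_params(ref$n[i], ref$nm[i], ref$a[i], ref$b[i],
                               ref$w[i]),
         qsat = ref$qsat[i]))
  names(out) <- paste0(ref$adsorbent, "_", ref$temperature)
  out
}

param_vec <- function(p) unlist(unclass(p))[c("n", "nm", "a", "b", "w")]
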