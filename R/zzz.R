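.datatable.aware <- TRUE

utils::globalVariables(c(
  "d", "scl", "w", "Is", "half", "img_pos", "n_half1", "n_half2",
  "I_half", "n_half", ".N"))
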