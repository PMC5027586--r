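# quiet R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", ".I", ".N", "p", "z", "p_adj", "enh_id", "feature_id", "class",
  "gap", "left"))
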