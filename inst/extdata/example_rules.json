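{
  "comment": "Illustrative CNA-profile rule set (synthetic; not the published classifier). First match wins.",
  "rules": [
    { "if": { "*": "NORMAL" }, "then": "GR" },
    { "if": { "IKZF1": "LOSS_DELETION" }, "then": "PR" },
    { "if": { "EBF1": "LOSS_DELETION", "PAX5": "LOSS_DELETION" }, "then": "PR" },
    { "if": { "ETV6": "LOSS_DELETION", "BTG1": "NORMAL" }, "then": "GR" }
  ],
  "default": "IR"
}
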