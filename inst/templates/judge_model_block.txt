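Model {index}:
Verdict: {verdict}
Explanation: {explanation}
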