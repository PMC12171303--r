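Example {index}:
Drug 1: {name_a} (SMILES: {smiles_a})
Drug 2: {name_b} (SMILES: {smiles_b})
Known interaction: {label}
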