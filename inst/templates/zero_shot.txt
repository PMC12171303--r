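## Input requirements
You are given two drugs, each identified by name and SMILES structure.
Drug 1: {name_a} (SMILES: {smiles_a})
Drug 2: {name_b} (SMILES: {smiles_b})

## Prediction task
Predict whether a drug-drug interaction exists between Drug 1 and Drug 2.
Answer with a single verdict, "yes" or "no", followed by a brief explanation
of your reasoning.

## Consideration factors
Consider the pharmacodynamics of both drugs, their metabolic pathways
(including shared cytochrome P450 enzymes), receptor interactions, and
relevant clinical data such as FDA labels and peer-reviewed literature.
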